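#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centered
#' (`-1/2 * J %*% D^2 %*% J` with `J` the centering projector), the Gram
#' matrix is eigendecomposed, and coordinates are the eigenvectors scaled by
#' the square roots of their (positive) eigenvalues. Negative eigenvalues --
#' which arise when the input is not Euclidean, as is typical for Jaccard
#' distances -- are reported but excluded from the variance fractions, so
#' the fraction for axis `i` is `lambda_i / sum(positive lambda)`.
#'
#' @param D a [pcm_dist()] or symmetric numeric matrix with zero diagonal.
#' @param n_axes number of axes to retain (capped at the number of positive
#'   eigenvalues, with a message when fewer exist).
#' @return an object of class `pcm_pcoa`: list with `coordinates` (taxa x
#'   axes), `eigenvalues` (all, descending), `variance_fractions` (over
#'   positive eigenvalues), `n_positive`.
#' @examples
#' d <- as.matrix(dist(cbind(c(0, 3, 0), c(0, 0, 4))))
#' rownames(d) <- colnames(d) <- c("A", "B", "C")
#' p <- pcoa(d)
#' round(p$variance_fractions, 3)
#' @export
pcoa <- function(D, n_axes = 2L) {
  v <- .dist_values(D)
  if (anyNA(v[lower.tri(v)])) stop("undefined distances present")
  n <- nrow(v)
  G <- -0.5 * v^2
  # sequential row/column sweeps yield G - r_i - c_j + g, i.e. -1/2 J D2 J
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))
  G <- (G + t(G)) / 2 # symmetrize against rounding
  eig <- eigen(G, symmetric = TRUE)
  pos <- which(eig$values > 1e-9 * max(abs(eig$values), 1))
  n_pos <- length(pos)
  keep <- seq_len(min(n_axes, n_pos))
  if (n_pos < n_axes) {
    message(sprintf("only %d positive eigenvalue(s); returning %d axes",
                    n_pos, n_pos))
  }
  coords <- eig$vectors[, pos[keep], drop = FALSE] %*%
    diag(sqrt(eig$values[pos[keep]]), length(keep))
  dimnames(coords) <- list(rownames(v), paste0("Axis", keep))
  structure(
    list(coordinates = coords,
         eigenvalues = eig$values,
         variance_fractions = eig$values[pos] / sum(eig$values[pos]),
         n_positive = n_pos),
    class = "pcm_pcoa"
  )
}

#' @export
print.pcm_pcoa <- function(x, ...) {
  k <- min(4L, x$n_positive)
  cat(sprintf("PCoA of %d taxa: %d positive eigenvalues\n",
              nrow(x$coordinates), x$n_positive))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("axis %d: %.0f%%", seq_len(k),
                            100 * x$variance_fractions[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.pcm_pcoa <- function(x, axes = c(1L, 2L), labels = TRUE, ...) {
  co <- x$coordinates
  if (ncol(co) < max(axes)) stop("requested axes not retained")
  graphics::plot(co[, axes[1L]], co[, axes[2L]],
                 xlab = sprintf("Axis %d (%.0f%%)", axes[1L],
                                100 * x$variance_fractions[axes[1L]]),
                 ylab = sprintf("Axis %d (%.0f%%)", axes[2L],
                                100 * x$variance_fractions[axes[2L]]),
                 pch = 19, ...)
  if (labels) {
    graphics::text(co[, axes[1L]], co[, axes[2L]], rownames(co),
                   pos = 3, cex = 0.6)
  }
  invisible(x)
}

#' Leaf ordering induced by hierarchical clustering
#'
#' The tip order of the UPGMA tree, with subtrees rotated so that at every
#' node the subtree containing the lexicographically smallest label comes
#' first. Deterministic and invariant to the input taxon order; used to
#' arrange heatmap rows/columns so that similar languages sit together.
#'
#' @param D a [pcm_dist()] or symmetric labelled matrix.
#' @return character vector of taxon labels.
#' @export
hclust_order <- function(D) {
  upgma(D)$tip.label
}

#' Heatmap table: reordered distances with shade bins
#'
#' Reorders the distance matrix by a clustering-based leaf order and bins
#' every cell relative to the median off-diagonal distance: cells at or
#' below the median form the "cool" half (ties at the median are cool),
#' cells above form the "warm" half, and each half is divided into
#' equal-width shade bins. The result is a plot-ready table rather than an
#' image.
#'
#' @param D a [pcm_dist()] or symmetric labelled matrix.
#' @param order leaf ordering (default [hclust_order()]).
#' @param shades_per_half number of shade bins per half.
#' @return a list of class `pcm_heatmap`: `values` (reordered matrix),
#'   `bins` (character matrix of bin labels, `cool1..coolK` nearest the
#'   diagonal colours through `warmK`), `median`, `cool_range`,
#'   `warm_range`, `breaks`.
#' @export
heatmap_table <- function(D, order = NULL, shades_per_half = 5L) {
  v <- .dist_values(D)
  if (is.null(order)) order <- hclust_order(v)
  if (!setequal(order, rownames(v)) || length(order) != nrow(v)) {
    stop("`order` must be a permutation of the taxon labels")
  }
  v <- v[order, order]
  off <- v[row(v) != col(v)]
  med <- stats::median(off)
  lo <- min(off); hi <- max(off)
  cool_breaks <- seq(lo, med, length.out = shades_per_half + 1L)
  warm_breaks <- seq(med, hi, length.out = shades_per_half + 1L)
  bins <- matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  cool <- v <= med
  # degenerate halves (constant matrices) collapse into a single bin
  bin_of <- function(vals, breaks, prefix) {
    if (breaks[1L] == breaks[length(breaks)]) {
      return(rep(paste0(prefix, 1L), length(vals)))
    }
    idx <- findInterval(vals, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    paste0(prefix, idx)
  }
  bins[cool] <- bin_of(v[cool], cool_breaks, "cool")
  bins[!cool] <- bin_of(v[!cool], warm_breaks, "warm")
  structure(
    list(values = v, bins = bins, median = med,
         cool_range = c(lo, med), warm_range = c(med, hi),
         breaks = list(cool = cool_breaks, warm = warm_breaks)),
    class = "pcm_heatmap"
  )
}

#' @export
print.pcm_heatmap <- function(x, ...) {
  cat(sprintf("heatmap table, %d taxa\n", nrow(x$values)))
  cat(sprintf("  cool half: %.3f-%.3f (at/below median), warm half: %.3f-%.3f\n",
              x$cool_range[1L], x$cool_range[2L],
              x$warm_range[1L], x$warm_range[2L]))
  invisible(x)
}

#' @export
plot.pcm_heatmap <- function(x, ...) {
  n <- nrow(x$values)
  pal <- c(grDevices::hcl.colors(length(x$breaks$cool) - 1L, "Blues"),
           grDevices::hcl.colors(length(x$breaks$warm) - 1L, "Reds", rev = TRUE))
  brks <- unique(c(x$breaks$cool, x$breaks$warm))
  graphics::image(seq_len(n), seq_len(n), t(x$values[n:1, ]),
                  col = pal[seq_len(length(brks) - 1L)], breaks = brks,
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(x$values),
                 las = 2, cex.axis = 0.5, tick = FALSE)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(x$values)),
                 las = 2, cex.axis = 0.5, tick = FALSE)
  invisible(x)
}
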