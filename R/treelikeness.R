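#' Quartet pairing sums
#'
#' For four taxa there are three ways to pair them; each pairing has a sum of
#' two disjoint distances: `d(i,j)+d(k,l)`, `d(i,k)+d(j,l)`, `d(i,l)+d(j,k)`.
#' On an additive (tree-realizable) metric the two largest sums are equal
#' (the four-point condition); their spread measures conflict with any tree.
#'
#' @param D a [pcm_dist()] or symmetric labelled matrix.
#' @param quartet four distinct taxon labels (or indices).
#' @return numeric vector `c(m1, m2, m3)`, sorted descending.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' quartet_sums(cophenetic(tr), c("A", "B", "C", "D"))
#' @export
quartet_sums <- function(D, quartet) {
  v <- .dist_values(D)
  if (is.character(quartet)) quartet <- match(quartet, rownames(v))
  if (length(unique(quartet)) != 4L || anyNA(quartet)) {
    stop("quartet must name four distinct taxa present in the matrix")
  }
  i <- quartet[1L]; j <- quartet[2L]; k <- quartet[3L]; l <- quartet[4L]
  if (anyNA(c(v[i, j], v[k, l], v[i, k], v[j, l], v[i, l], v[j, k]))) {
    stop("undefined distance within the quartet")
  }
  sort(c(v[i, j] + v[k, l], v[i, k] + v[j, l], v[i, l] + v[j, k]),
       decreasing = TRUE)
}

#' Delta-score of one quartet
#'
#' `(m1 - m2) / (m1 - m3)` on the descending pairing sums: 0 for a perfectly
#' tree-like (additive) quartet, 1 for maximal conflict. Degenerate quartets
#' with `m1 = m3` (all three pairings equal) score 0 by convention.
#'
#' @param sums descending pairing sums from [quartet_sums()].
#' @return a value in `[0, 1]`.
#' @export
delta_quartet <- function(sums) {
  if (sums[1L] == sums[3L]) return(0)
  (sums[1L] - sums[2L]) / (sums[1L] - sums[3L])
}

#' Q-residual of one quartet
#'
#' `(m1 - m2)^2` on pairing sums computed from distances pre-scaled so the
#' mean off-diagonal distance is 1 (which makes the score invariant to the
#' overall scale of the matrix). 0 iff the quartet satisfies the four-point
#' condition.
#'
#' @param sums descending pairing sums computed on scaled distances.
#' @return a nonnegative value.
#' @export
q_residual_quartet <- function(sums) {
  (sums[1L] - sums[2L])^2
}

#' Per-taxon delta-scores and Q-residuals
#'
#' Enumerates every quartet of taxa (streaming accumulation, no per-quartet
#' storage), scores each with the delta-score and the Q-residual, and
#' averages over the quartets containing each taxon (`choose(n-1, 3)` of
#' them). Matrix-level summaries (median, mean, SD across taxa) are attached.
#' A low delta-score indicates a sharply tree-like (vertical) signal for that
#' taxon; high scores flag taxa whose distances conflict with every tree,
#' e.g. through contact or homoplasy.
#'
#' @param D a [pcm_dist()] or symmetric labelled matrix; at least 4 taxa,
#'   all distances defined.
#' @return a data frame of class `pcm_treelikeness` with columns `taxon`,
#'   `delta`, `q_residual`, sorted as the input taxa; attribute `summary` is
#'   a data frame with the median/mean/SD of both scores across taxa.
#' @export
taxon_scores <- function(D) {
  v <- .dist_values(D)
  n <- nrow(v)
  if (n < 4L) stop("need at least 4 taxa")
  if (anyNA(v[lower.tri(v)])) stop("undefined distances present")
  vs <- v / mean(v[row(v) != col(v)]) # mean-1 scaling for Q-residuals
  q4 <- utils::combn(n, 4L)
  i <- q4[1L, ]; j <- q4[2L, ]; k <- q4[3L, ]; l <- q4[4L, ]
  s1 <- v[cbind(i, j)] + v[cbind(k, l)]
  s2 <- v[cbind(i, k)] + v[cbind(j, l)]
  s3 <- v[cbind(i, l)] + v[cbind(j, k)]
  m1 <- pmax(s1, s2, s3)
  m3 <- pmin(s1, s2, s3)
  m2 <- s1 + s2 + s3 - m1 - m3
  delta <- ifelse(m1 > m3, (m1 - m2) / (m1 - m3), 0)
  t1 <- vs[cbind(i, j)] + vs[cbind(k, l)]
  t2 <- vs[cbind(i, k)] + vs[cbind(j, l)]
  t3 <- vs[cbind(i, l)] + vs[cbind(j, k)]
  qm1 <- pmax(t1, t2, t3)
  qm3 <- pmin(t1, t2, t3)
  qm2 <- t1 + t2 + t3 - qm1 - qm3
  qres <- (qm1 - qm2)^2
  # each quartet contributes its score once to each of its four members
  delta_sum <- as.vector(rowsum(rep(delta, each = 4L), c(q4)))
  q_sum <- as.vector(rowsum(rep(qres, each = 4L), c(q4)))
  per_taxon <- choose(n - 1L, 3L)
  out <- data.frame(taxon = rownames(v),
                    delta = delta_sum / per_taxon,
                    q_residual = q_sum / per_taxon,
                    row.names = NULL)
  attr(out, "summary") <- data.frame(
    score = c("delta", "q_residual"),
    median = c(stats::median(out$delta), stats::median(out$q_residual)),
    mean = c(mean(out$delta), mean(out$q_residual)),
    sd = c(stats::sd(out$delta), stats::sd(out$q_residual))
  )
  class(out) <- c("pcm_treelikeness", class(out))
  out
}

#' @export
print.pcm_treelikeness <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("tree-likeness scores for %d taxa\n", nrow(x)))
  cat(sprintf("  delta:      median %.3f, mean %.3f, SD %.3f\n",
              s$median[1L], s$mean[1L], s$sd[1L]))
  cat(sprintf("  Q-residual: median %.3f, mean %.3f, SD %.3f\n",
              s$median[2L], s$mean[2L], s$sd[2L]))
  invisible(x)
}

#' Least tree-like taxa
#'
#' Ranks taxa by decreasing delta-score (default) or Q-residual, flagging
#' the taxa whose signal departs most from a tree.
#'
#' @param scores a [taxon_scores()] result.
#' @param n how many taxa to report.
#' @param by `"delta"` or `"q_residual"`.
#' @return the top-`n` rows of the score table, most conflicted first.
#' @export
least_treelike <- function(scores, n = 10L, by = c("delta", "q_residual")) {
  by <- match.arg(by)
  ord <- order(scores[[by]], decreasing = TRUE)
  utils::head(as.data.frame(scores)[ord, , drop = FALSE], n)
}
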