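#' Count state agreements and disagreements for one language pair
#'
#' Tallies, over the parameters where both languages carry a binary value,
#' the four joint states: `n_pp` (+/+), `n_pm` (+/-), `n_mp` (-/+), `n_mm`
#' (-/-). Positions where either language is null (`"0"`) or unknown (`"?"`)
#' are excluded and counted in `n_excluded`. Two derived supports are
#' attached: `overlap` (all four counts; the Hamming denominator) and
#' `jaccard_support` (`n_pp + n_pm + n_mp`; the Jaccard denominator, which
#' discards the -/- matches).
#'
#' @param a,b character vectors of equal length with states in
#'   `+`, `-`, `0`, `?`.
#' @return a list of class `pair_comparison`.
#' @examples
#' compare_pair(c("+", "0", "-", "+"), c("-", "-", "0", "+"))
#' @export
compare_pair <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("state rows differ in length (%d vs %d)", length(a), length(b)))
  }
  a <- .normalize_states(as.character(a))
  b <- .normalize_states(as.character(b))
  res <- list(
    n_pp = sum(a == "+" & b == "+"),
    n_pm = sum(a == "+" & b == "-"),
    n_mp = sum(a == "-" & b == "+"),
    n_mm = sum(a == "-" & b == "-")
  )
  res$n_excluded <- length(a) - res$n_pp - res$n_pm - res$n_mp - res$n_mm
  res$overlap <- res$n_pp + res$n_pm + res$n_mp + res$n_mm
  res$jaccard_support <- res$n_pp + res$n_pm + res$n_mp
  class(res) <- "pair_comparison"
  res
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("pair comparison: +/+ %d  +/- %d  -/+ %d  -/- %d  excluded %d\n",
              x$n_pp, x$n_pm, x$n_mp, x$n_mm, x$n_excluded))
  cat(sprintf("  overlap %d, Jaccard support %d\n", x$overlap, x$jaccard_support))
  invisible(x)
}

#' Jaccard distance for a pair comparison
#'
#' `(n_pm + n_mp) / (n_pm + n_mp + n_pp)`: the fraction of differences among
#' the positions that are informative under the assumption that only shared
#' non-default (+/+) values count as identities. Undefined (returned as `NA`)
#' when the Jaccard support is zero.
#'
#' @param cmp a [compare_pair()] result.
#' @return a number in `[0, 1]`, or `NA` when undefined.
#' @export
jaccard_distance <- function(cmp) {
  stopifnot(inherits(cmp, "pair_comparison"))
  if (cmp$jaccard_support == 0L) return(NA_real_)
  (cmp$n_pm + cmp$n_mp) / cmp$jaccard_support
}

#' Normalized Hamming distance for a pair comparison
#'
#' `(n_pm + n_mp) / overlap`: differences divided by the sum of identities
#' and differences, where both +/+ and -/- count as identities. Undefined
#' (`NA`) when the pair shares no non-null positions.
#'
#' @param cmp a [compare_pair()] result.
#' @return a number in `[0, 1]`, or `NA` when undefined.
#' @export
hamming_distance <- function(cmp) {
  stopifnot(inherits(cmp, "pair_comparison"))
  if (cmp$overlap == 0L) return(NA_real_)
  (cmp$n_pm + cmp$n_mp) / cmp$overlap
}

#' Pairwise distance matrix from a parameter matrix
#'
#' Computes all pairwise Jaccard or normalized Hamming distances, restricted
#' for each pair to the parameters valued in both languages. Per-pair support
#' counts (overlap and Jaccard support) are retained so that downstream
#' consumers can judge how many characters each distance rests on.
#'
#' @param m a [parameter_matrix()].
#' @param metric `"jaccard"` (default) or `"hamming"`.
#' @param undefined what to do with pairs whose support is zero: `"error"`
#'   (default) aborts naming the first offending pair; `"flag"` records `NA`
#'   for such pairs.
#' @return an object of class `pcm_dist`: a list with `values` (symmetric
#'   numeric matrix, zero diagonal), `metric`, `overlap` and
#'   `jaccard_support` (symmetric integer matrices), `taxa`.
#' @examples
#' m <- parameter_matrix(matrix(c("+", "-", "+", "+", "-", "0"), 2, 3,
#'   dimnames = list(c("A", "B"), c("p1", "p2", "p3"))))
#' pcm_dist(m)$values
#' @export
pcm_dist <- function(m, metric = c("jaccard", "hamming"),
                     undefined = c("error", "flag")) {
  metric <- match.arg(metric)
  undefined <- match.arg(undefined)
  stopifnot(inherits(m, "parameter_matrix"))
  if (nrow(m) < 2L) stop("need at least 2 taxa")
  x <- unclass(m)
  P <- (x == "+") * 1L
  M <- (x == "-") * 1L
  n_pp <- tcrossprod(P)
  n_mm <- tcrossprod(M)
  n_pm <- P %*% t(M) # row language '+', column language '-'
  diff <- n_pm + t(n_pm)
  overlap <- n_pp + n_mm + diff
  jsupport <- n_pp + diff
  denom <- if (metric == "jaccard") jsupport else overlap
  values <- ifelse(denom > 0, diff / denom, NA_real_)
  diag(values) <- 0
  if (undefined == "error" && anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("distance undefined for pair (%s, %s): no shared support",
                 rownames(x)[bad[1L]], rownames(x)[bad[2L]]))
  }
  structure(
    list(values = values, metric = metric, overlap = overlap,
         jaccard_support = jsupport, taxa = rownames(x)),
    class = "pcm_dist"
  )
}

#' @export
print.pcm_dist <- function(x, ...) {
  off <- x$values[lower.tri(x$values)]
  cat(sprintf("%s distance matrix, %d taxa\n", x$metric, length(x$taxa)))
  if (all(is.na(off))) {
    cat("  all pairs undefined\n")
  } else {
    cat(sprintf("  off-diagonal range %.3f-%.3f (median %.3f)%s\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE),
                stats::median(off, na.rm = TRUE),
                if (anyNA(off)) sprintf(", %d undefined pairs", sum(is.na(off)))
                else ""))
  }
  invisible(x)
}

#' @export
as.matrix.pcm_dist <- function(x, ...) x$values

#' @export
as.dist.pcm_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Mean distance between two groups of taxa
#'
#' Averages the distances over all cross pairs (one taxon from each group),
#' e.g. to quantify the closeness of two families.
#'
#' @param D a [pcm_dist()].
#' @param group1,group2 character vectors of taxon labels; must be disjoint.
#' @return the mean cross-pair distance.
#' @export
cross_group_mean <- function(D, group1, group2) {
  stopifnot(inherits(D, "pcm_dist"))
  missing <- setdiff(c(group1, group2), D$taxa)
  if (length(missing) > 0) stop("taxa not in matrix: ", paste(missing, collapse = ", "))
  if (length(intersect(group1, group2)) > 0) stop("groups must be disjoint")
  mean(D$values[group1, group2, drop = FALSE])
}

#' Write a distance matrix to disk
#'
#' @param D a [pcm_dist()].
#' @param path output file path.
#' @param format `"phylip"` (square dialect, taxon count on line 1) or
#'   `"csv"` (wide, with a header row and label column). PHYLIP labels are
#'   truncated to 10 characters and uniquified deterministically; any
#'   renaming is reported via a warning.
#' @return `path`, invisibly.
#' @export
write_distances <- function(D, path, format = c("phylip", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(D, "pcm_dist"))
  v <- D$values
  if (format == "csv") {
    tab <- cbind(taxon = rownames(v), as.data.frame(v, check.names = FALSE))
    utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    labels <- gsub("[[:space:]]+", "_", rownames(v))
    if (any(nchar(labels) > 10L)) {
      short <- substr(labels, 1L, 10L)
      short <- make.unique(short, sep = "")
      short <- substr(short, 1L, 10L) # make.unique may push past 10 again
      if (anyDuplicated(short)) {
        short <- sprintf("%-.7s%03d", short, seq_along(short))
      }
      warning("PHYLIP labels truncated: ",
              paste(sprintf("%s->%s", labels[labels != short], short[labels != short]),
                    collapse = ", "))
      labels <- short
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(v)), con)
    writeLines(sprintf("%-10s %s", labels,
                       apply(v, 1L, function(r) paste(sprintf("%.9f", r), collapse = " "))),
               con)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distances()]
#'
#' @param path file path.
#' @param format `"phylip"` or `"csv"`.
#' @param metric metric name to record on the result.
#' @return a [pcm_dist()] (support matrices are not stored in either format
#'   and come back as `NA`).
#' @export
read_distances <- function(path, format = c("phylip", "csv"),
                           metric = "jaccard") {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    v <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(v) <- tab[[1L]]
  } else {
    lines <- readLines(path)
    n <- as.integer(trimws(lines[1L]))
    parts <- strsplit(trimws(lines[1L + seq_len(n)]), "[[:space:]]+")
    labels <- vapply(parts, `[[`, "", 1L)
    v <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
    dimnames(v) <- list(labels, labels)
  }
  na_mat <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  structure(
    list(values = v, metric = metric, overlap = na_mat,
         jaccard_support = na_mat, taxa = rownames(v)),
    class = "pcm_dist"
  )
}
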