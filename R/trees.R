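# Internal: extract a validated full distance matrix from pcm_dist / matrix.
.dist_values <- function(D) {
  v <- if (inherits(D, "pcm_dist")) D$values else as.matrix(D)
  if (is.null(rownames(v))) rownames(v) <- colnames(v) <- paste0("t", seq_len(nrow(v)))
  if (nrow(v) != ncol(v) || any(abs(v - t(v)) > 1e-12, na.rm = TRUE)) {
    stop("distance matrix must be square and symmetric")
  }
  v
}

# Quote a Newick label if it contains characters outside the safe set.
.newick_label <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.|/-]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering: at each step the two closest
#' clusters merge at height `d/2`, and the distance from the new cluster to
#' any other is the size-weighted mean of its members' distances. The result
#' is a rooted ultrametric tree (all root-to-tip path lengths equal). When
#' several pairs tie for the minimum distance, the pair whose sorted pair of
#' smallest member labels is lexicographically smallest merges first, so the
#' output is deterministic regardless of input order. Within each merge the
#' subtree containing the smallest label is written first, which fixes the
#' tip ordering used by [hclust_order()].
#'
#' @param D a [pcm_dist()] or a symmetric numeric matrix with labels; all
#'   off-diagonal entries must be defined (no `NA`).
#' @return an object of class `phylo` (rooted, ultrametric).
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(d))
#' @export
upgma <- function(D) {
  v <- .dist_values(D)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 taxa")
  if (anyNA(v[lower.tri(v)])) {
    bad <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop(sprintf("undefined distance between '%s' and '%s'",
                 rownames(v)[bad[1L]], rownames(v)[bad[2L]]))
  }
  labels <- rownames(v)
  # Active cluster state: newick fragment, height, size, smallest member label.
  nwk <- .newick_label(labels)
  height <- numeric(n)
  size <- rep(1L, n)
  minlab <- labels
  active <- seq_len(n)
  d <- v
  while (length(active) > 1L) {
    sub <- d[active, active, drop = FALSE]
    dmin <- min(sub[lower.tri(sub)])
    idx <- which(sub == dmin & lower.tri(sub), arr.ind = TRUE)
    # candidate pairs as (active) indices; tie-break on sorted label pairs
    cand_i <- active[idx[, 2L]]
    cand_j <- active[idx[, 1L]]
    lab1 <- pmin(minlab[cand_i], minlab[cand_j])
    lab2 <- pmax(minlab[cand_i], minlab[cand_j])
    pick <- order(lab1, lab2)[1L]
    i <- cand_i[pick]; j <- cand_j[pick]
    h <- dmin / 2
    # child with the smaller minimum label comes first
    if (minlab[j] < minlab[i]) { tmp <- i; i <- j; j <- tmp }
    new_nwk <- sprintf("(%s:%.15g,%s:%.15g)",
                       nwk[i], h - height[i], nwk[j], h - height[j])
    rest <- setdiff(active, c(i, j))
    if (length(rest) > 0) {
      d[i, rest] <- d[rest, i] <-
        (size[i] * d[i, rest] + size[j] * d[j, rest]) / (size[i] + size[j])
    }
    nwk[i] <- new_nwk
    height[i] <- h
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    active <- setdiff(active, j)
  }
  tree <- ape::read.tree(text = paste0(nwk[active], ";"))
  tree
}

# Internal: sorted-tip-set key for every internal node of a rooted tree,
# ordered as node numbers n_tip+1, ..., n_tip+Nnode (single postorder pass).
.clade_keys <- function(tree) {
  n_tip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  sets <- vector("list", n_tip + tr$Nnode)
  sets[seq_len(n_tip)] <- as.list(tr$tip.label)
  for (k in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  vapply(sets[n_tip + seq_len(tr$Nnode)],
         function(s) paste(sort(s), collapse = "\r"), "")
}

#' Is a group recovered as an exact clade?
#'
#' `TRUE` iff some node of the rooted tree has exactly the group's members as
#' its descendant tips (no partial credit). Singleton groups are trivially
#' recovered.
#'
#' @param tree a rooted `phylo`.
#' @param members character vector of tip labels.
#' @return logical.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' clade_recovered(tr, c("A", "B"))
#' clade_recovered(tr, c("B", "C"))
#' @export
clade_recovered <- function(tree, members) {
  members <- unique(members)
  missing <- setdiff(members, tree$tip.label)
  if (length(missing) > 0) {
    stop("group members not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(members) <= 1L) return(TRUE)
  key <- paste(sort(members), collapse = "\r")
  key %in% .clade_keys(tree)
}

#' Score a tree against Gold-Standard groups
#'
#' For each group, checks whether the tree contains it as an exact clade, and
#' reports the fraction recovered over the included groups.
#'
#' @param tree a rooted `phylo`.
#' @param groups named list of character vectors (e.g. [pcm_gold_standard()]).
#' @param exclude optional character vector of group names to leave out of
#'   the score (e.g. `"Altaic"`).
#' @return a data frame of class `gold_score` with columns `group`,
#'   `n_members`, `recovered`; attributes `n_recovered`, `n_groups`,
#'   `fraction`.
#' @export
gold_standard_score <- function(tree, groups, exclude = NULL) {
  if (!is.null(exclude)) groups <- groups[setdiff(names(groups), exclude)]
  if (length(groups) == 0L) {
    out <- data.frame(group = character(), n_members = integer(),
                      recovered = logical())
  } else {
    keys <- .clade_keys(tree)
    out <- data.frame(
      group = names(groups),
      n_members = lengths(groups),
      recovered = vapply(groups, function(g) {
        g <- unique(g)
        length(g) <= 1L ||
          paste(sort(g), collapse = "\r") %in% keys
      }, TRUE),
      row.names = NULL
    )
  }
  attr(out, "n_recovered") <- sum(out$recovered)
  attr(out, "n_groups") <- nrow(out)
  attr(out, "fraction") <- if (nrow(out) > 0) mean(out$recovered) else NA_real_
  class(out) <- c("gold_score", class(out))
  out
}

#' @export
print.gold_score <- function(x, ...) {
  print.data.frame(x, ...)
  if (nrow(x) > 0) {
    cat(sprintf("recovered %d/%d groups (%.0f%%)\n",
                attr(x, "n_recovered"), attr(x, "n_groups"),
                100 * attr(x, "fraction")))
  }
  invisible(x)
}

#' Bootstrap support for a UPGMA tree
#'
#' Standard character bootstrap: the parameter columns are resampled with
#' replacement, distances and the UPGMA tree are recomputed per replicate,
#' and each clade of the original tree is annotated with the percentage of
#' retained replicates containing it. Replicates in which any pair's distance
#' is undefined (zero support, possible on sparse matrices) are discarded and
#' counted.
#'
#' @param m a [parameter_matrix()].
#' @param metric `"jaccard"` or `"hamming"`.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed; the run is fully reproducible from it.
#' @param consensus if `TRUE`, also return the majority-rule consensus tree
#'   of the retained replicates.
#' @return a list of class `pcm_boot`: `tree` (the original UPGMA tree with
#'   `node.label` set to rounded percent support), `support` (numeric vector
#'   per internal node), `n_reps`, `n_retained`, `n_discarded`, and
#'   optionally `consensus`.
#' @export
bootstrap_upgma <- function(m, metric = c("jaccard", "hamming"),
                            n_reps = 100L, seed = 1L, consensus = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(m, "parameter_matrix"), n_reps >= 1L)
  tree <- upgma(pcm_dist(m, metric))
  keys <- .clade_keys(tree)
  counts <- stats::setNames(numeric(length(keys)), keys)
  x <- unclass(m)
  P <- ncol(x)
  set.seed(seed)
  retained <- 0L
  rep_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(P, P, replace = TRUE)
    xb <- x[, cols, drop = FALSE]
    colnames(xb) <- paste0("c", seq_len(P))
    mb <- parameter_matrix(xb)
    Db <- tryCatch(pcm_dist(mb, metric, undefined = "error"),
                   error = function(e) NULL)
    if (is.null(Db)) next
    tb <- upgma(Db)
    retained <- retained + 1L
    rep_trees[[retained]] <- tb
    kb <- .clade_keys(tb)
    hit <- keys %in% kb
    counts[hit] <- counts[hit] + 1
  }
  if (retained == 0L) stop("all bootstrap replicates were discarded")
  support <- 100 * counts / retained
  tree$node.label <- sprintf("%.0f", support)
  out <- list(tree = tree, support = support, n_reps = n_reps,
              n_retained = retained, n_discarded = n_reps - retained)
  if (consensus) {
    out$consensus <- ape::consensus(rep_trees[seq_len(retained)], p = 0.5)
  }
  class(out) <- "pcm_boot"
  out
}

#' @export
print.pcm_boot <- function(x, ...) {
  cat(sprintf("UPGMA tree with bootstrap support (%d/%d replicates retained)\n",
              x$n_retained, x$n_reps))
  cat(sprintf("  clade support: min %.0f%%, median %.0f%%, max %.0f%%\n",
              min(x$support), stats::median(x$support), max(x$support)))
  invisible(x)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions, plus the count
#' normalized by its maximum `2(n-3)`. Trees must share an identical leaf
#' set; rootedness is ignored (bipartitions are unrooted objects).
#'
#' @param t1,t2 `phylo` trees on the same leaves.
#' @return list with `count` and `normalized`.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  u1 <- ape::unroot(t1); u2 <- ape::unroot(t2)
  count <- as.numeric(phangorn::RF.dist(u1, u2, normalize = FALSE,
                                        check.labels = TRUE))
  normalized <- as.numeric(phangorn::RF.dist(u1, u2, normalize = TRUE,
                                             check.labels = TRUE))
  list(count = count, normalized = normalized)
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over the `ape` serializers keeping enough digits for
#' round-trips at `1e-9` precision; support values travel as internal node
#' labels.
#'
#' @param tree a `phylo`.
#' @param path file path.
#' @param digits significant digits for branch lengths.
#' @return `path` (writer) or a `phylo` (reader).
#' @export
write_newick <- function(tree, path, digits = 15L) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

# Internal: height (distance to tips) of every node of an ultrametric tree.
.node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}
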