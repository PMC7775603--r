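# Shared fixture builders; everything is generated in code.

# A small parameter matrix with the given rows (character vectors of states).
pm <- function(..., languages = NULL, params = NULL) {
  rows <- list(...)
  x <- do.call(rbind, rows)
  if (is.null(languages)) languages <- LETTERS[seq_len(nrow(x))]
  if (is.null(params)) params <- paste0("p", seq_len(ncol(x)))
  dimnames(x) <- list(languages, params)
  parameter_matrix(x)
}

# Split a compact state string like "+-0?" into a state vector.
st <- function(s) strsplit(s, "")[[1]]

# Random fully-defined parameter matrix (no nulls).
random_binary_matrix <- function(n_lang, n_par, seed) {
  set.seed(seed)
  x <- matrix(sample(c("+", "-"), n_lang * n_par, replace = TRUE),
              n_lang, n_par,
              dimnames = list(paste0("L", seq_len(n_lang)),
                              paste0("p", seq_len(n_par))))
  parameter_matrix(x)
}

# Random symmetric distance matrix with distinct off-diagonal entries.
random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[lower.tri(v)] <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2) +
    stats::runif(n * (n - 1) / 2, 0, 1e-4)
  v <- v + t(v)
  dimnames(v) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  v
}

# Independent average-linkage oracle: naive agglomeration that recomputes
# every cluster-to-cluster distance as the plain mean over member pairs of
# the ORIGINAL matrix (no Lance-Williams update), with the same tie-break.
# Returns merge heights and the clades (sorted member sets) created.
oracle_average_linkage <- function(v) {
  labels <- rownames(v)
  clusters <- as.list(labels)
  heights <- numeric(0)
  clades <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_len(a - 1L)) {
        d <- mean(v[clusters[[a]], clusters[[b]]])
        lab <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        cand <- list(d = d, a = a, b = b, lab = lab)
        if (is.null(best) || d < best$d ||
            (d == best$d && (lab[1] < best$lab[1] ||
                             (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    heights <- c(heights, best$d / 2)
    clades <- c(clades, list(merged))
    clusters[[best$b]] <- merged
    clusters[[best$a]] <- NULL
  }
  list(heights = heights, clades = clades)
}

# Clades (sorted tip sets) and heights of the internal nodes of a phylo.
tree_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  lapply(n_tip + seq_len(tree$Nnode), function(node) {
    sort(ape::extract.clade(tree, node)$tip.label)
  })
}

tree_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  (max(depth) - depth)[n_tip + seq_len(tree$Nnode)]
}
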