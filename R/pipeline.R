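#' Run the full parametric-comparison analysis
#'
#' One call from a parameter matrix to every analysis product: state
#' summary, pairwise distances, UPGMA tree (optionally bootstrapped), PCoA,
#' heatmap table, per-taxon tree-likeness scores, and (when groups are
#' supplied) Gold-Standard clade recovery. Returns a classed object with
#' `print`, `summary` and `plot` methods; [run_pipeline()] writes the same
#' products to disk.
#'
#' @param m a [parameter_matrix()] (or a path readable by
#'   [read_parameter_matrix()]).
#' @param metric `"jaccard"` (default) or `"hamming"`.
#' @param groups optional named list of Gold-Standard groups
#'   (e.g. [pcm_gold_standard()]); scored when all members are in the matrix.
#' @param exclude_groups group names excluded from the recovery fraction.
#' @param boot_reps bootstrap replicates (0 skips the bootstrap).
#' @param seed integer seed (used by the bootstrap).
#' @param n_axes PCoA axes to retain.
#' @return an object of class `pcm_analysis` with components `matrix`,
#'   `summary`, `dist`, `tree`, `boot` (or `NULL`), `pcoa`, `heatmap`,
#'   `treelikeness` (`NULL` when fewer than 4 taxa), `gold` (or `NULL`),
#'   `metric`, `seed`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_taxa = 8, n_params = 60, seed = 7))
#' fit <- pcm(sim$matrix, boot_reps = 20)
#' fit
#' @export
pcm <- function(m, metric = c("jaccard", "hamming"), groups = NULL,
                exclude_groups = NULL, boot_reps = 0L, seed = 1L,
                n_axes = 2L) {
  metric <- match.arg(metric)
  if (is.character(m) && length(m) == 1L) m <- read_parameter_matrix(m)
  stopifnot(inherits(m, "parameter_matrix"))
  D <- pcm_dist(m, metric)
  tree <- upgma(D)
  boot <- if (boot_reps > 0L) {
    bootstrap_upgma(m, metric, n_reps = boot_reps, seed = seed)
  }
  gold <- if (!is.null(groups)) {
    gold_standard_score(tree, groups, exclude = exclude_groups)
  }
  structure(
    list(matrix = m, summary = summary(m), dist = D,
         tree = if (is.null(boot)) tree else boot$tree,
         boot = boot, pcoa = pcoa(D, n_axes = n_axes),
         heatmap = heatmap_table(D),
         treelikeness = if (nrow(m) >= 4L) taxon_scores(D),
         gold = gold, metric = metric, seed = as.integer(seed)),
    class = "pcm_analysis"
  )
}

#' @export
print.pcm_analysis <- function(x, ...) {
  cat("Parametric comparison analysis\n")
  print(x$summary)
  print(x$dist)
  print(x$pcoa)
  if (!is.null(x$treelikeness)) print(x$treelikeness)
  if (!is.null(x$boot)) print(x$boot)
  if (!is.null(x$gold)) {
    cat(sprintf("Gold-Standard recovery: %d/%d groups (%.0f%%)\n",
                attr(x$gold, "n_recovered"), attr(x$gold, "n_groups"),
                100 * attr(x$gold, "fraction")))
  }
  invisible(x)
}

#' @export
summary.pcm_analysis <- function(object, ...) {
  s <- object$summary
  tl <- if (!is.null(object$treelikeness)) attr(object$treelikeness, "summary")
  out <- list(
    n_languages = s$n_languages, n_parameters = s$n_parameters,
    n_null = s$n_null, n_plus = s$n_plus,
    overlap_mean = s$overlap_mean, overlap_range = s$overlap_range,
    metric = object$metric,
    max_distance = max(object$dist$values),
    axis1_pct = 100 * object$pcoa$variance_fractions[1L],
    delta_median = if (!is.null(tl)) tl$median[tl$score == "delta"],
    gold_fraction = if (!is.null(object$gold)) attr(object$gold, "fraction")
  )
  class(out) <- "summary.pcm_analysis"
  out
}

#' @export
print.summary.pcm_analysis <- function(x, ...) {
  cat(sprintf("%d languages, %d parameters; %d null cells, %d '+'\n",
              x$n_languages, x$n_parameters, x$n_null, x$n_plus))
  cat(sprintf("mean non-null overlap %d (range %d-%d); max %s distance %.3f\n",
              x$overlap_mean, x$overlap_range[1L], x$overlap_range[2L],
              x$metric, x$max_distance))
  cat(sprintf("PCoA axis 1: %.0f%% of variance\n", x$axis1_pct))
  if (!is.null(x$delta_median)) {
    cat(sprintf("median per-language delta-score: %.3f\n", x$delta_median))
  }
  if (!is.null(x$gold_fraction)) {
    cat(sprintf("Gold-Standard recovery: %.0f%%\n", 100 * x$gold_fraction))
  }
  invisible(x)
}

#' @export
plot.pcm_analysis <- function(x, which = c("tree", "pcoa", "heatmap"), ...) {
  which <- match.arg(which)
  switch(which,
    tree = ape::plot.phylo(x$tree, cex = 0.6, ...),
    pcoa = plot(x$pcoa, ...),
    heatmap = plot(x$heatmap, ...)
  )
  invisible(x)
}

#' Run the pipeline and write every product to disk
#'
#' Orchestrates the full analysis from files to files, reproducibly. Each
#' stage's output is written in a standard plain-text format; a manifest
#' records the inputs, seed and settings. A stage failure aborts with the
#' stage named, leaving earlier outputs in place.
#'
#' @param matrix_path path to the parameter matrix (CSV/TSV).
#' @param out_dir output directory (created if needed).
#' @param orientation matrix orientation, see [read_parameter_matrix()].
#' @param metric `"jaccard"` or `"hamming"`.
#' @param stages character vector of stages to run, a subset of
#'   `"summary"`, `"dist"`, `"tree"`, `"boot"`, `"pcoa"`, `"heatmap"`,
#'   `"delta"`, `"gold"`, `"nexus"` (default: all, with `"boot"` only when
#'   `boot_reps > 0`).
#' @param boot_reps bootstrap replicates for the `"boot"` stage.
#' @param seed integer seed.
#' @param gold_file optional path to a Gold-Standard group table; by default
#'   the packaged table is used when all its members appear in the matrix.
#' @param exclude_groups group names excluded from the recovery fraction.
#' @return invisibly, a named list of the files written.
#' @export
run_pipeline <- function(matrix_path, out_dir,
                         orientation = c("languages", "parameters"),
                         metric = c("jaccard", "hamming"),
                         stages = NULL, boot_reps = 100L, seed = 1L,
                         gold_file = NULL, exclude_groups = "Altaic") {
  orientation <- match.arg(orientation)
  metric <- match.arg(metric)
  all_stages <- c("summary", "dist", "tree", "boot", "pcoa", "heatmap",
                  "delta", "gold", "nexus")
  if (is.null(stages)) {
    stages <- setdiff(all_stages, if (boot_reps <= 0L) "boot")
  }
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible())
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  path_of <- function(file) file.path(out_dir, file)

  m <- read_parameter_matrix(matrix_path, orientation = orientation)
  # distances/tree computed on first use, so failures belong to their stage
  D_cache <- NULL
  D <- function() {
    if (is.null(D_cache)) D_cache <<- pcm_dist(m, metric)
    D_cache
  }
  tree_cache <- NULL
  tree <- function() {
    if (is.null(tree_cache)) tree_cache <<- upgma(D())
    tree_cache
  }

  run_stage("summary", function() {
    s <- summary(m)
    tab <- data.frame(
      quantity = c("n_languages", "n_parameters", "n_cells", "n_plus",
                   "n_minus", "n_null", "n_unknown", "plus_mean",
                   "plus_median", "overlap_mean", "overlap_min", "overlap_max"),
      value = c(s$n_languages, s$n_parameters, s$n_cells, s$n_plus, s$n_minus,
                s$n_null, s$n_unknown, s$plus_mean, s$plus_median,
                s$overlap_mean, s$overlap_range)
    )
    utils::write.csv(tab, path_of("summary.csv"), row.names = FALSE)
    written$summary <<- path_of("summary.csv")
  })
  run_stage("dist", function() {
    write_distances(D(), path_of("distances.csv"), "csv")
    write_distances(D(), path_of("distances.phy"), "phylip")
    support <- cbind(taxon = D()$taxa,
                     as.data.frame(D()$overlap, check.names = FALSE))
    utils::write.csv(support, path_of("overlap_support.csv"), row.names = FALSE)
    written$dist <<- path_of("distances.csv")
  })
  run_stage("tree", function() {
    write_newick(tree(), path_of("upgma.nwk"))
    written$tree <<- path_of("upgma.nwk")
  })
  run_stage("boot", function() {
    bt <- bootstrap_upgma(m, metric, n_reps = boot_reps, seed = seed)
    write_newick(bt$tree, path_of("upgma_boot.nwk"))
    utils::write.csv(
      data.frame(node = seq_along(bt$support) + nrow(m),
                 support_pct = round(bt$support)),
      path_of("bootstrap_support.csv"), row.names = FALSE)
    if (bt$n_discarded > 0L) {
      message(sprintf("bootstrap: %d/%d replicates discarded (undefined pairs)",
                      bt$n_discarded, bt$n_reps))
    }
    written$boot <<- path_of("upgma_boot.nwk")
  })
  run_stage("pcoa", function() {
    p <- pcoa(D())
    utils::write.csv(cbind(taxon = rownames(p$coordinates),
                           as.data.frame(round(p$coordinates, 6))),
                     path_of("pcoa_coordinates.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(axis = seq_along(p$eigenvalues),
                 eigenvalue = round(p$eigenvalues, 9),
                 variance_fraction = round(
                   c(p$variance_fractions,
                     rep(NA, length(p$eigenvalues) - p$n_positive)), 6)),
      path_of("pcoa_eigenvalues.csv"), row.names = FALSE)
    written$pcoa <<- path_of("pcoa_coordinates.csv")
  })
  run_stage("heatmap", function() {
    h <- heatmap_table(D())
    utils::write.csv(cbind(taxon = rownames(h$values),
                           as.data.frame(round(h$values, 3),
                                         check.names = FALSE)),
                     path_of("heatmap_values.csv"), row.names = FALSE)
    utils::write.csv(cbind(taxon = rownames(h$bins),
                           as.data.frame(h$bins, check.names = FALSE)),
                     path_of("heatmap_bins.csv"), row.names = FALSE)
    written$heatmap <<- path_of("heatmap_values.csv")
  })
  run_stage("delta", function() {
    ts <- taxon_scores(D())
    tab <- as.data.frame(ts)
    tab$delta <- round(tab$delta, 3)
    tab$q_residual <- round(tab$q_residual, 3)
    utils::write.csv(tab, path_of("treelikeness.csv"), row.names = FALSE)
    utils::write.csv(attr(ts, "summary"), path_of("treelikeness_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(least_treelike(ts), path_of("least_treelike.csv"),
                     row.names = FALSE)
    written$delta <<- path_of("treelikeness.csv")
  })
  run_stage("gold", function() {
    groups <- pcm_gold_standard(file = gold_file)
    usable <- vapply(groups, function(g) all(g %in% rownames(m)), TRUE)
    if (!all(usable)) {
      message(sprintf("gold: %d group(s) skipped (members not in matrix)",
                      sum(!usable)))
    }
    groups <- groups[usable]
    if (length(groups) == 0L) {
      message("gold: no scorable groups; stage skipped")
      return(invisible())
    }
    sc <- gold_standard_score(tree(), groups,
                              exclude = intersect(exclude_groups, names(groups)))
    utils::write.csv(as.data.frame(sc), path_of("gold_standard.csv"),
                     row.names = FALSE)
    written$gold <<- path_of("gold_standard.csv")
  })
  run_stage("nexus", function() {
    write_nexus(m, path_of("matrix.nex"))
    written$nexus <<- path_of("matrix.nex")
  })

  manifest <- c(
    sprintf("matrix_path: %s", normalizePath(matrix_path)),
    sprintf("orientation: %s", orientation),
    sprintf("metric: %s", metric),
    sprintf("stages: %s", paste(stages, collapse = ",")),
    sprintf("boot_reps: %d", boot_reps),
    sprintf("seed: %d", seed),
    sprintf("n_languages: %d", nrow(m)),
    sprintf("n_parameters: %d", ncol(m))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  written$manifest <- file.path(out_dir, "manifest.txt")
  invisible(written)
}
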