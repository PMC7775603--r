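# Cell symbols: "+" non-default value, "-" default value, "0" implied/irrelevant
# (null), "?" not observed. "0" and "?" are both excluded from comparisons but
# tracked separately in summaries.
.pcm_states <- c("+", "-", "0", "?")

# Alternative glyphs accepted on input (true minus sign and en dash map to "-").
.pcm_aliases <- list(
  "+" = "+",
  "-" = c("-", "−", "–"),
  "0" = "0",
  "?" = "?"
)

.normalize_states <- function(x) {
  out <- x
  for (canon in names(.pcm_aliases)) {
    out[x %in% .pcm_aliases[[canon]]] <- canon
  }
  out
}

#' Construct a syntactic parameter matrix
#'
#' A `parameter_matrix` is a languages-by-parameters character matrix whose
#' cells are one of `"+"` (non-default value, set from positive evidence),
#' `"-"` (default value), `"0"` (null: implied or irrelevant given the states
#' of other parameters, hence no independent information) and `"?"` (not
#' observed). Rows are languages, columns are parameters; both must be
#' uniquely labelled.
#'
#' @param x character matrix (or object coercible to one) with row and column
#'   names; cells drawn from `+`, `-` (minus-sign and en-dash glyphs are
#'   accepted), `0`, `?`.
#' @return an object of class `parameter_matrix`.
#' @examples
#' m <- parameter_matrix(matrix(c("+", "-", "0", "+"), 2, 2,
#'   dimnames = list(c("L1", "L2"), c("p1", "p2"))))
#' summary(m)
#' @export
parameter_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "character"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("matrix must have language (row) and parameter (column) names")
  }
  x[] <- .normalize_states(trimws(x))
  ok <- x %in% .pcm_states
  dim(ok) <- dim(x)
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "unknown state symbol %s at language '%s', parameter '%s'",
      dQuote(x[i, j]), rownames(x)[i], colnames(x)[j]
    ))
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate language labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate parameter labels: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  class(x) <- c("parameter_matrix", class(x))
  x
}

#' Read a parameter matrix from a delimited text file
#'
#' The file must have one header row and one leading label column. Cells are
#' validated against the four-state alphabet; offending cells are reported by
#' language and parameter label.
#'
#' @param path path to a CSV/TSV file.
#' @param orientation `"languages"` if rows are languages (the canonical
#'   layout), `"parameters"` if rows are parameters; the returned matrix is
#'   always languages-as-rows.
#' @param sep field separator; `NULL` (default) auto-detects comma vs. tab
#'   from the header line.
#' @return a [parameter_matrix()].
#' @export
read_parameter_matrix <- function(path, orientation = c("languages", "parameters"),
                                  sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    stop(sprintf("ragged rows: line(s) %s have %s fields, expected %d",
                 paste(which(nf != nf[1L]), collapse = ", "),
                 paste(unique(nf[nf != nf[1L]]), collapse = "/"), nf[1L]))
  }
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  labels <- tab[[1L]]
  x <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(x) <- labels
  if (orientation == "parameters") x <- t(x)
  parameter_matrix(x)
}

#' Write a parameter matrix to a delimited text file
#'
#' @param m a [parameter_matrix()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @param orientation write languages as rows (default) or as columns.
#' @return `path`, invisibly.
#' @export
write_parameter_matrix <- function(m, path, sep = ",",
                                   orientation = c("languages", "parameters")) {
  orientation <- match.arg(orientation)
  x <- unclass(m)
  if (orientation == "parameters") x <- t(x)
  label_col <- if (orientation == "languages") "language" else "parameter"
  tab <- cbind(rownames(x), as.data.frame(x, check.names = FALSE))
  names(tab)[1L] <- label_col
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.parameter_matrix <- function(x, ...) {
  cat(sprintf("Syntactic parameter matrix: %d languages x %d parameters\n",
              nrow(x), ncol(x)))
  tab <- table(factor(x, levels = .pcm_states))
  cat(sprintf("  states: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = "  ")))
  invisible(x)
}

#' Summarize a parameter matrix
#'
#' Exhaustive state counts, per-language counts of `"+"` values, and the
#' distribution of pairwise non-null overlap (the number of parameters valued
#' `+` or `-` in both languages of a pair -- the effective number of
#' comparable characters for that pair).
#'
#' @param object a [parameter_matrix()].
#' @param ... unused.
#' @return a list of class `summary.parameter_matrix` with components
#'   `n_languages`, `n_parameters`, `n_cells`, `n_plus`, `n_minus`, `n_null`,
#'   `n_unknown`, `plus_per_language` (named integer vector), `plus_mean`,
#'   `plus_median` (rounded to nearest integer, as conventionally reported),
#'   `overlap` (pairwise non-null overlap counts), `overlap_mean`
#'   (rounded), `overlap_range`.
#' @export
summary.parameter_matrix <- function(object, ...) {
  x <- unclass(object)
  counts <- table(factor(x, levels = .pcm_states))
  plus_per_lang <- rowSums(x == "+")
  defined <- (x == "+") | (x == "-")
  ov <- tcrossprod(defined * 1L)
  overlap <- ov[lower.tri(ov)]
  res <- list(
    n_languages = nrow(x),
    n_parameters = ncol(x),
    n_cells = length(x),
    n_plus = unname(counts[["+"]]),
    n_minus = unname(counts[["-"]]),
    n_null = unname(counts[["0"]]),
    n_unknown = unname(counts[["?"]]),
    plus_per_language = plus_per_lang,
    plus_mean = round(mean(plus_per_lang)),
    plus_median = round(stats::median(plus_per_lang)),
    overlap = overlap,
    overlap_mean = round(mean(overlap)),
    overlap_range = range(overlap)
  )
  class(res) <- "summary.parameter_matrix"
  res
}

#' @export
print.summary.parameter_matrix <- function(x, ...) {
  cat(sprintf("%d languages x %d parameters (%d cells)\n",
              x$n_languages, x$n_parameters, x$n_cells))
  cat(sprintf("  '+' %d   '-' %d   null '0' %d   unknown '?' %d\n",
              x$n_plus, x$n_minus, x$n_null, x$n_unknown))
  cat(sprintf("  '+' per language: mean %d, median %d\n",
              x$plus_mean, x$plus_median))
  cat(sprintf("  pairwise non-null overlap: mean %d, range %d-%d\n",
              x$overlap_mean, x$overlap_range[1L], x$overlap_range[2L]))
  invisible(x)
}

#' Check a matrix against declared implicational dependencies
#'
#' A dependency declares that a parameter is defined only when a condition on
#' other parameters holds; the condition is a conjunction of
#' (parameter, required state) terms. A cell violates the declaration if it is
#' null (`"0"`) although the condition is met, or valued (`"+"`/`"-"`)
#' although the condition is unmet. Cells (or controlling cells) marked `"?"`
#' are never flagged. Parameters without declared dependencies are
#' unconditionally defined.
#'
#' @param m a [parameter_matrix()].
#' @param deps data frame with columns `param`, `requires`, `state`; several
#'   rows with the same `param` form a conjunction. `state` must be `"+"` or
#'   `"-"`.
#' @return data frame of violations with columns `language`, `param`,
#'   `problem` (`"null_but_condition_met"` or
#'   `"valued_but_condition_unmet"`); zero rows when the matrix is consistent.
#' @export
validate_dependencies <- function(m, deps) {
  stopifnot(inherits(m, "parameter_matrix"))
  empty <- data.frame(language = character(), param = character(),
                      problem = character(), stringsAsFactors = FALSE)
  if (is.null(deps) || nrow(deps) == 0L) return(empty)
  deps <- as.data.frame(deps, stringsAsFactors = FALSE)
  stopifnot(all(c("param", "requires", "state") %in% names(deps)))
  unknown <- setdiff(unique(c(deps$param, deps$requires)), colnames(m))
  if (length(unknown) > 0) {
    stop("dependency references unknown parameter code(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!all(deps$state %in% c("+", "-"))) {
    stop("dependency required states must be '+' or '-'")
  }
  .check_dependency_acyclic(deps)

  out <- empty
  for (p in unique(deps$param)) {
    terms <- deps[deps$param == p, , drop = FALSE]
    ctrl <- unclass(m)[, terms$requires, drop = FALSE]
    met <- rowSums(ctrl == matrix(terms$state, nrow(m), nrow(terms),
                                  byrow = TRUE)) == nrow(terms)
    known <- rowSums(ctrl == "?") == 0L
    cell <- unclass(m)[, p]
    bad_null <- met & known & cell == "0"
    bad_val <- !met & known & cell %in% c("+", "-")
    if (any(bad_null)) {
      out <- rbind(out, data.frame(language = rownames(m)[bad_null], param = p,
                                   problem = "null_but_condition_met",
                                   stringsAsFactors = FALSE))
    }
    if (any(bad_val)) {
      out <- rbind(out, data.frame(language = rownames(m)[bad_val], param = p,
                                   problem = "valued_but_condition_unmet",
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# DFS cycle check on the param -> requires graph.
.check_dependency_acyclic <- function(deps) {
  nodes <- unique(c(deps$param, deps$requires))
  adj <- split(deps$requires, factor(deps$param, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) stop("cyclic dependency involving parameter '", v, "'")
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w)
    state[[v]] <<- 2L
  }
  for (v in nodes) visit(v)
  invisible(TRUE)
}

#' Export a parameter matrix as a NEXUS DATA block
#'
#' Recodes the matrix for character-based phylogenetic tools: `"+"` becomes
#' `1`, `"-"` becomes `0`, and both `"0"` (null) and `"?"` (unknown) become
#' the missing symbol `?`, so that implied states carry no information.
#' Taxon labels are made NEXUS-safe (whitespace to underscores; labels with
#' other special characters are quoted).
#'
#' @param m a [parameter_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(m, path) {
  stopifnot(inherits(m, "parameter_matrix"))
  if (nrow(m) == 0L || ncol(m) == 0L) stop("cannot export an empty matrix")
  x <- unclass(m)
  recode <- c("+" = "1", "-" = "0", "0" = "?", "?" = "?")
  rows <- apply(x, 1L, function(r) paste(recode[r], collapse = ""))
  labels <- gsub("[[:space:]]+", "_", rownames(x))
  needs_quote <- grepl("[^A-Za-z0-9_.-]", labels)
  labels[needs_quote] <- paste0("'", gsub("'", "''", labels[needs_quote]), "'")
  width <- max(nchar(labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(x), ncol(x)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
    "  MATRIX",
    sprintf("    %-*s %s", width, labels, rows),
    "  ;",
    "END;"
  ), con)
  invisible(path)
}

#' Re-import a NEXUS binary matrix as a parameter matrix
#'
#' Inverse of [write_nexus()] up to the null/unknown distinction: `1` becomes
#' `"+"`, `0` becomes `"-"`, and the missing symbol becomes `"?"` (the
#' exporter collapses null and unknown into missing, so nulls cannot be
#' recovered).
#'
#' @param path path to a NEXUS file with a binary (0/1/?) matrix.
#' @return a [parameter_matrix()].
#' @export
read_nexus_matrix <- function(path) {
  dat <- ape::read.nexus.data(path)
  x <- do.call(rbind, lapply(dat, function(s) {
    recode <- c("1" = "+", "0" = "-", "?" = "?")
    unname(recode[as.character(s)])
  }))
  colnames(x) <- paste0("p", seq_len(ncol(x)))
  parameter_matrix(x)
}

#' Gold-Standard language groups
#'
#' The clades safely established by classical etymological comparison for the
#' 69-language Eurasian sample, used as ground truth when scoring trees. The
#' packaged table transcribes the published Gold Standard (24 groups; the
#' controversial Altaic grouping can be excluded, leaving the 23 groups used
#' for the headline recovery figure).
#'
#' @param exclude character vector of group names to drop (e.g. `"Altaic"`).
#' @param file optional path to a custom group table (CSV with columns
#'   `group`, `members` with `;`-separated labels).
#' @return named list of character vectors (group members), with the source
#'   table attached as attribute `"table"`.
#' @export
pcm_gold_standard <- function(exclude = NULL, file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "gold_standard.csv", package = "pcmphylo")
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(exclude)) {
    missing <- setdiff(exclude, tab$group)
    if (length(missing) > 0) stop("unknown group(s): ", paste(missing, collapse = ", "))
    tab <- tab[!(tab$group %in% exclude), , drop = FALSE]
  }
  groups <- lapply(strsplit(tab$members, ";", fixed = TRUE), trimws)
  names(groups) <- tab$group
  attr(groups, "table") <- tab
  groups
}

#' Language roster for the Eurasian sample
#'
#' The 69 languages of the published sample with their family (13
#' traditionally irreducible families) and, where applicable, subgroup.
#'
#' @param file optional path to a custom roster (CSV with columns `name`,
#'   `family`, `subgroup`).
#' @return data frame with columns `name`, `family`, `subgroup`.
#' @export
pcm_languages <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "languages.csv", package = "pcmphylo")
  }
  utils::read.csv(file, stringsAsFactors = FALSE)
}
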