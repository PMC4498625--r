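#' Read a plain-text expression matrix
#'
#' Reads the tab- or whitespace-delimited genes-by-timepoints layout used by
#' circadian time-course supplements: one row per gene, an optional leading
#' identifier column (detected by a non-numeric first field) and one numeric
#' column per timepoint. A header row is auto-detected and skipped.
#' Duplicate identifiers are made unique with a suffix.
#'
#' @param path Path to the text file.
#' @param timepoints Optional sampling times in hours; default
#'   0, 4, ..., 4*(n_cols - 1).
#' @return Numeric matrix with gene identifiers as rownames and attribute
#'   `"timepoints"`.
#' @export
read_expression_matrix <- function(path, timepoints = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (length(fields) == 0L) stop("empty file: ", path, call. = FALSE)

  is_num <- function(v) !is.na(suppressWarnings(as.numeric(v)))
  # a data-like line has every field numeric except possibly the first
  data_like <- vapply(fields, function(f) all(is_num(f[-1L])) && length(f) >= 2L,
                      logical(1L))
  header <- !data_like[1L] ||
    (length(fields) > 1L && !is_num(fields[[1L]][1L]) &&
       !any(is_num(fields[[1L]])) && is_num(fields[[2L]][1L]))
  if (header && length(fields) == 1L) {
    stop("no numeric data rows found in ", path, call. = FALSE)
  }
  if (header) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  nf <- lengths(fields)
  ncol_mode <- as.integer(names(which.max(table(nf))))
  bad <- which(nf != ncol_mode)
  if (length(bad)) {
    stop("ragged row(s) at line ", paste(line_no[bad], collapse = ", "),
         ": expected ", ncol_mode, " fields, found ",
         paste(unique(nf[bad]), collapse = "/"), call. = FALSE)
  }
  first <- vapply(fields, `[`, character(1L), 1L)
  has_ids <- !all(is_num(first))
  if (has_ids) {
    ids <- make.unique(first, sep = "_")
    num <- lapply(fields, function(f) suppressWarnings(as.numeric(f[-1L])))
  } else {
    ids <- sprintf("gene_%d", seq_along(fields))
    num <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  }
  bad_num <- which(vapply(num, function(v) any(is.na(v)), logical(1L)))
  if (length(bad_num)) {
    stop("non-numeric measurement(s) at line ",
         paste(line_no[bad_num], collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, num)
  rownames(mat) <- ids
  if (is.null(timepoints)) timepoints <- seq(0, by = 4, length.out = ncol(mat))
  if (length(timepoints) != ncol(mat)) {
    stop("`timepoints` length does not match the number of measurement columns",
         call. = FALSE)
  }
  colnames(mat) <- sprintf("t%g", timepoints)
  attr(mat, "timepoints") <- as.numeric(timepoints)
  mat
}

#' Write an expression matrix in the plain-text layout
#'
#' Inverse of [read_expression_matrix()]: tab-delimited, a header line, gene
#' identifiers in the first column. Files written this way double as inputs
#' for the command-line driver.
#'
#' @param x Numeric matrix, genes in rows.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("gene_%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("t%g", seq(0, by = 4, length.out = ncol(x)))
  }
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis results, summary and provenance to a directory
#'
#' Writes three files: `config.txt` (key: value provenance, including seed
#' and RNG kind, sufficient to reproduce the run), `gene_results.tsv` (the
#' per-gene table) and `phase_summary.tsv` (per-bin counts, percentages and
#' a Total row). The summary is written last so a failing directory errors
#' before any per-gene output is produced.
#'
#' @param fit A `phase_analysis` object from [analyze_dataset()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, outdir) {
  stopifnot(inherits(fit, "phase_analysis"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  cfg_path <- file.path(outdir, "config.txt")
  cfg <- fit$config
  writeLines(vapply(names(cfg), function(nm) {
    paste0(nm, ": ", paste(format(cfg[[nm]], digits = 15), collapse = " "))
  }, character(1L)), cfg_path)
  res_path <- file.path(outdir, "gene_results.tsv")
  utils::write.table(fit$results, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(fit$skipped) > 0L) {
    utils::write.table(fit$skipped, file.path(outdir, "skipped_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sum_path <- file.path(outdir, "phase_summary.tsv")
  utils::write.table(fit$summary, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(config = cfg_path, results = res_path, summary = sum_path))
}
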