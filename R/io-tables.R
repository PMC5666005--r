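## Readers and writers for the remaining table formats: SEG / gene-level
## copy, GMT gene sets, expression matrices (TSV or MatrixMarket), and
## dose-response plate tables.

#' Read a copy-number table (SEG or gene-level TSV)
#'
#' SEG-style input carries `chrom`, `start`, `end` and a log2-ratio column
#' (`log2_ratio` or `seg.mean`), converted to absolute copy via
#' [copy_from_log2()]. A TSV with an `absolute_copy` column is taken as is.
#'
#' @param path file to read.
#' @return data.frame of class `copy_segments` with columns `chrom`,
#'   `start`, `end`, `log2_ratio`, `absolute_copy`, plus `gene`/`sample`
#'   when present. Coordinates are 1-based inclusive.
#' @export
read_copy_segments <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  names(df)[names(df) == "seg.mean"] <- "log2_ratio"
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("copy table must have columns chrom, start, end", call. = FALSE)
  if (any(df$start > df$end)) stop("segment start exceeds end", call. = FALSE)
  if (!"absolute_copy" %in% names(df)) {
    if (!"log2_ratio" %in% names(df))
      stop("copy table needs log2_ratio (or seg.mean) or absolute_copy",
           call. = FALSE)
    df$absolute_copy <- copy_from_log2(df$log2_ratio)
  } else if (!"log2_ratio" %in% names(df)) df$log2_ratio <- NA_real_
  class(df) <- c("copy_segments", "data.frame")
  df
}

#' @rdname read_copy_segments
#' @param segments a `copy_segments` data.frame.
#' @export
write_copy_segments <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated GMT: set name, description, then gene identifiers. File
#' order is preserved; duplicate genes within a set are removed with a
#' warning; a line with fewer than three fields is a parse error.
#'
#' @param path GMT file.
#' @return named list of character vectors (class `gene_set_collection`),
#'   with set descriptions in `attr(, "description")`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_parse(path, i, "GMT line has fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set ", f[1], " deduplicated")
      genes <- unique(genes)
    }
    if (length(genes) == 0L)
      stop_parse(path, i, sprintf("gene set %s is empty", f[1]))
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(sets, description = desc, class = "gene_set_collection")
}

#' @rdname read_gene_sets
#' @param sets a `gene_set_collection` (or plain named list of genes).
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix (genes x cells)
#'
#' TSV input has gene identifiers in the first column and one column per
#' cell. MatrixMarket input (`.mtx`) requires companion `genes` and `cells`
#' index files (one identifier per line, or TSV with a header).
#'
#' @param path matrix file (TSV or MTX).
#' @param genes,cells index files for MTX input.
#' @return list of class `expression_matrix`: dense numeric matrix `expr`
#'   with gene rownames and cell colnames.
#' @export
read_expression_matrix <- function(path, genes = NULL, cells = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes) || is.null(cells))
      stop("MTX input requires genes and cells index files", call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(cells)
  } else {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  if (any(m < 0)) stop("expression values must be non-negative",
                       call. = FALSE)
  structure(list(expr = m), class = "expression_matrix")
}

#' @rdname read_expression_matrix
#' @param expr numeric matrix (genes x cells).
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response plate table
#'
#' TSV with columns `condition` (`cancer+fibroblast` or `fibroblast-only`),
#' `drug`, `dose` (micromolar; 0 = vehicle), `replicate`, and `signal`
#' (raw luminescence). Every condition must include at least one vehicle
#' row and doses must be non-negative.
#'
#' @param path TSV file.
#' @return data.frame of class `dose_response_table`.
#' @export
read_dose_response <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("condition", "drug", "dose", "replicate", "signal")
  if (!all(need %in% names(df)))
    stop("plate table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$dose < 0)) stop("doses must be >= 0", call. = FALSE)
  for (cond in unique(df$condition))
    if (!any(df$dose[df$condition == cond] == 0))
      stop("condition ", cond, " has no vehicle (zero-dose) row",
           call. = FALSE)
  class(df) <- c("dose_response_table", "data.frame")
  df
}

#' @rdname read_dose_response
#' @param plate a `dose_response_table`.
#' @export
write_dose_response <- function(plate, path) {
  write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
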