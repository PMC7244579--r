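#' Read a labelled peak BED file
#'
#' Parses a tab-separated BED file of open chromatin regions. Coordinates are
#' kept in BED convention (0-based half-open). The accessibility label
#' (`gained`/`stable`/`lost`) is taken from `label_column` (1-based column
#' index, default 4 = BED name column).
#'
#' @param path path to the BED file.
#' @param label_column integer column index holding the label.
#' @return A [peak_set()].
#' @export
read_bed_peaks <- function(path, label_column = 4L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty peak file: ", path)
    return(peak_set(character(0), integer(0), integer(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < max(3L, label_column))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": expected >= ",
         max(3L, label_column), " tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))
    stop("malformed BED line ", bad[1], ": non-integer coordinates")
  }
  label <- vapply(fields, `[[`, "", label_column)
  peak_set(chrom, start, end, label)
}

#' Write a peak set as BED
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential feature table
#'
#' Expects a tab-separated file with header columns `feature_id`, `log2fc`,
#' `p_value`, `fdr` and optionally `status`. Extra columns are ignored.
#'
#' @param path path to the TSV file.
#' @return A [differential_table()]; `status` is `NA` when the column is
#'   absent.
#' @export
read_differential_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("feature_id", "log2fc", "p_value", "fdr")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("differential table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("log2fc", "p_value", "fdr"))
    if (!is.numeric(df[[col]]))
      stop("column '", col, "' is not numeric")
  differential_table(df$feature_id, df$log2fc, df$p_value, df$fdr,
                     status = if ("status" %in% names(df)) df$status else NULL)
}

#' Write a differential table as TSV
#' @param table a [differential_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED or minimal GTF
#'
#' BED input (`.bed`): columns chrom, start, end, gene_id, score (optional),
#' strand; the TSS is the strand-aware 5' end of the interval (start for `+`,
#' `end - 1` for `-`, both 0-based). GTF input (`.gtf`): `gene` feature rows;
#' 1-based closed coordinates are converted to the internal 0-based
#' convention on read.
#'
#' @param path path to the annotation file.
#' @param format `"bed"`, `"gtf"`, or `"auto"` (by file extension).
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "bed"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("annotation BED needs 6 columns (strand in column 6)")
    start <- as.integer(df[[2]]); end <- as.integer(df[[3]])
    strand <- as.character(df[[6]])
    tss <- ifelse(strand == "+", start, end - 1L)
    gene_annotation(df[[4]], df[[1]], tss, strand)
  } else {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    df <- df[df[[3]] == "gene", , drop = FALSE]
    if (!nrow(df)) stop("no 'gene' feature rows in GTF: ", path)
    gid <- sub('.*gene_id[ =]*"?([^";]+)"?.*', "\\1", df[[9]])
    start0 <- as.integer(df[[4]]) - 1L  # GTF is 1-based closed
    end0 <- as.integer(df[[5]])
    strand <- as.character(df[[7]])
    tss <- ifelse(strand == "+", start0, end0 - 1L)
    gene_annotation(gid, df[[1]], tss, strand)
  }
}

#' Write gene annotation as 6-column BED
#' @param annotation a [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  df <- data.frame(annotation$chrom, annotation$tss, annotation$tss + 1L,
                   annotation$gene_id, 0L, annotation$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix and its sample metadata
#'
#' @param values_path TSV with feature ids in the first column and one column
#'   per sample.
#' @param meta_path TSV with columns `sample`, `condition`, `time_h`,
#'   `replicate`; row order defines column matching by sample name.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(values_path, meta_path) {
  vals <- utils::read.delim(values_path, row.names = 1, check.names = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(meta)) stop("metadata needs a 'sample' column")
  miss <- setdiff(meta$sample, colnames(vals))
  if (length(miss)) stop("metadata samples absent from matrix: ",
                         paste(miss, collapse = ", "))
  vals <- as.matrix(vals[, meta$sample, drop = FALSE])
  expression_matrix(vals, meta[, c("condition", "time_h", "replicate")])
}

#' Write an expression matrix and sample metadata as TSV
#' @param matrix an [expression_matrix()].
#' @param values_path,meta_path output paths.
#' @return `values_path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, values_path, meta_path) {
  df <- data.frame(feature_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample = colnames(matrix$values), matrix$sample_meta)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}

#' Read a two-column edge list
#' @param path TSV with two columns (no header) of node ids.
#' @param directed logical; interpret pairs as regulator -> target.
#' @return An [edge_list()].
#' @export
read_edge_list <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0)
    return(edge_list(character(0), character(0), directed = directed))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs two tab-separated columns")
  edge_list(df[[1]], df[[2]], directed = directed)
}

#' Write an edge list as two-column TSV
#' @param edges an [edge_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("from", "to")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
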