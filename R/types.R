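#' Construct a differential feature table
#'
#' A differential table holds per-feature effect estimates from one
#' differential analysis (one omics layer at one time point): a log2
#' fold-change, a raw p-value, a false-discovery-rate adjusted value, and an
#' optional status label (`up`, `down`, `stable`, `not_expressed`).
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param log2fc numeric log2 fold-changes (finite).
#' @param p_value numeric raw p-values in `[0, 1]`.
#' @param fdr numeric adjusted p-values in `[0, 1]`.
#' @param status optional character vector of status labels; `NA` entries are
#'   allowed and mean "not yet derived".
#' @return A `data.frame` of class `differential_table`.
#' @export
differential_table <- function(feature_id, log2fc, p_value, fdr, status = NULL) {
  feature_id <- as.character(feature_id)
  n <- length(feature_id)
  if (anyDuplicated(feature_id))
    stop("duplicate feature_id: ",
         paste(unique(feature_id[duplicated(feature_id)])[1:min(3, n)], collapse = ", "))
  log2fc <- as.numeric(log2fc)
  p_value <- as.numeric(p_value)
  fdr <- as.numeric(fdr)
  if (length(log2fc) != n || length(p_value) != n || length(fdr) != n)
    stop("all columns must have the same length")
  if (anyNA(log2fc) || any(!is.finite(log2fc)))
    stop("log2fc must be finite and non-missing")
  .check_prob(p_value, "p_value")
  .check_prob(fdr, "fdr")
  if (is.null(status)) status <- rep(NA_character_, n)
  status <- as.character(status)
  ok <- is.na(status) | status %in% c("up", "down", "stable", "not_expressed")
  if (!all(ok))
    stop("unknown status label(s): ", paste(unique(status[!ok]), collapse = ", "))
  out <- data.frame(feature_id = feature_id, log2fc = log2fc,
                    p_value = p_value, fdr = fdr, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_table", "data.frame")
  out
}

.check_prob <- function(x, name) {
  if (anyNA(x)) stop(name, " must not contain missing values")
  if (any(x < 0 | x > 1)) stop(name, " must lie in [0, 1]")
  invisible(x)
}

#' Construct a peak set
#'
#' Genomic intervals in BED convention (0-based half-open) with an
#' accessibility label per peak: `gained`, `stable` or `lost`.
#'
#' @param chrom character chromosome names.
#' @param start,end integer interval bounds, `0 <= start < end`.
#' @param label accessibility label per peak.
#' @param peak_id optional unique identifiers; generated when missing.
#' @return A `data.frame` of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, label, peak_id = NULL) {
  chrom <- as.character(chrom)
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  label <- as.character(label)
  if (length(start) != n || length(end) != n || length(label) != n)
    stop("all columns must have the same length")
  if (anyNA(start) || anyNA(end)) stop("peak coordinates must not be missing")
  if (any(start < 0)) stop("peak start must be >= 0")
  bad <- which(start >= end)
  if (length(bad))
    stop("invalid interval (start >= end) at record ", bad[1])
  ok <- label %in% c("gained", "stable", "lost")
  if (!all(ok))
    stop("unknown peak label(s): ", paste(unique(label[!ok]), collapse = ", "))
  if (is.null(peak_id)) peak_id <- if (n) sprintf("peak_%d", seq_len(n)) else character(0)
  out <- data.frame(peak_id = as.character(peak_id), chrom = chrom,
                    start = start, end = end, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Construct a gene annotation
#'
#' Strand-aware transcription start sites: the anchor for window-based
#' linkage of open chromatin regions to genes.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param tss integer TSS coordinate (0-based), `>= 0`.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  tss <- as.integer(tss)
  if (anyNA(tss) || any(tss < 0)) stop("tss must be a non-negative integer")
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    tss = tss, strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Construct an expression matrix with sample metadata
#'
#' Log-scale feature-by-sample values plus per-column condition, time and
#' replicate annotations.
#'
#' @param values numeric matrix, rows = features, columns = samples; finite.
#' @param sample_meta `data.frame` with columns `condition`
#'   (`control`/`treated`), `time_h` (numeric) and `replicate` (integer);
#'   one row per column of `values`.
#' @return A list of class `expression_matrix` with elements `values` and
#'   `sample_meta`.
#' @export
expression_matrix <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be a finite numeric matrix")
  if (is.null(rownames(values))) stop("values must have feature rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids in rownames")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  req <- c("condition", "time_h", "replicate")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss)) stop("sample_meta missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(sample_meta) != ncol(values))
    stop("sample_meta must have one row per sample column")
  if (!all(sample_meta$condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  rownames(sample_meta) <- colnames(values)
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' Construct an edge list
#'
#' A simple graph given as node-id pairs. Self-loops are removed and
#' duplicate edges collapsed (for undirected graphs, regardless of
#' orientation).
#'
#' @param from,to character vectors of node ids.
#' @param directed logical; `TRUE` for regulator-to-target networks.
#' @return A `data.frame` of class `edge_list` with attribute `directed`.
#' @export
edge_list <- function(from, to, directed = FALSE) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop("from and to must have the same length")
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  if (directed) {
    key <- paste(from, to, sep = "\r")
  } else {
    key <- ifelse(from < to, paste(from, to, sep = "\r"), paste(to, from, sep = "\r"))
  }
  dup <- duplicated(key)
  out <- data.frame(from = from[!dup], to = to[!dup], stringsAsFactors = FALSE)
  attr(out, "directed") <- isTRUE(directed)
  class(out) <- c("edge_list", "data.frame")
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$sample_meta$condition, x$sample_meta$time_h)
  cat("samples by condition x time_h:\n")
  print(tab)
  invisible(x)
}

#' Nodes of an edge list
#' @param edges an `edge_list`.
#' @return Character vector of unique node ids.
#' @export
edge_list_nodes <- function(edges) {
  unique(c(edges$from, edges$to))
}

#' Convert an edge list to an igraph graph
#' @param edges an `edge_list`.
#' @param nodes optional full node universe (isolated nodes retained).
#' @return An `igraph` graph.
#' @export
as_igraph <- function(edges, nodes = NULL) {
  directed <- isTRUE(attr(edges, "directed"))
  if (is.null(nodes)) nodes <- edge_list_nodes(edges)
  igraph::graph_from_data_frame(edges[, c("from", "to")], directed = directed,
                                vertices = data.frame(name = nodes))
}
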