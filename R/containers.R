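## Core data containers shared by the pipeline stages.

#' Gene-level count matrix with gene lengths
#'
#' Bundles a genes x samples matrix of non-negative integer read counts with
#' per-gene exon lengths (needed for RPKM).
#'
#' @param values Integer matrix, genes in rows, samples in columns. Must have
#'   row and column names.
#' @param gene_length_bp Numeric vector of per-gene lengths in base pairs,
#'   recycled if scalar; all entries must be positive.
#' @return An object of class `count_matrix` with elements `values`,
#'   `gene_ids`, `sample_ids`, `gene_length_bp`.
#' @export
count_matrix <- function(values, gene_length_bp) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix needs gene (row) and sample (column) names")
  if (any(values < 0)) stop("counts must be non-negative")
  gene_length_bp <- rep_len(as.numeric(gene_length_bp), nrow(values))
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be positive")
  names(gene_length_bp) <- rownames(values)
  structure(
    list(values = values, gene_ids = rownames(values),
         sample_ids = colnames(values), gene_length_bp = gene_length_bp),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Time-series sample design
#'
#' Maps each sample to its condition (e.g. trehalose pretreatment or
#' rehydration), time label, and replicate index.
#'
#' @param sample Character vector of sample identifiers.
#' @param condition Character vector, one level per experimental arm.
#' @param time_h Numeric time in hours for each sample.
#' @param replicate Integer replicate index.
#' @return A `data.frame` of class `time_series_design`.
#' @export
time_series_design <- function(sample, condition, time_h, replicate) {
  d <- data.frame(sample = as.character(sample),
                  condition = as.character(condition),
                  time_h = as.numeric(time_h),
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample)) stop("duplicate sample ids in design")
  class(d) <- c("time_series_design", "data.frame")
  d
}

#' Position weight matrix
#'
#' @param id Motif identifier.
#' @param matrix Numeric matrix, positions in rows, columns named A, C, G, T;
#'   each row must sum to 1 (tolerance 1e-6) and the motif must span at least
#'   4 positions.
#' @param tf Identifier of the transcription factor the motif belongs to
#'   (optional).
#' @return An object of class `pwm`.
#' @export
pwm <- function(id, matrix, tf = NA_character_) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  colnames(matrix) <- c("A", "C", "G", "T")
  if (nrow(matrix) < 4) stop("PWM must span at least 4 positions")
  if (any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("PWM rows must sum to 1")
  structure(list(id = id, matrix = matrix, tf = tf), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%d bp, TF %s), consensus %s\n",
              x$id, nrow(x$matrix), x$tf, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (argmax base per position, ties to the
#' first of A, C, G, T)
#'
#' @param x A [pwm()] object.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(colnames(x$matrix)[apply(x$matrix, 1, which.max)], collapse = "")
}

#' Signed directed regulatory network
#'
#' @param edges `data.frame` with columns `source`, `target`, `sign`
#'   (+1/-1), and optionally `score`, `conditions`, `lag1_cc`, `conflict`.
#' @param nodes Character vector of node identifiers; defaults to the union of
#'   edge endpoints.
#' @return An object of class `signed_network`.
#' @export
signed_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("source", "target", "sign")
  if (!all(required %in% names(edges)))
    stop("edges need columns source, target, sign")
  if (nrow(edges)) {
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    if (anyDuplicated(edges[c("source", "target")]))
      stop("at most one edge per ordered pair")
    if (!all(edges$sign %in% c(-1, 1))) stop("edge signs must be +1 or -1")
  }
  for (col in c("score", "lag1_cc")) if (is.null(edges[[col]]))
    edges[[col]] <- NA_real_
  if (is.null(edges$conditions)) edges$conditions <- NA_character_
  if (is.null(edges$conflict)) edges$conflict <- FALSE
  nodes <- sort(unique(c(nodes, edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  invisible(x)
}

## Signed adjacency matrix (+1/-1/0) for a signed_network.
sign_matrix <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$nodes)
  S <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges))
    S[cbind(net$edges$source, net$edges$target)] <- net$edges$sign
  S
}
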