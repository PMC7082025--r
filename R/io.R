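## Plain-text readers and writers for the pipeline's artifacts.

#' Write counts (with gene lengths) as TSV
#'
#' Columns: gene_id, gene_length_bp, then one column per sample.
#' @param counts A [count_matrix()].
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = counts$gene_ids,
                   gene_length_bp = counts$gene_length_bp,
                   counts$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read counts written by [write_counts_tsv()]
#' @param path Input file.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$gene_id
  count_matrix(values, df$gene_length_bp)
}

#' Write / read a time-series design as TSV
#' @param design A [time_series_design()].
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  time_series_design(df$sample, df$condition, df$time_h, df$replicate)
}

#' Write promoter sequences as FASTA (record id = gene id)
#' @param promoters Named character vector of sequences.
#' @param path Output file.
#' @export
write_promoters_fasta <- function(promoters, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}

#' Read promoters from FASTA as a named character vector
#' @param path Input file.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write PWMs in MEME minimal format
#' @param pwm_set List of [pwm()] objects.
#' @param path Output file.
#' @export
write_meme <- function(pwm_set, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwm_set) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a MEME minimal file
#' @param path Input file.
#' @return List of [pwm()] objects (TF ids are not stored in MEME and come
#'   back as `NA`).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(s) {
    id <- sub("^MOTIF +", "", lines[s])
    w_line <- grep("letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[w_line]))
    m <- do.call(rbind, lapply(lines[(w_line + 1):(w_line + w)], function(l)
      as.numeric(strsplit(trimws(l), " +")[[1]])))
    m <- m / rowSums(m)  # guard rounding from the fixed-precision dump
    pwm(id, m)
  })
}

#' Write a signed network edge list as TSV
#' @param net A [signed_network()].
#' @param path Output file.
#' @export
write_network_tsv <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signed network edge list written by [write_network_tsv()]
#' @param path Input file.
#' @export
read_network_tsv <- function(path) {
  signed_network(read.delim(path, stringsAsFactors = FALSE))
}

#' Export a signed network to GraphML
#' @param net A [signed_network()].
#' @param path Output file.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

## Manifest of written files with MD5 checksums.
build_manifest <- function(paths) {
  data.frame(file = basename(unlist(paths)),
             md5 = unname(tools::md5sum(unlist(paths))),
             stringsAsFactors = FALSE, row.names = NULL)
}
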