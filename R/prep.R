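## Expression preprocessing (RPKM, PCA) and time-course differential
## expression by a per-gene negative-binomial likelihood-ratio test.

#' RPKM transformation
#'
#' `rpkm = 1e9 * count / (gene_length_bp * sample_total)`.
#'
#' @param counts A [count_matrix()].
#' @return Numeric genes x samples matrix.
#' @export
rpkm_transform <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- colSums(counts$values)
  if (any(totals <= 0)) stop("zero library size in sample(s): ",
                             paste(counts$sample_ids[totals <= 0], collapse = ", "))
  1e9 * sweep(counts$values / counts$gene_length_bp, 2, totals, "/")
}

#' Principal components of samples
#'
#' PCA of the centered samples-by-genes matrix; contribution ratios are the
#' eigenvalue fractions of the sample covariance.
#'
#' @param rpkm Genes x samples matrix (e.g. from [rpkm_transform()]).
#' @param n_components Number of components to return scores for.
#' @return List of class `pca_result` with `scores` (sample x component) and
#'   `contribution_ratio` over all components.
#' @export
principal_components <- function(rpkm, n_components = 3L) {
  if (ncol(rpkm) < 2) stop("need at least two samples")
  x <- t(rpkm)
  if (all(apply(x, 2, var) < .Machine$double.eps)) {
    warning("constant expression matrix; contribution ratios undefined")
    k <- min(n_components, ncol(rpkm))
    return(structure(list(
      scores = matrix(0, ncol(rpkm), k,
                      dimnames = list(colnames(rpkm), paste0("PC", seq_len(k)))),
      contribution_ratio = rep(0, k)), class = "pca_result"))
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ratio <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_components, ncol(fit$x))
  structure(list(scores = fit$x[, seq_len(k), drop = FALSE],
                 contribution_ratio = ratio),
            class = "pca_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

## Method-of-moments estimate of the NB dispersion shared across time points
## of one gene, on counts rescaled to a common library size.
mom_dispersion <- function(scaled_counts, group, floor = 1e-8) {
  ms <- tapply(scaled_counts, group, mean)
  vs <- tapply(scaled_counts, group, var)
  num <- sum(vs - ms, na.rm = TRUE)
  den <- sum(ms^2, na.rm = TRUE)
  max(floor, if (den > 0) num / den else floor)
}

#' Negative-binomial likelihood-ratio test for a time course
#'
#' Per gene, compares a full NB log-link model with one mean per time point
#' against a reduced single-mean model, both with library-total offsets and a
#' shared gene-wise method-of-moments dispersion (floored at 1e-8). Because
#' the dispersion is estimated from few replicates, the statistic
#' `2 * (l_full - l_reduced)` divided by its `n_timepoints - 1` degrees of
#' freedom is referred to an F distribution with residual denominator df
#' (the quasi-likelihood convention), which keeps the test calibrated at
#' small replicate numbers; p-values are Benjamini-Hochberg adjusted within
#' the condition.
#'
#' @param counts A [count_matrix()].
#' @param design A [time_series_design()].
#' @param condition Condition label to test.
#' @param go_annotation Optional `data.frame(gene, go)`; genes annotated with
#'   `tf_go` are flagged as transcription factors.
#' @param alpha FDR cutoff for the `is_deg` flag.
#' @param tf_go GO identifier marking DNA-binding transcription factor
#'   activity.
#' @return `data.frame` of class `deg_table`: gene, lrt_statistic, df,
#'   p_value, fdr, is_deg, is_tf, flagged (all-zero or failed fits).
#' @export
nb_lrt <- function(counts, design, condition, go_annotation = NULL,
                   alpha = 0.05, tf_go = "GO:0003700") {
  stopifnot(inherits(counts, "count_matrix"))
  des <- design[design$condition == condition, , drop = FALSE]
  if (!nrow(des)) stop("unknown condition: ", condition)
  tab <- table(des$time_h)
  if (length(tab) < 2 || any(tab < 2))
    stop("condition needs >= 2 time points with >= 2 replicates each")
  y <- counts$values[, des$sample, drop = FALSE]
  totals <- colSums(y)
  tp <- factor(des$time_h)
  off <- log(totals)
  scale_fac <- mean(totals) / totals

  genes <- counts$gene_ids
  n_tp <- nlevels(tp)
  stat <- rep(NA_real_, length(genes)); pval <- rep(1, length(genes))
  flagged <- rep(FALSE, length(genes))
  for (i in seq_along(genes)) {
    yi <- y[i, ]
    if (all(yi == 0)) { flagged[i] <- TRUE; next }
    phi <- mom_dispersion(yi * scale_fac, tp)
    fam <- negative.binomial(theta = 1 / phi)
    fit <- tryCatch({
      full <- glm(yi ~ tp + offset(off), family = fam)
      red <- glm(yi ~ 1 + offset(off), family = fam)
      2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
    }, error = function(e) NA_real_, warning = function(w) {
      ## refit quietly; glm warnings here are convergence chatter
      full <- suppressWarnings(glm(yi ~ tp + offset(off), family = fam))
      red <- suppressWarnings(glm(yi ~ 1 + offset(off), family = fam))
      2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
    })
    if (is.na(fit)) { flagged[i] <- TRUE; next }
    stat[i] <- max(0, fit)
    df1 <- n_tp - 1; df2 <- length(yi) - n_tp
    pval[i] <- if (df2 > 0)
      pf(stat[i] / df1, df1, df2, lower.tail = FALSE)
    else pchisq(stat[i], df = df1, lower.tail = FALSE)
  }

  fdr <- rep(1, length(genes))
  tested <- !flagged
  if (any(tested)) fdr[tested] <- bh_adjust(pval[tested])
  is_tf <- rep(FALSE, length(genes))
  if (!is.null(go_annotation))
    is_tf <- genes %in% go_annotation$gene[go_annotation$go == tf_go]
  out <- data.frame(gene = genes, lrt_statistic = stat, df = n_tp - 1,
                    p_value = pval, fdr = fdr, is_deg = fdr < alpha & tested,
                    is_tf = is_tf, flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "condition") <- condition
  out
}

#' Partition differentially expressed genes into TFs and targets
#'
#' Splits DEGs of each condition by GO:0003700 annotation and reports the
#' condition-exclusive and shared counts for each class (the four-way Venn of
#' the two-condition design).
#'
#' @param deg_list Named list of [nb_lrt()] tables, one per condition (two
#'   conditions expected).
#' @param go_annotation `data.frame(gene, go)`.
#' @param tf_go GO identifier defining the TF class.
#' @return List with `tf` and `other`, each containing per-cell counts and
#'   gene-id sets (`only_<condition>` and `both`).
#' @export
partition_tf_targets <- function(deg_list, go_annotation,
                                 tf_go = "GO:0003700") {
  stopifnot(length(deg_list) == 2, !is.null(names(deg_list)))
  tf_genes <- unique(go_annotation$gene[go_annotation$go == tf_go])
  degs <- lapply(deg_list, function(d) d$gene[d$is_deg])
  conds <- names(deg_list)
  split_class <- function(keep) {
    a <- intersect(degs[[1]], keep); b <- intersect(degs[[2]], keep)
    both <- intersect(a, b)
    sets <- list(setdiff(a, both), setdiff(b, both), both)
    names(sets) <- c(paste0("only_", conds[1]), paste0("only_", conds[2]),
                     "both")
    list(counts = lengths(sets), sets = sets)
  }
  all_genes <- unique(unlist(degs))
  list(tf = split_class(tf_genes),
       other = split_class(setdiff(all_genes, tf_genes)))
}
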