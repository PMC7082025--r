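## Coexpression module detection: soft-thresholded correlation adjacency,
## topological overlap dissimilarity, average-linkage clustering with a
## pseudo-F selected minimum module size, and GO enrichment.

## WGCNA-style module color palette, assigned by decreasing module size.
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "white")
UNASSIGNED <- "grey"

## Scale-free fit index of a connectivity vector: equal-width binning of k,
## log10 of the per-bin node proportion regressed on log10 of the mean k.
## signed R2 = -sign(slope) * R2, so scale-free (decaying) fits score > 0.
scale_free_index <- function(k, n_bins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  p <- tapply(k, bin, length) / length(k)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(p) & p > 0 & mk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- lm(log10(p[keep]) ~ log10(mk[keep]))
  -sign(coef(fit)[2]) * summary(fit)$r.squared
}

#' Select the soft-thresholding power
#'
#' For each candidate power the unsigned adjacency `|cor|^power` is formed
#' and node connectivity is tested for a scale-free degree law; the selected
#' power is the smallest whose signed fit R-squared exceeds the threshold.
#'
#' @param expression Gene x sample matrix (Z-scores or any expression scale;
#'   Pearson correlation is scale-free).
#' @param powers Candidate integer powers.
#' @param r2_threshold Signed R-squared needed to qualify.
#' @return List of class `soft_power_selection` with `selected_power` and the
#'   per-power `table`.
#' @export
select_soft_power <- function(expression, powers = 1:20,
                              r2_threshold = 0.75) {
  if (nrow(expression) < 3) stop("need at least three genes")
  cmat <- abs(cor(t(expression)))
  diag(cmat) <- 0
  ks <- lapply(powers, function(b) rowSums(cmat^b))
  r2 <- vapply(ks, scale_free_index, numeric(1))
  mean_k <- vapply(ks, mean, numeric(1))
  tab <- data.frame(power = powers, signed_r_squared = r2, mean_k = mean_k)
  ## a power whose network retains less than one neighbour per gene on
  ## average is vacuous no matter how well the handful of occupied bins fit
  qual <- which(!is.na(r2) & r2 > r2_threshold & mean_k >= 1)
  if (!length(qual)) {
    best <- if (all(is.na(r2))) NA_integer_ else powers[which.max(r2)]
    stop(sprintf("no power reaches signed R^2 > %.2f (best: power %s, R^2 = %.3f)",
                 r2_threshold, best, suppressWarnings(max(r2, na.rm = TRUE))))
  }
  structure(list(selected_power = powers[qual[1]], table = tab,
                 r2_threshold = r2_threshold),
            class = "soft_power_selection")
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` with `TOM_ii = 1`; the dissimilarity is `1 - TOM`.
#'
#' @param adjacency Symmetric matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @return List of class `tom_matrix` with `tom` and `dissimilarity`.
#' @export
tom_dissimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  structure(list(tom = tom, dissimilarity = 1 - tom), class = "tom_matrix")
}

#' Calinski-Harabasz pseudo-F
#'
#' Ratio of between- to within-cluster dispersion,
#' `(BSS / (k - 1)) / (WSS / (n - k))`.
#'
#' @param x Observation x variable matrix (a vector is treated as one
#'   variable).
#' @param labels Cluster assignment, one label per observation; at least two
#'   clusters are required.
#' @return Numeric pseudo-F (Inf when WSS is zero).
#' @export
pseudo_f <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  k <- length(unique(labels)); n <- nrow(x)
  if (k < 2) stop("pseudo-F needs at least two clusters")
  if (k >= n) stop("pseudo-F needs fewer clusters than observations")
  centroid <- colMeans(x)
  wss <- 0; bss <- 0
  for (lab in unique(labels)) {
    xi <- x[labels == lab, , drop = FALSE]
    ci <- colMeans(xi)
    wss <- wss + sum(sweep(xi, 2, ci)^2)
    bss <- bss + nrow(xi) * sum((ci - centroid)^2)
  }
  if (wss == 0) return(Inf)
  (bss / (k - 1)) / (wss / (n - k))
}

#' Detect coexpression modules with a pseudo-F selected minimum size
#'
#' Builds one average-linkage dendrogram from the TOM dissimilarity, then
#' scans cut granularities (2 to `max_clusters` clusters). For each candidate
#' minimum module size, clusters below the size threshold are collected into
#' the designated unassigned module and the Calinski-Harabasz pseudo-F of the
#' remaining partition is computed on the expression profiles; the size
#' maximizing pseudo-F (ties to the smallest size) and its best cut give the
#' final partition. Modules are named by the conventional color palette in
#' decreasing size order; the unassigned module is `grey`.
#'
#' @param dissimilarity A [tom_dissimilarity()] result or a plain
#'   dissimilarity matrix.
#' @param profiles Gene x sample matrix used for pseudo-F (typically
#'   Z-scores).
#' @param size_range Candidate minimum module sizes.
#' @param max_clusters Largest number of dendrogram clusters scanned.
#' @return List of class `module_partition`: `assignment` (gene, module),
#'   `profiles` (module mean Z-score profiles), `min_cluster_size`,
#'   `pseudo_f_by_size`, `selected_k`.
#' @export
cluster_modules <- function(dissimilarity, profiles, size_range = 1:200,
                            max_clusters = 30L) {
  d <- if (inherits(dissimilarity, "tom_matrix")) dissimilarity$dissimilarity
    else as.matrix(dissimilarity)
  n <- nrow(d)
  if (n < 2) stop("need at least two genes")
  if (min(size_range) > n) stop("fewer genes than the smallest candidate size")
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == n)
  hc <- hclust(as.dist(d), method = "average")
  ks <- 2:min(max_clusters, n - 1)
  cuts <- lapply(ks, function(k) cutree(hc, k = k))

  best_f <- rep(-Inf, length(size_range))
  best_cut <- rep(NA_integer_, length(size_range))
  cache <- new.env(parent = emptyenv())
  for (ki in seq_along(ks)) {
    cl <- cuts[[ki]]
    sz <- table(cl)
    for (si in seq_along(size_range)) {
      s <- size_range[si]
      big <- names(sz)[sz >= s]
      if (length(big) < 2) next
      key <- paste(ki, paste(sort(big), collapse = ","))
      f <- cache[[key]]
      if (is.null(f)) {
        ## undersized clusters are pooled into the unassigned label, which
        ## competes as one (incoherent) cluster so that discarding genes
        ## cannot inflate the index
        lab <- ifelse(cl %in% big, as.character(cl), UNASSIGNED)
        f <- if (length(unique(lab)) < n)
          pseudo_f(profiles, lab) else -Inf
        cache[[key]] <- f
      }
      if (f > best_f[si]) { best_f[si] <- f; best_cut[si] <- ki }
    }
  }
  if (all(!is.finite(best_f)))
    stop("no candidate size admits a partition with >= 2 modules")
  sel <- which.max(best_f)              # first max = smallest size on ties
  s_star <- size_range[sel]
  cl <- cuts[[best_cut[sel]]]
  sz <- table(cl)
  big <- names(sz)[sz >= s_star]
  module <- rep(UNASSIGNED, n)
  ord <- big[order(-sz[big])]
  colors <- c(MODULE_COLORS, sprintf("module%02d", seq_len(max(0,
    length(ord) - length(MODULE_COLORS)))))
  for (i in seq_along(ord)) module[cl == ord[i]] <- colors[i]
  names(module) <- rownames(d)

  prof <- do.call(rbind, lapply(split(seq_len(n), module), function(ix)
    colMeans(profiles[ix, , drop = FALSE])))
  structure(list(
    assignment = data.frame(gene = rownames(d), module = module,
                            stringsAsFactors = FALSE, row.names = NULL),
    profiles = prof, min_cluster_size = s_star,
    pseudo_f_by_size = data.frame(size = size_range, pseudo_f = best_f),
    selected_k = ks[best_cut[sel]]), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$assignment$module)
  cat(sprintf("module_partition: %d modules (minClusterSize %d)\n",
              sum(names(tab) != UNASSIGNED), x$min_cluster_size))
  print(tab)
  invisible(x)
}

#' GO enrichment of modules by one-sided Fisher's exact test
#'
#' For each (module, GO) pair, tests over-representation of the annotation in
#' the module against the gene universe via the hypergeometric upper tail
#' (equivalent to one-sided Fisher's exact test). No multiple-testing
#' correction is applied; terms with p < `alpha` are flagged enriched.
#'
#' @param partition A [cluster_modules()] result (or a data.frame gene,
#'   module).
#' @param go_annotation `data.frame(gene, go)`.
#' @param universe Character vector of all genes considered.
#' @param alpha Enrichment p-value cutoff.
#' @return `data.frame` of class `go_enrichment`: module, go, overlap,
#'   module_size, term_size, p, enriched; plus attribute `representative`
#'   (min-p GO per module).
#' @export
go_enrichment <- function(partition, go_annotation, universe, alpha = 0.05) {
  assign <- if (inherits(partition, "module_partition"))
    partition$assignment else as.data.frame(partition)
  if (!all(assign$gene %in% universe))
    stop("universe must contain every module gene")
  universe <- unique(universe)
  n_univ <- length(universe)
  go_annotation <- go_annotation[go_annotation$gene %in% universe, ]
  go_sets <- split(go_annotation$gene, go_annotation$go)
  rows <- list()
  for (mod in unique(assign$module)) {
    members <- assign$gene[assign$module == mod]
    for (go in names(go_sets)) {
      hits <- go_sets[[go]]
      a <- length(intersect(members, hits))
      p <- phyper(a - 1, length(hits), n_univ - length(hits),
                  length(members), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, go = go, overlap = a, module_size = length(members),
        term_size = length(hits), p = p, enriched = p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(module = character(), go = character(),
                                      overlap = integer(),
                                      module_size = integer(),
                                      term_size = integer(), p = numeric(),
                                      enriched = logical())
  class(out) <- c("go_enrichment", "data.frame")
  rep_rows <- do.call(rbind, lapply(split(out, out$module), function(d)
    d[which.min(d$p), , drop = FALSE]))
  attr(out, "representative") <- rep_rows
  out
}
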