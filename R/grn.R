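## Inference of signed transcriptional regulatory networks among TFs from
## time-series expression: boosted-tree regulator scoring, scale-free
## threshold selection, lag-1 cross-correlation signs, and integration of the
## per-condition networks.

## Normalize input to a list of TF x time matrices (one per replicate).
as_replicate_list <- function(tf_expression) {
  if (is.matrix(tf_expression)) list(tf_expression)
  else if (is.list(tf_expression)) tf_expression
  else stop("tf_expression must be a matrix or a list of replicate matrices")
}

## Total split gain per named feature, parsed from the booster's text dump
## (split lines look like "1:[TF07<0.43] yes=3,no=4,...,gain=12.3,cover=57").
gain_importance <- function(booster, feature_names) {
  dump <- xgboost::xgb.dump(booster, with_stats = TRUE)
  splits <- grep("\\[.+<", dump, value = TRUE)
  gain <- setNames(numeric(length(feature_names)), feature_names)
  if (!length(splits)) return(gain)
  feat <- sub("^[0-9]+:\\[(.+)<.*", "\\1", splits)
  g <- as.numeric(sub(".*gain=([-0-9.eE+]+),.*", "\\1", splits))
  for (i in seq_along(feat)) gain[feat[i]] <- gain[feat[i]] + g[i]
  gain
}

#' Score candidate regulators with boosted regression trees
#'
#' For each target TF, a gradient-boosted tree ensemble predicts its
#' expression at time `t` from all other TFs at `t - lag`, pooling replicates
#' as separate training pairs. The score of regulator `j` for target `i` is
#' the total split gain attributed to feature `j`, normalized so each
#' target's scores sum to 1 (all zero when the ensemble makes no splits).
#'
#' @param tf_expression TF x time matrix (RPKM), or a list of such matrices,
#'   one per replicate.
#' @param n_trees Number of boosting rounds.
#' @param lag Time lag between features and response.
#' @param seed Integer seed.
#' @param eta,max_depth Boosting hyperparameters (learning rate, tree depth).
#' @return Regulator x target matrix of class `score_matrix`; the diagonal is
#'   `NA` (self-regulation is not scored).
#' @export
score_regulators <- function(tf_expression, n_trees = 100L, lag = 1L,
                             seed = 1L, eta = 0.1, max_depth = 3L) {
  reps <- as_replicate_list(tf_expression)
  tfs <- rownames(reps[[1]])
  if (length(tfs) < 2) stop("need at least two TFs")
  n_time <- ncol(reps[[1]])
  if (n_time < lag + 2) stop("need at least lag + 2 time points")

  ## training pairs: columns t - lag (features) vs t (response)
  Xlag <- do.call(cbind, lapply(reps, function(m)
    m[, seq_len(n_time - lag), drop = FALSE]))
  Xnow <- do.call(cbind, lapply(reps, function(m)
    m[, (lag + 1):n_time, drop = FALSE]))

  S <- matrix(NA_real_, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (target in tfs) {
    others <- setdiff(tfs, target)
    y <- Xnow[target, ]
    S[others, target] <- 0
    if (var(y) < .Machine$double.eps) {
      warning("constant target series for ", target, "; scores set to 0")
      next
    }
    feats <- t(Xlag[others, , drop = FALSE])
    set.seed(seed)
    dm <- xgboost::xgb.DMatrix(feats, label = y, nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(eta = eta, max_depth = max_depth, subsample = 1,
                    objective = "reg:squarederror", nthread = 1),
      data = dm, nrounds = n_trees)
    gain <- gain_importance(booster, others)
    if (sum(gain) > 0)
      S[others, target] <- gain / sum(gain)
  }
  structure(S, class = c("score_matrix", "matrix"))
}

#' Fit the scale-free degree law by log-log regression
#'
#' The empirical degree distribution `p(k)` over distinct observed degrees is
#' regressed as `log10 p(k) = -gamma * log10 k + log10 C`. A scale-free
#' network yields a negative fitted slope, reported here as `gamma = -slope`
#' (positive for a decaying degree law). `f_test_p` is the regression
#' F-test p-value; threshold selection additionally gates on the slope sign.
#'
#' @param degrees Vector of positive integer node degrees.
#' @return List of class `scale_free_fit` with `gamma`, `log10_C`, `slope`,
#'   `r_squared`, `f_test_p`, `n_degree_bins`, and `defined`.
#' @export
fit_scale_free <- function(degrees) {
  degrees <- degrees[degrees > 0]
  k <- sort(unique(degrees))
  if (length(k) < 2)
    return(structure(list(gamma = NA_real_, log10_C = NA_real_,
                          slope = NA_real_, r_squared = NA_real_,
                          f_test_p = NA_real_, n_degree_bins = length(k),
                          defined = FALSE), class = "scale_free_fit"))
  pk <- as.vector(table(factor(degrees, levels = k))) / length(degrees)
  fit <- lm(log10(pk) ~ log10(k))
  slope <- unname(coef(fit)[2])
  sm <- suppressWarnings(summary(fit))   # quiet on numerically perfect fits
  r2 <- sm$r.squared
  ## the regression F-test (one-sided in the F distribution); the sign of
  ## the slope is gated separately by the threshold-selection rule
  p1 <- unname(if (is.null(sm$fstatistic) || !is.finite(slope)) 1 else
    pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
       lower.tail = FALSE))
  if (!is.finite(p1)) p1 <- 1     # perfectly flat p(k): no evidence either way
  structure(list(gamma = -slope, log10_C = unname(coef(fit)[1]),
                 slope = slope, r_squared = r2, f_test_p = p1,
                 n_degree_bins = length(k), defined = TRUE),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("scale_free_fit: gamma = %.3f, R2 = %.3f, one-sided F p = %.3g (%d degree values)\n",
              x$gamma, x$r_squared, x$f_test_p, x$n_degree_bins))
  invisible(x)
}

## Min-max normalize scores to [0, 1], preserving NA diagonal.
normalize_scores <- function(scores) {
  v <- scores[!is.na(scores)]
  rng <- range(v)
  if (diff(rng) == 0) return(scores - rng[1])
  (scores - rng[1]) / diff(rng)
}

## Edge list above threshold a from a (normalized) score matrix.
edges_at <- function(norm, a) {
  keep <- which(!is.na(norm) & norm >= a, arr.ind = TRUE)
  data.frame(source = rownames(norm)[keep[, 1]],
             target = colnames(norm)[keep[, 2]],
             score = norm[keep], stringsAsFactors = FALSE)
}

#' Select a score threshold by the scale-free criterion
#'
#' Scores are min-max normalized to \[0, 1\]; each distinct value is a
#' candidate threshold `a`. For each candidate the network keeps edges with
#' score >= `a`, node degrees (in + out, isolated nodes excluded) are fitted
#' with [fit_scale_free()], and the selected threshold is the minimum
#' candidate whose fitted log-log slope is negative with one-sided F-test
#' p < 0.05.
#'
#' @param scores A [score_regulators()] matrix.
#' @param alpha Significance level of the F-test.
#' @param r2_min Minimum R-squared of the log-log fit for a candidate to
#'   qualify; guards against spurious significance of poorly fitting dense
#'   graphs (set to 0 to disable the gate).
#' @param max_candidates When the number of distinct scores exceeds this, a
#'   quantile-spaced subset of the distinct values is scanned instead.
#' @return List of class `threshold_scan` with `selected_a`, the per-candidate
#'   `scan` table, and the normalized score matrix.
#' @export
select_threshold <- function(scores, alpha = 0.05, r2_min = 0.6,
                             max_candidates = 200L) {
  norm <- normalize_scores(scores)
  cand <- sort(unique(norm[!is.na(norm)]))
  if (!length(cand)) stop("empty score matrix")
  if (length(cand) > max_candidates)
    cand <- unique(quantile(cand, probs = seq(0, 1, length.out = max_candidates),
                            type = 1, names = FALSE))
  rows <- lapply(cand, function(a) {
    ed <- edges_at(norm, a)
    deg <- table(c(ed$source, ed$target))
    fit <- fit_scale_free(as.integer(deg))
    data.frame(a = a, n_edges = nrow(ed), gamma = fit$gamma,
               slope = fit$slope, r_squared = fit$r_squared,
               f_test_p = fit$f_test_p, defined = fit$defined)
  })
  scan <- do.call(rbind, rows)
  ok <- scan$defined & !is.na(scan$slope) & scan$slope < 0 &
    scan$f_test_p < alpha & scan$r_squared >= r2_min
  if (!any(ok)) {
    best <- scan[scan$defined & !is.na(scan$slope) & scan$slope < 0, ]
    hint <- if (nrow(best)) sprintf(" (best candidate a = %.6g, F p = %.3g)",
                                    best$a[which.min(best$f_test_p)],
                                    min(best$f_test_p)) else ""
    stop("no threshold satisfies the scale-free criterion", hint)
  }
  structure(list(selected_a = scan$a[which(ok)[1]], scan = scan,
                 normalized_scores = norm, alpha = alpha),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan: %d candidates, selected a = %.6g\n",
              nrow(x$scan), x$selected_a))
  invisible(x)
}

## ccf-style normalized cross-correlation at positive lag (x leads y).
lag_crosscorr <- function(x, y, lag = 1L) {
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc[seq_len(n - lag)] * yc[(lag + 1):n]) /
    (n * sd(x) * sd(y) * (n - 1) / n)
}

#' Assign regulation signs by lag-1 cross-correlation
#'
#' Replicates are averaged per time point, then each edge receives the sign
#' of the normalized cross-correlation between its source (leading by `lag`)
#' and target series. Edges with zero or undefined cross-correlation are
#' dropped with a warning.
#'
#' @param edges `data.frame` with columns `source`, `target` (and optionally
#'   `score`).
#' @param tf_expression TF x time matrix or list of replicate matrices.
#' @param condition Condition label recorded on the edges.
#' @param lag Lag of the cross-correlation.
#' @return A [signed_network()].
#' @export
assign_signs <- function(edges, tf_expression, condition = NA_character_,
                         lag = 1L) {
  reps <- as_replicate_list(tf_expression)
  avg <- Reduce(`+`, reps) / length(reps)
  missing <- setdiff(unique(c(edges$source, edges$target)), rownames(avg))
  if (length(missing)) stop("no expression series for: ",
                            paste(missing, collapse = ", "))
  cc <- vapply(seq_len(nrow(edges)), function(i)
    lag_crosscorr(avg[edges$source[i], ], avg[edges$target[i], ], lag),
    numeric(1))
  drop <- is.na(cc) | cc == 0
  if (any(drop))
    warning(sum(drop), " edge(s) dropped: zero or undefined cross-correlation")
  edges <- edges[!drop, , drop = FALSE]
  cc <- cc[!drop]
  signed_network(data.frame(
    source = edges$source, target = edges$target,
    sign = as.integer(sign(cc)),
    score = if (is.null(edges$score)) NA_real_ else edges$score,
    conditions = condition, lag1_cc = cc, conflict = FALSE,
    stringsAsFactors = FALSE), nodes = rownames(avg))
}

#' Integrate two per-condition signed networks
#'
#' Node and edge union; edges present in both conditions keep one record with
#' both condition labels. When the same edge carries opposite signs, the sign
#' with the larger absolute cross-correlation wins and the edge is flagged as
#' a conflict.
#'
#' @param net_a,net_b [signed_network()] objects.
#' @return A [signed_network()].
#' @export
integrate_networks <- function(net_a, net_b) {
  ea <- net_a$edges; eb <- net_b$edges
  key <- function(e) paste(e$source, e$target, sep = "\r")
  eb_new <- eb[!(key(eb) %in% key(ea)), , drop = FALSE]
  merged <- ea
  common <- intersect(key(ea), key(eb))
  if (length(common)) {
    ia <- match(common, key(ea)); ib <- match(common, key(eb))
    merged$conditions[ia] <- paste(ea$conditions[ia], eb$conditions[ib],
                                   sep = ";")
    conflict <- ea$sign[ia] != eb$sign[ib]
    use_b <- conflict & abs(eb$lag1_cc[ib]) > abs(ea$lag1_cc[ia])
    merged$sign[ia][use_b] <- eb$sign[ib][use_b]
    merged$lag1_cc[ia][use_b] <- eb$lag1_cc[ib][use_b]
    merged$conflict[ia] <- conflict
    merged$score[ia] <- pmax(ea$score[ia], eb$score[ib])
  }
  signed_network(rbind(merged, eb_new),
                 nodes = union(net_a$nodes, net_b$nodes))
}
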