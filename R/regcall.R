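## TF -> module regulation calls: upstream motif enrichment by a best-hit
## randomization test over multiple window lengths, and time-series Granger
## causality (VAR F-test with BH correction). A call requires both.

BASES <- c("A", "C", "G", "T")

## Per-position log2 odds (bits) with probabilities floored at 1e-3 and
## renormalized; column 5 scores 0 for ambiguity codes.
pwm_logodds <- function(p) {
  m <- pmax(p$matrix, 1e-3)
  m <- m / rowSums(m)
  cbind(log2(m / 0.25), 0)
}

seq_codes <- function(sequence) {
  x <- match(strsplit(toupper(sequence), "")[[1]], BASES)
  x[is.na(x)] <- 5L
  x
}

revcomp_codes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[codes])
}

best_hit_codes <- function(lo, codes) {
  L <- nrow(lo); n <- length(codes)
  n_off <- n - L + 1L
  score <- numeric(n_off)
  for (j in seq_len(L))
    score <- score + lo[cbind(j, codes[j:(j + n_off - 1L)])]
  max(score)
}

#' Best-hit log-odds score of a PWM in a sequence
#'
#' Maximum over both strands and all offsets of the summed per-position
#' log2(p/0.25) score, with PWM probabilities floored at 1e-3 (and
#' renormalized); non-ACGT characters score as background (0 bits).
#'
#' @param pwm A [pwm()] object.
#' @param sequence Nucleotide string at least as long as the PWM.
#' @return Best-hit score in bits, or `NA` (with a warning) for sequences
#'   shorter than the PWM.
#' @export
scan_pwm <- function(pwm, sequence) {
  stopifnot(inherits(pwm, "pwm"))
  codes <- seq_codes(sequence)
  if (length(codes) < nrow(pwm$matrix)) {
    warning("sequence shorter than PWM; excluded")
    return(NA_real_)
  }
  lo <- pwm_logodds(pwm)
  max(best_hit_codes(lo, codes), best_hit_codes(lo, revcomp_codes(codes)))
}

## TSS-proximal window: upstream sequences are written 5'->3' ending at the
## transcription start, so a window keeps the last `w` bases.
truncate_window <- function(sequence, w) {
  n <- nchar(sequence)
  if (n <= w) sequence else substr(sequence, n - w + 1L, n)
}

#' Motif enrichment of module promoters by randomization
#'
#' Per window length, sequences are truncated to their TSS-proximal window
#' and the statistic is the mean best-hit PWM score over the module
#' promoters. The null distribution is the same statistic on random
#' equal-sized subsets of the background promoters;
#' `p = (1 + #(null >= observed)) / (1 + n_draws)`.
#'
#' @param pwm A [pwm()] object.
#' @param module_upstreams Named character vector of module promoter
#'   sequences.
#' @param background_upstreams Character vector of background promoters (at
#'   least as many as the module has).
#' @param window_lengths Window lengths in bp; windows shorter than the PWM
#'   are skipped.
#' @param n_draws Number of background resamples.
#' @param seed Integer seed.
#' @param alpha Per-window significance level.
#' @return List of class `motif_hit_result` with the per-window `table`
#'   (window, statistic, p) and `any_window_significant`.
#' @export
motif_enrichment <- function(pwm, module_upstreams, background_upstreams,
                             window_lengths = c(100, 500, 1000, 2000, 3000,
                                                4000, 5000, 10000),
                             n_draws = 1000L, seed = 1L, alpha = 0.05) {
  if (!length(module_upstreams)) stop("empty module sequence set")
  if (length(background_upstreams) < length(module_upstreams))
    stop("background set must be at least as large as the module set")
  if (n_draws < 1) stop("n_draws must be >= 1")
  set.seed(seed)
  L <- nrow(pwm$matrix)
  n_mod <- length(module_upstreams)
  rows <- list()
  for (w in window_lengths) {
    if (w < L) next
    ms <- vapply(module_upstreams, function(s)
      scan_pwm(pwm, truncate_window(s, w)), numeric(1))
    bs <- vapply(background_upstreams, function(s)
      scan_pwm(pwm, truncate_window(s, w)), numeric(1))
    ms <- ms[!is.na(ms)]; bs <- bs[!is.na(bs)]
    if (!length(ms) || length(bs) < n_mod) next
    obs <- mean(ms)
    null <- vapply(seq_len(n_draws), function(d)
      mean(bs[sample.int(length(bs), n_mod)]), numeric(1))
    p <- (1 + sum(null >= obs)) / (1 + n_draws)
    rows[[length(rows) + 1L]] <- data.frame(window = w, statistic = obs, p = p)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no window is at least as long as the PWM")
  structure(list(table = tab,
                 any_window_significant = min(tab$p) < alpha,
                 pwm = pwm$id, alpha = alpha),
            class = "motif_hit_result")
}

## Lagged design matrix: columns are series values at lags 1..p.
lag_matrix <- function(x, p, from) {
  sapply(seq_len(p), function(l) x[(from - l):(length(x) - l)])
}

## Multivariate AIC of a bivariate VAR(p), VARselect-style: all candidate
## orders are compared on the sample trimmed by max_lag.
var_aic <- function(cause, effect, p, max_lag) {
  Tn <- length(effect)
  from <- max_lag + 1L
  n_obs <- Tn - max_lag
  X <- cbind(1, lag_matrix(effect, p, from), lag_matrix(cause, p, from))
  resid <- vapply(list(effect, cause), function(y) {
    yy <- y[from:Tn]
    qr_fit <- lm.fit(X, yy)
    qr_fit$residuals
  }, numeric(n_obs))
  sigma <- crossprod(resid) / n_obs
  log(det(sigma)) + 2 * p * 4 / n_obs
}

#' Granger causality of a TF series on a module profile
#'
#' Fits a bivariate vector autoregression of (cause, effect); the lag order
#' is selected by AIC over `1..max_lag`, then the restriction that all
#' cause lags vanish from the effect equation is tested with a one-sided
#' F-test.
#'
#' @param tf_zscore Cause series (TF time-series Z-score).
#' @param module_mean_zscore Effect series (module mean Z-score).
#' @param max_lag Largest lag order considered.
#' @return List of class `granger_result`: `lag`, `f_statistic`, `p_value`,
#'   `flagged` (degenerate input).
#' @export
granger_causality <- function(tf_zscore, module_mean_zscore, max_lag = 2L) {
  cause <- as.numeric(tf_zscore); effect <- as.numeric(module_mean_zscore)
  Tn <- length(effect)
  if (length(cause) != Tn) stop("series lengths differ")
  if (Tn < 2 * max_lag + 2) stop("series too short for max_lag")
  if (!all(is.finite(cause)) || !all(is.finite(effect)) ||
      sd(cause) == 0 || sd(effect) == 0)
    return(structure(list(lag = NA_integer_, f_statistic = NA_real_,
                          p_value = 1, flagged = TRUE),
                     class = "granger_result"))
  aics <- vapply(seq_len(max_lag), function(p)
    var_aic(cause, effect, p, max_lag), numeric(1))
  p_sel <- which.min(aics)
  from <- p_sel + 1L
  y <- effect[from:Tn]
  own <- lag_matrix(effect, p_sel, from)
  xc <- lag_matrix(cause, p_sel, from)
  full <- lm.fit(cbind(1, own, xc), y)
  red <- lm.fit(cbind(1, own), y)
  rss_f <- sum(full$residuals^2); rss_r <- sum(red$residuals^2)
  df2 <- length(y) - (2 * p_sel + 1)
  if (df2 <= 0 || rss_f <= 0)
    return(structure(list(lag = p_sel, f_statistic = NA_real_, p_value = 1,
                          flagged = TRUE), class = "granger_result"))
  f <- ((rss_r - rss_f) / p_sel) / (rss_f / df2)
  structure(list(lag = p_sel, f_statistic = f,
                 p_value = pf(f, p_sel, df2, lower.tail = FALSE),
                 flagged = FALSE), class = "granger_result")
}

#' Granger scan over all TF-module pairs
#'
#' Runs [granger_causality()] for every combination of TF and module series
#' within each condition and BH-adjusts the p-values across all tested
#' (tf, module, condition) triples.
#'
#' @param tf_profiles Named list (by condition) of TF x time Z-score
#'   matrices.
#' @param module_profiles Named list (by condition) of module x time mean
#'   Z-score matrices.
#' @param max_lag Largest VAR lag order.
#' @return `data.frame`: tf, module, condition, lag, f_statistic, p_value,
#'   bh_adjusted_p.
#' @export
granger_scan <- function(tf_profiles, module_profiles, max_lag = 2L) {
  stopifnot(identical(names(tf_profiles), names(module_profiles)))
  rows <- list()
  for (cond in names(tf_profiles)) {
    tfm <- tf_profiles[[cond]]; mm <- module_profiles[[cond]]
    for (tf in rownames(tfm)) for (mod in rownames(mm)) {
      g <- granger_causality(tfm[tf, ], mm[mod, ], max_lag)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, module = mod, condition = cond, lag = g$lag,
        f_statistic = g$f_statistic, p_value = g$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$bh_adjusted_p <- bh_adjust(out$p_value)
  out
}

#' Link TFs to PWMs through a protein-similarity hit table
#'
#' A TF may use a PWM only when the similarity table connects it to the
#' motif's source TF below the e-value threshold.
#'
#' @param hit_table `data.frame` with columns `query` (TF id), `subject`
#'   (PWM source TF id), `evalue`.
#' @param pwm_set List of [pwm()] objects.
#' @param e_threshold Strict e-value cutoff.
#' @return `data.frame(tf, pwm)` of usable pairs.
#' @export
tf_pwm_links <- function(hit_table, pwm_set, e_threshold = 1e-5) {
  names(pwm_set) <- vapply(pwm_set, `[[`, character(1), "id")
  keep <- hit_table[hit_table$evalue < e_threshold, , drop = FALSE]
  src <- vapply(pwm_set, `[[`, character(1), "tf")
  rows <- lapply(names(pwm_set), function(id) {
    q <- keep$query[keep$subject == src[[id]]]
    if (length(q)) data.frame(tf = unique(q), pwm = id,
                              stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(tf = character(), pwm = character()) else out
}

#' Joint regulation calls from motif and Granger evidence
#'
#' A TF -> module regulation is called when the motif-enrichment p-value is
#' below `alpha` for at least one window and the BH-adjusted Granger p-value
#' is below `alpha` in at least one condition.
#'
#' @param motif_table `data.frame`: tf, module, min_p, any_window_significant
#'   (one row per tested pair).
#' @param granger_table A [granger_scan()] result.
#' @param alpha Significance level for both gates.
#' @return `data.frame` of class `regulation_calls`: tf, module, called,
#'   motif_min_p, granger_min_bh_p.
#' @export
call_regulators <- function(motif_table, granger_table, alpha = 0.05) {
  gr <- stats::aggregate(bh_adjusted_p ~ tf + module, data = granger_table,
                         FUN = min)
  names(gr)[3] <- "granger_min_bh_p"
  merged <- merge(motif_table, gr, by = c("tf", "module"), all = TRUE)
  orphan <- is.na(merged$min_p) | is.na(merged$granger_min_bh_p)
  if (any(orphan))
    warning(sum(orphan), " pair(s) present in only one evidence table; not called")
  merged$called <- !orphan & merged$min_p < alpha &
    merged$granger_min_bh_p < alpha
  out <- merged[, c("tf", "module", "called", "min_p", "granger_min_bh_p")]
  names(out)[4] <- "motif_min_p"
  class(out) <- c("regulation_calls", "data.frame")
  out
}
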