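test_that("PWM scanning scores consensus hits in bits on both strands", {
  p <- pwm("acgt", diag(4), tf = "X")
  s <- scan_pwm(p, "TTTTACGTTTTT")
  ## probabilities floored at 1e-3 and renormalized: 4 * log2(0.997/0.25)
  expect_equal(s, 4 * log2((1 / 1.003) / 0.25), tolerance = 1e-9)
  expect_lt(abs(s - 8), 0.05)
  ## uniform PWM scores 0 everywhere
  u <- pwm("uni", matrix(0.25, 4, 4))
  expect_equal(scan_pwm(u, "ACGTACGTAC"), 0)
  ## strand symmetry: the reverse complement scores identically
  seqs <- "GGACGTACGTTTCA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
  q <- consensus_pwm("m", "ACGTACGT")
  expect_equal(scan_pwm(q, seqs), scan_pwm(q, rc))
  ## ambiguity codes score as background; short sequences are excluded
  expect_equal(scan_pwm(u, "ACGTNNNN"), 0)
  expect_warning(expect_true(is.na(scan_pwm(q, "ACG"))), "shorter")
})

test_that("motif enrichment detects planted sites and respects granularity", {
  p <- consensus_pwm("M1", "ACGTACGT")
  mt <- rbind(data.frame(gene = sprintf("g%02d", 1:10), module = "M"),
              data.frame(gene = sprintf("b%03d", 1:80), module = "bg"))
  seqs <- generate_promoters(mt, list(p),
    data.frame(pwm = "M1", module = "M", insert_probability = 1),
    400, 0.4, seed = 7)
  mh <- motif_enrichment(p, seqs[1:10], seqs[-(1:10)],
                         window_lengths = c(100, 400),
                         n_draws = 500, seed = 3)
  ## the full-length window contains every planted site
  expect_lt(mh$table$p[mh$table$window == 400], 0.05)
  expect_true(mh$any_window_significant)
  ## a single draw can only give p in {1/2, 1}
  mh1 <- motif_enrichment(p, seqs[1:10], seqs[-(1:10)], 400,
                          n_draws = 1, seed = 4)
  expect_true(all(mh1$table$p %in% c(0.5, 1)))
  ## duplicating every background sequence leaves the p-values unchanged
  mh2 <- motif_enrichment(p, seqs[1:10], rep(seqs[-(1:10)], 2), 400,
                          n_draws = 500, seed = 3)
  ## (same seed, doubled pool: identical null law, near-identical p)
  expect_lt(abs(mh2$table$p - mh$table$p[mh$table$window == 400]), 0.05)
  expect_error(motif_enrichment(p, character(0), seqs, 400), "empty module")
  expect_error(motif_enrichment(p, seqs[1:10], seqs[1:3], 400),
               "at least as large")
})

test_that("Granger causality is directional and degenerate-safe", {
  set.seed(9)
  x <- rnorm(100); y <- 0.9 * c(0, x[-100]) + rnorm(100, 0, 0.3)
  fwd <- granger_causality(x, y, max_lag = 2)
  rev <- granger_causality(y, x, max_lag = 2)
  expect_lt(fwd$p_value, 0.01)
  expect_gt(rev$p_value, 0.05)
  ## constant series: flagged, p = 1
  flat <- granger_causality(x, rep(1, 100))
  expect_true(flat$flagged)
  expect_equal(flat$p_value, 1)
  ## invariance to affine rescaling of either series
  resc <- granger_causality(3 * x + 5, -2 * y + 1, max_lag = 2)
  expect_equal(resc$p_value, fwd$p_value, tolerance = 1e-8)
  expect_error(granger_causality(x[1:4], y[1:4], max_lag = 2), "too short")
})

test_that("the F-test at a fixed lag matches an independent implementation", {
  skip_if_not_installed("lmtest")
  set.seed(13)
  x <- rnorm(80); y <- 0.7 * c(0, x[-80]) + rnorm(80, 0, 0.5)
  ours <- granger_causality(x, y, max_lag = 1)
  ref <- lmtest::grangertest(y ~ x, order = 1)
  expect_equal(ours$f_statistic, ref$F[2], tolerance = 1e-8)
  expect_equal(ours$p_value, ref$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("joint regulation calls require both evidence gates", {
  motif <- data.frame(tf = c("T1", "T1", "T2"),
                      module = c("blue", "brown", "blue"),
                      min_p = c(0.01, 0.01, 0.30),
                      any_window_significant = c(TRUE, TRUE, FALSE))
  granger <- data.frame(tf = c("T1", "T1", "T2"),
                        module = c("blue", "brown", "blue"),
                        condition = "trehalose", lag = 1,
                        f_statistic = 5,
                        p_value = c(0.001, 0.2, 0.001))
  granger$bh_adjusted_p <- bh_adjust(granger$p_value)
  calls <- call_regulators(motif, granger)
  expect_true(calls$called[calls$tf == "T1" & calls$module == "blue"])
  expect_false(calls$called[calls$tf == "T1" & calls$module == "brown"])
  expect_false(calls$called[calls$tf == "T2" & calls$module == "blue"])
  ## the called set is inside both single-evidence significant sets
  expect_true(all(calls$motif_min_p[calls$called] < 0.05))
  expect_true(all(calls$granger_min_bh_p[calls$called] < 0.05))
  ## orphan pairs are warned about and never called
  orphan <- rbind(motif, data.frame(tf = "T3", module = "blue", min_p = 0.01,
                                    any_window_significant = TRUE))
  expect_warning(c2 <- call_regulators(orphan, granger), "only one evidence")
  expect_false(c2$called[c2$tf == "T3"])
})

test_that("the similarity bridge links TFs to PWMs below the e-value gate", {
  pwms <- list(consensus_pwm("m1", "ACGTACGT", tf = "REF_A"),
               consensus_pwm("m2", "TTGACGCA", tf = "REF_B"))
  hits <- data.frame(query = c("TF1", "TF2", "TF3"),
                     subject = c("REF_A", "REF_B", "REF_A"),
                     evalue = c(1e-10, 1e-3, 1e-20))
  links <- tf_pwm_links(hits, pwms, e_threshold = 1e-5)
  expect_setequal(paste(links$tf, links$pwm), c("TF1 m1", "TF3 m1"))
})
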