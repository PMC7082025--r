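test_that("boosted-tree scoring finds a lagged driver and keeps its contracts", {
  set.seed(5)
  Tn <- 200
  A <- rnorm(Tn); B <- c(0, A[-Tn]); C <- rnorm(Tn); D <- rnorm(Tn)
  m <- rbind(A = A, B = B, C = C, D = D)
  S <- score_regulators(m, seed = 3)
  expect_equal(rownames(S)[which.max(S[, "B"])], "A")
  ## per-target score sums are 0 or 1; the diagonal is not scored
  expect_true(all(abs(colSums(S, na.rm = TRUE) - 1) < 1e-8))
  expect_true(all(is.na(diag(S))))
  ## constant target yields a zero score row with a warning
  m2 <- m; m2["B", ] <- 5
  expect_warning(S2 <- score_regulators(m2, seed = 3), "constant target")
  expect_true(all(S2[setdiff(rownames(S2), "B"), "B"] == 0))
  ## permutation near-equivariance over regulator ordering (greedy tree
  ## learners break ties by feature position, so only the ranking is stable)
  S3 <- score_regulators(m[c("C", "A", "D", "B"), ], seed = 3)
  S3 <- S3[rownames(S), colnames(S)]
  expect_gt(cor(S3[!is.na(S3)], S[!is.na(S)]), 0.98)
  for (tgt in colnames(S))
    expect_equal(which.max(S3[, tgt]), which.max(S[, tgt]))
  expect_error(score_regulators(m[, 1:2], seed = 1), "time points")
  expect_error(score_regulators(m[1, , drop = FALSE], seed = 1), "two TFs")
})

test_that("scale-free fit is exact on collinear degrees and flat on uniform ones", {
  deg <- rep(c(1, 2, 4, 8), c(8, 4, 2, 1))
  f <- suppressWarnings(fit_scale_free(deg))
  expect_equal(f$gamma, 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$log10_C, log10(8 / 15), tolerance = 1e-10)
  ## a single distinct degree has no defined fit
  expect_false(fit_scale_free(rep(3, 10))$defined)
  ## uniform degree distribution: gamma ~ 0 and no significance
  flat <- fit_scale_free(rep(1:4, each = 25))
  expect_lt(abs(flat$gamma), 0.2)
  expect_gt(flat$f_test_p, 0.05)
})

test_that("threshold selection rejects degenerate score sets", {
  s <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(s) <- NA
  expect_error(select_threshold(s), "no threshold|scale-free")
})

test_that("threshold edge count is antitone in the candidate", {
  S <- planted_score_matrix(seed = 1)
  scan <- select_threshold(S)
  expect_true(all(diff(scan$scan$n_edges) <= 0))
  expect_true(scan$selected_a %in% scan$scan$a)
})

test_that("lag-1 cross-correlation signs match shifted and negated copies", {
  set.seed(9)
  x <- rnorm(60); y <- c(0, x[-60])
  m <- rbind(A = x, B = y, C = -y)
  ed <- data.frame(source = c("A", "A"), target = c("B", "C"), score = 1)
  sn <- assign_signs(ed, m, condition = "c1")
  expect_equal(sn$edges$sign[sn$edges$target == "B"], 1L)
  expect_equal(sn$edges$sign[sn$edges$target == "C"], -1L)
  ## constant endpoint: edge dropped with a warning
  m2 <- rbind(A = x, B = y, C = rep(1, 60))
  expect_warning(sn2 <- assign_signs(ed, m2, condition = "c1"), "dropped")
  expect_equal(nrow(sn2$edges), 1)
  expect_error(assign_signs(data.frame(source = "A", target = "Z"), m),
               "no expression series")
})

test_that("network integration unions edges and resolves sign conflicts", {
  na <- signed_network(data.frame(source = "X", target = "Y", sign = 1L,
                                  score = 0.9, conditions = "trehalose",
                                  lag1_cc = 0.8, conflict = FALSE))
  nb <- signed_network(data.frame(source = "Y", target = "Z", sign = -1L,
                                  score = 0.7, conditions = "rehydration",
                                  lag1_cc = -0.6, conflict = FALSE))
  u <- integrate_networks(na, nb)
  expect_equal(nrow(u$edges), 2)
  expect_setequal(u$edges$conditions, c("trehalose", "rehydration"))
  ## identical edge in both conditions collapses to one record
  nb2 <- signed_network(data.frame(source = "X", target = "Y", sign = 1L,
                                   score = 0.5, conditions = "rehydration",
                                   lag1_cc = 0.5, conflict = FALSE))
  u2 <- integrate_networks(na, nb2)
  expect_equal(nrow(u2$edges), 1)
  expect_equal(u2$edges$conditions, "trehalose;rehydration")
  expect_false(u2$edges$conflict)
  ## opposite signs: the larger |cross-correlation| wins, conflict flagged
  nb3 <- signed_network(data.frame(source = "X", target = "Y", sign = -1L,
                                   score = 0.5, conditions = "rehydration",
                                   lag1_cc = -0.95, conflict = FALSE))
  u3 <- integrate_networks(na, nb3)
  expect_equal(u3$edges$sign, -1L)
  expect_true(u3$edges$conflict)
})

test_that("thresholded boosted-tree inference recovers planted edges", {
  ## regression guard on the whole scoring + thresholding path: averages
  ## over ten planted scale-free networks simulated at low noise
  pr <- vapply(1:10, function(sd) {
    net <- generate_planted_network(30, 44, 0.7,
      c("coherent_ffl", "coherent_ffl", "incoherent_ffl", "positive_fbl"),
      seed = sd, master = TRUE, hub_bias = TRUE)
    reps <- lapply(1:3, function(r)
      simulate_latent(net, 20, x0 = NULL, noise_sd = 0.8,
                      coef_scale = 0.9, seed = sd * 100 + r))
    S <- suppressWarnings(score_regulators(reps, seed = sd))
    scan <- tryCatch(select_threshold(S), error = function(e) NULL)
    if (is.null(scan)) return(c(NA_real_, NA_real_))
    ed <- anhydronet:::edges_at(scan$normalized_scores, scan$selected_a)
    tru <- paste(net$edges$source, net$edges$target)
    inf <- paste(ed$source, ed$target)
    tp <- length(intersect(inf, tru))
    c(tp / length(inf), tp / length(tru))
  }, numeric(2))
  expect_gt(mean(pr[1, ], na.rm = TRUE), 0.6)
  expect_gt(mean(pr[2, ], na.rm = TRUE), 0.6)
})

test_that("signed networks survive a TSV and GraphML round trip", {
  sn <- signed_network(data.frame(source = c("A", "B"), target = c("B", "C"),
                                  sign = c(1L, -1L), score = c(0.5, 0.4),
                                  conditions = "trehalose",
                                  lag1_cc = c(0.7, -0.5), conflict = FALSE))
  tmp <- withr::local_tempdir()
  write_network_tsv(sn, file.path(tmp, "net.tsv"))
  back <- read_network_tsv(file.path(tmp, "net.tsv"))
  expect_equal(back$edges$sign, sn$edges$sign)
  expect_equal(back$edges$lag1_cc, sn$edges$lag1_cc)
  write_network_graphml(sn, file.path(tmp, "net.graphml"))
  g <- igraph::read_graph(file.path(tmp, "net.graphml"), format = "graphml")
  expect_equal(igraph::gsize(g), 2)
})
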