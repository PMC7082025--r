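test_that("planted motifs are realized with class-consistent signs", {
  net <- generate_planted_network(3, 0, 1.0, "coherent_ffl", seed = 1)
  ed <- net$edges[order(net$edges$source, net$edges$target), ]
  expect_equal(ed$source, c("TF01", "TF01", "TF02"))
  expect_equal(ed$target, c("TF02", "TF03", "TF03"))
  expect_true(all(ed$sign == 1))

  fbl <- generate_planted_network(3, 0, 1.0, "positive_fbl", seed = 1)
  expect_setequal(paste(fbl$edges$source, fbl$edges$target),
                  c("TF01 TF02", "TF02 TF03", "TF03 TF01"))
  expect_equal(sum(fbl$edges$sign == -1) %% 2, 0)

  ## every planted motif's edges exist with signs matching the class
  net2 <- generate_planted_network(20, 15, 0.5,
                                   c("coherent_ffl", "incoherent_ffl",
                                     "positive_fbl", "negative_fbl"),
                                   seed = 3)
  S <- matrix(0, 20, 20, dimnames = list(net2$tf_ids, net2$tf_ids))
  S[cbind(net2$edges$source, net2$edges$target)] <- net2$edges$sign
  for (m in net2$planted_motifs) {
    tr <- m$nodes
    if (grepl("ffl", m$class)) {
      expect_true(all(S[tr[1], tr[2]] != 0, S[tr[2], tr[3]] != 0,
                      S[tr[1], tr[3]] != 0))
      coh <- S[tr[1], tr[3]] == S[tr[1], tr[2]] * S[tr[2], tr[3]]
      expect_equal(coh, m$class == "coherent_ffl")
    } else {
      signs <- c(S[tr[1], tr[2]], S[tr[2], tr[3]], S[tr[3], tr[1]])
      expect_true(all(signs != 0))
      expect_equal(sum(signs < 0) %% 2 == 0, m$class == "positive_fbl")
    }
  }
})

test_that("network generation is deterministic and validates edge budgets", {
  a <- generate_planted_network(10, 20, 0.6, c("coherent_ffl"), seed = 7)
  b <- generate_planted_network(10, 20, 0.6, c("coherent_ffl"), seed = 7)
  expect_identical(a$edges, b$edges)
  expect_error(generate_planted_network(3, 100, 0.5, "coherent_ffl", seed = 1),
               "infeasible")
  expect_error(generate_planted_network(3, 0, 0.5,
                                        c("coherent_ffl", "positive_fbl")),
               "too small")
  ## no self-loops, no duplicate ordered pairs
  expect_false(any(a$edges$source == a$edges$target))
  expect_equal(anyDuplicated(a$edges[c("source", "target")]), 0L)
})

test_that("master regulator has zero in-degree and reaches motif roots", {
  net <- generate_planted_network(20, 30, 0.5,
                                  c("coherent_ffl", "positive_fbl"),
                                  seed = 2, master = TRUE)
  m <- net$master_regulator
  expect_false(m %in% net$edges$target)
  roots <- vapply(net$planted_motifs, function(x) x$nodes[1], character(1))
  expect_true(all(roots %in% net$edges$target[net$edges$source == m]))
})

test_that("noise-free dynamics shift a lagged copy and are linear", {
  net <- generate_planted_network(3, 0, 1.0, character(), seed = 1)
  net$edges <- data.frame(source = "TF01", target = "TF02", sign = 1L,
                          weight = 1)
  x0 <- c(TF01 = 1, TF02 = 0, TF03 = 0)
  lat <- simulate_latent(net, 6, x0 = x0, noise_sd = 0)
  expect_equal(unname(lat["TF02", 2:6]), unname(lat["TF01", 1:5]))

  ## doubling a root's initial value doubles every descendant's latent value
  chain <- generate_planted_network(4, 0, 1.0, character(), seed = 1)
  chain$edges <- data.frame(source = c("TF01", "TF02", "TF03"),
                            target = c("TF02", "TF03", "TF04"),
                            sign = 1L, weight = c(0.8, 0.6, 0.9))
  l1 <- simulate_latent(chain, 8, x0 = c(TF01 = 1), noise_sd = 0)
  l2 <- simulate_latent(chain, 8, x0 = c(TF01 = 2), noise_sd = 0)
  expect_equal(l2, 2 * l1)
})

test_that("simulated datasets conserve the gene inventory and the design", {
  net <- generate_planted_network(8, 6, 0.7, "coherent_ffl", seed = 4)
  truth <- make_module_truth(c(M1 = "TF01", M2 = "TF04"), 15, seed = 5)
  cfg <- simulation_config(n_timepoints = 5, n_replicates = 3,
                           n_background = 40, seed = 6)
  ds <- simulate_expression(net, truth, cfg)
  expect_equal(nrow(ds$counts$values), 8 + 30 + 40)
  expect_equal(ncol(ds$counts$values), 2 * 5 * 3)
  expect_true(all(ds$counts$values >= 0))
  expect_equal(sort(unique(ds$design$condition)),
               c("rehydration", "trehalose"))
  ## condition-prefixed sample labels at the five-time-point design
  expect_true(all(c("T0_1", "T48_3", "R0_1", "R72_3") %in%
                    ds$design$sample))
  ## determinism
  ds2 <- simulate_expression(net, truth, cfg)
  expect_identical(ds$counts$values, ds2$counts$values)
  expect_error(simulate_expression(net, truth,
                                   within(cfg, nb_dispersion <- -1)))
})

test_that("negative-binomial count noise approaches Poisson as dispersion vanishes", {
  ## replicates at a fixed time point are iid draws around the same mean, so
  ## at nb_dispersion = 0 their variance must match their mean (Poisson
  ## limit of the NB variance function mean + dispersion * mean^2)
  net <- generate_planted_network(3, 2, 1.0, character(), seed = 1)
  cfg <- simulation_config(n_timepoints = 3, n_replicates = 400,
                           nb_dispersion = 0, n_background = 3,
                           library_size = 1e4, seed = 2)
  ds <- simulate_expression(net, NULL, cfg)
  des <- ds$design[ds$design$condition == "trehalose" &
                     ds$design$time_h == 0, ]
  y <- ds$counts$values["BG001", des$sample]
  expect_gt(mean(y), 10)
  expect_lt(abs(var(y) / mean(y) - 1), 0.2)
  ## and at positive dispersion the quadratic term appears
  cfg2 <- simulation_config(n_timepoints = 3, n_replicates = 400,
                            nb_dispersion = 0.2, n_background = 3,
                            library_size = 1e4, seed = 2)
  y2 <- simulate_expression(net, NULL, cfg2)$counts$values["BG001", des$sample]
  expect_gt(var(y2) / mean(y2), 2)
})

test_that("replicate correlation spans shared to independent trajectories", {
  net <- generate_planted_network(6, 5, 0.7, "coherent_ffl", seed = 3)
  shared <- simulate_expression(net, NULL,
    simulation_config(n_timepoints = 8, n_background = 5, seed = 11,
                      replicate_cor = 1))
  expect_true(is.matrix(shared$latent$trehalose))
  mixed <- simulate_expression(net, NULL,
    simulation_config(n_timepoints = 8, n_background = 5, seed = 11,
                      replicate_cor = 0.5))
  expect_type(mixed$latent$trehalose, "list")
  expect_length(mixed$latent$trehalose, 3)
  ## distinct trajectories, but correlated through the shared innovations
  z1 <- mixed$latent$trehalose[[1]]["TF01", ]
  z2 <- mixed$latent$trehalose[[2]]["TF01", ]
  expect_false(isTRUE(all.equal(z1, z2)))
})

test_that("promoter generation plants consensus sites as requested", {
  p <- consensus_pwm("M1", "ACGTACGT")
  mt <- rbind(data.frame(gene = sprintf("g%02d", 1:10), module = "M"),
              data.frame(gene = sprintf("b%02d", 1:10), module = "bg"))
  plan1 <- data.frame(pwm = "M1", module = "M", insert_probability = 1)
  seqs <- generate_promoters(mt, list(p), plan1, 300, 0.4, seed = 7)
  expect_true(all(grepl("ACGTACGT", seqs[1:10])))
  plan0 <- data.frame(pwm = "M1", module = "M", insert_probability = 0)
  seqs0 <- generate_promoters(mt, list(p), plan0, 300, 0.4, seed = 7)
  expect_false(any(grepl("ACGTACGT", seqs0[1:10], fixed = TRUE)))
  expect_error(generate_promoters(mt, list(p), plan1, 4, 0.4, seed = 1),
               "longer than")
  ## GC content within 3 binomial standard errors
  big <- generate_promoters(data.frame(gene = sprintf("s%03d", 1:100),
                                       module = "bg"),
                            list(), NULL, 10000, 0.5, seed = 8)
  gc <- mean(strsplit(paste(big, collapse = ""), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e6))
  ## determinism
  expect_identical(seqs, generate_promoters(mt, list(p), plan1, 300, 0.4,
                                            seed = 7))
})

test_that("dataset writers round-trip through their plain-text formats", {
  net <- generate_planted_network(5, 3, 0.7, "coherent_ffl", seed = 2)
  ds <- simulate_expression(net, NULL,
    simulation_config(n_timepoints = 4, n_background = 5, seed = 3))
  tmp <- withr::local_tempdir()
  write_counts_tsv(ds$counts, file.path(tmp, "counts.tsv"))
  back <- read_counts_tsv(file.path(tmp, "counts.tsv"))
  expect_equal(back$values, ds$counts$values)
  expect_equal(back$gene_length_bp, ds$counts$gene_length_bp)
  write_design_tsv(ds$design, file.path(tmp, "design.tsv"))
  expect_equal(read_design_tsv(file.path(tmp, "design.tsv")),
               ds$design, ignore_attr = TRUE)
  p <- consensus_pwm("M1", "ACGTAACC")
  write_meme(list(p), file.path(tmp, "motifs.meme"))
  back_p <- read_meme(file.path(tmp, "motifs.meme"))
  expect_equal(back_p[[1]]$matrix, p$matrix, tolerance = 1e-5)
  seqs <- c(g1 = "ACGTACGTAA", g2 = "TTTTCCCCGG")
  write_promoters_fasta(seqs, file.path(tmp, "prom.fa"))
  expect_equal(read_promoters_fasta(file.path(tmp, "prom.fa")), seqs)
})
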