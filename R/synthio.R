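## Synthetic regulatory networks, time-series counts, and promoters with
## planted structure. Every downstream stage of the pipeline can be exercised
## against the ground truth these generators record.

MOTIF_CLASSES <- c("coherent_ffl", "incoherent_ffl", "positive_fbl",
                   "negative_fbl")

#' Generate a planted signed regulatory network
#'
#' Builds a directed signed network over transcription factors in which each
#' requested three-node motif (coherent/incoherent feed-forward loop,
#' positive/negative feedback loop) is realized on its own disjoint node
#' triple; remaining edges are sampled uniformly over the free ordered pairs.
#'
#' @param n_tf Number of transcription factors (must be at least
#'   `3 * length(motif_requests)`, plus one when `master = TRUE`).
#' @param n_extra_edges Number of additional random edges beyond the motif
#'   edges.
#' @param positive_ratio Probability that a free edge sign is +1.
#' @param motif_requests Character vector drawn from `coherent_ffl`,
#'   `incoherent_ffl`, `positive_fbl`, `negative_fbl`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param master If `TRUE`, one additional node is designated a master
#'   regulator: it has zero in-degree and one positive edge into the first
#'   node of every planted motif.
#' @param hub_bias If `TRUE`, extra edges are sampled with source
#'   probability proportional to the current out-degree plus one
#'   (preferential attachment), so the planted network has the scale-free
#'   out-degree topology regulatory networks are expected to show; the
#'   default samples uniformly.
#' @param master_out Number of planted motifs whose first node receives a
#'   master edge (default: all of them).
#' @return An object of class `planted_network` with elements `tf_ids`,
#'   `edges` (source, target, sign, weight), `planted_motifs`, and
#'   `master_regulator` (or `NA`).
#' @export
generate_planted_network <- function(n_tf, n_extra_edges, positive_ratio,
                                     motif_requests = character(),
                                     seed = 1L, master = FALSE,
                                     hub_bias = FALSE, master_out = Inf) {
  stopifnot(positive_ratio >= 0, positive_ratio <= 1)
  motif_requests <- as.character(motif_requests)
  if (!all(motif_requests %in% MOTIF_CLASSES))
    stop("unknown motif class in motif_requests")
  n_motif_nodes <- 3L * length(motif_requests)
  need <- n_motif_nodes + as.integer(master)
  if (n_tf < max(need, 3L))
    stop(sprintf("n_tf = %d too small for %d motifs%s", n_tf,
                 length(motif_requests), if (master) " plus a master" else ""))
  tf_ids <- sprintf("TF%02d", seq_len(n_tf))

  set.seed(seed)
  src <- character(0); tgt <- character(0); sgn <- integer(0)
  motifs <- list()
  rsign <- function(k) ifelse(runif(k) < positive_ratio, 1L, -1L)
  for (i in seq_along(motif_requests)) {
    cls <- motif_requests[i]
    trip <- tf_ids[(3L * (i - 1L) + 1L):(3L * i)]
    s12 <- rsign(1); s23 <- rsign(1)
    if (cls %in% c("coherent_ffl", "incoherent_ffl")) {
      ## direct edge sign equals (coherent) or opposes (incoherent) the
      ## product of the indirect path signs
      s13 <- if (cls == "coherent_ffl") s12 * s23 else -s12 * s23
      src <- c(src, trip[1], trip[2], trip[1])
      tgt <- c(tgt, trip[2], trip[3], trip[3])
      sgn <- c(sgn, s12, s23, s13)
    } else {
      ## 3-cycle; parity of negative signs fixes the class
      s31 <- if (cls == "positive_fbl") s12 * s23 else -s12 * s23
      src <- c(src, trip[1], trip[2], trip[3])
      tgt <- c(tgt, trip[2], trip[3], trip[1])
      sgn <- c(sgn, s12, s23, s31)
    }
    motifs[[i]] <- list(class = cls, nodes = trip)
  }

  master_id <- NA_character_
  if (master) {
    master_id <- tf_ids[n_motif_nodes + 1L]
    roots <- vapply(motifs, function(m) m$nodes[1], character(1))
    if (master_out < length(roots)) roots <- roots[seq_len(master_out)]
    src <- c(src, rep(master_id, length(roots)))
    tgt <- c(tgt, roots)
    sgn <- c(sgn, rep(1L, length(roots)))
  }

  ## free ordered pairs: no self-loops, no duplicate pairs, nothing into the
  ## master regulator
  all_pairs <- expand.grid(source = tf_ids, target = tf_ids,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  if (master) all_pairs <- all_pairs[all_pairs$target != master_id, ]
  used <- paste(src, tgt)
  free <- all_pairs[!(paste(all_pairs$source, all_pairs$target) %in% used), ]
  if (n_extra_edges > nrow(free))
    stop(sprintf("infeasible edge count: %d extra edges requested, only %d free ordered pairs",
                 n_extra_edges, nrow(free)))
  if (n_extra_edges > 0) {
    if (hub_bias) {
      for (e in seq_len(n_extra_edges)) {
        outdeg <- table(factor(src, levels = tf_ids))
        w <- as.numeric(outdeg[free$source]) + 1
        i <- sample.int(nrow(free), 1L, prob = w)
        src <- c(src, free$source[i]); tgt <- c(tgt, free$target[i])
        free <- free[-i, , drop = FALSE]
      }
    } else {
      pick <- free[sample.int(nrow(free), n_extra_edges), ]
      src <- c(src, pick$source); tgt <- c(tgt, pick$target)
    }
    sgn <- c(sgn, rsign(n_extra_edges))
  }

  weight <- runif(length(src), 0.5, 1)
  ## the master's edges carry full weight so its downstream influence is not
  ## drowned by the recipients' other inputs
  if (master) weight[src == master_id] <- 1
  edges <- data.frame(source = src, target = tgt, sign = as.integer(sgn),
                      weight = weight, stringsAsFactors = FALSE)
  structure(list(tf_ids = tf_ids, edges = edges, planted_motifs = motifs,
                 master_regulator = master_id),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("planted_network: %d TFs, %d edges, %d planted motifs%s\n",
              length(x$tf_ids), nrow(x$edges), length(x$planted_motifs),
              if (!is.na(x$master_regulator))
                paste0(", master ", x$master_regulator) else ""))
  invisible(x)
}

#' Simulation configuration
#'
#' Defaults mirror a two-arm time-series design with five time points and
#' three biological replicates per condition.
#'
#' @param n_timepoints Time points per condition (>= 3).
#' @param n_replicates Biological replicates per time point (>= 1).
#' @param coef_scale Multiplier applied to planted edge weights in the lag-1
#'   linear dynamics.
#' @param noise_sd Standard deviation of the innovations driving the latent
#'   dynamics (also the only source of temporal signal for root regulators).
#' @param nb_dispersion Negative-binomial dispersion of the count noise
#'   (variance = mean + dispersion * mean^2); 0 gives the Poisson limit.
#' @param library_size Target total counts per sample.
#' @param n_background Number of pure-noise background genes (true negatives
#'   for the differential-expression stage).
#' @param init_sd Standard deviation of the condition-specific initial latent
#'   state.
#' @param replicate_cor Correlation of the latent innovations across
#'   replicates, in \[0, 1\]. At 1 (default) replicates share one latent
#'   trajectory and differ only in count noise (a deterministic response
#'   read three times); below 1 each replicate culture mixes the shared
#'   condition response with its own stochastic dynamics of the same
#'   network.
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_timepoints = 5L, n_replicates = 3L,
                              coef_scale = 0.9, noise_sd = 1, nb_dispersion = 0.05,
                              library_size = 2e5, n_background = 100L,
                              init_sd = 1, replicate_cor = 1, seed = 1L) {
  stopifnot(replicate_cor >= 0, replicate_cor <= 1)
  if (n_timepoints < 3L) stop("n_timepoints must be >= 3")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  structure(list(n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 coef_scale = coef_scale, noise_sd = noise_sd,
                 nb_dispersion = nb_dispersion, library_size = library_size,
                 n_background = as.integer(n_background), init_sd = init_sd,
                 replicate_cor = replicate_cor,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Weight matrix W[target, source] of the lag-1 dynamics, rescaled when its
## spectral radius would make the linear system unstable.
dynamics_matrix <- function(net, coef_scale = 1) {
  n <- length(net$tf_ids)
  W <- matrix(0, n, n, dimnames = list(net$tf_ids, net$tf_ids))
  if (nrow(net$edges))
    W[cbind(net$edges$target, net$edges$source)] <-
      net$edges$sign * net$edges$weight * coef_scale
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho > 0.95) W <- W * (0.9 / rho)
  W
}

#' Simulate latent lag-1 linear dynamics of a planted network
#'
#' `x(t) = W x(t-1) + e`, `e ~ N(0, noise_sd^2)`; regulators without parents
#' are driven by the innovations alone (beyond the initial state).
#'
#' @param net A [generate_planted_network()] result.
#' @param n_timepoints Number of time points to simulate.
#' @param x0 Initial state (named or positional vector over TFs); default 0.
#' @param noise_sd Innovation standard deviation.
#' @param coef_scale Weight multiplier, see [simulation_config()].
#' @param seed Integer seed (ignored when `noise_sd == 0`).
#' @return TF x time matrix of latent values.
#' @export
simulate_latent <- function(net, n_timepoints, x0 = NULL, noise_sd = 0,
                            coef_scale = 1, seed = 1L) {
  W <- dynamics_matrix(net, coef_scale)
  n <- length(net$tf_ids)
  if (is.null(x0)) x0 <- numeric(n)
  if (!is.null(names(x0))) x0 <- x0[net$tf_ids]
  x0[is.na(x0)] <- 0
  set.seed(seed)
  X <- matrix(0, n, n_timepoints, dimnames = list(net$tf_ids, NULL))
  X[, 1] <- x0
  for (t in 2:n_timepoints)
    X[, t] <- as.vector(W %*% X[, t - 1]) +
      if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  X
}

#' Build a module ground-truth table
#'
#' @param drivers Named character vector: `names()` are module labels, values
#'   the driver TF ids.
#' @param genes_per_module Genes per module (scalar or per-module vector).
#' @param positive_fraction Fraction of module members responding with the
#'   same sign as the driver.
#' @param coef_range Range of the member response coefficients; values above
#'   1 make members track their driver more tightly than their own noise.
#' @param seed Integer seed for member signs and coefficients.
#' @return `data.frame` with columns gene, module, driver, sign, coef.
#' @export
make_module_truth <- function(drivers, genes_per_module = 30L,
                              positive_fraction = 0.8,
                              coef_range = c(0.6, 1), seed = 1L) {
  stopifnot(!is.null(names(drivers)))
  sizes <- rep_len(genes_per_module, length(drivers))
  set.seed(seed)
  out <- lapply(seq_along(drivers), function(i) {
    g <- sprintf("%s_G%03d", names(drivers)[i], seq_len(sizes[i]))
    data.frame(gene = g, module = names(drivers)[i], driver = drivers[[i]],
               sign = ifelse(runif(sizes[i]) < positive_fraction, 1L, -1L),
               coef = runif(sizes[i], coef_range[1], coef_range[2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

softplus <- function(x) {
  ## numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

paper_times <- list(trehalose = c(0, 12, 24, 36, 48),
                    rehydration = c(0, 3, 12, 24, 72))

condition_times <- function(condition, n_timepoints) {
  if (n_timepoints == 5L) paper_times[[condition]]
  else seq(0, by = 12, length.out = n_timepoints)
}

#' Simulate a full synthetic expression dataset
#'
#' Latent TF abundance follows the lag-1 signed linear dynamics of the
#' planted network; module members track their driver's lagged abundance with
#' a planted sign; background genes are pure noise. The two conditions are
#' independent runs of the same network with different initial states.
#' Observed counts are negative-binomial with mean proportional to the
#' softplus of the latent value; replicates share the latent trajectory and
#' differ only in count noise.
#'
#' @param net A [generate_planted_network()] result.
#' @param module_truth A [make_module_truth()] table; every driver must be a
#'   TF of `net`.
#' @param cfg A [simulation_config()].
#' @return An object of class `synthetic_dataset` with elements `counts`
#'   ([count_matrix()]), `design` ([time_series_design()]), `network`,
#'   `module_truth`, `latent` (per-condition gene x time matrices), and
#'   `config`.
#' @export
simulate_expression <- function(net, module_truth = NULL,
                                cfg = simulation_config()) {
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (is.null(module_truth))
    module_truth <- data.frame(gene = character(), module = character(),
                               driver = character(), sign = integer(),
                               coef = numeric())
  if (!all(module_truth$driver %in% net$tf_ids))
    stop("every module driver must be a TF of the network")

  bg_ids <- if (cfg$n_background > 0)
    sprintf("BG%03d", seq_len(cfg$n_background)) else character(0)
  genes <- c(net$tf_ids, module_truth$gene, bg_ids)
  if (anyDuplicated(genes)) stop("gene identifiers collide")

  set.seed(cfg$seed)
  gene_length <- round(runif(length(genes), 500, 3000))
  names(gene_length) <- genes
  ## background genes have a constant latent level: their counts vary only by
  ## NB noise, making them true negatives for the DEG stage
  bg_latent <- rnorm(length(bg_ids))

  conditions <- c("trehalose", "rehydration")
  prefix <- c(trehalose = "T", rehydration = "R")
  latent <- list(); counts_blocks <- list(); design_blocks <- list()
  W <- dynamics_matrix(net, cfg$coef_scale)
  n_tf <- length(net$tf_ids); Tn <- cfg$n_timepoints
  ## replicate innovations = sqrt(rho) * shared + sqrt(1 - rho) * own draw;
  ## every replicate trajectory is a valid realization of the same linear
  ## system, and rho = 1 collapses to one shared trajectory
  mix <- function(shared, rho) {
    if (rho >= 1) return(function() shared)
    function() sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(rnorm(length(shared)), nrow(shared))
  }
  one_trajectory <- function(innov_tf, innov_x0, innov_mem) {
    X <- matrix(0, n_tf, Tn, dimnames = list(net$tf_ids, NULL))
    X[, 1] <- cfg$init_sd * innov_x0
    for (t in 2:Tn)
      X[, t] <- as.vector(W %*% X[, t - 1]) + cfg$noise_sd * innov_tf[, t]
    Z <- matrix(0, length(genes), Tn, dimnames = list(genes, NULL))
    Z[net$tf_ids, ] <- X
    if (nrow(module_truth)) {
      lagged <- X[module_truth$driver, c(1, seq_len(Tn - 1)), drop = FALSE]
      Z[module_truth$gene, ] <-
        module_truth$sign * module_truth$coef * lagged +
        cfg$noise_sd * innov_mem
    }
    if (length(bg_ids))
      Z[bg_ids, ] <- matrix(bg_latent, length(bg_ids), Tn)
    Z
  }
  nb_mean <- function(Z) {
    rel <- softplus(Z) * gene_length / 1000   # length-weighted abundance
    ## hold the summed abundance of the time-varying block constant across
    ## time points, so constant-latent background genes keep a constant share
    ## of the library (exact nulls under total-count normalization)
    if (length(bg_ids)) {
      tv <- setdiff(genes, bg_ids)
      cs <- colSums(rel[tv, , drop = FALSE])
      rel[tv, ] <- sweep(rel[tv, , drop = FALSE], 2, mean(cs) / cs, "*")
    }
    sweep(rel, 2, colSums(rel), "/") * cfg$library_size
  }
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    rho <- cfg$replicate_cor
    s_tf <- matrix(rnorm(n_tf * Tn), n_tf)
    s_x0 <- rnorm(n_tf)
    s_mem <- matrix(rnorm(max(1, nrow(module_truth)) * Tn),
                    max(1, nrow(module_truth)))
    draw_tf <- mix(s_tf, rho); draw_x0 <- mix(matrix(s_x0), rho)
    draw_mem <- mix(s_mem, rho)
    if (rho >= 1) {
      Z <- one_trajectory(s_tf, s_x0, s_mem)
      latent[[cond]] <- Z
      mu_reps <- rep(list(nb_mean(Z)), cfg$n_replicates)
    } else {
      Zs <- lapply(seq_len(cfg$n_replicates), function(r)
        one_trajectory(draw_tf(), as.vector(draw_x0()), draw_mem()))
      latent[[cond]] <- Zs
      mu_reps <- lapply(Zs, nb_mean)
    }
    times <- condition_times(cond, cfg$n_timepoints)
    for (t in seq_len(cfg$n_timepoints)) for (r in seq_len(cfg$n_replicates)) {
      lab <- sprintf("%s%g_%d", prefix[[cond]], times[t], r)
      m <- pmax(mu_reps[[r]][, t], 1e-8)
      counts_blocks[[lab]] <- if (cfg$nb_dispersion < 1e-12) rpois(length(m), m)
        else rnbinom(length(m), mu = m, size = 1 / cfg$nb_dispersion)
      design_blocks[[lab]] <- data.frame(sample = lab, condition = cond,
                                         time_h = times[t], replicate = r,
                                         stringsAsFactors = FALSE)
    }
  }

  values <- do.call(cbind, counts_blocks)
  rownames(values) <- genes
  des <- do.call(rbind, design_blocks)
  structure(list(
    counts = count_matrix(values, gene_length),
    design = time_series_design(des$sample, des$condition, des$time_h,
                                des$replicate),
    network = net, module_truth = module_truth, latent = latent,
    config = cfg), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes (%d TFs, %d module genes, %d background), %d samples\n",
              nrow(x$counts$values), length(x$network$tf_ids),
              nrow(x$module_truth),
              x$config$n_background, ncol(x$counts$values)))
  invisible(x)
}

#' Generate promoter sequences with planted motif sites
#'
#' Background sequence is i.i.d. with the stated GC content; for each
#' enrichment-plan entry, each promoter of the target module receives one
#' exact-consensus site of the motif at a uniformly chosen position with the
#' stated probability.
#'
#' @param module_truth `data.frame` with columns `gene` and `module` (extra
#'   columns ignored); one promoter is generated per gene.
#' @param pwm_set List of [pwm()] objects (used for consensus sites).
#' @param enrichment_plan `data.frame` with columns `pwm`, `module`,
#'   `insert_probability`.
#' @param upstream_length Promoter length in bp; must be at least the longest
#'   planted PWM.
#' @param gc_content Background G+C fraction.
#' @param seed Integer seed.
#' @return Named character vector of promoter sequences (names = gene ids).
#' @export
generate_promoters <- function(module_truth, pwm_set = list(),
                               enrichment_plan = NULL, upstream_length = 1000L,
                               gc_content = 0.4, seed = 1L) {
  stopifnot(gc_content >= 0, gc_content <= 1)
  names(pwm_set) <- vapply(pwm_set, `[[`, character(1), "id")
  if (is.null(enrichment_plan))
    enrichment_plan <- data.frame(pwm = character(), module = character(),
                                  insert_probability = numeric())
  if (nrow(enrichment_plan)) {
    if (any(enrichment_plan$insert_probability < 0 |
            enrichment_plan$insert_probability > 1))
      stop("insert_probability must be in [0, 1]")
    lens <- vapply(pwm_set[enrichment_plan$pwm], function(p) nrow(p$matrix), 1L)
    if (any(lens > upstream_length))
      stop("PWM longer than upstream_length")
  }
  set.seed(seed)
  base_p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
              G = gc_content / 2, T = (1 - gc_content) / 2)
  seqs <- vapply(seq_len(nrow(module_truth)), function(i) {
    paste(sample(names(base_p), upstream_length, replace = TRUE, prob = base_p),
          collapse = "")
  }, character(1))
  names(seqs) <- module_truth$gene
  for (i in seq_len(nrow(enrichment_plan))) {
    p <- pwm_set[[enrichment_plan$pwm[i]]]
    site <- pwm_consensus(p)
    members <- module_truth$gene[module_truth$module == enrichment_plan$module[i]]
    for (g in members) if (runif(1) < enrichment_plan$insert_probability[i]) {
      pos <- sample.int(upstream_length - nchar(site) + 1L, 1L)
      substr(seqs[g], pos, pos + nchar(site) - 1L) <- site
    }
  }
  seqs
}
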