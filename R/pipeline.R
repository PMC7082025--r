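## Pipeline orchestration: configuration, a fully synthetic study with
## planted ground truth, and the staged end-to-end run
## deg -> infer (x2 conditions) -> integrate -> motifs -> modules ->
## regulate -> contract.

#' Pipeline configuration
#'
#' Defaults mirror the analysis conventions of the method: 100 boosting
#' trees, lag 1, 10,000 randomization iterations, upstream windows from 100
#' to 10,000 bp, signed R-squared threshold 0.75, candidate minimum module
#' sizes 1..200, alpha 0.05, and similarity e-value gates 1e-5 (PWM bridge) /
#' 1e-15 (cross-species homology).
#'
#' @param ... Named overrides of the defaults; unknown keys are rejected.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    alpha = 0.05, trees = 100L, lag = 1L,
    motif_null_iterations = 10000L,
    windows = c(100, 500, 1000, 2000, 3000, 4000, 5000, 10000),
    enrichment_draws = 1000L, r2_threshold = 0.75, powers = 1:20,
    size_range = 1:200, max_clusters = 30L, max_lag = 2L,
    e_pwm = 1e-5, e_homology = 1e-15, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

## Z-score rows; constant rows map to 0.
zscore_rows <- function(m) {
  mu <- rowMeans(m); s <- apply(m, 1, sd)
  s[s == 0] <- Inf
  (m - mu) / s
}

## Replicate-averaged expression per time point for one condition,
## columns ordered by time.
timepoint_average <- function(expr, design, condition) {
  des <- design[design$condition == condition, , drop = FALSE]
  times <- sort(unique(des$time_h))
  out <- sapply(times, function(t)
    rowMeans(expr[, des$sample[des$time_h == t], drop = FALSE]))
  colnames(out) <- as.character(times)
  out
}

## One expression matrix per replicate (genes x timepoints), for the
## boosted-tree scoring which pools replicates as training pairs.
replicate_matrices <- function(expr, design, condition) {
  des <- design[design$condition == condition, , drop = FALSE]
  times <- sort(unique(des$time_h))
  lapply(sort(unique(des$replicate)), function(r) {
    cols <- vapply(times, function(t)
      des$sample[des$time_h == t & des$replicate == r][1], character(1))
    m <- expr[, cols, drop = FALSE]
    colnames(m) <- as.character(times)
    m
  })
}

#' Build a fully synthetic study with planted ground truth
#'
#' The planted scenario mirrors the structure the pipeline is designed to
#' recover: a master regulator with zero in-degree sits above planted
#' feed-forward and feedback loops; the members of the first feed-forward
#' loop and the master each drive a coexpressed module; module promoters
#' carry planted consensus motifs; the master and the first loop's TFs have
#' no homolog in the reference species' network while peripheral TFs do.
#'
#' @param seed Integer seed controlling every random choice.
#' @param n_tf Number of transcription factors.
#' @param n_extra_edges Random edges beyond motif and master edges.
#' @param genes_per_module Module size.
#' @param n_timepoints,n_replicates Time-series dimensions per condition.
#' @param noise_sd,nb_dispersion,library_size,replicate_cor Passed to
#'   [simulation_config()].
#' @param upstream_length Promoter length in bp.
#' @param insert_probability Planted motif insertion probability.
#' @return List of class `synthetic_study`: `data`
#'   ([simulate_expression()] result), `promoters`, `pwms`, `pwm_hits`,
#'   `go_annotation`, `reference_network`, `homology_hits`, `hsf_id`,
#'   `module_drivers`.
#' @export
synthetic_study <- function(seed = 1L, n_tf = 30L, n_extra_edges = 25L,
                            genes_per_module = 30L, n_timepoints = 20L,
                            n_replicates = 3L, noise_sd = 1,
                            nb_dispersion = 0.02, library_size = 2e6,
                            replicate_cor = 0.3, upstream_length = 1000L,
                            insert_probability = 0.9) {
  net <- generate_planted_network(
    n_tf, n_extra_edges, positive_ratio = 0.7,
    motif_requests = c("coherent_ffl", "coherent_ffl", "incoherent_ffl",
                       "positive_fbl"),
    seed = seed, master = TRUE, hub_bias = TRUE, master_out = 2L)
  master <- net$master_regulator
  ## module drivers: the roots of the two master-driven feed-forward loops
  ## plus the master itself; roots are siblings through the white-noise
  ## master, so lag-1 inference does not confuse them with each other
  drivers <- c(M1 = net$planted_motifs[[1]]$nodes[1],
               M2 = net$planted_motifs[[2]]$nodes[1],
               M3 = master)
  truth <- make_module_truth(drivers, genes_per_module,
                             positive_fraction = 1, coef_range = c(1.5, 2.5),
                             seed = seed + 1L)
  cfg <- simulation_config(n_timepoints = n_timepoints,
                           n_replicates = n_replicates, noise_sd = noise_sd,
                           nb_dispersion = nb_dispersion,
                           library_size = library_size,
                           replicate_cor = replicate_cor,
                           seed = seed + 2L)
  data <- simulate_expression(net, truth, cfg)

  ## one sharply informative PWM per module driver
  consensi <- c("ACGTACGT", "TTGACGCA", "GGATCCAT", "CACGTGTT")
  pwms <- lapply(seq_along(drivers), function(i) {
    b <- strsplit(consensi[i], "")[[1]]
    m <- matrix(0.01, length(b), 4, dimnames = list(NULL, BASES))
    m[cbind(seq_along(b), match(b, BASES))] <- 0.97
    pwm(sprintf("MOTIF_%s", names(drivers)[i]), m,
        tf = sprintf("REF_%s", drivers[[i]]))
  })
  plan <- data.frame(pwm = vapply(pwms, `[[`, character(1), "id"),
                     module = names(drivers),
                     insert_probability = insert_probability)
  prom_truth <- rbind(truth[, c("gene", "module")],
                      data.frame(gene = sprintf("BG%03d",
                                                seq_len(cfg$n_background)),
                                 module = "background"))
  promoters <- generate_promoters(prom_truth, pwms, plan, upstream_length,
                                  gc_content = 0.4, seed = seed + 3L)
  ## similarity bridge linking each driver TF to its motif's source TF
  pwm_hits <- data.frame(query = unname(drivers),
                         subject = sprintf("REF_%s", unname(drivers)),
                         evalue = 1e-10, stringsAsFactors = FALSE)

  go <- rbind(
    data.frame(gene = net$tf_ids, go = "GO:0003700"),
    data.frame(gene = truth$gene, go = paste0("GO:MOD_", truth$module)),
    data.frame(gene = sprintf("BG%03d", seq_len(cfg$n_background)),
               go = "GO:BACKGROUND"))

  ## reference species network over its own TF ids; peripheral TFs are
  ## homologous to it, the master and module-driving loop TFs are not
  ref_ids <- sprintf("Dm%02d", 1:10)
  set.seed(seed + 4L)
  ref_edges <- unique(data.frame(
    source = sample(ref_ids, 20, replace = TRUE),
    target = sample(ref_ids, 20, replace = TRUE)))
  ref_edges <- ref_edges[ref_edges$source != ref_edges$target, ]
  peripheral <- setdiff(net$tf_ids, c(drivers, master))
  peripheral <- peripheral[as.integer(sub("TF", "", peripheral)) > 13]
  homology_hits <- data.frame(
    query = peripheral,
    subject = ref_ids[(seq_along(peripheral) - 1L) %% length(ref_ids) + 1L],
    evalue = 1e-30, stringsAsFactors = FALSE)

  structure(list(data = data, promoters = promoters, pwms = pwms,
                 pwm_hits = pwm_hits, go_annotation = go,
                 reference_network = ref_edges,
                 homology_hits = homology_hits,
                 hsf_id = drivers[["M2"]], module_drivers = drivers,
                 seed = seed),
            class = "synthetic_study")
}

## Threshold the score matrix by the scale-free rule; when no candidate
## qualifies, fall back to keeping the top 2 * n_tf scoring edges (about the
## edge density regulatory networks of this size show).
threshold_with_fallback <- function(scores, alpha = 0.05) {
  tryCatch(select_threshold(scores, alpha = alpha),
           error = function(e) {
             norm <- normalize_scores(scores)
             v <- sort(norm[!is.na(norm)], decreasing = TRUE)
             a <- v[min(length(v), 2L * nrow(scores))]
             warning("scale-free threshold selection failed (", conditionMessage(e),
                     "); keeping the top ", 2L * nrow(scores), " edges")
             structure(list(selected_a = a, scan = NULL,
                            normalized_scores = norm, alpha = alpha),
                       class = "threshold_scan")
           })
}

#' Run the full analysis pipeline
#'
#' Executes all stages on a [synthetic_study()] (or equivalently shaped
#' inputs): differential expression per condition, TF/target partition,
#' per-condition network inference with scale-free thresholding and
#' cross-correlation signs, integration, signed motif census with the
#' Erdos-Renyi null, coexpression module detection, GO enrichment, joint
#' motif/Granger regulation calls, cross-species conservation flags, and
#' contraction to the species-specific core.
#'
#' @param study A [synthetic_study()] (list with `data`, `promoters`,
#'   `pwms`, `pwm_hits`, `go_annotation`, `reference_network`,
#'   `homology_hits`, `hsf_id`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, stage artifacts are
#'   written as TSV/JSON/FASTA/GraphML with an MD5 manifest.
#' @return List of class `pipeline_result` with one element per stage.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out_dir = NULL) {
  counts <- study$data$counts; design <- study$data$design
  conditions <- unique(design$condition)
  expr <- rpkm_transform(counts)
  pca <- principal_components(expr, 3L)

  deg <- lapply(conditions, function(cond)
    nb_lrt(counts, design, cond, go_annotation = study$go_annotation,
           alpha = config$alpha))
  names(deg) <- conditions
  venn <- partition_tf_targets(deg, study$go_annotation)

  nets <- list(); scans <- list()
  for (cond in conditions) {
    tf_degs <- deg[[cond]]$gene[deg[[cond]]$is_deg & deg[[cond]]$is_tf]
    if (length(tf_degs) < 3) {
      warning("fewer than 3 TF DEGs in ", cond, "; using all TF DEGs pooled")
      tf_degs <- unique(unlist(lapply(deg, function(d)
        d$gene[d$is_deg & d$is_tf])))
    }
    if (length(tf_degs) < 3) {
      warning("fewer than 3 TF DEGs overall; using every annotated TF")
      tf_degs <- intersect(counts$gene_ids, unique(
        study$go_annotation$gene[study$go_annotation$go == "GO:0003700"]))
    }
    ## boosted trees are fed log2(RPKM + 1): tree splits are invariant to
    ## the monotone transform on the features, and the log stabilizes the
    ## multiplicative count noise of the regression target
    reps <- lapply(replicate_matrices(expr, design, cond), function(m)
      log2(m[tf_degs, , drop = FALSE] + 1))
    scores <- score_regulators(reps, n_trees = config$trees,
                               lag = config$lag, seed = config$seed)
    scan <- threshold_with_fallback(scores, config$alpha)
    ed <- edges_at(scan$normalized_scores, scan$selected_a)
    avg <- timepoint_average(expr, design, cond)[tf_degs, , drop = FALSE]
    nets[[cond]] <- suppressWarnings(
      assign_signs(ed, avg, condition = cond, lag = config$lag))
    scans[[cond]] <- scan
  }
  integrated <- integrate_networks(nets[[1]], nets[[2]])

  census <- census_motifs(integrated)
  pos_ratio <- if (nrow(integrated$edges))
    mean(integrated$edges$sign == 1) else 0.5
  null_test <- erdos_renyi_null_test(
    census, n_nodes = length(integrated$nodes),
    n_edges = nrow(integrated$edges), positive_ratio = pos_ratio,
    iterations = config$motif_null_iterations, seed = config$seed)

  ## modules from non-TF DEGs (both conditions pooled)
  tf_genes <- unique(study$go_annotation$gene[
    study$go_annotation$go == "GO:0003700"])
  deg_any <- unique(unlist(lapply(deg, function(d) d$gene[d$is_deg])))
  mod_genes <- setdiff(deg_any, tf_genes)
  avg_all <- do.call(cbind, lapply(conditions, function(cond)
    timepoint_average(expr, design, cond)))
  z_all <- zscore_rows(avg_all)
  zm <- z_all[mod_genes, , drop = FALSE]
  power_sel <- tryCatch(
    select_soft_power(zm, powers = config$powers,
                      r2_threshold = config$r2_threshold),
    error = function(e) {
      warning("soft-power selection failed (", conditionMessage(e),
              "); using power 6")
      list(selected_power = 6L, table = NULL)
    })
  adj <- abs(cor(t(zm)))^power_sel$selected_power
  diag(adj) <- 0
  tom <- tom_dissimilarity(adj)
  partition <- cluster_modules(tom, zm, size_range = config$size_range,
                               max_clusters = config$max_clusters)
  enrichment <- go_enrichment(partition, study$go_annotation,
                              universe = counts$gene_ids)

  ## regulation calls: motif gate x Granger gate
  links <- tf_pwm_links(study$pwm_hits, study$pwms,
                        e_threshold = config$e_pwm)
  links <- links[links$tf %in% integrated$nodes, , drop = FALSE]
  pwms <- study$pwms
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")
  modules <- setdiff(unique(partition$assignment$module), UNASSIGNED)
  bg_genes <- setdiff(names(study$promoters),
                      c(partition$assignment$gene, tf_genes))
  windows <- config$windows[config$windows <=
                              max(nchar(study$promoters))]
  motif_rows <- list()
  if (nrow(links) == 0 || !length(modules)) links <- links[0, , drop = FALSE]
  for (i in seq_len(nrow(links))) for (mod in modules) {
    members <- partition$assignment$gene[partition$assignment$module == mod]
    members <- intersect(members, names(study$promoters))
    if (!length(members)) next
    mh <- tryCatch(
      motif_enrichment(pwms[[links$pwm[i]]], study$promoters[members],
                       study$promoters[bg_genes], windows,
                       n_draws = config$enrichment_draws,
                       seed = config$seed, alpha = config$alpha),
      error = function(e) {
        warning("motif enrichment skipped for ", links$tf[i], " -> ", mod,
                ": ", conditionMessage(e))
        NULL
      })
    if (is.null(mh)) next
    motif_rows[[length(motif_rows) + 1L]] <- data.frame(
      tf = links$tf[i], module = mod, min_p = min(mh$table$p),
      any_window_significant = mh$any_window_significant,
      stringsAsFactors = FALSE)
  }
  motif_table <- do.call(rbind, motif_rows)
  empty_calls <- data.frame(tf = character(), module = character(),
                            called = logical(), motif_min_p = numeric(),
                            granger_min_bh_p = numeric())
  if (is.null(motif_table)) {
    granger <- NULL
    calls <- empty_calls
  } else {
  tf_profiles <- lapply(conditions, function(cond) {
    cols <- if (cond == conditions[1])
      seq_len(ncol(avg_all) / 2) else (ncol(avg_all) / 2 + 1):ncol(avg_all)
    z_all[unique(links$tf), cols, drop = FALSE]
  })
  names(tf_profiles) <- conditions
  module_profiles <- lapply(conditions, function(cond) {
    cols <- if (cond == conditions[1])
      seq_len(ncol(avg_all) / 2) else (ncol(avg_all) / 2 + 1):ncol(avg_all)
    sapply(modules, function(mod) {
      members <- partition$assignment$gene[partition$assignment$module == mod]
      colMeans(z_all[members, cols, drop = FALSE])
    }) |> t()
  })
  names(module_profiles) <- conditions
  granger <- granger_scan(tf_profiles, module_profiles,
                          max_lag = config$max_lag)
  calls <- call_regulators(motif_table, granger, alpha = config$alpha)
  }

  hom <- load_homology(study$homology_hits, e_threshold = config$e_homology)
  conserved <- flag_conserved_edges(integrated, study$reference_network, hom)
  contracted <- contract_network(integrated, conserved, hom, calls,
                                 hsf_id = study$hsf_id)

  result <- structure(list(
    pca = pca, deg = deg, venn = venn, scans = scans, networks = nets,
    integrated = integrated, census = census, null_test = null_test,
    power_selection = power_sel, partition = partition,
    enrichment = enrichment, motif_table = motif_table, granger = granger,
    calls = calls, conserved = conserved, contracted = contracted,
    config = config), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    p <- function(f) file.path(out_dir, f)
    for (cond in conditions) {
      paths[[paste0("deg_", cond)]] <- p(sprintf("deg_%s.tsv", cond))
      write.table(deg[[cond]], paths[[paste0("deg_", cond)]], sep = "\t",
                  quote = FALSE, row.names = FALSE)
      paths[[paste0("net_", cond)]] <-
        write_network_tsv(nets[[cond]], p(sprintf("network_%s.tsv", cond)))
    }
    paths$integrated <- write_network_tsv(integrated, p("network_integrated.tsv"))
    paths$graphml <- write_network_graphml(integrated,
                                           p("network_integrated.graphml"))
    paths$venn <- p("venn_counts.json")
    jsonlite::write_json(list(tf = venn$tf$counts, other = venn$other$counts),
                         paths$venn, auto_unbox = TRUE)
    paths$census <- p("motif_census.json")
    jsonlite::write_json(list(counts = as.list(census$counts),
                              p_values = as.list(null_test$p_value)),
                         paths$census, auto_unbox = TRUE, digits = NA)
    paths$partition <- p("modules.tsv")
    write.table(partition$assignment, paths$partition, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths$calls <- p("regulation_calls.tsv")
    write.table(calls, paths$calls, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$contracted <- p("contracted_nodes.tsv")
    write.table(contracted$nodes, paths$contracted, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths$config <- p("config.json")
    jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE)
    manifest <- build_manifest(paths)
    write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    result$manifest <- manifest
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (cond in names(x$deg))
    cat(sprintf("  %s: %d DEGs (%d TFs)\n", cond, sum(x$deg[[cond]]$is_deg),
                sum(x$deg[[cond]]$is_deg & x$deg[[cond]]$is_tf)))
  cat(sprintf("  integrated network: %d nodes, %d edges\n",
              length(x$integrated$nodes), nrow(x$integrated$edges)))
  cat(sprintf("  modules: %d; regulation calls: %d; most upstream: %s\n",
              sum(unique(x$partition$assignment$module) != UNASSIGNED),
              sum(x$calls$called),
              paste(most_upstream(x$contracted), collapse = ", ")))
  invisible(x)
}

#' Precision and recall of inferred edges against a planted network
#'
#' @param inferred A [signed_network()].
#' @param planted A [generate_planted_network()] result.
#' @return Named vector: precision, recall, n_inferred, n_planted.
#' @export
edge_precision_recall <- function(inferred, planted) {
  key <- function(s, t) paste(s, t, sep = "\r")
  inf <- key(inferred$edges$source, inferred$edges$target)
  tru <- key(planted$edges$source, planted$edges$target)
  tp <- length(intersect(inf, tru))
  c(precision = if (length(inf)) tp / length(inf) else NA_real_,
    recall = if (length(tru)) tp / length(tru) else NA_real_,
    n_inferred = length(inf), n_planted = length(tru))
}
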