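## Signed three-node motif census (feed-forward and feedback loops) and the
## Erdos-Renyi randomization null with binomially assigned edge signs.

## Fast class counts from a signed adjacency matrix (+1/-1/0).
## FFL instances are ordered triples (r, m, t) with edges r->m, m->t, r->t;
## FBLs are directed 3-cycles counted once per rotation class.
motif_counts_matrix <- function(S) {
  P <- (S > 0) * 1; N <- (S < 0) * 1
  path_pos <- P %*% P + N %*% N     # r->m->t with positive sign product
  path_neg <- P %*% N + N %*% P
  coherent <- sum(path_pos * P) + sum(path_neg * N)
  incoherent <- sum(path_pos * N) + sum(path_neg * P)
  A <- P + N
  total_fbl <- sum(diag(A %*% A %*% A)) / 3
  signed_fbl <- sum(diag((P - N) %*% (P - N) %*% (P - N))) / 3
  c(coherent_ffl = coherent, incoherent_ffl = incoherent,
    positive_fbl = (total_fbl + signed_fbl) / 2,
    negative_fbl = (total_fbl - signed_fbl) / 2)
}

#' Census of signed three-node motifs
#'
#' Enumerates feed-forward loops (ordered triples `(r, m, t)` with edges
#' `r->m`, `m->t`, `r->t`) and feedback loops (directed 3-cycles, one count
#' per rotation class). An FFL is coherent when the sign of the direct edge
#' equals the product of the indirect path's signs; an FBL is positive when
#' its number of negative edges is even. Triples forming both structures are
#' counted in both classes.
#'
#' @param net A [signed_network()] (or an edge `data.frame` accepted by it).
#' @return List of class `motif_census` with `counts` and per-class
#'   `instances` (data frames of node triples with edge signs).
#' @export
census_motifs <- function(net) {
  if (!inherits(net, "signed_network")) net <- signed_network(net)
  S <- sign_matrix(net)
  n <- nrow(S)
  inst <- list(coherent_ffl = list(), incoherent_ffl = list(),
               positive_fbl = list(), negative_fbl = list())
  if (n >= 3 && nrow(net$edges)) {
    idx <- which(S != 0, arr.ind = TRUE)
    for (e in seq_len(nrow(idx))) {
      r <- idx[e, 1]; m <- idx[e, 2]
      ## FFLs through edge r->m
      t_hits <- which(S[m, ] != 0 & S[r, ] != 0)
      t_hits <- t_hits[t_hits != r]
      for (t in t_hits) {
        cls <- if (S[r, t] == S[r, m] * S[m, t]) "coherent_ffl"
          else "incoherent_ffl"
        inst[[cls]][[length(inst[[cls]]) + 1L]] <- data.frame(
          regulator = rownames(S)[r], mediator = rownames(S)[m],
          target = rownames(S)[t],
          sign_rm = S[r, m], sign_mt = S[m, t], sign_rt = S[r, t])
      }
      ## FBLs r->m->t->r, canonical representative: r is the smallest index
      if (m < r) next                     # canonical: r is the smallest index
      t_cyc <- which(S[m, ] != 0 & S[, r] != 0)
      t_cyc <- t_cyc[t_cyc != r & t_cyc > r]
      for (t in t_cyc) {
        n_neg <- sum(c(S[r, m], S[m, t], S[t, r]) < 0)
        cls <- if (n_neg %% 2 == 0) "positive_fbl" else "negative_fbl"
        inst[[cls]][[length(inst[[cls]]) + 1L]] <- data.frame(
          a = rownames(S)[r], b = rownames(S)[m], c = rownames(S)[t],
          sign_ab = S[r, m], sign_bc = S[m, t], sign_ca = S[t, r])
      }
    }
  }
  instances <- lapply(inst, function(l)
    if (length(l)) do.call(rbind, l) else NULL)
  structure(list(counts = vapply(instances, function(d)
    if (is.null(d)) 0L else nrow(d), integer(1)),
    instances = instances), class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("motif_census:",
      paste(names(x$counts), x$counts, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

## Uniform simple directed graph with exactly m edges (no self-loops,
## mutual edges allowed), returned as edge endpoints.
sample_gnm_directed <- function(n, m) {
  cell <- sample.int(n * (n - 1L), m)      # off-diagonal cells, column-major
  col <- (cell - 1L) %/% (n - 1L) + 1L
  row <- (cell - 1L) %% (n - 1L) + 1L
  row <- row + (row >= col)                # skip the diagonal entry
  cbind(row, col)
}

#' Randomization test of motif counts against an Erdos-Renyi null
#'
#' Each null draw is a uniform simple digraph with exactly `n_edges` edges
#' and no self-loops; each edge is positive with probability
#' `positive_ratio`. The per-class p-value is the fraction of draws whose
#' count strictly exceeds the observed count.
#'
#' @param observed A [census_motifs()] result (or a named count vector).
#' @param n_nodes,n_edges Size of the null model (match the observed
#'   network).
#' @param positive_ratio Probability of a positive edge sign.
#' @param iterations Number of null draws.
#' @param seed Integer seed.
#' @param alpha Significance level reported alongside the p-values.
#' @return List of class `null_test_result`: `observed`, `p_value`,
#'   `significant`, `null_counts` (iterations x class matrix), and the null
#'   parameters.
#' @export
erdos_renyi_null_test <- function(observed, n_nodes, n_edges, positive_ratio,
                                  iterations = 10000L, seed = 1L,
                                  alpha = 0.05) {
  if (n_edges > n_nodes * (n_nodes - 1))
    stop("infeasible n_edges for a simple digraph without self-loops")
  if (iterations < 1) stop("iterations must be >= 1")
  obs <- if (inherits(observed, "motif_census")) observed$counts else observed
  obs <- obs[MOTIF_CLASSES]
  set.seed(seed)
  null_counts <- matrix(0, iterations, 4,
                        dimnames = list(NULL, MOTIF_CLASSES))
  S <- matrix(0, n_nodes, n_nodes)
  for (it in seq_len(iterations)) {
    ij <- sample_gnm_directed(n_nodes, n_edges)
    S[] <- 0
    S[ij] <- ifelse(runif(n_edges) < positive_ratio, 1, -1)
    null_counts[it, ] <- motif_counts_matrix(S)
  }
  p <- colMeans(sweep(null_counts, 2, obs, ">"))
  structure(list(observed = obs, p_value = p, significant = p < alpha,
                 null_counts = null_counts,
                 params = list(n_nodes = n_nodes, n_edges = n_edges,
                               positive_ratio = positive_ratio,
                               iterations = iterations, seed = seed)),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat("randomization test (", x$params$iterations, " draws):\n", sep = "")
  for (cl in names(x$p_value))
    cat(sprintf("  %-15s observed %4d  p = %.4f%s\n", cl, x$observed[[cl]],
                x$p_value[[cl]], if (x$significant[[cl]]) " *" else ""))
  invisible(x)
}
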