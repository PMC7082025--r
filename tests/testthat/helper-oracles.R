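## Independent oracles and shared fixtures, kept deliberately separate from
## the implementation paths they check.

## Brute-force signed three-node motif census by scanning every ordered
## triple against the definitions.
brute_census <- function(S) {
  n <- nrow(S)
  counts <- c(coherent_ffl = 0L, incoherent_ffl = 0L,
              positive_fbl = 0L, negative_fbl = 0L)
  for (r in seq_len(n)) for (m in seq_len(n)) {
    if (r == m || S[r, m] == 0) next
    for (t in seq_len(n)) {
      if (t == r || t == m) next
      if (S[m, t] != 0 && S[r, t] != 0) {
        cls <- if (S[r, t] == S[r, m] * S[m, t]) "coherent_ffl"
          else "incoherent_ffl"
        counts[cls] <- counts[cls] + 1L
      }
    }
  }
  ## 3-cycles once per rotation class: each unordered triple a < b < cc has
  ## exactly two possible orientations
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    if (a >= b || b >= cc) next
    for (ord in list(c(a, b, cc), c(a, cc, b))) {
      s1 <- S[ord[1], ord[2]]; s2 <- S[ord[2], ord[3]]; s3 <- S[ord[3], ord[1]]
      if (s1 != 0 && s2 != 0 && s3 != 0) {
        cls <- if (sum(c(s1, s2, s3) < 0) %% 2 == 0) "positive_fbl"
          else "negative_fbl"
        counts[cls] <- counts[cls] + 1L
      }
    }
  }
  counts
}

## Random signed digraph as a sign matrix with named nodes.
random_signed_digraph <- function(n, m, positive_ratio = 0.5) {
  ids <- sprintf("N%02d", seq_len(n))
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  cells <- which(row(S) != col(S))
  pick <- sample(cells, min(m, length(cells)))
  S[pick] <- ifelse(runif(length(pick)) < positive_ratio, 1, -1)
  S
}

sign_matrix_to_network <- function(S) {
  idx <- which(S != 0, arr.ind = TRUE)
  signed_network(data.frame(source = rownames(S)[idx[, 1]],
                            target = colnames(S)[idx[, 2]],
                            sign = S[idx], stringsAsFactors = FALSE),
                 nodes = rownames(S))
}

## Literal step-up definition of the BH adjustment.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(m * p[o[js]] / js))
  }
  adj
}

## Score matrix with a preferential-attachment signal above 0.5 and dense
## two-tier noise below: the 0.45 tier is a dense random layer, the 0.15
## tier completes the digraph (a complete graph has a single degree value,
## so its scale-free fit is undefined).
planted_score_matrix <- function(seed, n = 200) {
  set.seed(seed)
  g <- igraph::sample_pa(n, m = 2, directed = TRUE)
  el <- igraph::as_edgelist(g)
  ids <- sprintf("T%03d", seq_len(n))
  S <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  S[el] <- runif(nrow(el), 0.5, 1)
  free <- which(is.na(S) & row(S) != col(S))
  mid <- sample(free, 12000)
  S[mid] <- 0.45
  S[setdiff(free, mid)] <- 0.15
  S
}

## Three coherent planted modules with within-module correlation ~0.95.
planted_module_data <- function(seed, n_modules = 3, size = 50,
                                n_samples = 40, noise = 0.23) {
  set.seed(seed)
  f <- matrix(rnorm(n_modules * n_samples), n_modules)
  truth <- rep(seq_len(n_modules), each = size)
  X <- f[truth, ] + matrix(rnorm(n_modules * size * n_samples, 0, noise),
                           n_modules * size)
  rownames(X) <- sprintf("G%03d", seq_len(nrow(X)))
  list(x = X, truth = truth)
}

## A sharply informative PWM whose consensus is the given string.
consensus_pwm <- function(id, consensus, tf = NA_character_) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix(0.01, length(b), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(b), match(b, colnames(m)))] <- 0.97
  pwm(id, m, tf = tf)
}
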