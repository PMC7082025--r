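## Comparison of the inferred network against a reference species' regulatory
## network through a homology map, and contraction to the species-specific
## core (most-upstream regulator, FFL blocks, module regulators).

#' Load a homology map from a similarity hit table
#'
#' Accepts a 12-column BLAST tabular file (outfmt 6) or a `data.frame` with
#' columns `query`, `subject`, `evalue`; only hits with e-value strictly
#' below the threshold are retained.
#'
#' @param hits File path or `data.frame`.
#' @param e_threshold Strict e-value cutoff.
#' @return `data.frame` of class `homology_map`: query, subject, evalue.
#' @export
load_homology <- function(hits, e_threshold = 1e-15) {
  if (is.character(hits)) {
    raw <- read.delim(hits, header = FALSE, stringsAsFactors = FALSE)
    bad <- ncol(raw) < 12
    if (bad) stop("expected 12-column BLAST tabular input")
    hits <- data.frame(query = as.character(raw[[1]]),
                       subject = as.character(raw[[2]]),
                       evalue = suppressWarnings(as.numeric(raw[[11]])),
                       stringsAsFactors = FALSE)
  } else {
    hits <- as.data.frame(hits)[, c("query", "subject", "evalue")]
  }
  malformed <- is.na(hits$evalue) | !nzchar(hits$query) | !nzchar(hits$subject)
  if (any(malformed))
    message(sum(malformed), " malformed row(s) skipped")
  hits <- hits[!malformed & hits$evalue < e_threshold, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("homology_map", "data.frame")
  attr(hits, "e_threshold") <- e_threshold
  hits
}

homologs_of <- function(hom, id) unique(hom$subject[hom$query == id])

#' Flag edges conserved in a reference network
#'
#' An edge `u -> v` is conserved when some reference homolog of `u` reaches
#' some homolog of `v` by a directed path of length >= 1 in the reference
#' network; endpoints without homologs yield unconserved edges.
#'
#' @param net A [signed_network()].
#' @param ref Reference network: an igraph object or an edge `data.frame`
#'   (source, target).
#' @param hom A [load_homology()] map.
#' @param max_path_length Optional bound on the path length (default
#'   unbounded).
#' @return Logical vector, one flag per edge of `net`.
#' @export
flag_conserved_edges <- function(net, ref, hom, max_path_length = Inf) {
  if (!igraph::is_igraph(ref))
    ref <- igraph::graph_from_data_frame(ref[, c("source", "target")],
                                         directed = TRUE)
  ref_nodes <- igraph::V(ref)$name
  edges <- net$edges
  if (!nrow(edges)) return(logical(0))
  dmat <- igraph::distances(ref, mode = "out")
  vapply(seq_len(nrow(edges)), function(i) {
    hu <- intersect(homologs_of(hom, edges$source[i]), ref_nodes)
    hv <- intersect(homologs_of(hom, edges$target[i]), ref_nodes)
    if (!length(hu) || !length(hv)) return(FALSE)
    d <- dmat[hu, hv, drop = FALSE]
    any(is.finite(d) & d >= 1 & d <= max_path_length)
  }, logical(1))
}

## FFL node triples of an unsigned edge set, with their edges.
ffl_triples <- function(edges) {
  if (!nrow(edges)) return(list())
  adj <- split(edges$target, edges$source)
  out <- list()
  for (i in seq_len(nrow(edges))) {
    r <- edges$source[i]; m <- edges$target[i]
    tt <- intersect(adj[[m]], adj[[r]])
    tt <- setdiff(tt, r)
    for (t in tt)
      out[[length(out) + 1L]] <- list(
        nodes = c(r, m, t),
        edges = rbind(c(r, m), c(m, t), c(r, t)))
  }
  out
}

#' Contract a network to its species-specific regulatory core
#'
#' Candidate TFs are those without a reference homolog that directly regulate
#' at least one module (per the regulation calls). Retained are candidates
#' that (1) are most upstream (no in-edge among species-specific edges), or
#' (2) are components of a feed-forward loop, plus (3) the designated heat
#' shock factor and the connector TFs on shortest directed species-specific
#' paths between retained TFs. Only species-specific (unconserved) edges are
#' kept. Overlapping FFLs (sharing an edge) among retained nodes are
#' collapsed into single block nodes, and TFs strictly between the heat
#' shock factor and a block are elided in favor of a direct edge.
#'
#' @param net A [signed_network()] (the integrated network).
#' @param conserved Logical per-edge conservation flags from
#'   [flag_conserved_edges()].
#' @param hom A [load_homology()] map.
#' @param calls A [call_regulators()] table.
#' @param hsf_id Identifier of the heat shock factor (may be absent from the
#'   network, with a message).
#' @return List of class `contracted_network`: `nodes` (id, type), `edges`,
#'   `blocks` (block id -> TF members), `module_edges` (regulator -> module),
#'   `retained` breakdown by criterion.
#' @export
contract_network <- function(net, conserved, hom, calls, hsf_id) {
  edges <- net$edges
  stopifnot(length(conserved) == nrow(edges))
  spec <- edges[!conserved, , drop = FALSE]      # species-specific edges
  has_hom <- vapply(net$nodes, function(v) length(homologs_of(hom, v)) > 0,
                    logical(1))
  direct_regulators <- unique(calls$tf[calls$called])
  candidates <- setdiff(intersect(direct_regulators, net$nodes),
                        net$nodes[has_hom])
  if (!length(candidates)) {
    warning("empty candidate set; contraction is empty")
    return(structure(list(nodes = data.frame(id = character(),
                                             type = character()),
                          edges = spec[0, ], blocks = list(),
                          module_edges = calls[0, ],
                          retained = list()), class = "contracted_network"))
  }
  ## most-upstream: no in-edge within the species-specific subgraph induced
  ## on the candidate set
  cand_edges <- spec[spec$source %in% candidates &
                       spec$target %in% candidates, , drop = FALSE]
  crit1 <- setdiff(candidates, cand_edges$target)
  ffls <- ffl_triples(spec)
  ffl_nodes <- unique(unlist(lapply(ffls, `[[`, "nodes")))
  crit2 <- intersect(candidates, ffl_nodes)
  core <- union(crit1, crit2)

  g <- igraph::graph_from_data_frame(spec[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  connectors <- character(0)
  for (u in core) for (v in setdiff(core, u)) {
    sp <- suppressWarnings(igraph::shortest_paths(g, from = u, to = v,
                                                  mode = "out")$vpath[[1]])
    if (length(sp) > 2)
      connectors <- union(connectors, names(sp)[-c(1, length(sp))])
  }
  if (!hsf_id %in% net$nodes) {
    message("heat shock factor ", hsf_id, " absent from the network")
    hsf <- character(0)
  } else hsf <- hsf_id
  retained <- unique(c(core, connectors, hsf))

  kept <- spec[spec$source %in% retained & spec$target %in% retained, ,
               drop = FALSE]

  ## FFLs fully inside the retained set; merge FFLs sharing an edge
  rffl <- Filter(function(f) all(f$nodes %in% retained), ffl_triples(kept))
  blocks <- list()
  if (length(rffl)) {
    ekey <- lapply(rffl, function(f) paste(f$edges[, 1], f$edges[, 2]))
    comp <- seq_along(rffl)
    repeat {
      changed <- FALSE
      for (i in seq_along(rffl)) for (j in seq_along(rffl)) {
        if (comp[i] != comp[j] && length(intersect(ekey[[i]], ekey[[j]]))) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (ci in unique(comp)) {
      members <- unique(unlist(lapply(rffl[comp == ci], `[[`, "nodes")))
      nf <- sum(comp == ci)
      blocks[[sprintf("FFL_block%d", length(blocks) + 1L)]] <-
        list(members = members, n_ffls = nf)
    }
  }

  node_of <- setNames(rep(NA_character_, length(retained)), retained)
  for (b in names(blocks)) node_of[blocks[[b]]$members] <- b
  plain <- retained[is.na(node_of[retained])]
  node_of[plain] <- plain

  cedges <- unique(data.frame(source = node_of[kept$source],
                              target = node_of[kept$target],
                              stringsAsFactors = FALSE, row.names = NULL))
  cedges <- cedges[cedges$source != cedges$target, , drop = FALSE]

  ## elide plain TFs strictly between the heat shock factor and a block
  if (length(hsf) && length(blocks)) {
    mids <- setdiff(plain, c(hsf, unique(calls$tf[calls$called])))
    repeat {
      drop <- mids[vapply(mids, function(v) {
        ins <- cedges$source[cedges$target == v]
        outs <- cedges$target[cedges$source == v]
        length(ins) && length(outs) && all(ins == hsf) &&
          all(outs %in% names(blocks))
      }, logical(1))]
      if (!length(drop)) break
      for (v in drop) {
        outs <- cedges$target[cedges$source == v]
        cedges <- cedges[cedges$source != v & cedges$target != v, ,
                         drop = FALSE]
        cedges <- unique(rbind(cedges,
                               data.frame(source = hsf, target = outs,
                                          stringsAsFactors = FALSE)))
      }
      plain <- setdiff(plain, drop)
      mids <- setdiff(mids, drop)
    }
  }

  nodes <- data.frame(
    id = c(plain, names(blocks)),
    type = c(rep("tf", length(plain)), rep("ffl_block", length(blocks))),
    stringsAsFactors = FALSE)
  module_edges <- calls[calls$called & calls$tf %in% retained, ,
                        drop = FALSE]
  if (nrow(module_edges))
    module_edges$regulator_node <- node_of[module_edges$tf]
  structure(list(nodes = nodes, edges = cedges, blocks = blocks,
                 module_edges = module_edges,
                 retained = list(most_upstream = crit1, ffl = crit2,
                                 connectors = connectors, hsf = hsf)),
            class = "contracted_network")
}

#' @export
print.contracted_network <- function(x, ...) {
  cat(sprintf("contracted_network: %d nodes (%d blocks), %d edges, %d module links\n",
              nrow(x$nodes), length(x$blocks), nrow(x$edges),
              nrow(x$module_edges)))
  invisible(x)
}

#' Most-upstream nodes of a contracted network
#'
#' Nodes (TFs or FFL blocks) with zero in-degree among the contracted edges.
#'
#' @param contracted A [contract_network()] result.
#' @return Character vector of node ids.
#' @export
most_upstream <- function(contracted) {
  setdiff(contracted$nodes$id, contracted$edges$target)
}
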