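#' MCODE parameters
#'
#' Defaults are the conventional default settings of the MCODE molecular
#' complex detection algorithm: loops ignored, degree cutoff 2, node score
#' cutoff 0.2, k-core filter 2, haircut on, fluff off (fluff density
#' cutoff 0.1), maximum expansion depth 100.
#'
#' @param include_loops Count self-loops in weighting (graphs built here
#'   never have any).
#' @param degree_cutoff Nodes with fewer neighbors score 0 and never seed.
#' @param node_score_cutoff Fraction of the seed weight a node may fall
#'   short by and still join the complex (larger = more permissive).
#' @param k_core_filter Complexes without a k-core of this order are
#'   dropped.
#' @param fluff Add boundary neighbors whose neighborhood density exceeds
#'   `fluff_density_cutoff` (applied before haircut).
#' @param fluff_density_cutoff Density threshold for fluff.
#' @param haircut Remove complex members with fewer than 2 connections
#'   into the complex (the complex's 2-core).
#' @param max_depth Maximum breadth-first expansion depth from the seed.
#' @return Object of class `mcode_params`.
#' @export
mcode_params <- function(include_loops = FALSE, degree_cutoff = 2,
                         node_score_cutoff = 0.2, k_core_filter = 2,
                         fluff = FALSE, fluff_density_cutoff = 0.1,
                         haircut = TRUE, max_depth = 100) {
  stopifnot(
    node_score_cutoff >= 0, node_score_cutoff <= 1,
    degree_cutoff >= 0, k_core_filter >= 0, max_depth >= 1
  )
  structure(
    list(
      include_loops = include_loops,
      degree_cutoff = as.integer(degree_cutoff),
      node_score_cutoff = node_score_cutoff,
      k_core_filter = as.integer(k_core_filter),
      fluff = fluff,
      fluff_density_cutoff = fluff_density_cutoff,
      haircut = haircut,
      max_depth = as.integer(max_depth)
    ),
    class = "mcode_params"
  )
}

#' k-core decomposition
#'
#' Core number of a node: the largest k such that the node belongs to a
#' maximal subgraph of minimum degree k (standard iterative peeling).
#'
#' @param graph An igraph graph (simple, undirected).
#' @return Named integer vector of core numbers.
#' @export
core_decomposition <- function(graph) {
  if (igraph::vcount(graph) == 0) {
    return(setNames(integer(0), character(0)))
  }
  cores <- igraph::coreness(graph)
  storage.mode(cores) <- "integer"
  nm <- igraph::V(graph)$name
  if (!is.null(nm)) names(cores) <- nm
  cores
}

# density of a simple undirected graph: 2E / (V (V - 1))
graph_density <- function(graph) {
  v <- igraph::vcount(graph)
  if (v < 2) return(0)
  2 * igraph::ecount(graph) / (v * (v - 1))
}

#' MCODE vertex weight
#'
#' The weight of `v` is computed on the subgraph induced by `v` and its
#' neighbors: take that subgraph's highest k-core (the k-max core) and
#' multiply its core number by its edge density. Dense, tightly
#' interlinked neighborhoods score high; isolated nodes score 0, as do
#' nodes with fewer than `degree_cutoff` neighbors.
#'
#' @param graph An igraph graph.
#' @param v Node names (default all).
#' @param params [mcode_params()].
#' @return Named numeric vector of weights.
#' @export
vertex_weight <- function(graph, v = NULL, params = mcode_params()) {
  nm <- igraph::V(graph)$name %||%
    as.character(seq_len(igraph::vcount(graph)))
  v <- v %||% nm
  adj <- igraph::adjacent_vertices(graph, v)
  vidx <- match(v, nm)
  w <- vapply(seq_along(v), function(k) {
    nbrs <- as.integer(adj[[k]])
    if (length(nbrs) < params$degree_cutoff) return(0)
    h <- igraph::induced_subgraph(graph, unique(c(vidx[k], nbrs)))
    cores <- igraph::coreness(h)
    kmax <- max(cores)
    if (kmax == 0) return(0)
    kcore <- igraph::induced_subgraph(h, which(cores >= kmax))
    kmax * graph_density(kcore)
  }, numeric(1))
  setNames(w, v)
}

#' Detect dense clusters with MCODE
#'
#' Molecular-complex detection: nodes are weighted by the density of the
#' highest k-core of their closed neighborhood; complexes grow
#' breadth-first from the highest-weighted unvisited seed, admitting
#' nodes whose weight is within `node_score_cutoff` of the seed weight;
#' optional fluff adds dense boundary neighborhoods, haircut then trims
#' members with fewer than two links into the complex, and complexes
#' lacking a `k_core_filter`-core are dropped. Complexes are
#' vertex-disjoint and each induces a connected subgraph. Rank is by
#' score = density x size, descending; all ties break lexicographically
#' so the result is deterministic.
#'
#' @param graph An igraph graph (e.g. a `cooc_network`).
#' @param params [mcode_params()].
#' @return Tibble with `rank`, `seed`, `score`, `n_nodes`,
#'   `n_edges_internal`, `density`, and list-column `members` (sorted
#'   names).
#' @export
find_complexes <- function(graph, params = mcode_params()) {
  empty <- tibble(
    rank = integer(0), seed = character(0), score = numeric(0),
    n_nodes = integer(0), n_edges_internal = integer(0),
    density = numeric(0), members = list()
  )
  nv <- igraph::vcount(graph)
  if (nv == 0 || igraph::ecount(graph) == 0) return(empty)
  nm <- igraph::V(graph)$name %||% as.character(seq_len(nv))
  weights <- vertex_weight(graph, nm, params)
  adj <- igraph::adjacent_vertices(graph, nm)
  adj <- lapply(adj, function(x) nm[as.integer(x)])
  names(adj) <- nm

  seed_order <- nm[lex_order(-weights, nm)]
  visited <- setNames(rep(FALSE, nv), nm)
  complexes <- list()

  for (seed in seed_order) {
    if (visited[[seed]] || weights[[seed]] <= 0) next
    threshold <- weights[[seed]] * (1 - params$node_score_cutoff)
    members <- seed
    visited[[seed]] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < params$max_depth) {
      nbrs <- unique(unlist(adj[frontier], use.names = FALSE))
      nbrs <- nbrs[!visited[nbrs] & weights[nbrs] >= threshold]
      if (length(nbrs) == 0) break
      visited[nbrs] <- TRUE
      members <- c(members, nbrs)
      frontier <- nbrs
      depth <- depth + 1
    }
    if (params$fluff) {
      boundary <- setdiff(
        unique(unlist(adj[members], use.names = FALSE)), members
      )
      add <- boundary[vapply(boundary, function(b) {
        closed <- c(b, adj[[b]])
        h <- igraph::induced_subgraph(graph, closed)
        graph_density(h) > params$fluff_density_cutoff
      }, logical(1))]
      members <- c(members, add)  # fluff nodes stay available to others
    }
    sub <- igraph::induced_subgraph(graph, unique(members))
    if (params$haircut) {
      # iteratively shave singly-connected members: the complex 2-core
      cores <- igraph::coreness(sub)
      sub <- igraph::induced_subgraph(sub, which(cores >= 2))
    }
    if (igraph::vcount(sub) == 0) next
    if (params$k_core_filter > 0 &&
        max(igraph::coreness(sub)) < params$k_core_filter) {
      next
    }
    # keep the connected part containing the seed (trimming can in
    # principle disconnect a complex)
    if (igraph::vcount(sub) > 0 && !(seed %in% igraph::V(sub)$name)) {
      comp <- igraph::components(sub)
      keep <- which.max(comp$csize)
      sub <- igraph::induced_subgraph(sub, which(comp$membership == keep))
    } else if (igraph::vcount(sub) > 0) {
      comp <- igraph::components(sub)
      keep <- comp$membership[[which(igraph::V(sub)$name == seed)]]
      sub <- igraph::induced_subgraph(sub, which(comp$membership == keep))
    }
    complexes[[length(complexes) + 1]] <- list(
      seed = seed,
      members = lex_sort(igraph::V(sub)$name),
      n_edges = igraph::ecount(sub),
      density = graph_density(sub)
    )
  }
  if (length(complexes) == 0) return(empty)
  out <- tibble(
    seed = vapply(complexes, `[[`, character(1), "seed"),
    score = vapply(complexes, function(cx) {
      cx$density * length(cx$members)
    }, numeric(1)),
    n_nodes = vapply(complexes, function(cx) length(cx$members),
                     integer(1)),
    n_edges_internal = as.integer(
      vapply(complexes, function(cx) as.numeric(cx$n_edges), numeric(1))
    ),
    density = vapply(complexes, `[[`, numeric(1), "density"),
    members = lapply(complexes, `[[`, "members")
  )
  first_member <- vapply(out$members, function(m) m[1], character(1))
  out <- out[lex_order(-out$score, first_member), ]
  out %>%
    mutate(rank = row_number()) %>%
    select("rank", "seed", "score", "n_nodes", "n_edges_internal",
           "density", "members")
}

#' Write an MCODE cluster report as TSV
#'
#' @param clusters Tibble from [find_complexes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  flat <- clusters %>%
    mutate(members = vapply(.data$members, paste, character(1),
                            collapse = ";"))
  atomic_write(function(tmp) {
    readr::write_tsv(flat, tmp, progress = FALSE)
  }, path)
}
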