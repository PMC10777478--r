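#' Build a co-occurrence network from a pair table
#'
#' Nodes are the ingredients participating in at least one kept pair
#' (ingredients never significant do not appear); edges are the pairs.
#' The graph is simple: duplicate pairs collapse to one edge and
#' self-loops are impossible by construction of the pair table.
#'
#' @param pairs Pair tibble ([find_significant_pairs()]), or any tibble
#'   with `ingredient_i`, `ingredient_j` and optional `odds_ratio`,
#'   `a`, `co_fraction` columns.
#' @param keep_only_significant Keep only rows with `significant == TRUE`
#'   (default); set `FALSE` to graph an arbitrary pair list.
#' @param product_type Optional provenance label stored on the graph.
#' @param multi_type_pairs Optional character vector of `"i|j"` keys (see
#'   [pair_overlap()]); matching edges get `multi_type = TRUE`.
#' @return A `cooc_network` (an igraph graph with extras); nodes carry
#'   `name`, edges carry `odds_ratio`, `co_count`, `co_fraction`,
#'   `multi_type` where available.
#' @export
build_network <- function(pairs, keep_only_significant = TRUE,
                          product_type = NA_character_,
                          multi_type_pairs = character(0)) {
  if (keep_only_significant && "significant" %in% names(pairs)) {
    pairs <- pairs %>% filter(.data$significant)
  }
  edges <- pairs %>%
    mutate(key = pair_key(.data$ingredient_i, .data$ingredient_j)) %>%
    distinct(.data$key, .keep_all = TRUE)
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  } else {
    el <- edges %>%
      select("ingredient_i", "ingredient_j") %>%
      as.data.frame()
    g <- igraph::graph_from_data_frame(el, directed = FALSE)
    if ("odds_ratio" %in% names(edges)) {
      igraph::E(g)$odds_ratio <- edges$odds_ratio
    }
    if ("a" %in% names(edges)) igraph::E(g)$co_count <- edges$a
    if ("co_fraction" %in% names(edges)) {
      igraph::E(g)$co_fraction <- edges$co_fraction
    }
    igraph::E(g)$multi_type <- edges$key %in% multi_type_pairs
    g <- igraph::simplify(
      g, remove.multiple = TRUE, remove.loops = TRUE,
      edge.attr.comb = "first"
    )
  }
  g$product_type <- product_type
  class(g) <- c("cooc_network", class(g))
  g
}

#' Connected components as node-name sets
#'
#' @param net A `cooc_network` (or any igraph graph).
#' @return List of character vectors, ordered by decreasing size, ties by
#'   the lexicographically smallest member; members sorted within each.
#' @export
connected_components <- function(net) {
  if (igraph::vcount(net) == 0) return(list())
  comp <- igraph::components(net)
  sets <- split(igraph::V(net)$name, comp$membership)
  sets <- lapply(sets, lex_sort)
  sizes <- vapply(sets, length, integer(1))
  firsts <- vapply(sets, function(s) s[1], character(1))
  unname(sets[lex_order(-sizes, firsts)])
}

#' Summary statistics of a co-occurrence network
#'
#' Average degree is reported both over all nodes (`2E/V`) and over the
#' largest component only — published network tables typically use the
#' main component. The characteristic path length is the mean unweighted
#' shortest-path length over connected node pairs (pairs in different
#' components are excluded, the only convention that yields finite values
#' for disconnected graphs); the diameter is the largest finite
#' shortest-path length.
#'
#' @param net A `cooc_network`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `avg_neighbors_overall`,
#'   `avg_neighbors_main_component`, `characteristic_path_length`,
#'   `diameter`, `n_components`, plus a list-column `components`. Path
#'   stats are `NA` for edgeless graphs.
#' @export
network_stats <- function(net) {
  v <- igraph::vcount(net)
  e <- igraph::ecount(net)
  comps <- connected_components(net)
  if (e == 0) {
    return(tibble(
      n_nodes = v, n_edges = e,
      avg_neighbors_overall = if (v > 0) 0 else NA_real_,
      avg_neighbors_main_component = NA_real_,
      characteristic_path_length = NA_real_,
      diameter = NA_integer_,
      n_components = length(comps),
      components = list(comps)
    ))
  }
  main <- comps[[1]]
  sub <- igraph::induced_subgraph(net, main)
  tibble(
    n_nodes = v,
    n_edges = e,
    avg_neighbors_overall = 2 * e / v,
    avg_neighbors_main_component =
      2 * igraph::ecount(sub) / igraph::vcount(sub),
    characteristic_path_length =
      igraph::mean_distance(net, unconnected = TRUE),
    diameter = as.integer(
      igraph::diameter(net, unconnected = TRUE, weights = NA)
    ),
    n_components = length(comps),
    components = list(comps)
  )
}

#' Deterministic spring (force-directed) layout
#'
#' Fruchterman-Reingold embedding: edges act as springs pulling their
#' endpoints together, all node pairs repel, and the iteration relaxes the
#' system into a plane. Coordinates are centered on the origin and fully
#' determined by the seed. The layout is cosmetic — it carries no
#' statistical meaning beyond placing tightly interconnected ingredients
#' near each other.
#'
#' @param net A `cooc_network`.
#' @param seed Integer seed (required).
#' @param iterations Iteration budget (default 500).
#' @return Tibble `name`, `x`, `y`.
#' @export
spring_layout <- function(net, seed, iterations = 500) {
  if (missing(seed)) abort("spring_layout() requires an explicit seed")
  v <- igraph::vcount(net)
  if (v == 0) return(tibble(name = character(0), x = numeric(0),
                            y = numeric(0)))
  xy <- withr::with_seed(seed, {
    igraph::layout_with_fr(net, niter = iterations)
  })
  xy <- scale(xy, scale = FALSE)  # center: a lone node sits at the origin
  tibble(
    name = igraph::V(net)$name %||% as.character(seq_len(v)),
    x = xy[, 1],
    y = xy[, 2]
  )
}

#' @rdname build_network
#' @param x A `cooc_network`.
#' @param ... Unused.
#' @return `tidy()`: the edge table; `glance()`: [network_stats()] without
#'   the list-column.
#' @export
tidy.cooc_network <- function(x, ...) {
  if (igraph::ecount(x) == 0) {
    return(tibble(
      ingredient_i = character(0), ingredient_j = character(0)
    ))
  }
  el <- igraph::as_data_frame(x, what = "edges")
  el %>%
    tibble::as_tibble() %>%
    rename(ingredient_i = "from", ingredient_j = "to")
}

#' @rdname build_network
#' @export
glance.cooc_network <- function(x, ...) {
  network_stats(x) %>% select(-"components")
}

#' @rdname build_network
#' @param object A `cooc_network`.
#' @param seed,iterations Passed to [spring_layout()].
#' @export
autoplot.cooc_network <- function(object, seed = 1, iterations = 500, ...) {
  coords <- spring_layout(object, seed = seed, iterations = iterations)
  edges <- tidy.cooc_network(object)
  seg <- edges %>%
    left_join(coords, by = c(ingredient_i = "name")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(coords, by = c(ingredient_j = "name"))
  p <- ggplot2::ggplot()
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x, yend = .data$y),
      linewidth = if ("multi_type" %in% names(seg)) {
        ifelse(seg$multi_type %||% FALSE, 0.9, 0.3)
      } else {
        0.3
      },
      colour = "grey60"
    )
  }
  p +
    ggplot2::geom_point(data = coords,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2, colour = "steelblue") +
    ggplot2::geom_text(data = coords,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       size = 2.3, vjust = -1) +
    ggplot2::theme_void()
}

#' Export a network in SIF format
#'
#' One line per edge: `nodeA<TAB>co<TAB>nodeB`. Isolated nodes (possible
#' only in hand-built graphs) are written as bare node lines.
#'
#' @param net A `cooc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  edges <- tidy.cooc_network(net)
  lines <- character(0)
  if (nrow(edges) > 0) {
    lines <- paste(edges$ingredient_i, "co", edges$ingredient_j,
                   sep = "\t")
  }
  deg <- igraph::degree(net)
  isolated <- names(deg)[deg == 0]
  lines <- c(lines, isolated)
  atomic_write(function(tmp) {
    writeLines(lines, tmp)
  }, path)
}

#' Export a network as GraphML with attributes
#'
#' @param net A `cooc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- net
  class(g) <- setdiff(class(g), "cooc_network")
  # GraphML cannot carry Inf; serialize as a large sentinel-free string
  if ("odds_ratio" %in% igraph::edge_attr_names(g)) {
    or <- igraph::E(g)$odds_ratio
    igraph::E(g)$odds_ratio_label <- ifelse(
      is.infinite(or), "Inf", format(or, digits = 6)
    )
    igraph::E(g)$odds_ratio <- ifelse(is.finite(or), or, NA_real_)
  }
  atomic_write(function(tmp) {
    igraph::write_graph(g, tmp, format = "graphml")
  }, path)
}

#' Export a network as a plain edge-list TSV
#'
#' @param net A `cooc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(net, path) {
  atomic_write(function(tmp) {
    readr::write_tsv(tidy.cooc_network(net), tmp, progress = FALSE)
  }, path)
}
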