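pairs_tbl <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(
    ingredient_i = pmin(el[, 1], el[, 2]),
    ingredient_j = pmax(el[, 1], el[, 2]),
    odds_ratio = 20, a = 15, co_fraction = 0.1, significant = TRUE
  )
}

test_that("build_network keeps significant pairs as a simple graph", {
  net <- build_network(pairs_tbl("a", "b", "b", "c", "c", "d"))
  expect_equal(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 3)

  empty <- build_network(pairs_tbl("a", "b")[0, ])
  expect_equal(igraph::vcount(empty), 0)
  expect_equal(igraph::ecount(empty), 0)

  dup <- build_network(dplyr::bind_rows(pairs_tbl("a", "b"),
                                        pairs_tbl("b", "a")))
  expect_equal(igraph::ecount(dup), 1)

  # non-significant rows are dropped; never-significant nodes never appear
  p <- pairs_tbl("a", "b", "c", "d")
  p$significant[2] <- FALSE
  net2 <- build_network(p)
  expect_equal(sort(igraph::V(net2)$name), c("a", "b"))
})

test_that("connected components are ordered by size then smallest member", {
  net <- build_network(pairs_tbl("a", "b", "c", "d"))
  comps <- connected_components(net)
  expect_equal(lengths(comps), c(2L, 2L))
  expect_equal(comps[[1]], c("a", "b"))

  path <- build_network(pairs_tbl("a", "b", "b", "c"))
  expect_equal(connected_components(path), list(c("a", "b", "c")))

  clique6 <- t(utils::combn(paste0("k", 1:6), 2))
  fixture <- build_network(dplyr::bind_rows(
    pairs_tbl(t(clique6)), pairs_tbl("y1", "y2", "z1", "z2")
  ))
  expect_equal(lengths(connected_components(fixture)), c(6L, 2L, 2L))
})

test_that("network stats match hand-enumerated small graphs", {
  path <- build_network(pairs_tbl("a", "b", "b", "c"))
  s <- network_stats(path)
  expect_equal(s$avg_neighbors_overall, 4 / 3)
  expect_equal(s$characteristic_path_length, (1 + 1 + 2) / 3,
               tolerance = 1e-12)
  expect_equal(s$diameter, 2L)

  cyc <- paste0("c", 1:5)
  cycle5 <- build_network(pairs_tbl(t(
    cbind(cyc, c(cyc[-1], cyc[1]))
  )))
  s5 <- network_stats(cycle5)
  expect_equal(s5$characteristic_path_length, 1.5, tolerance = 1e-12)
  expect_equal(s5$diameter, 2L)

  edgeless <- build_network(pairs_tbl("a", "b")[0, ])
  se <- network_stats(edgeless)
  expect_true(is.na(se$characteristic_path_length))
  expect_true(is.na(se$diameter))
})

test_that("main-component average degree excludes isolated pairs", {
  # 62 nodes / 214 edges with three isolated pairs: the main component
  # has 56 nodes and 211 edges, so its average degree is 2*211/56
  set.seed(77)
  main_nodes <- sprintf("m%02d", 1:56)
  tree <- cbind(main_nodes[-1],
                main_nodes[sapply(2:56, function(i) sample(i - 1, 1))])
  all_pairs <- t(utils::combn(main_nodes, 2))
  key <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
               pmax(all_pairs[, 1], all_pairs[, 2]))
  tree_key <- paste(pmin(tree[, 1], tree[, 2]),
                    pmax(tree[, 1], tree[, 2]))
  extra <- all_pairs[!key %in% tree_key, , drop = FALSE]
  extra <- extra[sample(nrow(extra), 211 - 55), ]
  net <- build_network(dplyr::bind_rows(
    pairs_tbl(t(rbind(tree, extra))),
    pairs_tbl("i1", "i2", "i3", "i4", "i5", "i6")
  ))
  s <- network_stats(net)
  expect_equal(s$n_nodes, 62)
  expect_equal(s$n_edges, 214)
  expect_equal(s$avg_neighbors_main_component, 2 * 211 / 56)
  expect_equal(round(s$avg_neighbors_main_component, 1), 7.5)
  expect_equal(s$avg_neighbors_overall, 2 * 214 / 62)
})

test_that("CPL and diameter agree with an all-pairs BFS oracle", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    g <- igraph::sample_gnp(n, p = runif(1, 0.05, 0.2))
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    if (igraph::ecount(g) == 0) next
    el <- igraph::as_edgelist(g)
    net <- build_network(pairs_tbl(t(el)))
    s <- network_stats(net)
    o <- oracle_path_stats(net)
    expect_equal(s$characteristic_path_length, o$cpl, tolerance = 1e-12)
    expect_equal(s$diameter, as.integer(o$diameter))
    expect_true(s$characteristic_path_length <= s$diameter)
    # degree sum identity
    expect_equal(sum(igraph::degree(net)), 2 * s$n_edges)
  }
})

test_that("adding an edge never increases the CPL of its component", {
  set.seed(29)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(15, 0.25)
    igraph::V(g)$name <- sprintf("v%02d", 1:15)
    comp <- igraph::components(g)
    big <- which(comp$membership == which.max(comp$csize))
    if (length(big) < 4) next
    sub <- igraph::induced_subgraph(g, big)
    el <- igraph::as_edgelist(sub)
    net <- build_network(pairs_tbl(t(el)))
    before <- network_stats(net)$characteristic_path_length
    nm <- igraph::V(sub)$name
    missing <- t(utils::combn(nm, 2))
    have <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    cand <- missing[!paste(missing[, 1], missing[, 2]) %in% have, ,
                    drop = FALSE]
    if (nrow(cand) == 0) next
    add <- cand[sample(nrow(cand), 1), ]
    net2 <- build_network(dplyr::bind_rows(
      pairs_tbl(t(el)), pairs_tbl(add[1], add[2])
    ))
    after <- network_stats(net2)$characteristic_path_length
    expect_lte(after, before + 1e-12)
  }
})

test_that("spring layout is deterministic, centered, and clusters cliques", {
  one <- build_network(pairs_tbl("a", "b"))
  single <- igraph::make_empty_graph(n = 1, directed = FALSE)
  igraph::V(single)$name <- "solo"
  class(single) <- c("cooc_network", class(single))
  xy <- spring_layout(single, seed = 5)
  expect_equal(unlist(xy[, c("x", "y")]), c(x = 0, y = 0),
               tolerance = 1e-12)

  l1 <- spring_layout(one, seed = 3)
  l2 <- spring_layout(one, seed = 3)
  expect_identical(l1, l2)

  # barbell: two 5-cliques joined by a single edge
  c1 <- paste0("a", 1:5); c2 <- paste0("b", 1:5)
  barbell <- build_network(dplyr::bind_rows(
    pairs_tbl(t(t(utils::combn(c1, 2)))),
    pairs_tbl(t(t(utils::combn(c2, 2)))),
    pairs_tbl("a1", "b1")
  ))
  coords <- spring_layout(barbell, seed = 11)
  xyv <- as.matrix(coords[, c("x", "y")])
  rownames(xyv) <- coords$name
  dist_of <- function(set1, set2) {
    d <- as.matrix(stats::dist(xyv))[set1, set2]
    mean(d[d > 0])
  }
  intra <- mean(c(dist_of(c1, c1), dist_of(c2, c2)))
  inter <- dist_of(c1, c2)
  expect_lt(intra, inter)
})

test_that("exports write SIF, GraphML and edge lists that round-trip", {
  net <- build_network(pairs_tbl("a", "b", "b", "c"),
                       multi_type_pairs = "a|b")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  expect_equal(length(readLines(sif)), 2)
  expect_match(readLines(sif)[1], "\tco\t")

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 2)
  expect_setequal(igraph::V(back)$name, c("a", "b", "c"))

  elp <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist_tsv(net, elp)
  el <- readr::read_tsv(elp, show_col_types = FALSE)
  expect_equal(nrow(el), 2)
  expect_true("multi_type" %in% names(el))
  expect_equal(sum(el$multi_type), 1)
})
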