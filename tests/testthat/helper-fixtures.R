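# fixture builders and independent oracles shared across test files

# long product tibble from a logical products-x-ingredients matrix; every
# product additionally carries a carrier ingredient so all-false rows keep
# their product in the presence matrix
products_from_matrix <- function(m, product_type = "E_LIQUID") {
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("p%04d", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("ing%02d", seq_len(ncol(m)))
  }
  hits <- which(m, arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(
      product_id = rownames(m)[hits[, 1]],
      product_type = factor(product_type),
      ingredient = colnames(m)[hits[, 2]],
      function_tag = "flavour and/or taste enhancer",
      concentration = NA_real_
    ),
    tibble::tibble(
      product_id = rownames(m),
      product_type = factor(product_type),
      ingredient = "propylene glycol",
      function_tag = "carrier/solvent",
      concentration = NA_real_
    )
  )
}

pm_from_matrix <- function(m, product_type = "E_LIQUID",
                           vocabulary = NULL) {
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("ing%02d", seq_len(ncol(m)))
  }
  if (is.null(vocabulary)) vocabulary <- colnames(m)
  build_presence_matrix(
    products_from_matrix(m, product_type), product_type,
    vocabulary = vocabulary
  )
}

random_presence <- function(n, k, p = 0.3) {
  matrix(stats::runif(n * k) < p, nrow = n, ncol = k)
}

# --- graph oracles ---------------------------------------------------------

# all-pairs shortest paths by plain breadth-first search over an adjacency
# list; independent of igraph's distance machinery
bfs_all_pairs <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  adj <- lapply(igraph::adjacent_vertices(g, nm), as.integer)
  d <- matrix(Inf, n, n, dimnames = list(nm, nm))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

oracle_path_stats <- function(g) {
  d <- bfs_all_pairs(g)
  vals <- d[upper.tri(d)]
  finite <- vals[is.finite(vals) & vals > 0]
  list(cpl = mean(finite), diameter = max(finite))
}

# core numbers by direct peeling: a node has core number >= k iff it
# survives iterated deletion of all nodes with degree < k
oracle_core_numbers <- function(g) {
  nm <- igraph::V(g)$name
  out <- stats::setNames(rep(0L, length(nm)), nm)
  k <- 1L
  repeat {
    h <- g
    repeat {
      low <- igraph::V(h)[igraph::degree(h) < k]
      if (length(low) == 0) break
      h <- igraph::delete_vertices(h, low)
    }
    if (igraph::vcount(h) == 0) break
    out[igraph::V(h)$name] <- k
    k <- k + 1L
  }
  out
}

# --- CMLE oracle -----------------------------------------------------------

# conditional MLE by brute-force likelihood maximization: coarse grid over
# log psi followed by local refinement of the noncentral hypergeometric
# log-likelihood itself (not its score), so the route is independent of
# the implementation's root solve
oracle_cmle <- function(a, b, c, d) {
  n <- a + b + c + d
  k1 <- a + b
  k2 <- a + c
  lo <- max(0, k1 + k2 - n)
  hi <- min(k1, k2)
  stopifnot(a > lo, a < hi)  # interior cases only
  support <- lo:hi
  logw0 <- lchoose(k1, support) + lchoose(n - k1, k2 - support)
  loglik <- function(t) {
    logw <- logw0 + support * t
    m <- max(logw)
    (logw0[support == a] + a * t) - (m + log(sum(exp(logw - m))))
  }
  grid <- seq(-15, 15, by = 0.05)
  ll <- vapply(grid, loglik, numeric(1))
  i <- which.max(ll)
  lo_t <- grid[max(1, i - 1)]
  hi_t <- grid[min(length(grid), i + 1)]
  exp(stats::optimize(loglik, c(lo_t, hi_t), maximum = TRUE,
                      tol = 1e-10)$maximum)
}

# presence matrix realizing a given 2x2 table
table_to_matrix <- function(a, b, c, d) {
  m <- matrix(FALSE, a + b + c + d, 2, dimnames = list(NULL, c("i", "j")))
  if (a > 0) m[seq_len(a), ] <- TRUE
  if (b > 0) m[a + seq_len(b), "i"] <- TRUE
  if (c > 0) m[a + b + seq_len(c), "j"] <- TRUE
  m
}

# all non-negative 2x2 tables with total n whose cell a is interior to its
# conditional support
interior_tables <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    k1 <- a + b
    k2 <- a + cc
    lo <- max(0, k1 + k2 - n)
    hi <- min(k1, k2)
    if (a > lo && a < hi) {
      out[[length(out) + 1]] <- c(a = a, b = b, c = cc, d = d)
    }
  }
  do.call(rbind, out)
}
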