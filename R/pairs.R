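#' Compound significance rule for ingredient pairs
#'
#' A pair is significant when its co-occurrence count reaches
#' `max(ceiling(min_fraction * n), min_count)` — i.e. at least 3% of the
#' products and at least 10 products, whichever is larger — and its odds
#' ratio is at least `min_odds_ratio` (an infinite odds ratio passes: it
#' signals extreme overrepresentation). The rule is deliberately
#' threshold-based; exact-test p-values are reported alongside but play no
#' part in the verdict.
#'
#' @param min_fraction Minimum co-occurrence fraction of products
#'   (default 0.03).
#' @param min_count Minimum co-occurrence product count (default 10).
#' @param min_odds_ratio Minimum odds ratio (default 10).
#' @return An object of class `significance_rule`.
#' @export
significance_rule <- function(min_fraction = 0.03, min_count = 10,
                              min_odds_ratio = 10) {
  stopifnot(min_fraction > 0, min_count > 0, min_odds_ratio > 0)
  structure(
    list(
      min_fraction = min_fraction,
      min_count = as.integer(min_count),
      min_odds_ratio = min_odds_ratio
    ),
    class = "significance_rule"
  )
}

#' @export
print.significance_rule <- function(x, ...) {
  cat(
    "<significance_rule> co-count >= max(ceiling(", x$min_fraction,
    " * n), ", x$min_count, ") and OR >= ", x$min_odds_ratio, "\n",
    sep = ""
  )
  invisible(x)
}

#' Minimum co-occurrence count implied by a rule for n products
#'
#' @param n Number of products (>= 0).
#' @param rule A [significance_rule()].
#' @return Integer threshold `max(ceiling(min_fraction * n), min_count)`.
#' @export
#' @examples
#' significance_threshold_count(33179, significance_rule())  # 996
significance_threshold_count <- function(n, rule = significance_rule()) {
  stopifnot(n >= 0)
  max(as.integer(ceiling(rule$min_fraction * n)), rule$min_count)
}

#' 2x2 contingency table for one ingredient pair
#'
#' Cells over the products of one type: `a` contain both ingredients, `b`
#' only `i`, `c` only `j`, `d` neither; `n = a + b + c + d`.
#'
#' @param pm A `presence_matrix`.
#' @param i,j Distinct ingredient (column) names.
#' @return One-row tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(pm, i, j) {
  stopifnot(i != j)
  cols <- pm$ingredient_names
  if (!(i %in% cols) || !(j %in% cols)) {
    abort(paste0(
      "unknown ingredient(s): ",
      paste(setdiff(c(i, j), cols), collapse = ", ")
    ))
  }
  xi <- as.logical(pm$presence[, i])
  xj <- as.logical(pm$presence[, j])
  a <- sum(xi & xj)
  tibble(
    a = a,
    b = sum(xi) - a,
    c = sum(xj) - a,
    d = pm$n_products - sum(xi) - sum(xj) + a,
    n = pm$n_products
  )
}

#' Sample odds ratio of a 2x2 table
#'
#' `(a d) / (b c)`; `Inf` when `b c = 0` with `a d > 0`; `NA` when both
#' products vanish (the table carries no information about association).
#'
#' @param a,b,c,d Non-negative cell counts (vectorized).
#' @return Numeric vector of odds ratios.
#' @export
#' @examples
#' odds_ratio_sample(20, 5, 5, 20)  # 16
odds_ratio_sample <- function(a, b, c, d) {
  num <- as.numeric(a) * as.numeric(d)
  den <- as.numeric(b) * as.numeric(c)
  out <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, NA_real_))
  as.numeric(out)
}

#' Conditional maximum-likelihood odds ratio of a 2x2 table
#'
#' The estimate reported by Fisher's exact test: the value of the odds
#' ratio maximizing the noncentral hypergeometric likelihood of cell `a`
#' given both margins. Found by solving the conditional score equation
#' `E_psi[A] = a` for `psi` (the conditional likelihood is log-concave, so
#' the score root is the maximizer). Returns `Inf` when `a` sits at its
#' maximum attainable value given the margins, `0` at its minimum, and
#' `NA` for degenerate margins (a zero row or column margin, where the
#' support is a single point).
#'
#' @param a,b,c,d Non-negative cell counts (vectorized).
#' @param tol Relative tolerance of the root search.
#' @return Numeric vector of conditional MLEs.
#' @export
#' @examples
#' odds_ratio_cmle(10, 10, 10, 10)  # 1
odds_ratio_cmle <- function(a, b, c, d, tol = 1e-8) {
  mapply(function(a, b, c, d) cmle_one(a, b, c, d, tol), a, b, c, d)
}

cmle_one <- function(a, b, c, d, tol = 1e-8) {
  n <- a + b + c + d
  k1 <- a + b  # margin of ingredient i
  k2 <- a + c  # margin of ingredient j
  lo <- max(0, k1 + k2 - n)
  hi <- min(k1, k2)
  if (lo == hi) return(NA_real_)  # degenerate margins: single-point support
  if (a >= hi) return(Inf)
  if (a <= lo) return(0)
  support <- lo:hi
  logw0 <- lchoose(k1, support) + lchoose(n - k1, k2 - support)
  # conditional mean of A at log-odds ratio t, computed stably
  cond_mean <- function(t) {
    logw <- logw0 + support * t
    w <- exp(logw - max(logw))
    sum(support * w) / sum(w)
  }
  f <- function(t) cond_mean(t) - a
  # bracket the root; cond_mean is strictly increasing in t
  span <- 1
  while (f(-span) > 0 || f(span) < 0) {
    span <- span * 2
    if (span > 1e4) break
  }
  root <- uniroot(f, c(-span, span), tol = tol)$root
  exp(root)
}

# two-sided Fisher exact p-value: sum of hypergeometric point
# probabilities not exceeding the observed one (with the customary
# relative slack for ties), matching the convention of the standard
# exact-test implementation
fisher_p_one <- function(a, b, c, d) {
  n <- a + b + c + d
  k1 <- a + b
  k2 <- a + c
  lo <- max(0, k1 + k2 - n)
  hi <- min(k1, k2)
  support <- lo:hi
  dens <- stats::dhyper(support, k2, n - k2, k1)
  p_obs <- dens[support == a]
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

#' Evaluate all ingredient pairs of a presence matrix
#'
#' Enumerates all `n_ing (n_ing - 1) / 2` unordered column pairs, computes
#' each pair's 2x2 table, odds ratio and (optionally) Fisher exact
#' p-value, and applies the significance rule. Co-occurrence counts for
#' all pairs come from one sparse cross-product, so the enumeration is
#' cheap even for tens of thousands of products.
#'
#' @param pm A `presence_matrix` with at least 2 ingredients.
#' @param rule A [significance_rule()].
#' @param estimator `"cmle"` (default; the estimate Fisher's exact test
#'   reports) or `"sample"` (`ad/bc`).
#' @param p_values Compute two-sided Fisher exact p-values? They are
#'   reported for inspection only and never enter the significance rule.
#' @return Tibble with one row per unordered pair (`ingredient_i <
#'   ingredient_j` lexicographically): cells `a b c d n`, `co_fraction`,
#'   `odds_ratio`, `p_value` (if requested), `estimator`, `significant`;
#'   sorted by decreasing odds ratio, ties by names.
#' @export
find_significant_pairs <- function(pm, rule = significance_rule(),
                                   estimator = c("cmle", "sample"),
                                   p_values = TRUE) {
  estimator <- match.arg(estimator)
  vocab <- pm$ingredient_names
  n_ing <- length(vocab)
  stopifnot(n_ing >= 2)
  n <- pm$n_products

  cells <- pair_cells(pm)
  or <- switch(estimator,
    sample = odds_ratio_sample(cells$a, cells$b, cells$c, cells$d),
    cmle = odds_ratio_cmle(cells$a, cells$b, cells$c, cells$d)
  )
  thr <- significance_threshold_count(n, rule)
  signif_flag <- cells$a >= thr &
    !is.na(or) & or >= rule$min_odds_ratio

  n_prod <- pm$n_products
  out <- cells %>%
    mutate(
      co_fraction = if (n_prod > 0) .data$a / n_prod else NA_real_,
      odds_ratio = or,
      estimator = estimator,
      significant = signif_flag
    )
  if (p_values) {
    out$p_value <- mapply(
      fisher_p_one, cells$a, cells$b, cells$c, cells$d
    )
  }
  out %>%
    arrange(desc(.data$odds_ratio), .data$ingredient_i, .data$ingredient_j)
}

# cell counts for every unordered column pair via sparse crossprod
pair_cells <- function(pm) {
  vocab <- pm$ingredient_names
  n_ing <- length(vocab)
  n <- pm$n_products
  x <- methods::as(pm$presence, "dMatrix")
  co <- as.matrix(Matrix::crossprod(x))
  counts <- Matrix::colSums(x)
  idx <- which(upper.tri(co), arr.ind = TRUE)
  ii <- idx[, 1]
  jj <- idx[, 2]
  a <- as.integer(co[idx])
  bi <- as.integer(counts[ii]) - a
  cj <- as.integer(counts[jj]) - a
  tibble(
    ingredient_i = vocab[ii],
    ingredient_j = vocab[jj],
    a = a,
    b = bi,
    c = cj,
    d = n - a - bi - cj,
    n = n
  )
}

#' Write a pair table as TSV
#'
#' Infinite odds ratios serialize as the literal string `Inf`.
#'
#' @param pairs Pair tibble from [find_significant_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  atomic_write(function(tmp) {
    readr::write_tsv(pairs, tmp, progress = FALSE)
  }, path)
}
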