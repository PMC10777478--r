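#' Permute a presence matrix under the independence null
#'
#' `scheme = "column"` (default) shuffles each ingredient's presence
#' vector independently across products: every column sum — the marginal
#' prevalence the odds ratio conditions on — is preserved exactly, while
#' all between-ingredient associations are destroyed. `scheme = "global"`
#' reshuffles all presence bits over the whole matrix, preserving only the
#' total count.
#'
#' Randomness is drawn from the current RNG state; callers that need
#' reproducibility seed it (as [permutation_null()] does).
#'
#' @param pm A `presence_matrix`.
#' @param scheme `"column"` or `"global"`.
#' @return A `presence_matrix` of the same shape.
#' @export
permute_presence <- function(pm, scheme = c("column", "global")) {
  scheme <- match.arg(scheme)
  n <- pm$n_products
  counts <- ingredient_counts(pm)
  n_ing <- length(counts)
  if (scheme == "column") {
    # new row indices per column, in column order so the RNG stream is
    # well defined and mirrorable by an independent oracle
    rows <- lapply(counts, function(k) sample.int(n, k))
    i <- unlist(rows, use.names = FALSE)
    j <- rep.int(seq_len(n_ing), counts)
  } else {
    total <- sum(counts)
    pos <- sample.int(n * n_ing, total)
    i <- ((pos - 1L) %% n) + 1L
    j <- ((pos - 1L) %/% n) + 1L
  }
  mat <- Matrix::sparseMatrix(
    i = i, j = j, x = TRUE,
    dims = dim(pm$presence),
    dimnames = dimnames(pm$presence)
  )
  new_presence_matrix(mat, pm$product_type)
}

#' Calibrate the significance rule on permuted data
#'
#' Repeats the pair screening on `n_reps` independently permuted copies of
#' the presence matrix and records how many pairs come out significant in
#' each — the expected degree of chance findings under the rule. Odds
#' ratios are only evaluated for pairs whose co-occurrence count already
#' reaches the rule's count threshold; this shortcut is exact (the rule is
#' a conjunction) and keeps full-scale calibration fast.
#'
#' @param pm A `presence_matrix`.
#' @param rule A [significance_rule()].
#' @param estimator `"cmle"` or `"sample"`, as in
#'   [find_significant_pairs()].
#' @param n_reps Number of permutation replicates (>= 1).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param scheme Permutation scheme, see [permute_presence()].
#' @return An object of class `null_calibration`: list with `replicates`
#'   (tibble `replicate`, `n_significant`), `n_reps`, `seed`, `scheme`,
#'   `rule`, `estimator`.
#' @export
permutation_null <- function(pm, rule = significance_rule(),
                             estimator = c("cmle", "sample"),
                             n_reps = 10, seed,
                             scheme = c("column", "global")) {
  estimator <- match.arg(estimator)
  scheme <- match.arg(scheme)
  stopifnot(n_reps >= 1)
  if (missing(seed)) abort("permutation_null() requires an explicit seed")
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      perm <- permute_presence(pm, scheme)
      count_significant_pairs(perm, rule, estimator)
    }, integer(1))
  })
  structure(
    list(
      replicates = tibble(
        replicate = seq_len(n_reps),
        n_significant = counts
      ),
      n_reps = n_reps, seed = seed, scheme = scheme,
      rule = rule, estimator = estimator
    ),
    class = "null_calibration"
  )
}

# exact fast path: count pairs passing the conjunction rule without
# materializing odds ratios for pairs that already fail the count arm
count_significant_pairs <- function(pm, rule, estimator) {
  if (length(pm$ingredient_names) < 2) return(0L)
  cells <- pair_cells(pm)
  thr <- significance_threshold_count(pm$n_products, rule)
  cand <- cells %>% filter(.data$a >= thr)
  if (nrow(cand) == 0) return(0L)
  or <- switch(estimator,
    sample = odds_ratio_sample(cand$a, cand$b, cand$c, cand$d),
    cmle = odds_ratio_cmle(cand$a, cand$b, cand$c, cand$d)
  )
  sum(!is.na(or) & or >= rule$min_odds_ratio)
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(
    "<null_calibration> ", x$n_reps, " x ", x$scheme,
    "-permutation replicates (seed ", x$seed, ", estimator ",
    x$estimator, ")\n",
    "significant pairs per replicate: ",
    paste(x$replicates$n_significant, collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname permutation_null
#' @param x A `null_calibration`.
#' @param ... Unused.
#' @export
tidy.null_calibration <- function(x, ...) x$replicates

#' @rdname permutation_null
#' @export
glance.null_calibration <- function(x, ...) {
  tibble(
    n_reps = x$n_reps,
    mean_significant = mean(x$replicates$n_significant),
    max_significant = max(x$replicates$n_significant),
    seed = x$seed,
    scheme = x$scheme,
    estimator = x$estimator
  )
}
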