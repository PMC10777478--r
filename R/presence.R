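#' Default trivially-ubiquitous ingredients
#'
#' Propylene glycol and glycerol are the carrier liquids of essentially
#' every e-liquid, and water is nearly as common; their presence carries no
#' information, so they are excluded from co-occurrence analysis.
#'
#' @return Character vector of canonical names.
#' @export
trivial_ingredients <- function() {
  c("propylene glycol", "glycerol", "water")
}

#' Build a products-by-ingredients presence matrix for one product type
#'
#' @param products Curated product tibble ([curate_ingredients()]).
#' @param product_type One of [liquid_types].
#' @param exclude Canonical names to drop as trivial; default
#'   [trivial_ingredients()].
#' @param vocabulary Optional character vector fixing the column set (and
#'   admitting all-zero columns); by default the ingredients observed in
#'   this type. Columns are always in lexicographic order.
#' @return A `presence_matrix`: sparse logical incidence with product ids
#'   as rows (every product of the type keeps its row, even if all its
#'   ingredients were excluded) and canonical ingredient names as columns.
#' @export
build_presence_matrix <- function(products, product_type,
                                  exclude = trivial_ingredients(),
                                  vocabulary = NULL) {
  stopifnot(product_type %in% product_type_levels)
  rows <- products %>%
    filter(as.character(.data$product_type) == !!product_type)
  ids <- lex_sort(unique(rows$product_id))
  keep <- rows %>%
    filter(!(.data$ingredient %in% exclude)) %>%
    distinct(.data$product_id, .data$ingredient)
  vocab <- vocabulary %||% unique(keep$ingredient)
  vocab <- lex_sort(setdiff(vocab, exclude))
  keep <- keep %>% filter(.data$ingredient %in% vocab)
  mat <- Matrix::sparseMatrix(
    i = match(keep$product_id, ids),
    j = match(keep$ingredient, vocab),
    x = TRUE,
    dims = c(length(ids), length(vocab)),
    dimnames = list(ids, vocab)
  )
  new_presence_matrix(mat, product_type)
}

new_presence_matrix <- function(mat, product_type) {
  structure(
    list(
      presence = mat,
      product_type = product_type,
      product_ids = rownames(mat),
      ingredient_names = colnames(mat),
      n_products = nrow(mat)
    ),
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(
    "<presence_matrix> ", x$product_type, ": ",
    x$n_products, " products x ", length(x$ingredient_names),
    " ingredients (", sum(x$presence), " presences)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$presence)

#' @export
as.matrix.presence_matrix <- function(x, ...) {
  m <- as.matrix(x$presence)
  storage.mode(m) <- "logical"
  m
}

#' Per-ingredient product counts of a presence matrix
#'
#' @param pm A `presence_matrix`.
#' @return Named integer vector of column sums.
#' @export
ingredient_counts <- function(pm) {
  counts <- Matrix::colSums(pm$presence)
  setNames(as.integer(counts), pm$ingredient_names)
}

#' Apply the cross-type prevalence filter
#'
#' An ingredient is kept iff in at least one product type its product count
#' reaches `ceiling(min_fraction * n_products)` of that type (and is at
#' least 1). The same kept set is applied to every matrix, so all types
#' share one vocabulary afterwards — a prerequisite for comparing pair
#' sets across types.
#'
#' @param matrices Named list of `presence_matrix`, one per type.
#' @param min_fraction Minimum use fraction; default 0.01 (i.e. "used in at
#'   least 1% of at least one type").
#' @return List of `presence_matrix` with identical, reduced column sets.
#' @export
prevalence_filter <- function(matrices, min_fraction = 0.01) {
  stopifnot(min_fraction >= 0)
  vocab <- lex_sort(unique(unlist(
    lapply(matrices, function(m) m$ingredient_names)
  )))
  kept <- rep(FALSE, length(vocab))
  names(kept) <- vocab
  for (m in matrices) {
    thr <- max(1L, as.integer(ceiling(min_fraction * m$n_products)))
    counts <- ingredient_counts(m)
    pass <- names(counts)[counts >= thr]
    kept[pass] <- TRUE
  }
  kept_names <- vocab[kept]
  lapply(matrices, function(m) {
    mat <- m$presence[, intersect(kept_names, m$ingredient_names),
                      drop = FALSE]
    # re-expand to the shared vocabulary with all-zero columns where the
    # ingredient never occurs in this type
    full <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = logical(0),
      dims = c(m$n_products, length(kept_names)),
      dimnames = list(m$product_ids, kept_names)
    )
    if (ncol(mat) > 0) full[, colnames(mat)] <- mat
    new_presence_matrix(full, m$product_type)
  })
}

#' Per-ingredient use prevalence and median concentration
#'
#' Prevalence is the percentage of products of the type containing the
#' ingredient (one decimal). The median concentration is computed over the
#' products that contain the ingredient and report a concentration (two
#' decimals); it is `NA` when no product reports one.
#'
#' @param products Curated product tibble.
#' @param product_type One of [liquid_types].
#' @return Tibble with `ingredient`, `function_tag`, `n_products`,
#'   `use_prevalence` (percent), `median_concentration` (mg/mL), sorted by
#'   decreasing prevalence.
#' @export
ingredient_summary <- function(products, product_type) {
  rows <- products %>%
    filter(as.character(.data$product_type) == !!product_type)
  n_total <- n_distinct(rows$product_id)
  if (n_total == 0) {
    return(tibble(
      ingredient = character(0), function_tag = character(0),
      n_products = integer(0), use_prevalence = numeric(0),
      median_concentration = numeric(0)
    ))
  }
  rows %>%
    group_by(.data$ingredient) %>%
    summarise(
      function_tag = names(which.max(table(.data$function_tag))) %||%
        NA_character_,
      n_products = n_distinct(.data$product_id),
      median_concentration = round(
        median(.data$concentration, na.rm = TRUE), 2
      ),
      .groups = "drop"
    ) %>%
    mutate(
      use_prevalence = round(100 * .data$n_products / n_total, 1),
      median_concentration = ifelse(
        is.nan(.data$median_concentration), NA_real_,
        .data$median_concentration
      )
    ) %>%
    select(
      "ingredient", "function_tag", "n_products",
      "use_prevalence", "median_concentration"
    ) %>%
    arrange(desc(.data$use_prevalence), .data$ingredient)
}

#' Write a presence matrix as 0/1 TSV
#'
#' First column `product_id`, one 0/1 column per ingredient.
#'
#' @param pm A `presence_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(pm, path) {
  dense <- as.matrix(pm$presence) * 1L
  df <- tibble(product_id = pm$product_ids) %>%
    dplyr::bind_cols(tibble::as_tibble(dense))
  atomic_write(function(tmp) {
    readr::write_tsv(df, tmp, progress = FALSE)
  }, path)
}
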