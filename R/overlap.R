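#' Cross-product-type overlap of significant pair sets
#'
#' Partitions the union of significant pairs by the exact subset of
#' product types each pair is significant in (the regions of a Venn
#' diagram), and flags pairs significant in two or more types.
#'
#' @param pair_sets Named list, one element per product type: either a
#'   pair tibble (rows with `significant == TRUE` are used when the
#'   column exists) or a character vector of `"i|j"` keys.
#' @return Object of class `overlap_report`: list with `types`,
#'   `region_counts` (tibble `region` — `+`-joined type subset — and
#'   `count`), and `multi_type_pairs` (tibble `pair`, `types`,
#'   `n_types`).
#' @export
#' @examples
#' pair_overlap(list(
#'   E_LIQUID = c("a|b", "c|d"),
#'   DISPOSABLE = c("a|b")
#' ))
pair_overlap <- function(pair_sets) {
  stopifnot(length(pair_sets) >= 1, !is.null(names(pair_sets)))
  types <- names(pair_sets)
  keys <- lapply(pair_sets, function(x) {
    if (is.data.frame(x)) {
      if ("significant" %in% names(x)) x <- x[x$significant, ]
      unique(pair_key(x$ingredient_i, x$ingredient_j))
    } else {
      unique(as.character(x))
    }
  })
  membership <- tibble(
    pair = unlist(keys, use.names = FALSE),
    type = rep(types, lengths(keys))
  )
  if (nrow(membership) == 0) {
    by_pair <- tibble(pair = character(0), types = character(0),
                      n_types = integer(0))
  } else {
    by_pair <- membership %>%
      group_by(.data$pair) %>%
      summarise(
        # subset label in the fixed type order, so regions are stable
        types = paste(types[types %in% .data$type], collapse = "+"),
        n_types = dplyr::n(),
        .groups = "drop"
      )
  }
  region_counts <- by_pair %>%
    count(.data$types, name = "count") %>%
    rename(region = "types")
  # include empty regions so every subset of types is reported
  all_regions <- unlist(lapply(seq_along(types), function(k) {
    apply(utils::combn(types, k), 2, paste, collapse = "+")
  }))
  region_counts <- tibble(region = all_regions) %>%
    left_join(region_counts, by = "region") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
  multi <- by_pair %>%
    filter(.data$n_types >= 2) %>%
    arrange(desc(.data$n_types), .data$pair)
  structure(
    list(
      types = types,
      region_counts = region_counts,
      multi_type_pairs = multi
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> types: ", paste(x$types, collapse = ", "), "\n",
      sep = "")
  print(x$region_counts, n = Inf)
  invisible(x)
}

#' @rdname pair_overlap
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @export
tidy.overlap_report <- function(x, ...) x$region_counts

#' Write an overlap report as TSV
#'
#' Region rows first, then one row per multi-type pair.
#'
#' @param report An `overlap_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_tsv <- function(report, path) {
  regions <- report$region_counts %>%
    mutate(record = "region", pair = NA_character_) %>%
    select("record", "region", "count", "pair")
  multi <- report$multi_type_pairs %>%
    mutate(record = "multi_type_pair", count = .data$n_types) %>%
    rename(region = "types") %>%
    select("record", "region", "count", "pair")
  atomic_write(function(tmp) {
    readr::write_tsv(bind_rows(regions, multi), tmp, progress = FALSE)
  }, path)
}
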