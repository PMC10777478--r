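#' Default ingredient synonym map
#'
#' Ingredient notifications frequently list the same chemical under several
#' names: a stereoisomer (L-menthol for menthol), a tautomer (the
#' 2-hydroxy-3-methylcyclopent-2-en-1-one form of cyclotene), a hydrate
#' (citric acid monohydrate), or a hemiacetal formed in the liquid matrix
#' (vanillin propylene glycol acetal). These variants are chemically and
#' sensorially equivalent to their parent for co-occurrence purposes, so
#' curation folds them onto one canonical name.
#'
#' The shipped map covers one worked example of each merge class; real
#' analyses are expected to extend it via [read_synonym_map()].
#'
#' @return A tibble with columns `variant`, `canonical`, `reason`
#'   (one of `"stereoisomer"`, `"tautomer"`, `"hydrate"`, `"hemiacetal"`,
#'   `"other"`).
#' @export
#' @examples
#' default_synonym_map()
default_synonym_map <- function() {
  map <- tibble::tribble(
    ~variant,                             ~canonical,    ~reason,
    "l-menthol",                          "menthol",     "stereoisomer",
    "2-hydroxy-3-methylcyclopent-2-en-1-one", "cyclotene", "tautomer",
    "3-methyl-1,2-cyclopentanedione",     "cyclotene",   "tautomer",
    "citric acid monohydrate",            "citric acid", "hydrate",
    "vanillin propylene glycol acetal",   "vanillin",    "hemiacetal"
  )
  validate_synonym_map(map)
}

#' Read a synonym map from a TSV file
#'
#' The file needs columns `variant`, `canonical` and optionally `reason`.
#' Names are normalized (trimmed, case-folded, internal whitespace
#' collapsed) on read so the map matches curated names.
#'
#' @param path Path to a tab-separated file.
#' @return A validated synonym-map tibble (see [default_synonym_map()]).
#' @export
read_synonym_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("variant", "canonical") %in% names(map))) {
    abort("synonym map needs columns 'variant' and 'canonical'")
  }
  if (!"reason" %in% names(map)) map$reason <- "other"
  validate_synonym_map(map)
}

valid_merge_reasons <- c(
  "stereoisomer", "tautomer", "hydrate", "hemiacetal", "other"
)

validate_synonym_map <- function(map) {
  map <- map %>%
    mutate(
      variant = normalize_name(.data$variant),
      canonical = normalize_name(.data$canonical),
      reason = ifelse(.data$reason %in% valid_merge_reasons,
                      .data$reason, "other")
    ) %>%
    distinct(.data$variant, .keep_all = TRUE)
  # acyclicity: a canonical target must never itself be a variant key,
  # otherwise lookup order would matter
  bad <- intersect(map$canonical, map$variant)
  if (length(bad) > 0) {
    abort(paste0(
      "synonym map is not acyclic; canonical name(s) also listed as ",
      "variants: ", paste(bad, collapse = ", ")
    ))
  }
  map
}

# trim + case-fold + collapse internal whitespace; the normal form all
# curation and matching operates on
normalize_name <- function(x) {
  x <- stringr::str_squish(x)
  stringr::str_to_lower(x)
}
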