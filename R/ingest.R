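#' Liquid-containing product types
#'
#' The four notification product types that contain e-liquid and therefore
#' enter the co-occurrence analysis: e-liquid refills and disposable,
#' rechargeable, and refillable e-cigarettes. Everything else (device-only
#' products, parts) is mapped to `"OTHER"` and excluded.
#'
#' @format Character vector of the four type codes.
#' @export
liquid_types <- c("E_LIQUID", "DISPOSABLE", "RECHARGEABLE", "REFILLABLE")

product_type_levels <- c(liquid_types, "OTHER")

#' Map free-text product-type strings to type codes
#'
#' Matching is case- and punctuation-insensitive: `"E-Liquid"`,
#' `"e_liquid refill"` and `"ELIQUID"` all map to `"E_LIQUID"`. Unknown
#' strings map to `"OTHER"`.
#'
#' @param x Character vector of product-type strings as found in an export.
#' @return Factor with levels `E_LIQUID, DISPOSABLE, RECHARGEABLE,
#'   REFILLABLE, OTHER`.
#' @export
#' @examples
#' map_product_type(c("E-Liquid", "Device", "refillable e-cigarette"))
map_product_type <- function(x) {
  key <- stringr::str_to_lower(x)
  key <- stringr::str_replace_all(key, "[^a-z]+", "")
  code <- dplyr::case_when(
    stringr::str_detect(key, "eliquid|refillcontainer") &
      !stringr::str_detect(key, "device") ~ "E_LIQUID",
    stringr::str_detect(key, "disposable") ~ "DISPOSABLE",
    stringr::str_detect(key, "rechargeable") ~ "RECHARGEABLE",
    stringr::str_detect(key, "refillable") ~ "REFILLABLE",
    TRUE ~ "OTHER"
  )
  factor(code, levels = product_type_levels)
}

#' Default column mapping for the tab-delimited export dialect
#'
#' Maps the internal field names to the header names expected in an input
#' file. Override any element to adapt to a different export.
#'
#' @return Named character vector.
#' @export
default_columns <- function() {
  c(
    product_id = "Product_ID",
    product_type = "Product_Type",
    ingredient = "Ingredient_Name",
    function_tag = "Ingredient_Function",
    concentration = "Concentration_mg_ml"
  )
}

#' Read a tab-delimited product-ingredient table
#'
#' One input row per product-ingredient combination. Rows sharing a product
#' id belong to one product; the table is returned in the same long form
#' (one row per product-ingredient record), which is the shape the rest of
#' the pipeline consumes.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param columns Named character vector mapping internal names
#'   (`product_id`, `product_type`, `ingredient`, `function_tag`,
#'   `concentration`) to file headers; see [default_columns()].
#' @return Tibble with columns `product_id`, `product_type` (factor),
#'   `ingredient` (raw name), `function_tag`, `concentration` (mg/mL,
#'   `NA` when absent or unparseable; unparseable values emit a warning).
#' @export
read_products <- function(path, columns = default_columns()) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  columns <- utils::modifyList(as.list(default_columns()), as.list(columns))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("product_id", "product_type", "ingredient")
  missing <- setdiff(
    unlist(columns[required], use.names = FALSE), names(raw)
  )
  if (length(missing) > 0) {
    abort(paste0(
      "required column(s) missing from ", path, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  out <- tibble(
    product_id = raw[[columns$product_id]],
    product_type = map_product_type(raw[[columns$product_type]]),
    ingredient = raw[[columns$ingredient]],
    function_tag = if (columns$function_tag %in% names(raw)) {
      raw[[columns$function_tag]]
    } else {
      NA_character_
    }
  )
  conc_raw <- if (columns$concentration %in% names(raw)) {
    raw[[columns$concentration]]
  } else {
    rep(NA_character_, nrow(raw))
  }
  conc <- suppressWarnings(as.numeric(conc_raw))
  bad <- !is.na(conc_raw) & conc_raw != "" & is.na(conc)
  if (any(bad)) {
    warn(paste0(
      sum(bad), " concentration value(s) could not be parsed and were ",
      "recorded as missing"
    ))
  }
  conc[conc < 0 & !is.na(conc)] <- NA_real_
  out$concentration <- conc
  out
}

#' Normalize ingredient names and merge synonym variants
#'
#' Every raw ingredient name is trimmed, case-folded and
#' whitespace-collapsed, then resolved through the synonym map. When the
#' merge makes two entries of one product identical, they collapse to a
#' single entry whose concentration is the sum of the reported values
#' (missing treated as zero only if at least one value is present,
#' otherwise missing): the merged forms co-exist in one liquid, so the
#' total amount is the meaningful quantity. The operation is idempotent.
#'
#' @param products Tibble from [read_products()].
#' @param synonyms Synonym-map tibble; defaults to [default_synonym_map()].
#' @return Tibble with the same columns; `ingredient` now holds canonical
#'   names and each (product, ingredient) appears once.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   product_id = "p1", product_type = factor("E_LIQUID"),
#'   ingredient = c("Menthol", "L-menthol"), function_tag = NA_character_,
#'   concentration = c(1, 2)
#' )
#' curate_ingredients(p)$concentration  # 3
curate_ingredients <- function(products, synonyms = default_synonym_map()) {
  synonyms <- validate_synonym_map(synonyms)
  lookup <- setNames(synonyms$canonical, synonyms$variant)
  out <- products %>%
    mutate(ingredient = normalize_name(.data$ingredient)) %>%
    mutate(ingredient = dplyr::coalesce(
      unname(lookup[.data$ingredient]), .data$ingredient
    ))
  # duplicates within a product only arise from synonym collisions, so
  # aggregate just those rows and leave the (vast) remainder untouched
  key <- paste(out$product_id, out$ingredient, sep = "\r")
  dup <- key %in% key[duplicated(key)]
  merged <- out[dup, ] %>%
    group_by(.data$product_id, .data$ingredient) %>%
    summarise(
      product_type = first(.data$product_type),
      function_tag = first(.data$function_tag[!is.na(.data$function_tag)]) %||%
        NA_character_,
      concentration = if (all(is.na(.data$concentration))) {
        NA_real_
      } else {
        sum(.data$concentration, na.rm = TRUE)
      },
      .groups = "drop"
    )
  bind_rows(out[!dup, ], merged) %>%
    select(
      "product_id", "product_type", "ingredient",
      "function_tag", "concentration"
    ) %>%
    arrange(.data$product_id, .data$ingredient)
}

#' Keep only products of liquid-containing types
#'
#' @param products Product tibble.
#' @return The rows whose `product_type` is one of [liquid_types], order
#'   preserved.
#' @export
select_liquid_types <- function(products) {
  products %>% filter(as.character(.data$product_type) %in% liquid_types)
}

#' Write a product table in the tab-delimited export dialect
#'
#' Inverse of [read_products()]: the written file re-reads to the same
#' records.
#'
#' @param products Product tibble.
#' @param path Output path.
#' @param columns Column mapping as in [read_products()].
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path, columns = default_columns()) {
  columns <- utils::modifyList(as.list(default_columns()), as.list(columns))
  out <- tibble(
    !!columns$product_id := products$product_id,
    !!columns$product_type := as.character(products$product_type),
    !!columns$ingredient := products$ingredient,
    !!columns$function_tag := products$function_tag,
    !!columns$concentration := products$concentration
  )
  atomic_write(function(tmp) {
    readr::write_tsv(out, tmp, progress = FALSE)
  }, path)
}
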