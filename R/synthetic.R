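#' Configuration for the synthetic product-ingredient generator
#'
#' The generator emulates a notification-system export of the e-cigarette
#' market: four liquid-containing product types with counts on the order
#' of the Dutch market (33179 e-liquids, 10970 disposables, 248
#' rechargeables, 51 refillables), an analyzable vocabulary of 194
#' ingredients plus 30 deliberately rare ones (to exercise the 1%
#' prevalence filter) and the three trivial carriers (always present),
#' ubiquitous nicotine with benzoic acid co-planted as its protonating
#' partner, latent flavor categories whose signature ingredient sets
#' co-occur strongly, synonym variants of a few well-known ingredients,
#' and lognormal concentrations in the 0.03-1.15 mg/mL range typical of
#' flavorings.
#'
#' With the defaults, a product carries on average about 8 flavorings
#' (signature_size x p_signature + background + nicotine terms), in line
#' with the ~10 flavorings per e-liquid reported for this market.
#'
#' @param seed Integer seed (required); the dataset is a pure function of
#'   the config.
#' @param scale Multiplier on all product counts (e.g. 0.1 for fast
#'   runs); counts round to at least 1.
#' @param n_products_per_type Named integer vector over [liquid_types].
#' @param n_ingredients Analyzable vocabulary size (signatures +
#'   background + nicotine + benzoic acid).
#' @param n_rare Extra rare ingredients planted below the prevalence
#'   filter.
#' @param p_rare Per-product presence probability of each rare
#'   ingredient.
#' @param n_categories Latent flavor categories.
#' @param signature_size Signature ingredients per category.
#' @param p_signature P(product carries a given signature ingredient of
#'   its own category).
#' @param p_background P(product carries a given non-signature
#'   ingredient).
#' @param nicotine_prevalence P(product contains nicotine).
#' @param benzoic_acid_given_nicotine P(benzoic acid | nicotine); given
#'   no nicotine, benzoic acid appears at `p_background`.
#' @param synonym_variant_rate Fraction of mentions of
#'   synonym-map-covered ingredients emitted under a variant name.
#' @param concentration_median,concentration_dispersion Lognormal
#'   parameters (mg/mL median; sdlog) for flavoring concentrations.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             scale = 1,
                             n_products_per_type = c(
                               E_LIQUID = 33179, DISPOSABLE = 10970,
                               RECHARGEABLE = 248, REFILLABLE = 51
                             ),
                             n_ingredients = 194,
                             n_rare = 30,
                             p_rare = 0.002,
                             n_categories = 10,
                             signature_size = 8,
                             p_signature = 0.6,
                             p_background = 0.01,
                             nicotine_prevalence = 0.8,
                             benzoic_acid_given_nicotine = 0.5,
                             synonym_variant_rate = 0.05,
                             concentration_median = 0.3,
                             concentration_dispersion = 1.0) {
  if (missing(seed)) abort("synthetic_config() requires a seed")
  probs <- c(
    p_rare, p_signature, p_background, nicotine_prevalence,
    benzoic_acid_given_nicotine, synonym_variant_rate
  )
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  stopifnot(
    scale > 0, n_categories >= 1, signature_size >= 2,
    n_ingredients >= n_categories * signature_size + 2
  )
  n_products_per_type <- pmax(
    1L, as.integer(round(n_products_per_type[liquid_types] * scale))
  )
  names(n_products_per_type) <- liquid_types
  structure(
    list(
      seed = as.integer(seed),
      n_products_per_type = n_products_per_type,
      n_ingredients = as.integer(n_ingredients),
      n_rare = as.integer(n_rare),
      p_rare = p_rare,
      n_categories = as.integer(n_categories),
      signature_size = as.integer(signature_size),
      p_signature = p_signature,
      p_background = p_background,
      nicotine_prevalence = nicotine_prevalence,
      benzoic_acid_given_nicotine = benzoic_acid_given_nicotine,
      synonym_variant_rate = synonym_variant_rate,
      concentration_median = concentration_median,
      concentration_dispersion = concentration_dispersion
    ),
    class = "synthetic_config"
  )
}

# small illustrative vocabulary of real flavoring names; the remainder of
# the vocabulary is filled with generic identifiers
known_flavorings <- c(
  "vanillin", "ethyl vanillin", "piperonal", "p-anisaldehyde",
  "delta-decalactone", "gamma-nonalactone", "ethyl maltol", "maltol",
  "ethyl butyrate", "ethyl acetate", "ethyl 2-methylbutyrate",
  "ethyl hexanoate", "hexyl acetate", "methyl cinnamate",
  "(z)-3-hexenol", "gamma-decalactone",
  "acetic acid", "butanoic acid", "2-methylbutanoic acid",
  "hexanoic acid", "dimethyl sulfide", "isopentyl acetate",
  "furaneol", "raspberry ketone",
  "menthol", "menthone", "eucalyptol", "cyclotene", "guaiacol",
  "2,3,5-trimethyl pyrazine", "2-acetyl pyrazine", "citric acid",
  "linalool", "beta-ionone", "alpha-ionone", "geraniol", "limonene",
  "damascenone", "benzyl alcohol", "trimethyl isopropyl butanamide"
)

# vocabulary layout for a config: signatures, background, rare, specials
synthetic_vocabulary <- function(config) {
  n_sig_total <- config$n_categories * config$signature_size
  n_background <- config$n_ingredients - n_sig_total - 2L  # - nicotine, benzoic
  stopifnot(n_background >= 0)
  n_named <- n_sig_total + n_background
  base <- known_flavorings[known_flavorings != "benzyl alcohol"]
  extra_needed <- max(0, n_named - length(base))
  flavor_names <- c(
    base,
    sprintf("flavoring %03d", seq_len(extra_needed))
  )[seq_len(n_named)]
  signatures <- split(
    flavor_names[seq_len(n_sig_total)],
    rep(seq_len(config$n_categories), each = config$signature_size)
  )
  names(signatures) <- sprintf("category_%02d", seq_len(config$n_categories))
  list(
    signatures = signatures,
    background = flavor_names[seq_len(n_named)][-seq_len(n_sig_total)],
    rare = sprintf("rare compound %02d", seq_len(config$n_rare)),
    nicotine = "nicotine",
    benzoic = "benzoic acid",
    carriers = trivial_ingredients()
  )
}

type_dialect_strings <- c(
  E_LIQUID = "E-liquid",
  DISPOSABLE = "Disposable e-cigarette",
  RECHARGEABLE = "Rechargeable e-cigarette",
  REFILLABLE = "Refillable e-cigarette"
)

#' Generate a synthetic product-ingredient dataset with known truth
#'
#' Each product draws a latent flavor category, always carries the three
#' trivial carriers, carries each signature ingredient of its category
#' with `p_signature`, every other flavoring with `p_background` (rare
#' ingredients with `p_rare`), nicotine at its prevalence and benzoic
#' acid conditionally on nicotine. A fraction of mentions of ingredients
#' covered by [default_synonym_map()] is emitted under a variant name,
#' and name casing is jittered, so the curation stage has real work to
#' do. Concentrations are lognormal. Output is byte-identical for equal
#' configs.
#'
#' @param config A [synthetic_config()].
#' @return List with `products` (tibble in the tab-delimited export
#'   dialect, see [default_columns()]) and `truth` (list: `signatures`,
#'   `planted_pairs`, `planted_clusters`, `categories` tibble
#'   (`product_id`, `category`), `config`).
#' @export
generate_products <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vocab <- synthetic_vocabulary(config)
  withr::with_seed(config$seed, generate_products_impl(config, vocab))
}

generate_products_impl <- function(config, vocab) {
  syn <- default_synonym_map()
  all_rows <- list()
  all_cat <- list()
  type_codes <- c(E_LIQUID = "EL", DISPOSABLE = "DP",
                  RECHARGEABLE = "RC", REFILLABLE = "RF")

  sig_flat <- unlist(vocab$signatures, use.names = FALSE)
  sig_cat <- rep(seq_len(config$n_categories),
                 each = config$signature_size)

  for (ty in liquid_types) {
    n <- config$n_products_per_type[[ty]]
    ids <- sprintf("%s-%06d", type_codes[[ty]], seq_len(n))
    category <- sample.int(config$n_categories, n, replace = TRUE)
    rows_i <- list()

    # signature + cross-category background presence for signature names
    for (k in seq_along(sig_flat)) {
      p <- ifelse(category == sig_cat[k],
                  config$p_signature, config$p_background)
      hit <- which(runif(n) < p)
      rows_i[[length(rows_i) + 1]] <- tibble(
        row = hit, ingredient = sig_flat[k],
        function_tag = "flavour and/or taste enhancer"
      )
    }
    for (ing in vocab$background) {
      hit <- which(runif(n) < config$p_background)
      rows_i[[length(rows_i) + 1]] <- tibble(
        row = hit, ingredient = ing,
        function_tag = "flavour and/or taste enhancer"
      )
    }
    for (ing in vocab$rare) {
      hit <- which(runif(n) < config$p_rare)
      rows_i[[length(rows_i) + 1]] <- tibble(
        row = hit, ingredient = ing,
        function_tag = "flavour and/or taste enhancer"
      )
    }
    nic <- runif(n) < config$nicotine_prevalence
    rows_i[[length(rows_i) + 1]] <- tibble(
      row = which(nic), ingredient = vocab$nicotine,
      function_tag = "nicotine"
    )
    p_benz <- ifelse(nic, config$benzoic_acid_given_nicotine,
                     config$p_background)
    rows_i[[length(rows_i) + 1]] <- tibble(
      row = which(runif(n) < p_benz), ingredient = vocab$benzoic,
      function_tag = "additive"
    )
    for (ing in vocab$carriers) {
      rows_i[[length(rows_i) + 1]] <- tibble(
        row = seq_len(n), ingredient = ing,
        function_tag = "carrier/solvent"
      )
    }
    rows <- bind_rows(rows_i)
    rows$product_id <- ids[rows$row]
    rows$product_type <- type_dialect_strings[[ty]]
    all_rows[[ty]] <- rows %>% select(-"row")
    all_cat[[ty]] <- tibble(product_id = ids, category = category)
  }

  long <- bind_rows(all_rows)

  # concentrations: flavorings around the configured median, nicotine and
  # carriers on their own (cosmetic) scales
  base_median <- dplyr::case_when(
    long$function_tag == "nicotine" ~ 12,
    long$ingredient == "propylene glycol" ~ 450,
    long$ingredient == "glycerol" ~ 400,
    long$ingredient == "water" ~ 30,
    TRUE ~ config$concentration_median
  )
  long$concentration <- round(
    rlnorm(nrow(long), meanlog = log(base_median),
           sdlog = config$concentration_dispersion),
    4
  )

  # synonym variants: a fraction of mentions of covered ingredients goes
  # out under a variant name
  variants <- split(syn$variant, syn$canonical)
  covered <- long$ingredient %in% names(variants)
  flip <- covered & runif(nrow(long)) < config$synonym_variant_rate
  if (any(flip)) {
    long$ingredient[flip] <- vapply(long$ingredient[flip], function(cn) {
      v <- variants[[cn]]
      v[[sample.int(length(v), 1)]]
    }, character(1))
  }
  # jitter casing so curation's case-folding is exercised
  title <- runif(nrow(long)) < 0.3
  long$ingredient[title] <- stringr::str_to_title(long$ingredient[title])

  order_idx <- lex_order(long$product_id, long$ingredient)
  long <- long[order_idx, ]

  products <- tibble(
    Product_ID = long$product_id,
    Product_Type = long$product_type,
    Ingredient_Name = long$ingredient,
    Ingredient_Function = long$function_tag,
    Concentration_mg_ml = long$concentration
  )
  planted_pairs <- bind_rows(lapply(vocab$signatures, function(s) {
    s <- lex_sort(s)
    cmb <- utils::combn(s, 2)
    tibble(ingredient_i = cmb[1, ], ingredient_j = cmb[2, ])
  }), .id = "category")
  list(
    products = products,
    truth = list(
      signatures = vocab$signatures,
      planted_clusters = vocab$signatures,
      planted_pairs = planted_pairs,
      categories = bind_rows(all_cat),
      config = config
    )
  )
}

#' Parse a raw export-dialect table into the internal product table
#'
#' The in-memory equivalent of [read_products()], for tables produced by
#' [generate_products()] or assembled by hand.
#'
#' @param raw Data frame in the export dialect.
#' @param columns Column mapping, see [default_columns()].
#' @return Product tibble as returned by [read_products()].
#' @export
as_product_table <- function(raw, columns = default_columns()) {
  columns <- utils::modifyList(as.list(default_columns()),
                               as.list(columns))
  tibble(
    product_id = as.character(raw[[columns$product_id]]),
    product_type = map_product_type(raw[[columns$product_type]]),
    ingredient = as.character(raw[[columns$ingredient]]),
    function_tag = as.character(raw[[columns$function_tag]]),
    concentration = as.numeric(raw[[columns$concentration]])
  )
}

#' Score recovery of planted structure
#'
#' Compares a found pair set and cluster list against the generator's
#' planted truth. Pair precision/recall are computed against the planted
#' within-signature pairs, optionally restricted to the ingredients that
#' survived the prevalence filter (recall over unobservable pairs is not
#' meaningful). Cluster recovery is the best-match Jaccard index of each
#' planted signature set over the found clusters.
#'
#' @param found_pairs Pair tibble (significant rows used when the column
#'   exists) or character vector of `"i|j"` keys.
#' @param found_clusters List of character vectors, or a
#'   [find_complexes()] tibble (its `members` column is used).
#' @param truth Truth list from [generate_products()].
#' @param ingredients Optional character vector restricting the planted
#'   pairs (e.g. the post-filter vocabulary).
#' @return List: `pair_precision` (`NA` when nothing was found),
#'   `pair_recall`, `n_found`, `n_planted`, `cluster_recovery` (tibble
#'   `category`, `best_jaccard`), `cluster_jaccard_mean` (`NA` when no
#'   clusters are planted).
#' @export
evaluate_recovery <- function(found_pairs, found_clusters, truth,
                              ingredients = NULL) {
  if (is.data.frame(found_pairs)) {
    if ("significant" %in% names(found_pairs)) {
      found_pairs <- found_pairs[found_pairs$significant, ]
    }
    found <- unique(pair_key(found_pairs$ingredient_i,
                             found_pairs$ingredient_j))
  } else {
    found <- unique(as.character(found_pairs))
  }
  planted <- truth$planted_pairs
  if (!is.null(ingredients)) {
    planted <- planted %>%
      filter(.data$ingredient_i %in% ingredients,
             .data$ingredient_j %in% ingredients)
  }
  planted_keys <- unique(pair_key(planted$ingredient_i,
                                  planted$ingredient_j))
  tp <- length(intersect(found, planted_keys))
  precision <- if (length(found) == 0) NA_real_ else tp / length(found)
  recall <- if (length(planted_keys) == 0) {
    NA_real_
  } else {
    tp / length(planted_keys)
  }

  if (is.data.frame(found_clusters)) {
    found_clusters <- found_clusters$members
  }
  jaccard <- function(x, y) {
    length(intersect(x, y)) / length(union(x, y))
  }
  cluster_recovery <- tibble(
    category = names(truth$planted_clusters) %||%
      as.character(seq_along(truth$planted_clusters)),
    best_jaccard = vapply(truth$planted_clusters, function(s) {
      if (!is.null(ingredients)) s <- intersect(s, ingredients)
      if (length(s) == 0 || length(found_clusters) == 0) return(0)
      max(vapply(found_clusters, jaccard, numeric(1), y = s))
    }, numeric(1))
  )
  list(
    pair_precision = precision,
    pair_recall = recall,
    n_found = length(found),
    n_planted = length(planted_keys),
    cluster_recovery = cluster_recovery,
    cluster_jaccard_mean = if (nrow(cluster_recovery) == 0) {
      NA_real_
    } else {
      mean(cluster_recovery$best_jaccard)
    }
  )
}

#' Serialize a generator truth object to JSON
#'
#' @param truth Truth list from [generate_products()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    signatures = truth$signatures,
    planted_pairs = truth$planted_pairs,
    categories = truth$categories,
    seed = truth$config$seed
  )
  atomic_write(function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  }, path)
}
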