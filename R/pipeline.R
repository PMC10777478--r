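#' Assemble a pipeline configuration
#'
#' A plain list validated once, covering every stage: input (a TSV path
#' or a synthetic config), curation, filtering, the significance rule,
#' the permutation null, MCODE, and the output directory. Every
#' stochastic stage takes an explicit seed.
#'
#' @param input Path to a product TSV, or a [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param columns Column mapping for TSV input.
#' @param synonyms Synonym map tibble or path to one.
#' @param exclude Trivial-ingredient exclusion list.
#' @param min_fraction Prevalence-filter fraction.
#' @param rule [significance_rule()].
#' @param estimator `"cmle"` or `"sample"`.
#' @param null_reps Permutation replicates (0 disables the null stage).
#' @param null_seed Seed for the permutation null.
#' @param layout_seed Seed for the spring layout.
#' @param mcode [mcode_params()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir,
                            columns = default_columns(),
                            synonyms = default_synonym_map(),
                            exclude = trivial_ingredients(),
                            min_fraction = 0.01,
                            rule = significance_rule(),
                            estimator = c("cmle", "sample"),
                            null_reps = 10,
                            null_seed = 20221231,
                            layout_seed = 1,
                            mcode = mcode_params()) {
  estimator <- match.arg(estimator)
  if (is.character(synonyms)) synonyms <- read_synonym_map(synonyms)
  structure(
    list(
      input = input, out_dir = out_dir, columns = columns,
      synonyms = synonyms, exclude = exclude,
      min_fraction = min_fraction, rule = rule, estimator = estimator,
      null_reps = null_reps, null_seed = null_seed,
      layout_seed = layout_seed, mcode = mcode
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; nested
#' blocks `synthetic:`, `rule:` and `mcode:` map onto
#' [synthetic_config()], [significance_rule()] and [mcode_params()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$synthetic)) {
    do.call(synthetic_config, y$synthetic)
  } else {
    y$input %||% abort("config needs 'input' or a 'synthetic' block")
  }
  args <- list(
    input = input,
    out_dir = y$out_dir %||% abort("config needs 'out_dir'")
  )
  if (!is.null(y$columns)) args$columns <- unlist(y$columns)
  if (!is.null(y$synonyms)) args$synonyms <- y$synonyms
  if (!is.null(y$exclude)) args$exclude <- y$exclude
  if (!is.null(y$min_fraction)) args$min_fraction <- y$min_fraction
  if (!is.null(y$rule)) args$rule <- do.call(significance_rule, y$rule)
  if (!is.null(y$estimator)) args$estimator <- y$estimator
  if (!is.null(y$null_reps)) args$null_reps <- y$null_reps
  if (!is.null(y$null_seed)) args$null_seed <- y$null_seed
  if (!is.null(y$layout_seed)) args$layout_seed <- y$layout_seed
  if (!is.null(y$mcode)) args$mcode <- do.call(mcode_params, y$mcode)
  do.call(pipeline_config, args)
}

#' Run the full co-occurrence pipeline
#'
#' Stages, in order: simulate/read -> curate -> presence matrices +
#' prevalence filter -> per-type ingredient summaries -> per-type pair
#' screening -> permutation null -> network + statistics -> MCODE
#' clusters -> cross-type overlap -> reports. Every output file is
#' written atomically; a manifest (config hash, seeds, package version,
#' per-stage counts) records the run.
#'
#' @param config A `pipeline_config`, or a path to a YAML config.
#' @param stages Character vector of stage names to run (subsets must be
#'   contiguous from the start; later stages need earlier ones). Default
#'   all.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every intermediate result
#'   (`products`, `matrices`, `summaries`, `pairs`, `null`, `networks`,
#'   `stats`, `clusters`, `overlap`, `recovery` when synthetic,
#'   `manifest`).
#' @export
run_pipeline <- function(config,
                         stages = c("curate", "pairs", "null", "network",
                                    "mcode", "overlap", "report"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (!quiet) inform(paste0(...))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("coocnet")),
    config_hash = rlang::hash(config),
    null_seed = config$null_seed,
    layout_seed = config$layout_seed,
    estimator = config$estimator,
    stages_run = character(0),
    counts = list(),
    failed_stage = NULL
  )
  write_manifest <- function() {
    atomic_write(function(tmp) {
      jsonlite::write_json(manifest, tmp, auto_unbox = TRUE,
                           digits = NA, null = "null", force = TRUE)
    }, file.path(out_dir, "manifest.json"))
  }
  finish_stage <- function(name) {
    manifest$stages_run <<- c(manifest$stages_run, name)
    write_manifest()
  }
  on.exit(write_manifest(), add = TRUE)

  # --- input + curation -------------------------------------------------
  truth <- NULL
  if (inherits(config$input, "synthetic_config")) {
    say("simulate: generating synthetic dataset (seed ",
        config$input$seed, ")")
    manifest$synthetic_seed <- config$input$seed
    gen <- generate_products(config$input)
    truth <- gen$truth
    write_products(
      as_product_table(gen$products),
      file.path(out_dir, "products.tsv")
    )
    write_truth_json(truth, file.path(out_dir, "truth.json"))
    raw <- as_product_table(gen$products)
  } else {
    say("read: ", config$input)
    raw <- read_products(config$input, config$columns)
  }
  products <- raw %>%
    select_liquid_types() %>%
    curate_ingredients(config$synonyms)
  n_prod <- n_distinct(products$product_id)
  say("curate: ", n_prod, " liquid-containing products, ",
      n_distinct(products$ingredient), " distinct ingredients")
  manifest$counts$products <- n_prod
  res$products <- products
  res$truth <- truth

  matrices <- lapply(
    setNames(liquid_types, liquid_types),
    function(ty) build_presence_matrix(products, ty, config$exclude)
  )
  matrices <- prevalence_filter(matrices, config$min_fraction)
  kept <- matrices[[1]]$ingredient_names
  say("filter: ", length(kept), " ingredients pass the ",
      100 * config$min_fraction, "% prevalence filter")
  manifest$counts$ingredients_kept <- length(kept)
  res$matrices <- matrices
  res$summaries <- lapply(
    setNames(liquid_types, liquid_types),
    function(ty) ingredient_summary(products, ty)
  )
  if ("report" %in% stages) {
    for (ty in liquid_types) {
      write_presence_tsv(
        matrices[[ty]],
        file.path(out_dir, paste0("presence_", tolower(ty), ".tsv"))
      )
      atomic_write(function(tmp) {
        readr::write_tsv(res$summaries[[ty]], tmp, progress = FALSE)
      }, file.path(out_dir, paste0("summary_", tolower(ty), ".tsv")))
    }
  }
  finish_stage("curate")
  if (!"pairs" %in% stages) return(invisible(res))

  # --- pair screening ---------------------------------------------------
  res$pairs <- lapply(matrices, function(m) {
    if (length(m$ingredient_names) < 2) return(NULL)
    find_significant_pairs(m, config$rule, config$estimator)
  })
  for (ty in liquid_types) {
    p <- res$pairs[[ty]]
    n_sig <- if (is.null(p)) 0L else sum(p$significant)
    say("pairs [", ty, "]: ",
        if (is.null(p)) 0L else nrow(p), " pairs evaluated, ",
        n_sig, " significant")
    manifest$counts[[paste0("pairs_significant_", tolower(ty))]] <- n_sig
    if ("report" %in% stages && !is.null(p)) {
      write_pairs_tsv(
        p, file.path(out_dir, paste0("pairs_", tolower(ty), ".tsv"))
      )
    }
  }
  finish_stage("pairs")

  # --- permutation null -------------------------------------------------
  if ("null" %in% stages && config$null_reps > 0) {
    res$null <- lapply(
      setNames(liquid_types, liquid_types),
      function(ty) {
        m <- matrices[[ty]]
        if (length(m$ingredient_names) < 2) return(NULL)
        permutation_null(
          m, config$rule, config$estimator,
          n_reps = config$null_reps, seed = config$null_seed
        )
      }
    )
    for (ty in liquid_types) {
      nc <- res$null[[ty]]
      if (is.null(nc)) next
      say("null [", ty, "]: significant pairs per replicate: ",
          paste(nc$replicates$n_significant, collapse = " "))
      if ("report" %in% stages) {
        atomic_write(function(tmp) {
          readr::write_tsv(nc$replicates, tmp, progress = FALSE)
        }, file.path(out_dir, paste0("null_", tolower(ty), ".tsv")))
      }
    }
    finish_stage("null")
  }
  if (!"network" %in% stages) return(invisible(res))

  # --- overlap first (so networks can flag multi-type edges) -----------
  res$overlap <- pair_overlap(
    lapply(res$pairs, function(p) {
      if (is.null(p)) character(0) else p
    })
  )
  multi_keys <- res$overlap$multi_type_pairs$pair

  # --- networks + stats -------------------------------------------------
  res$networks <- lapply(
    setNames(liquid_types, liquid_types),
    function(ty) {
      p <- res$pairs[[ty]]
      if (is.null(p)) p <- tibble(ingredient_i = character(0),
                                  ingredient_j = character(0))
      build_network(p, product_type = ty, multi_type_pairs = multi_keys)
    }
  )
  res$stats <- lapply(res$networks, network_stats)
  for (ty in liquid_types) {
    s <- res$stats[[ty]]
    say("network [", ty, "]: ", s$n_nodes, " nodes, ", s$n_edges,
        " edges")
    if ("report" %in% stages) {
      net <- res$networks[[ty]]
      write_sif(net, file.path(out_dir, paste0("network_",
                                               tolower(ty), ".sif")))
      write_graphml(net, file.path(out_dir, paste0("network_",
                                                   tolower(ty),
                                                   ".graphml")))
      write_edgelist_tsv(net, file.path(out_dir, paste0("edges_",
                                                        tolower(ty),
                                                        ".tsv")))
    }
  }
  finish_stage("network")

  # --- clusters ---------------------------------------------------------
  if ("mcode" %in% stages) {
    res$clusters <- lapply(res$networks, find_complexes,
                           params = config$mcode)
    for (ty in liquid_types) {
      cl <- res$clusters[[ty]]
      say("mcode [", ty, "]: ", nrow(cl), " clusters")
      if ("report" %in% stages) {
        write_clusters_tsv(
          cl, file.path(out_dir, paste0("clusters_", tolower(ty),
                                        ".tsv"))
        )
      }
    }
    finish_stage("mcode")
  }

  if ("overlap" %in% stages) {
    if ("report" %in% stages) {
      write_overlap_tsv(res$overlap, file.path(out_dir, "overlap.tsv"))
    }
    finish_stage("overlap")
  }

  # --- summary report ---------------------------------------------------
  if ("report" %in% stages) {
    table1 <- lapply(
      setNames(liquid_types, liquid_types),
      function(ty) {
        s <- res$stats[[ty]]
        list(
          n_products = matrices[[ty]]$n_products,
          n_significant_pairs = s$n_edges,
          n_unique_ingredients = s$n_nodes,
          avg_neighbors_main_component =
            round(s$avg_neighbors_main_component, 1),
          characteristic_path_length =
            round(s$characteristic_path_length, 1),
          diameter = s$diameter
        )
      }
    )
    atomic_write(function(tmp) {
      jsonlite::write_json(table1, tmp, auto_unbox = TRUE, digits = NA,
                           null = "null")
    }, file.path(out_dir, "table1.json"))
    if (!is.null(truth)) {
      res$recovery <- evaluate_recovery(
        res$pairs$E_LIQUID, res$clusters$E_LIQUID %||%
          list(), truth,
        ingredients = kept
      )
      say("recovery: pair recall ",
          round(res$recovery$pair_recall, 3), ", precision ",
          round(res$recovery$pair_precision, 3), ", mean cluster Jaccard ",
          round(res$recovery$cluster_jaccard_mean, 3))
      atomic_write(function(tmp) {
        jsonlite::write_json(
          res$recovery[c("pair_precision", "pair_recall",
                         "cluster_jaccard_mean")],
          tmp, auto_unbox = TRUE, digits = NA
        )
      }, file.path(out_dir, "recovery.json"))
    }
    finish_stage("report")
  }
  manifest$counts -> res$counts
  res$manifest <- manifest
  invisible(res)
}
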