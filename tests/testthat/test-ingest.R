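write_fixture_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

header <- paste("Product_ID", "Product_Type", "Ingredient_Name",
                "Ingredient_Function", "Concentration_mg_ml", sep = "\t")

test_that("read_products aggregates rows by product id and maps types", {
  path <- write_fixture_tsv(c(
    header,
    "p1\tE-Liquid\tvanillin\tflavour and/or taste enhancer\t0.5",
    "p1\tE-Liquid\tmenthol\tflavour and/or taste enhancer\t1.0",
    "p1\tE-Liquid\tnicotine\tnicotine\t12",
    "p2\tDevice\tvanillin\tflavour and/or taste enhancer\t0.1"
  ))
  out <- read_products(path)
  expect_equal(nrow(out), 4)
  expect_equal(dplyr::n_distinct(out$product_id), 2)
  expect_equal(sum(out$product_id == "p1"), 3)
  expect_equal(
    as.character(out$product_type[out$product_id == "p1"][1]), "E_LIQUID"
  )
  expect_equal(
    as.character(out$product_type[out$product_id == "p2"][1]), "OTHER"
  )
})

test_that("read_products handles an empty file with a valid header", {
  path <- write_fixture_tsv(header)
  out <- read_products(path)
  expect_equal(nrow(out), 0)
  expect_named(
    out,
    c("product_id", "product_type", "ingredient", "function_tag",
      "concentration")
  )
})

test_that("read_products errors on missing required columns and warns on bad concentrations", {
  bad <- write_fixture_tsv(c(
    "Product_ID\tIngredient_Name", "p1\tvanillin"
  ))
  expect_error(read_products(bad), "required column")

  odd <- write_fixture_tsv(c(
    header,
    "p1\tE-Liquid\tvanillin\tflavour\tnot-a-number",
    "p1\tE-Liquid\tmenthol\tflavour\t2.5"
  ))
  expect_warning(out <- read_products(odd), "concentration")
  expect_true(is.na(out$concentration[out$ingredient == "vanillin"]))
  expect_equal(out$concentration[out$ingredient == "menthol"], 2.5)
})

test_that("product type strings map by the declared table", {
  types <- map_product_type(c(
    "E-Liquid", "e_liquid", "E-liquid refill", "Disposable e-cigarette",
    "RECHARGEABLE E-CIGARETTE", "refillable e-cigarette", "Device",
    "product part"
  ))
  expect_equal(
    as.character(types),
    c("E_LIQUID", "E_LIQUID", "E_LIQUID", "DISPOSABLE", "RECHARGEABLE",
      "REFILLABLE", "OTHER", "OTHER")
  )
})

make_product <- function(id, ingredient, conc = NA_real_,
                         type = "E_LIQUID") {
  tibble::tibble(
    product_id = id, product_type = factor(type),
    ingredient = ingredient, function_tag = NA_character_,
    concentration = conc
  )
}

test_that("curation merges the shipped synonym examples onto canonical names", {
  p <- dplyr::bind_rows(
    make_product("p1", c("Menthol", "L-menthol"), c(1, 2)),
    make_product("p2", "citric acid monohydrate", 0.4),
    make_product("p3", "  Vanillin ", 0.9),
    make_product("p4", "3-Methyl-1,2-cyclopentanedione", 0.2)
  )
  out <- curate_ingredients(p)
  expect_equal(out$ingredient[out$product_id == "p1"], "menthol")
  expect_equal(out$concentration[out$product_id == "p1"], 3)
  expect_equal(out$ingredient[out$product_id == "p2"], "citric acid")
  expect_equal(out$ingredient[out$product_id == "p3"], "vanillin")
  expect_equal(out$concentration[out$product_id == "p3"], 0.9)
  expect_equal(out$ingredient[out$product_id == "p4"], "cyclotene")
})

test_that("merged concentrations treat missing as zero only when a value exists", {
  p <- dplyr::bind_rows(
    make_product("p1", c("menthol", "L-menthol"), c(NA, 2)),
    make_product("p2", c("menthol", "L-menthol"), c(NA, NA))
  )
  out <- curate_ingredients(p)
  expect_equal(out$concentration[out$product_id == "p1"], 2)
  expect_true(is.na(out$concentration[out$product_id == "p2"]))
})

test_that("curation is idempotent", {
  p <- dplyr::bind_rows(
    make_product("p1", c("Menthol", "L-menthol", "Vanillin  Propylene glycol  acetal"),
                 c(1, 2, 0.5)),
    make_product("p2", c("ethyl maltol", "Citric Acid Monohydrate"), c(NA, 1))
  )
  once <- curate_ingredients(p)
  twice <- curate_ingredients(once)
  expect_equal(twice, once)
})

test_that("synonym maps reject cycles and unknown reasons degrade to other", {
  bad <- tibble::tibble(
    variant = c("a", "b"), canonical = c("b", "c"),
    reason = c("other", "other")
  )
  expect_error(validate <- curate_ingredients(make_product("p", "x"), bad),
               "acyclic")
  ok <- tibble::tibble(variant = "a", canonical = "b", reason = "weird")
  expect_equal(curate_ingredients(make_product("p", "A"), ok)$ingredient,
               "b")
})

test_that("select_liquid_types keeps exactly the four liquid types in order", {
  p <- dplyr::bind_rows(
    make_product("p1", "x", type = "E_LIQUID"),
    make_product("p2", "x", type = "OTHER"),
    make_product("p3", "x", type = "DISPOSABLE"),
    make_product("p4", "x", type = "RECHARGEABLE"),
    make_product("p5", "x", type = "OTHER"),
    make_product("p6", "x", type = "REFILLABLE")
  )
  out <- select_liquid_types(p)
  expect_equal(out$product_id, c("p1", "p3", "p4", "p6"))
  expect_equal(nrow(select_liquid_types(make_product("p", "x",
                                                     type = "OTHER"))), 0)
})

test_that("the shipped example export parses, curates and matrices correctly", {
  path <- system.file("extdata", "example_products.tsv",
                      package = "coocnet")
  curated <- curate_ingredients(select_liquid_types(read_products(path)))
  expect_equal(dplyr::n_distinct(curated$product_id), 4)  # device dropped
  # L-menthol + menthol merged with summed concentration
  el2 <- curated[curated$product_id == "EL-0002", ]
  expect_equal(el2$ingredient[el2$ingredient == "menthol"], "menthol")
  expect_equal(el2$concentration[el2$ingredient == "menthol"], 3.0)
  pm <- build_presence_matrix(curated, "E_LIQUID")
  expect_equal(pm$n_products, 3)
  expect_false(any(trivial_ingredients() %in% pm$ingredient_names))
  expect_true(all(c("vanillin", "citric acid") %in% pm$ingredient_names))
})

test_that("writing curated records and re-reading reproduces the presence matrix", {
  gen <- generate_products(synthetic_config(seed = 7, scale = 0.005))
  curated <- curate_ingredients(select_liquid_types(
    as_product_table(gen$products)
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_products(curated, path)
  reread <- curate_ingredients(select_liquid_types(read_products(path)))
  for (ty in c("E_LIQUID", "DISPOSABLE")) {
    pm1 <- build_presence_matrix(curated, ty)
    pm2 <- build_presence_matrix(reread, ty)
    expect_identical(pm1$ingredient_names, pm2$ingredient_names)
    expect_identical(pm1$product_ids, pm2$product_ids)
    expect_equal(as.matrix(pm1), as.matrix(pm2))
  }
})
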