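#' Validate a species-by-trait table against a schema
#'
#' Checks the structural invariants of a trait table: unique species ids, at
#' least two species, strictly positive continuous traits (body mass in
#' grams), binary traits coded 0/1, a valid three-level forest-dependency
#' classification, and — under the default foraging scheme — at least one
#' food-type trait and one foraging-stratum trait set per species.
#' Violations raise an error naming the offending species and column.
#'
#' @param traits a data frame with columns `species_id`, `forest_dependency`
#'   and one column per schema trait.
#' @param schema an [trait_schema()] describing the trait columns.
#' @return The validated trait table as a tibble (invisibly classed
#'   `fda_traits`).
#' @export
validate_trait_table <- function(traits, schema = default_trait_schema()) {
  traits <- tibble::as_tibble(traits)
  need <- c("species_id", "forest_dependency", schema$trait)
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    rlang::abort(sprintf("Trait table missing column(s): %s.", toString(miss)))
  }
  if (nrow(traits) < 2L) rlang::abort("Trait table needs at least 2 species.")
  dup <- traits$species_id[duplicated(traits$species_id)]
  if (length(dup)) {
    rlang::abort(sprintf("Duplicate species_id: %s.", toString(unique(dup))))
  }
  bad_dep <- !traits$forest_dependency %in% c("high", "medium", "low")
  if (any(bad_dep)) {
    rlang::abort(sprintf(
      "Invalid forest_dependency '%s' for species '%s' (use high/medium/low).",
      traits$forest_dependency[bad_dep][1], traits$species_id[bad_dep][1]
    ))
  }
  for (tr in schema_traits(schema, type = "continuous")) {
    v <- traits[[tr]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      i <- which(!is.numeric(v) | !is.finite(v) | v <= 0)[1]
      rlang::abort(sprintf(
        "Continuous trait '%s' must be finite and > 0; offending species '%s'.",
        tr, traits$species_id[i]
      ))
    }
  }
  for (tr in schema_traits(schema, type = "binary")) {
    v <- traits[[tr]]
    if (!is.numeric(v) || any(!v %in% c(0, 1))) {
      i <- which(!v %in% c(0, 1))[1]
      rlang::abort(sprintf(
        "Binary trait '%s' must be 0/1; offending species '%s' (value %s).",
        tr, traits$species_id[i], as.character(v[i])
      ))
    }
  }
  food <- schema_traits(schema, category = "food_type")
  strat <- schema_traits(schema, category = "foraging_stratum")
  if (length(food)) {
    none <- rowSums(as.matrix(traits[food])) == 0
    if (any(none)) {
      rlang::abort(sprintf(
        "Species '%s' has no food-type trait set.", traits$species_id[none][1]
      ))
    }
  }
  if (length(strat)) {
    none <- rowSums(as.matrix(traits[strat])) == 0
    if (any(none)) {
      rlang::abort(sprintf(
        "Species '%s' has no foraging-stratum trait set.", traits$species_id[none][1]
      ))
    }
  }
  class(traits) <- unique(c("fda_traits", class(traits)))
  traits
}

#' Read a species-by-trait table from CSV
#'
#' One species per row; the header names the columns; trait columns are
#' declared by the schema (see [read_trait_schema()]), never guessed.
#'
#' @param path path to the trait CSV.
#' @inheritParams validate_trait_table
#' @return A validated `fda_traits` tibble.
#' @export
read_trait_table <- function(path, schema = default_trait_schema()) {
  if (!file.exists(path)) rlang::abort(sprintf("Trait file '%s' not found.", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_trait_table(df, schema)
}

#' Write a trait table to CSV
#' @param traits an `fda_traits` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}

#' Ecological subgroup membership
#'
#' Returns the species ids belonging to one of the five analysis groups:
#' * `ALL` — every species;
#' * `SPE` — forest specialists (`forest_dependency == "high"`);
#' * `GEN` — habitat generalists (`forest_dependency == "low"`;
#'   medium-dependency species belong to neither SPE nor GEN);
#' * `FGr` — frugivores/granivores: diet contains fruits and/or seeds
#'   (schema roles `fruit`, `seed`);
#' * `INV` — insectivores: invertebrates in the diet (role `invertebrate`).
#'
#' Groups may overlap (a fruit-eating insectivore is in both FGr and INV).
#'
#' @param traits an `fda_traits` tibble.
#' @param group one of `"ALL"`, `"SPE"`, `"GEN"`, `"FGr"`, `"INV"`.
#' @param schema the trait schema (supplies the diet-role columns).
#' @return Character vector of species ids, in trait-table order.
#' @export
#' @examples
#' pool <- generate_pool(scenario_config(n_species_pool = 40, seed = 1))
#' length(subgroup_species(pool, "ALL"))
subgroup_species <- function(traits, group, schema = default_trait_schema()) {
  group <- as.character(group)
  if (length(group) != 1L || !group %in% c("ALL", "SPE", "GEN", "FGr", "INV")) {
    rlang::abort(sprintf(
      "Unknown subgroup '%s' (use ALL, SPE, GEN, FGr or INV).", toString(group)
    ))
  }
  keep <- switch(group,
    ALL = rep(TRUE, nrow(traits)),
    SPE = traits$forest_dependency == "high",
    GEN = traits$forest_dependency == "low",
    FGr = role_any(traits, schema, c("fruit", "seed")),
    INV = role_any(traits, schema, "invertebrate")
  )
  traits$species_id[keep]
}

role_any <- function(traits, schema, roles) {
  cols <- schema_traits(schema, role = roles)
  if (!length(cols)) {
    rlang::abort(sprintf(
      "Schema declares no trait with role(s) %s.", toString(roles)
    ))
  }
  rowSums(as.matrix(traits[cols])) > 0
}
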