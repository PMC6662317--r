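#' Trait schema: which columns are traits, and of what kind
#'
#' A trait schema declares, for every trait column of a species-by-trait
#' table, whether it is continuous or binary, which functional category it
#' belongs to (resource quantity, food type, foraging stratum, foraging
#' method, activity period, mixed flock), and — for the diet columns used to
#' build ecological subgroups — an optional role (`fruit`, `seed`,
#' `invertebrate`). The schema is declared explicitly rather than inferred
#' from the data: silently treating a 0/1-coded continuous column as binary
#' is the main I/O hazard for mixed-trait tables.
#'
#' @param trait character vector of trait column names.
#' @param type `"continuous"` or `"binary"`, one per trait.
#' @param category functional category label, one per trait.
#' @param role optional subgrouping role (`NA`, `"fruit"`, `"seed"`,
#'   `"invertebrate"`), one per trait.
#'
#' @return A tibble of class `fda_schema` with columns `trait`, `type`,
#'   `category`, `role`.
#' @export
#' @examples
#' sch <- default_trait_schema()
#' table(sch$type)
trait_schema <- function(trait, type, category, role = NA_character_) {
  type <- match_lengths(type, trait, "type")
  category <- match_lengths(category, trait, "category")
  role <- match_lengths(role, trait, "role")
  bad <- !type %in% c("continuous", "binary")
  if (any(bad)) {
    rlang::abort(sprintf(
      "Unknown trait type '%s' for trait '%s' (use 'continuous' or 'binary').",
      type[bad][1], trait[bad][1]
    ))
  }
  if (anyDuplicated(trait)) {
    rlang::abort("Duplicate trait names in schema.")
  }
  out <- tibble::tibble(
    trait = as.character(trait),
    type = type,
    category = category,
    role = as.character(role)
  )
  class(out) <- c("fda_schema", class(out))
  out
}

match_lengths <- function(x, template, what) {
  if (length(x) == 1L) x <- rep(x, length(template))
  if (length(x) != length(template)) {
    rlang::abort(sprintf("`%s` must have length 1 or %d.", what, length(template)))
  }
  x
}

#' Default foraging-trait schema (25 binary traits + body mass)
#'
#' The default scheme used throughout the package: one continuous trait
#' (mean body mass, grams) and 25 binary traits covering food types,
#' foraging strata/substrates, foraging methods, activity period and
#' mixed-flock participation. All traits carry equal weight in the Gower
#' dissimilarity.
#'
#' @return An `fda_schema` tibble with 26 rows.
#' @export
default_trait_schema <- function() {
  food <- c("invertebrates", "fruits", "seeds_grains", "nectar", "flowers",
            "foliage", "vertebrates")
  strata <- c("canopy", "midstory", "understory", "ground", "water", "mud", "air")
  method <- c("pursuit", "gleaning", "pouncing", "pecking", "grazing",
              "scavenging", "probing", "hawking")
  activity <- c("diurnal", "nocturnal")
  trait_schema(
    trait = c("body_mass", food, strata, method, activity, "mixed_flock"),
    type = c("continuous", rep("binary", 25L)),
    category = c("resource_quantity", rep("food_type", length(food)),
                 rep("foraging_stratum", length(strata)),
                 rep("foraging_method", length(method)),
                 rep("activity_period", length(activity)), "mixed_flock"),
    role = c(NA, "invertebrate", "fruit", "seed", rep(NA, 22L))
  )
}

#' Read a trait schema from a sidecar CSV
#'
#' Expects a CSV with columns `trait`, `type`, `category` and optionally
#' `role`.
#'
#' @param path path to the schema CSV.
#' @return An `fda_schema` tibble.
#' @export
read_trait_schema <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Schema file '%s' not found.", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trait", "type", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(sprintf("Schema file missing column(s): %s.", toString(miss)))
  }
  if (!"role" %in% names(df)) df$role <- NA_character_
  trait_schema(df$trait, df$type, df$category, df$role)
}

#' Write a trait schema to CSV
#'
#' @param schema an `fda_schema`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_schema <- function(schema, path) {
  utils::write.csv(as.data.frame(schema), path, row.names = FALSE)
  invisible(path)
}

schema_traits <- function(schema, type = NULL, category = NULL, role = NULL) {
  keep <- rep(TRUE, nrow(schema))
  if (!is.null(type)) keep <- keep & schema$type %in% type
  if (!is.null(category)) keep <- keep & schema$category %in% category
  if (!is.null(role)) keep <- keep & schema$role %in% role
  schema$trait[keep]
}
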