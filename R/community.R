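#' Validate a site-by-species community matrix
#'
#' A community matrix is a tidy table with one row per site: metadata
#' columns `site_id`, `landscape`, `habitat` (`"forest"` or
#' `"agroforestry"`), planar coordinates `coord_x`, `coord_y`, and one
#' abundance column (count, >= 0) per species. Every species column must
#' appear in the companion trait table, and every site must hold at least
#' one individual.
#'
#' @param community the community data frame.
#' @param traits the companion `fda_traits` table (optional; enables the
#'   species-coverage check).
#' @return The validated community as a tibble classed `fda_community`.
#' @export
validate_community <- function(community, traits = NULL) {
  community <- tibble::as_tibble(community)
  meta <- c("site_id", "landscape", "habitat", "coord_x", "coord_y")
  miss <- setdiff(meta, names(community))
  if (length(miss)) {
    rlang::abort(sprintf("Community matrix missing column(s): %s.", toString(miss)))
  }
  if (anyDuplicated(community$site_id)) {
    rlang::abort("Duplicate site_id in community matrix.")
  }
  bad_hab <- !community$habitat %in% c("forest", "agroforestry")
  if (any(bad_hab)) {
    rlang::abort(sprintf(
      "Invalid habitat '%s' at site '%s' (use forest/agroforestry).",
      community$habitat[bad_hab][1], community$site_id[bad_hab][1]
    ))
  }
  sp <- setdiff(names(community), meta)
  if (!length(sp)) rlang::abort("Community matrix has no species columns.")
  ab <- as.matrix(community[sp])
  if (!is.numeric(ab) || any(!is.finite(ab)) || any(ab < 0)) {
    rlang::abort("Abundances must be finite and >= 0.")
  }
  if (!is.null(traits)) {
    unknown <- setdiff(sp, traits$species_id)
    if (length(unknown)) {
      rlang::abort(sprintf(
        "Species column(s) absent from trait table: %s.",
        toString(utils::head(unknown, 5))
      ))
    }
  }
  empty <- rowSums(ab) == 0
  if (any(empty)) {
    rlang::abort(sprintf(
      "Site '%s' has no individuals.", community$site_id[empty][1]
    ))
  }
  class(community) <- unique(c("fda_community", class(community)))
  community
}

#' Read a community matrix from CSV
#' @param path path to the community CSV (sites as rows, species as columns).
#' @inheritParams validate_community
#' @return A validated `fda_community` tibble.
#' @export
read_community_matrix <- function(path, traits = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("Community file '%s' not found.", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_community(df, traits)
}

#' Write a community matrix to CSV
#' @param community an `fda_community` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(community, path) {
  utils::write.csv(as.data.frame(community), path, row.names = FALSE)
  invisible(path)
}

#' Species columns of a community matrix
#' @param community an `fda_community` tibble.
#' @return Character vector of species ids (column order).
#' @export
community_species <- function(community) {
  setdiff(names(community),
          c("site_id", "landscape", "habitat", "coord_x", "coord_y"))
}

#' Site-by-species abundance matrix
#'
#' @param community an `fda_community` tibble.
#' @param relative if `TRUE`, rows are normalized to relative abundances
#'   (each row sums to 1; all-zero rows stay zero).
#' @return Numeric matrix, sites as rows (named by `site_id`).
#' @export
abundance_matrix <- function(community, relative = FALSE) {
  sp <- community_species(community)
  m <- as.matrix(community[sp])
  rownames(m) <- community$site_id
  if (relative) {
    tot <- rowSums(m)
    m <- sweep(m, 1, ifelse(tot > 0, tot, 1), "/")
  }
  m
}

#' Restrict a community matrix to a species subset
#'
#' Drops abundance columns outside `species`. Sites left with zero
#' individuals are flagged in the `empty_sites` attribute and a warning is
#' issued; downstream index computations exclude them.
#'
#' @param community an `fda_community` tibble.
#' @param species character vector of species ids to keep (must be a subset
#'   of the community's species).
#' @return The restricted `fda_community`, with attribute `empty_sites`.
#' @export
restrict_community <- function(community, species) {
  if (!length(species)) rlang::abort("Empty species subset.")
  all_sp <- community_species(community)
  unknown <- setdiff(species, all_sp)
  if (length(unknown)) {
    rlang::abort(sprintf(
      "Subset species not in community: %s.", toString(utils::head(unknown, 5))
    ))
  }
  keep <- intersect(all_sp, species)  # preserve column order
  out <- community[c("site_id", "landscape", "habitat", "coord_x", "coord_y", keep)]
  empty <- out$site_id[rowSums(as.matrix(out[keep])) == 0]
  if (length(empty)) {
    rlang::warn(sprintf(
      "%d site(s) empty after restriction: %s.",
      length(empty), toString(utils::head(empty, 5))
    ))
  }
  attr(out, "empty_sites") <- empty
  class(out) <- unique(c("fda_community", class(out)))
  out
}
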