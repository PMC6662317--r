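#' Functional diversity (FD): dendrogram branch-length sum
#'
#' FD of a community is the total branch length of the UPGMA dendrogram
#' clustering the community's species by functional dissimilarity, excluding
#' the segment above the root. The dendrogram is rebuilt on the community's
#' subset of the pool distance matrix (per-community clustering). FD is
#' presence-based: abundances play no role. A single-species community has
#' FD = 0.
#'
#' @param d pool dissimilarity matrix (species dimnames).
#' @param species character vector of the community's species.
#' @return Non-negative FD value, in Gower-distance units.
#' @export
fd_index <- function(d, species) {
  missing_sp <- setdiff(species, rownames(d))
  if (length(missing_sp)) {
    rlang::abort(sprintf(
      "Species absent from dissimilarity matrix: %s.",
      toString(utils::head(missing_sp, 5))
    ))
  }
  if (length(species) < 2L) return(0)
  branch_length_sum(upgma_dendrogram(as.matrix(d)[species, species]))
}

#' Functional evenness (FEve) on the minimum spanning tree
#'
#' Measures the regularity of species abundances along the minimum spanning
#' tree of the community in trait space (Cailliez-corrected principal
#' coordinates). For each MST edge `l` joining species `i`, `j`:
#' `EW_l = dist(i, j) / (p_i + p_j)`, `PEW_l = EW_l / sum(EW)`, and
#' \deqn{FEve = \frac{\sum_l \min(PEW_l, 1/(S-1)) - 1/(S-1)}{1 - 1/(S-1)}.}
#' FEve is 1 for perfectly even spacing and abundance, and is undefined for
#' fewer than 3 species (returned as `NA` with a message, never as 0).
#'
#' @param coords pool trait-space coordinates (species x axes, rownames).
#' @param p named relative-abundance vector over the community's species
#'   (sums to 1).
#' @return FEve in (0, 1\], or `NA_real_` when S < 3.
#' @export
feve_index <- function(coords, p) {
  s <- length(p)
  if (s < 3L) {
    rlang::inform(sprintf("FEve undefined for S = %d (< 3); returning NA.", s))
    return(NA_real_)
  }
  stopifnot(!is.null(names(p)))
  dsub <- as.matrix(stats::dist(as.matrix(coords)[names(p), , drop = FALSE]))
  feve_from_dist(dsub, unname(p))
}

#' Rao quadratic entropy
#'
#' Expected functional dissimilarity between two individuals drawn at
#' random from the community:
#' \eqn{Q = \sum_i \sum_j d_{ij} p_i p_j} (both orders counted,
#' \eqn{d_{ii} = 0}).
#'
#' @param d pool dissimilarity matrix (species dimnames).
#' @param p named relative-abundance vector (sums to 1).
#' @return Q in \[0, max d).
#' @export
rao_index <- function(d, p) {
  stopifnot(!is.null(names(p)))
  dm <- as.matrix(d)[names(p), names(p), drop = FALSE]
  quad_form(dm, p)
}

#' Jost correction: equivalent numbers
#'
#' Transforms a concave index value `x` in \[0, 1) to the "equivalent
#' community" scale `1 / (1 - x)`: the number of equally abundant, maximally
#' distinct species giving the same index value.
#'
#' @param x index value(s) in \[0, 1).
#' @return `1 / (1 - x)`.
#' @export
#' @examples
#' jost_correct(0.5)  # 2
jost_correct <- function(x) {
  bad <- is.finite(x) & (x < 0 | x >= 1)
  if (any(bad)) {
    rlang::abort(sprintf(
      "Jost correction needs values in [0, 1); got %.4g.", x[bad][1]
    ))
  }
  1 / (1 - x)
}

#' Jost-corrected Simpson index (inverse Simpson)
#'
#' The taxonomic counterpart of Jost-corrected Rao: the Simpson
#' concentration complement run through the Jost correction, which reduces
#' to \eqn{D_{eq} = 1 / \sum_i p_i^2}. Equals S when all S species are
#' equally abundant.
#'
#' @param p relative-abundance vector (sums to 1).
#' @return `D_eq` in \[1, S\].
#' @export
simpson_equivalent <- function(p) {
  1 / sum(p^2)
}

#' Per-site diversity profile across ecological subgroups
#'
#' Computes, for every site and requested subgroup, species richness S,
#' FD (dendrogram branch-length sum), FEve (NA when the restricted
#' community has S < 3), Rao's Q, its Jost-corrected equivalent `Q_eq`, and
#' the Jost-corrected Simpson `D_eq`. Abundance-weighted indices use
#' relative abundances renormalized within the subgroup-restricted
#' community. The pool dissimilarity matrix and trait space are computed
#' once on the full trait table (pool-level ranging) and reused.
#'
#' @param community an `fda_community` tibble.
#' @param traits the companion `fda_traits` table.
#' @param schema the trait schema.
#' @param subgroups character vector of subgroup labels.
#' @param dissim optional precomputed pool dissimilarity matrix.
#' @param space optional precomputed `fda_trait_space`.
#' @return A tibble with one row per site x subgroup: `site_id`,
#'   `landscape`, `habitat`, `subgroup`, `S`, `FD`, `FEve`, `Q`, `Q_eq`,
#'   `D_eq`. Sites empty under a subgroup are omitted (with a message).
#' @export
#' @examples
#' sim <- simulate_landscapes(scenario_config(n_species_pool = 40, seed = 1))
#' head(community_indices(sim$communities, sim$traits, subgroups = "ALL"))
community_indices <- function(community, traits,
                              schema = default_trait_schema(),
                              subgroups = c("ALL", "SPE", "GEN", "FGr", "INV"),
                              dissim = NULL, space = NULL) {
  community <- validate_community(community, traits)
  if (is.null(dissim)) dissim <- gower_dissimilarity(traits, schema)
  if (is.null(space)) space <- pcoa_cailliez(dissim)
  ab <- abundance_matrix(community)
  purrr::map_dfr(subgroups, function(g) {
    members <- intersect(colnames(ab), subgroup_species(traits, g, schema))
    rows <- purrr::map_dfr(seq_len(nrow(ab)), function(i) {
      x <- ab[i, members]
      x <- x[x > 0]
      if (!length(x)) return(NULL)
      profile_row(community[i, ], g, x / sum(x), dissim, space)
    })
    n_drop <- nrow(ab) - nrow(rows)
    if (n_drop > 0) {
      rlang::inform(sprintf(
        "Subgroup %s: %d site(s) empty after restriction, omitted.", g, n_drop
      ))
    }
    rows
  })
}

profile_row <- function(site, subgroup, p, dissim, space) {
  s <- length(p)
  q <- rao_index(dissim, p)
  tibble::tibble(
    site_id = site$site_id,
    landscape = site$landscape,
    habitat = site$habitat,
    subgroup = subgroup,
    S = s,
    FD = fd_index(dissim, names(p)),
    FEve = if (s >= 3) feve_index(space$coordinates, p) else NA_real_,
    Q = q,
    Q_eq = jost_correct(q),
    D_eq = simpson_equivalent(p)
  )
}
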