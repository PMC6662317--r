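#' Shuffle species labels over trait rows
#'
#' The trait-shuffle null model: species names are randomly re-assigned to
#' the (unchanged) rows of the trait table. Trait covariance, the set of
#' phenotypes, species occupancy rates, community richness, abundance
#' distributions and beta diversity are all preserved — only the mapping
#' from a species name to a phenotype changes.
#'
#' @param traits an `fda_traits` table (the regional pool).
#' @param seed optional integer seed.
#' @return The trait table with `species_id` permuted uniformly at random.
#' @export
shuffle_trait_labels <- function(traits, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- traits
  out$species_id <- sample(traits$species_id)
  out
}

#' Standardized effect sizes of functional indices under a trait-shuffle null
#'
#' For every site, index and ecological subgroup, compares the observed
#' index with its distribution over `n_null` trait-label shuffles of the
#' landscape's regional species pool (each landscape is its own pool):
#' \deqn{SES = (\mathrm{observed} - \mathrm{mean}_{null}) / \mathrm{sd}_{null}.}
#' SES < 0 indicates functional clustering (niche filtering), SES > 0
#' overdispersion (limiting similarity), SES near 0 random assembly.
#'
#' Null replicates rebuild the per-community dendrogram / MST / quadratic
#' form from the permuted trait assignment; the site's richness, abundance
#' vector and occupancy are untouched. Subgroup membership travels with the
#' trait rows, so by default it is re-derived inside every replicate (a
#' shuffled "species" is a frugivore if the trait row it now points to eats
#' fruit). Set `shuffle_within_subgroup = TRUE` to instead permute labels
#' only among the subgroup's own members (sensitivity analysis).
#'
#' FEve null replicates use the Cailliez-corrected distance matrix
#' directly: pairwise Euclidean distances in the full corrected
#' principal-coordinate space equal the corrected dissimilarities, so the
#' MST never has to touch the coordinates.
#'
#' One RNG stream per (landscape, index, subgroup) is derived from `seed`,
#' so adding a subgroup or index never changes the draws of another.
#'
#' @inheritParams community_indices
#' @param indices which indices to standardize (`"FD"`, `"FEve"`, `"Rao"`).
#' @param n_null number of null replicates (999 by default).
#' @param seed master seed.
#' @param shuffle_within_subgroup see above.
#' @return A tibble with one row per site x subgroup x index: `site_id`,
#'   `landscape`, `habitat`, `subgroup`, `index`, `observed`, `null_mean`,
#'   `null_sd`, `ses`, `n_null` (valid replicates), `seed` (stream seed).
#' @export
#' @examples
#' sim <- simulate_landscapes(scenario_config(n_species_pool = 30, seed = 1))
#' ses_indices(sim$communities, sim$traits, indices = "Rao",
#'             n_null = 49, seed = 1)
ses_indices <- function(community, traits,
                        schema = default_trait_schema(),
                        indices = c("FD", "FEve", "Rao"),
                        subgroups = "ALL",
                        n_null = 999, seed = 1,
                        dissim = NULL, space = NULL,
                        shuffle_within_subgroup = FALSE) {
  indices <- match.arg(indices, c("FD", "FEve", "Rao"), several.ok = TRUE)
  community <- validate_community(community, traits)
  if (is.null(dissim)) dissim <- gower_dissimilarity(traits, schema)
  d <- unclass(as.matrix(dissim))
  # Euclidean distances in the full Cailliez-corrected trait space: the
  # corrected dissimilarities themselves.
  dc <- NULL
  if ("FEve" %in% indices) {
    cc <- if (!is.null(space)) space$correction else cailliez_constant(d)
    dc <- d + cc
    diag(dc) <- 0
  }
  ab <- abundance_matrix(community)
  stopifnot(all(colnames(ab) %in% rownames(d)))

  membership <- lapply(stats::setNames(nm = subgroups), function(g) {
    rownames(d) %in% subgroup_species(traits, g, schema)
  })

  out <- list()
  for (land in unique(community$landscape)) {
    in_land <- community$landscape == land
    ab_l <- ab[in_land, , drop = FALSE]
    pool <- colnames(ab_l)[colSums(ab_l) > 0]
    pool_rows <- match(pool, rownames(d))
    # per-site positive abundances and their global trait-row positions
    site_ab <- lapply(seq_len(nrow(ab_l)), function(i) {
      v <- ab_l[i, pool]
      keep <- v > 0
      list(p = unname(v[keep]), pos = pool_rows[keep])
    })
    meta <- community[in_land, c("site_id", "landscape", "habitat")]
    n_all <- nrow(d)
    for (idx in indices) {
      dmat <- if (idx == "FEve") dc else d
      for (g in subgroups) {
        s0 <- stream_seed(seed, land, idx, g)
        set.seed(s0)
        memb <- membership[[g]]
        id_map <- seq_len(n_all)
        obs <- vapply(site_ab, eval_site_index, numeric(1),
                      idx_map = id_map, index = idx, member = memb,
                      subgroup = g, d = dmat)
        nulls <- matrix(NA_real_, nrow = length(site_ab), ncol = n_null)
        for (r in seq_len(n_null)) {
          idx_map <- id_map
          idx_map[pool_rows] <- null_rows(pool_rows, memb,
                                          shuffle_within_subgroup && g != "ALL")
          nulls[, r] <- vapply(site_ab, eval_site_index, numeric(1),
                               idx_map = idx_map, index = idx, member = memb,
                               subgroup = g, d = dmat)
        }
        res <- summarize_ses(obs, nulls)
        out[[length(out) + 1L]] <- dplyr::bind_cols(
          meta,
          tibble::tibble(subgroup = g, index = idx),
          res,
          tibble::tibble(seed = s0)
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  n_degen <- sum(!is.na(res$observed) & is.na(res$ses))
  if (n_degen > 0) {
    rlang::warn(sprintf(
      "%d site/index combination(s) had a degenerate null (sd = 0 or too few valid replicates); SES set to NA.",
      n_degen
    ))
  }
  res
}

# Permuted trait-row assignment for the pool (global row positions).
null_rows <- function(pool_rows, member, within_subgroup) {
  if (!within_subgroup) return(sample(pool_rows))
  new <- pool_rows
  inside <- pool_rows[member[pool_rows]]
  if (length(inside) > 1L) new[match(inside, pool_rows)] <- sample(inside)
  new
}

# Index of one site under a trait-row assignment. `site_ab` holds positive
# abundances `p` and their global row positions `pos`; `idx_map[pos]` gives
# the trait row each species points to under the (possibly permuted)
# assignment. Returns NA when the index is undefined for the (possibly
# subgroup-restricted) community. For FEve, `d` must be the
# Cailliez-corrected distance matrix.
eval_site_index <- function(site_ab, idx_map, index, member, subgroup, d) {
  rows <- idx_map[site_ab$pos]
  p <- site_ab$p
  if (subgroup != "ALL") {
    keep <- member[rows]
    rows <- rows[keep]
    p <- p[keep]
  }
  s <- length(rows)
  if (s == 0L) return(NA_real_)
  ord <- order(rows)  # deterministic input order for clustering/MST
  rows <- rows[ord]
  p <- p[ord]
  p <- p / sum(p)
  switch(index,
    FD = {
      if (s < 2L) return(0)
      branch_length_sum(stats::hclust(
        stats::as.dist(d[rows, rows]), method = "average"
      ))
    },
    Rao = quad_form(d[rows, rows, drop = FALSE], p),
    FEve = {
      if (s < 3L) return(NA_real_)
      feve_from_dist(d[rows, rows], p)
    }
  )
}

# FEve from a (Euclidean) distance matrix and relative abundances in
# matching order.
feve_from_dist <- function(dsub, p) {
  s <- length(p)
  st <- vegan::spantree(dsub)
  from <- 2:s
  to <- st$kid
  ew <- st$dist / (p[from] + p[to])
  total <- sum(ew)
  pew <- if (total > 0) ew / total else rep(1 / (s - 1), s - 1)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

summarize_ses <- function(obs, nulls) {
  null_mean <- apply(nulls, 1, function(v) mean(v[is.finite(v)]))
  null_sd <- apply(nulls, 1, function(v) stats::sd(v[is.finite(v)]))
  n_valid <- apply(nulls, 1, function(v) sum(is.finite(v)))
  ses <- ifelse(
    is.finite(obs) & n_valid >= 2 & is.finite(null_sd) & null_sd > 0,
    (obs - null_mean) / null_sd, NA_real_
  )
  tibble::tibble(
    observed = obs, null_mean = null_mean, null_sd = null_sd,
    ses = ses, n_null = n_valid
  )
}
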