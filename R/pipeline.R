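#' Pipeline configuration
#'
#' Seeds, replicate counts and thresholds for [run_pipeline()]. Defaults
#' follow the analysis design: 999 trait-shuffle null replicates, 100,000
#' permutation-test iterations (the test switches to exhaustive enumeration
#' automatically whenever that is cheaper), conclusive threshold p < 0.01
#' with 0.05 / 0.10 annotation tiers.
#'
#' @param subgroups ecological subgroups to analyze.
#' @param indices functional indices to standardize.
#' @param n_null null replicates per site x index x subgroup.
#' @param n_iter permutation-test iterations.
#' @param seed master seed; every RNG stream is derived from it.
#' @return A list of class `fda_config`.
#' @export
pipeline_config <- function(subgroups = c("ALL", "SPE", "GEN", "FGr", "INV"),
                            indices = c("FD", "FEve", "Rao"),
                            n_null = 999, n_iter = 1e5, seed = 1) {
  structure(
    list(subgroups = subgroups, indices = indices,
         n_null = n_null, n_iter = n_iter, seed = seed),
    class = "fda_config"
  )
}

#' Long per-site metric table for contrasts
#'
#' Combines the taxonomic columns of a [community_indices()] table
#' (richness `S`, Jost-corrected Simpson `D_eq`) with the SES columns of a
#' [ses_indices()] table into one tidy table with columns `site_id`,
#' `landscape`, `habitat`, `subgroup`, `metric`, `value`, where `metric` is
#' one of `richness`, `D_eq`, `sesFD`, `sesFEve`, `sesRao`.
#'
#' @param indices_tbl output of [community_indices()].
#' @param ses_tbl output of [ses_indices()].
#' @return A tidy tibble of per-site metric values.
#' @export
metric_table <- function(indices_tbl, ses_tbl) {
  tax <- indices_tbl |>
    dplyr::select("site_id", "landscape", "habitat", "subgroup",
                  richness = "S", "D_eq") |>
    tidyr::pivot_longer(c("richness", "D_eq"),
                        names_to = "metric", values_to = "value")
  fun <- ses_tbl |>
    dplyr::mutate(metric = paste0("ses", .data$index)) |>
    dplyr::select("site_id", "landscape", "habitat", "subgroup",
                  "metric", value = "ses")
  dplyr::bind_rows(tax, fun)
}

#' Run the full trait-based assembly analysis
#'
#' Orchestrates every stage on a trait table plus community matrix:
#' per-site indices for each subgroup, trait-shuffle SES for FD/FEve/Rao,
#' forest-vs-agroforestry permutation contrasts with per-habitat assembly
#' t tests, Spearman correlations between taxonomic (S, D_eq) and
#' functional (SES) metrics, and Moran's I spatial checks per metric.
#' Every random stage draws from a stream derived from `config$seed`, so a
#' rerun with the same inputs and config is bit-identical.
#'
#' @param traits an `fda_traits` table.
#' @param community an `fda_community` table.
#' @param config an [pipeline_config()].
#' @param schema the trait schema.
#' @return A list of class `fda_report` with elements `indices`, `ses`,
#'   `metrics`, `contrasts`, `decoupling`, `spatial`, `config`.
#' @export
run_pipeline <- function(traits, community, config = pipeline_config(),
                         schema = default_trait_schema()) {
  traits <- validate_trait_table(traits, schema)
  community <- validate_community(community, traits)
  dissim <- gower_dissimilarity(traits, schema)
  space <- pcoa_cailliez(dissim)

  indices_tbl <- community_indices(community, traits, schema,
                                   subgroups = config$subgroups,
                                   dissim = dissim, space = space)
  ses_tbl <- ses_indices(community, traits, schema,
                         indices = config$indices,
                         subgroups = config$subgroups,
                         n_null = config$n_null, seed = config$seed,
                         dissim = dissim, space = space)
  metrics <- metric_table(indices_tbl, ses_tbl)
  contrasts <- habitat_contrasts(metrics, n_iter = config$n_iter,
                                 seed = config$seed)
  decoupling <- decoupling_correlations(metrics)
  spatial <- spatial_checks(metrics, community)

  structure(
    list(indices = indices_tbl, ses = ses_tbl, metrics = metrics,
         contrasts = contrasts, decoupling = decoupling, spatial = spatial,
         config = config),
    class = "fda_report"
  )
}

# Spearman correlations between taxonomic and functional (SES) metrics,
# across sites within each landscape x subgroup.
decoupling_correlations <- function(metrics) {
  wide <- tidyr::pivot_wider(metrics, names_from = "metric",
                             values_from = "value")
  tax <- intersect(c("richness", "D_eq"), names(wide))
  fun <- intersect(c("sesFD", "sesFEve", "sesRao"), names(wide))
  combos <- dplyr::distinct(wide, .data$landscape, .data$subgroup)
  purrr::pmap_dfr(combos, function(landscape, subgroup) {
    sub <- wide[wide$landscape == landscape & wide$subgroup == subgroup, ]
    purrr::map_dfr(tax, function(tm) {
      purrr::map_dfr(fun, function(fm) {
        ok <- sum(is.finite(sub[[tm]]) & is.finite(sub[[fm]])) >= 3 &&
          stats::sd(sub[[tm]], na.rm = TRUE) > 0 &&
          stats::sd(sub[[fm]], na.rm = TRUE) > 0
        res <- if (ok) spearman_cor(sub[[tm]], sub[[fm]])
               else tibble::tibble(rho = NA_real_, p_value = NA_real_,
                                   n = sum(is.finite(sub[[tm]]) &
                                             is.finite(sub[[fm]])))
        dplyr::bind_cols(
          tibble::tibble(landscape = landscape, subgroup = subgroup,
                         taxonomic = tm, functional = fm),
          res
        )
      })
    })
  })
}

# Moran's I per landscape x subgroup x metric over site coordinates.
spatial_checks <- function(metrics, community) {
  coords <- community[c("site_id", "coord_x", "coord_y")]
  dat <- dplyr::inner_join(metrics, coords, by = "site_id")
  combos <- dplyr::distinct(dat, .data$landscape, .data$subgroup, .data$metric)
  purrr::pmap_dfr(combos, function(landscape, subgroup, metric) {
    sub <- dat[dat$landscape == landscape & dat$subgroup == subgroup &
                 dat$metric == metric, ]
    ok <- sum(is.finite(sub$value)) >= 3 &&
      stats::sd(sub$value[is.finite(sub$value)]) > 0
    res <- if (ok) {
      morans_i(sub$value, sub$coord_x, sub$coord_y)
    } else {
      tibble::tibble(observed = NA_real_, expected = NA_real_, sd = NA_real_,
                     p_value = NA_real_, n = sum(is.finite(sub$value)))
    }
    dplyr::bind_cols(
      tibble::tibble(landscape = landscape, subgroup = subgroup,
                     metric = metric),
      res
    )
  })
}

#' Write an analysis report to tidy CSV files
#'
#' Writes `indices.csv`, `ses.csv`, `metrics.csv`, `contrasts.csv`,
#' `decoupling.csv`, `spatial.csv` and `manifest.txt` (config and seed)
#' into `dir`. Output is deterministic: the same report writes the same
#' bytes.
#'
#' @param report an `fda_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("indices", "ses", "metrics", "contrasts", "decoupling", "spatial")) {
    utils::write.csv(as.data.frame(report[[nm]]),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  cfg <- report$config
  lines <- c(
    paste0("subgroups=", paste(cfg$subgroups, collapse = ",")),
    paste0("indices=", paste(cfg$indices, collapse = ",")),
    paste0("n_null=", cfg$n_null),
    paste0("n_iter=", format(cfg$n_iter, scientific = FALSE)),
    paste0("seed=", cfg$seed)
  )
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.fda_report <- function(x, ...) {
  cat("<fda_report>\n")
  cat(sprintf("  sites: %d   subgroups: %s\n",
              length(unique(x$ses$site_id)),
              paste(unique(x$ses$subgroup), collapse = ", ")))
  cat(sprintf("  indices: %s   n_null: %d   seed: %d\n",
              paste(x$config$indices, collapse = ", "),
              x$config$n_null, x$config$seed))
  sig <- sum(x$contrasts$significant, na.rm = TRUE)
  cat(sprintf("  habitat contrasts: %d (%d conclusive at p < 0.01)\n",
              nrow(x$contrasts), sig))
  invisible(x)
}

#' Tidy a pipeline report
#'
#' Returns the habitat-contrast table (one row per landscape x subgroup x
#' metric) in broom style.
#'
#' @param x an `fda_report`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy fda_report
#' @export
tidy.fda_report <- function(x, ...) {
  x$contrasts
}

#' One-row summary of a pipeline report
#'
#' @param x an `fda_report`.
#' @param ... unused.
#' @return A one-row tibble: problem sizes, counts of conclusive habitat
#'   contrasts and of habitat x subgroup x index cells with conclusive
#'   clustering (negative mean SES) or overdispersion (positive mean SES).
#' @method glance fda_report
#' @export
glance.fda_report <- function(x, ...) {
  asm <- x$contrasts |>
    dplyr::filter(startsWith(.data$metric, "ses")) |>
    tidyr::pivot_longer(c("p_forest", "p_agroforestry"),
                        names_to = "habitat", names_prefix = "p_",
                        values_to = "p_assembly") |>
    dplyr::mutate(mean_ses = dplyr::if_else(.data$habitat == "forest",
                                            .data$mean_forest,
                                            .data$mean_agroforestry))
  tibble::tibble(
    n_sites = length(unique(x$ses$site_id)),
    n_landscapes = length(unique(x$ses$landscape)),
    n_contrasts = nrow(x$contrasts),
    n_contrasts_significant = sum(x$contrasts$significant, na.rm = TRUE),
    n_clustered = sum(asm$p_assembly < 0.01 & asm$mean_ses < 0, na.rm = TRUE),
    n_overdispersed = sum(asm$p_assembly < 0.01 & asm$mean_ses > 0, na.rm = TRUE)
  )
}
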