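#' Permutation t test for a difference in group means
#'
#' Two-sided test of the difference in means between two groups by
#' permutation of group labels. When the number of distinct arrangements
#' `choose(n1 + n2, n1)` does not exceed `n_iter` the test is exhaustive:
#' `p` is the exact proportion of arrangements (including the observed one)
#' whose absolute mean difference is at least the observed. Otherwise
#' `n_iter` Monte-Carlo permutations are drawn and the add-one rule
#' `p = (1 + #extreme) / (n_iter + 1)` keeps `p` strictly positive.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param n_iter maximum permutations (default 100,000).
#' @param seed optional seed for the Monte-Carlo draw.
#' @return A one-row tibble: `mean_diff` (`mean(x) - mean(y)`), `p_value`,
#'   `method` (`"exhaustive"` or `"monte-carlo"`), `n_perm`, `n_x`, `n_y`.
#' @export
#' @examples
#' permutation_t_test(c(1, 2, 3), c(10, 11, 12))  # exhaustive, p = 0.1
permutation_t_test <- function(x, y, n_iter = 1e5, seed = NULL) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    rlang::abort("Need at least 2 finite values per group.")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  z <- c(x, y)
  obs <- mean(x) - mean(y)
  tol <- 1e-12 * max(1, abs(obs))
  # |mean diff| is monotone in |sum of group-1 values|' deviation, but we
  # just recompute the statistic per arrangement for clarity.
  stat <- function(idx) mean(z[idx]) - mean(z[-idx])
  n_arr <- choose(n, n1)
  if (n_arr <= n_iter) {
    idx_all <- utils::combn(n, n1)
    stats_all <- apply(idx_all, 2, stat)
    p <- mean(abs(stats_all) >= abs(obs) - tol)
    method <- "exhaustive"
    n_perm <- n_arr
  } else {
    if (!is.null(seed)) set.seed(seed)
    extreme <- 0L
    for (r in seq_len(n_iter)) {
      if (abs(stat(sample.int(n, n1))) >= abs(obs) - tol) extreme <- extreme + 1L
    }
    p <- (1 + extreme) / (n_iter + 1)
    method <- "monte-carlo"
    n_perm <- n_iter
  }
  tibble::tibble(mean_diff = obs, p_value = p, method = method,
                 n_perm = n_perm, n_x = n1, n_y = n2)
}

#' One-sample t test against mu = 0
#'
#' Used on per-site SES values to ask whether an assembly process differs
#' from random expectation. Returns NA (with a warning) for degenerate
#' input (fewer than 2 finite values or zero variance).
#'
#' @param x numeric vector (SES values).
#' @param mu null mean (default 0).
#' @return A one-row tibble: `estimate` (mean), `statistic` (t), `df`,
#'   `p_value`, `n`.
#' @export
one_sample_t <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || stats::sd(x) == 0) {
    rlang::warn("One-sample t test undefined (n < 2 or sd = 0); returning NA.")
    return(tibble::tibble(estimate = if (n) mean(x) else NA_real_,
                          statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, n = n))
  }
  tt <- stats::t.test(x, mu = mu)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value, n = n)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; two-sided p from the
#' large-sample approximation (ties make the exact distribution
#' unavailable). Used to test independence between taxonomic and functional
#' metrics.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) rlang::abort("Need at least 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("Constant vector; Spearman correlation undefined.")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Moran's I spatial autocorrelation
#'
#' Moran's I with inverse-distance spatial weights (`w_ij = 1/dist(i,j)`,
#' zero diagonal), row-normalized; expectation `E[I] = -1/(n-1)`; two-sided
#' p from the normal approximation.
#'
#' @param values numeric vector, one value per site.
#' @param coord_x,coord_y planar site coordinates.
#' @return A one-row tibble: `observed`, `expected`, `sd`, `p_value`, `n`.
#' @export
morans_i <- function(values, coord_x, coord_y) {
  keep <- is.finite(values)
  values <- values[keep]; coord_x <- coord_x[keep]; coord_y <- coord_y[keep]
  n <- length(values)
  if (n < 3L) rlang::abort("Need at least 3 sites with finite values.")
  dm <- as.matrix(stats::dist(cbind(coord_x, coord_y)))
  off <- dm[upper.tri(dm)]
  if (any(off == 0)) {
    rlang::abort(
      "Coincident site coordinates give infinite weights; jitter or exclude duplicated sites."
    )
  }
  w <- 1 / dm
  diag(w) <- 0
  w <- w / rowSums(w)
  mi <- ape::Moran.I(values, w, alternative = "two.sided")
  tibble::tibble(observed = mi$observed, expected = mi$expected,
                 sd = mi$sd, p_value = mi$p.value, n = n)
}

significance_flags <- function(p) {
  tibble::tibble(
    significant = !is.na(p) & p < 0.01,
    suggestive_05 = !is.na(p) & p < 0.05,
    suggestive_10 = !is.na(p) & p < 0.10
  )
}

#' Habitat contrasts and assembly tests per landscape and subgroup
#'
#' For each landscape, subgroup and metric (species richness `S`, the
#' Jost-corrected Simpson `D_eq`, and the SES of FD, FEve and Rao):
#' forest vs agroforestry means/sds, a two-sided permutation t test on the
#' habitat difference, and — for SES metrics — per-habitat one-sample t
#' tests against 0 (the assembly test). Comparisons are flagged at the
#' conclusive threshold p < 0.01 and annotated at 0.05 / 0.10; `comparison`
#' numbers the SES contrasts within each landscape so the
#' 15-comparisons-per-landscape accounting (5 groups x 3 indices) is
#' auditable.
#'
#' @param metrics tibble of per-site metric values, as produced by
#'   [metric_table()]: columns `site_id`, `landscape`, `habitat`,
#'   `subgroup`, `metric`, `value`.
#' @param n_iter permutation iterations for the habitat test.
#' @param seed master seed (per-contrast streams are derived from it).
#' @return A tibble with one row per landscape x subgroup x metric, nested
#'   columns flattened: habitat means/sds, permutation p, per-habitat
#'   one-sample t and p (SES metrics only), significance flags.
#' @export
habitat_contrasts <- function(metrics, n_iter = 1e5, seed = 1) {
  stopifnot(all(c("landscape", "habitat", "subgroup", "metric", "value")
                %in% names(metrics)))
  combos <- dplyr::distinct(metrics, .data$landscape, .data$subgroup, .data$metric)
  purrr::pmap_dfr(combos, function(landscape, subgroup, metric) {
    sub <- metrics[metrics$landscape == landscape &
                     metrics$subgroup == subgroup &
                     metrics$metric == metric, ]
    xf <- sub$value[sub$habitat == "forest"]
    xa <- sub$value[sub$habitat == "agroforestry"]
    xf <- xf[is.finite(xf)]; xa <- xa[is.finite(xa)]
    perm <- if (length(xf) >= 2 && length(xa) >= 2) {
      permutation_t_test(xf, xa, n_iter = n_iter,
                         seed = stream_seed(seed, landscape, subgroup, metric))
    } else {
      tibble::tibble(mean_diff = NA_real_, p_value = NA_real_,
                     method = NA_character_, n_perm = NA_real_,
                     n_x = length(xf), n_y = length(xa))
    }
    is_ses <- startsWith(metric, "ses")
    assembly <- if (is_ses) {
      tf <- one_sample_t(xf); ta <- one_sample_t(xa)
      tibble::tibble(
        t_forest = tf$statistic, p_forest = tf$p_value,
        t_agroforestry = ta$statistic, p_agroforestry = ta$p_value
      )
    } else {
      tibble::tibble(t_forest = NA_real_, p_forest = NA_real_,
                     t_agroforestry = NA_real_, p_agroforestry = NA_real_)
    }
    dplyr::bind_cols(
      tibble::tibble(
        landscape = landscape, subgroup = subgroup, metric = metric,
        mean_forest = mean(xf), sd_forest = stats::sd(xf), n_forest = length(xf),
        mean_agroforestry = mean(xa), sd_agroforestry = stats::sd(xa),
        n_agroforestry = length(xa)
      ),
      perm[c("mean_diff", "p_value", "method", "n_perm")],
      significance_flags(perm$p_value),
      assembly
    )
  }) |>
    dplyr::group_by(.data$landscape) |>
    dplyr::mutate(
      comparison = dplyr::if_else(
        startsWith(.data$metric, "ses"),
        cumsum(startsWith(.data$metric, "ses")), NA_integer_
      )
    ) |>
    dplyr::ungroup()
}
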