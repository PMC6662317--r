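#' Scenario configuration for the community generator
#'
#' Defines a regional species pool and a two-landscape survey layout with
#' known assembly rules, emulating a tropical bird metacommunity sampled in
#' mature-forest fragments and cacao agroforestry (cabruca). Defaults:
#' a 150-species pool with 25 binary foraging traits plus lognormal body
#' mass clipped to 2-2172 g; landscape A with 12 forest + 6 agroforestry
#' sites and landscape B with 4 forest + 4 agroforestry sites; per-site
#' richness drawn around 30 species; lognormal abundances independent of
#' traits. Assembly per habitat is `neutral` (uniform draw from the pool),
#' `filtering` (inclusion probability falls off with Gower distance from a
#' habitat optimum phenotype as `exp(-g^2 / (2 sigma_f^2))`), or
#' `limiting_similarity` (greedy max-min Gower spacing).
#'
#' @param n_species_pool pool size.
#' @param n_binary number of binary traits (25 under the default schema).
#' @param mass_range body-mass clip range in grams.
#' @param mass_meanlog,mass_sdlog lognormal body-mass parameters.
#' @param prevalence_shape Beta(a, b) shape for per-trait prevalence draws.
#' @param dependency_probs probabilities of high/medium/low forest
#'   dependency.
#' @param sites tibble with columns `landscape`, `habitat`, `n` giving the
#'   number of sites per landscape x habitat.
#' @param richness_mean,richness_sd,richness_min per-site richness model
#'   (normal draw, rounded, clipped below at `richness_min`).
#' @param abundance_meanlog,abundance_sdlog lognormal abundance parameters
#'   (counts, rounded up to at least 1).
#' @param assembly named list habitat -> assembly rule.
#' @param sigma_f filtering strength, in Gower-distance units.
#' @param min_spacing minimum inter-site distance (same planar units as the
#'   coordinates; landscapes occupy disjoint 10 km boxes).
#' @param seed master seed.
#' @return A list of class `fda_scenario`.
#' @export
scenario_config <- function(n_species_pool = 150,
                            n_binary = 25,
                            mass_range = c(2, 2172),
                            mass_meanlog = log(35), mass_sdlog = 1.2,
                            prevalence_shape = c(2, 2),
                            dependency_probs = c(high = 0.3, medium = 0.4, low = 0.3),
                            sites = default_sites(),
                            richness_mean = 30, richness_sd = 5, richness_min = 5,
                            abundance_meanlog = log(5), abundance_sdlog = 1,
                            assembly = list(forest = "neutral",
                                            agroforestry = "neutral"),
                            sigma_f = 0.1,
                            min_spacing = 200,
                            seed = 1) {
  stopifnot(n_species_pool >= 2, n_binary > 0, sigma_f > 0,
            all(sites$n > 0), richness_min >= 1)
  assembly <- lapply(assembly, match.arg,
                     choices = c("neutral", "filtering", "limiting_similarity"))
  structure(
    list(
      n_species_pool = n_species_pool, n_binary = n_binary,
      mass_range = mass_range, mass_meanlog = mass_meanlog,
      mass_sdlog = mass_sdlog, prevalence_shape = prevalence_shape,
      dependency_probs = dependency_probs, sites = sites,
      richness_mean = richness_mean, richness_sd = richness_sd,
      richness_min = richness_min,
      abundance_meanlog = abundance_meanlog,
      abundance_sdlog = abundance_sdlog,
      assembly = assembly, sigma_f = sigma_f,
      min_spacing = min_spacing, seed = seed
    ),
    class = "fda_scenario"
  )
}

default_sites <- function() {
  tibble::tibble(
    landscape = c("A", "A", "B", "B"),
    habitat = c("forest", "agroforestry", "forest", "agroforestry"),
    n = c(12L, 6L, 4L, 4L)
  )
}

#' Generate a regional species pool
#'
#' Draws `n_species_pool` species: per-trait prevalence from
#' Beta(`prevalence_shape`), independent Bernoulli binary traits, lognormal
#' body mass clipped to `mass_range`, and forest dependency sampled from
#' `dependency_probs`. Species violating the structural constraints (at
#' least one food type and one foraging stratum) are redrawn by rejection,
#' so the pool always passes [validate_trait_table()].
#'
#' @param config an [scenario_config()].
#' @param schema the trait schema (must have `n_binary` binary traits).
#' @return A validated `fda_traits` tibble, with attribute `prevalence`
#'   recording the drawn per-trait prevalences.
#' @export
generate_pool <- function(config, schema = default_trait_schema()) {
  set.seed(stream_seed(config$seed, "pool"))
  bin <- schema_traits(schema, type = "binary")
  stopifnot(length(bin) == config$n_binary)
  n <- config$n_species_pool
  prev <- stats::rbeta(length(bin), config$prevalence_shape[1],
                       config$prevalence_shape[2])
  food <- schema_traits(schema, category = "food_type")
  strat <- schema_traits(schema, category = "foraging_stratum")
  draw <- function(m) {
    x <- matrix(stats::rbinom(m * length(bin), 1, rep(prev, each = m)),
                nrow = m, dimnames = list(NULL, bin))
    x
  }
  x <- draw(n)
  bad <- which(rowSums(x[, food, drop = FALSE]) == 0 |
                 rowSums(x[, strat, drop = FALSE]) == 0)
  while (length(bad)) {
    x[bad, ] <- draw(length(bad))
    bad <- bad[rowSums(x[bad, food, drop = FALSE]) == 0 |
                 rowSums(x[bad, strat, drop = FALSE]) == 0]
  }
  mass <- pmin(pmax(stats::rlnorm(n, config$mass_meanlog, config$mass_sdlog),
                    config$mass_range[1]), config$mass_range[2])
  dep <- sample(names(config$dependency_probs), n, replace = TRUE,
                prob = config$dependency_probs)
  pool <- dplyr::bind_cols(
    tibble::tibble(
      species_id = sprintf("sp%03d", seq_len(n)),
      forest_dependency = dep,
      body_mass = round(mass, 1)
    ),
    tibble::as_tibble(x)
  )
  pool <- validate_trait_table(
    pool[c("species_id", "forest_dependency", schema$trait)], schema
  )
  attr(pool, "prevalence") <- stats::setNames(prev, bin)
  pool
}

#' Assemble one site's abundance vector under a known process
#'
#' * `neutral`: species drawn uniformly without replacement.
#' * `filtering`: inclusion probability proportional to
#'   `exp(-g_i^2 / (2 sigma_f^2))` where `g_i` is the Gower distance from
#'   species i to the habitat's optimum phenotype.
#' * `limiting_similarity`: greedy max-min — start from a random species,
#'   then repeatedly add the species whose minimum Gower distance to those
#'   already chosen is largest (ties by species order).
#'
#' Abundances are lognormal counts, independent of traits.
#'
#' @param pool an `fda_traits` pool.
#' @param assembly assembly rule (see above).
#' @param richness target species richness (must not exceed the pool).
#' @param config an [scenario_config()] (abundance and sigma_f parameters).
#' @param dissim pool Gower dissimilarity matrix.
#' @param optimum species id of the habitat optimum (filtering only).
#' @return Named abundance vector over all pool species (zeros for absent).
#' @export
assemble_site <- function(pool, assembly, richness, config, dissim,
                          optimum = NULL) {
  sp <- pool$species_id
  if (richness > length(sp)) {
    rlang::abort(sprintf(
      "Target richness %d exceeds pool size %d.", richness, length(sp)
    ))
  }
  d <- as.matrix(dissim)
  chosen <- switch(assembly,
    neutral = sample(sp, richness),
    filtering = {
      stopifnot(!is.null(optimum), optimum %in% sp)
      g <- d[sp, optimum]
      w <- exp(-g^2 / (2 * config$sigma_f^2))
      sample(sp, richness, prob = w)
    },
    limiting_similarity = {
      chosen <- sample(sp, 1)
      while (length(chosen) < richness) {
        cand <- setdiff(sp, chosen)
        mind <- apply(d[cand, chosen, drop = FALSE], 1, min)
        chosen <- c(chosen, cand[which.max(mind)])
      }
      chosen
    },
    rlang::abort(sprintf("Unknown assembly rule '%s'.", assembly))
  )
  counts <- pmax(1, round(stats::rlnorm(richness, config$abundance_meanlog,
                                        config$abundance_sdlog)))
  ab <- stats::setNames(numeric(length(sp)), sp)
  ab[chosen] <- counts
  ab
}

#' Generate a two-landscape synthetic survey
#'
#' Builds the regional pool, draws per-habitat optimum phenotypes (one pool
#' species per habitat), places sites uniformly inside per-landscape 10 km
#' bounding boxes with a minimum spacing (rejection sampling), and
#' assembles every site under its habitat's assembly rule. The result
#' always passes community validation; a manifest attribute records the
#' configuration.
#'
#' @param config an [scenario_config()].
#' @param schema the trait schema.
#' @return A list of class `fda_simulation`: `traits` (`fda_traits`),
#'   `communities` (`fda_community`), `optima` (habitat -> species id),
#'   `config`.
#' @export
#' @examples
#' sim <- simulate_landscapes(scenario_config(n_species_pool = 40, seed = 7))
#' dplyr::count(sim$communities, landscape, habitat)
simulate_landscapes <- function(config = scenario_config(),
                                schema = default_trait_schema()) {
  pool <- generate_pool(config, schema)
  dissim <- gower_dissimilarity(pool, schema)
  set.seed(stream_seed(config$seed, "optima"))
  habitats <- unique(config$sites$habitat)
  optima <- stats::setNames(sample(pool$species_id, length(habitats)), habitats)

  rows <- list()
  for (li in seq_len(nrow(config$sites))) {
    land <- config$sites$landscape[li]
    hab <- config$sites$habitat[li]
    n_sites <- config$sites$n[li]
    set.seed(stream_seed(config$seed, "sites", land, hab))
    for (k in seq_len(n_sites)) {
      rich <- max(config$richness_min,
                  round(stats::rnorm(1, config$richness_mean, config$richness_sd)))
      rich <- min(rich, nrow(pool))
      ab <- assemble_site(pool, config$assembly[[hab]], rich, config, dissim,
                          optimum = optima[[hab]])
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          site_id = sprintf("%s_%s_%02d", land, substr(hab, 1, 3), k),
          landscape = land, habitat = hab
        ),
        tibble::as_tibble(as.list(ab))
      )
    }
  }
  comm <- dplyr::bind_rows(rows)
  coords <- place_sites(comm$landscape, config)
  comm <- dplyr::bind_cols(
    comm[c("site_id", "landscape", "habitat")],
    coords,
    comm[setdiff(names(comm), c("site_id", "landscape", "habitat"))]
  )
  structure(
    list(
      traits = pool,
      communities = validate_community(comm, pool),
      optima = optima,
      config = config
    ),
    class = "fda_simulation"
  )
}

# Uniform coordinates in disjoint per-landscape 10 km boxes with minimum
# spacing, by rejection.
place_sites <- function(landscape, config, box = 10000, max_tries = 10000) {
  lands <- unique(landscape)
  out <- matrix(NA_real_, length(landscape), 2)
  for (j in seq_along(lands)) {
    set.seed(stream_seed(config$seed, "coords", lands[j]))
    idx <- which(landscape == lands[j])
    offset <- (j - 1) * 3 * box
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pts) < length(idx)) {
      cand <- stats::runif(2, 0, box)
      if (nrow(pts) == 0 ||
            min(sqrt(colSums((t(pts) - cand)^2))) >= config$min_spacing) {
        pts <- rbind(pts, cand)
      }
      tries <- tries + 1
      if (tries > max_tries) {
        rlang::abort("Could not place sites with the requested minimum spacing.")
      }
    }
    out[idx, ] <- pts + offset
  }
  tibble::tibble(coord_x = out[, 1], coord_y = out[, 2])
}
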