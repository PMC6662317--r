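test_that("generated pools are valid, seeded, and match drawn prevalences", {
  cfg <- scenario_config(n_species_pool = 200, seed = 17)
  pool <- generate_pool(cfg)
  expect_s3_class(pool, "fda_traits")  # construction passed validation
  expect_equal(nrow(pool), 200)
  expect_true(all(pool$body_mass >= 2 & pool$body_mass <= 2172))

  # same seed reproduces the pool exactly
  expect_equal(as.data.frame(generate_pool(cfg)), as.data.frame(pool))

  # empirical prevalences of unconstrained columns stay within binomial
  # error of the drawn Beta(2,2) prevalences (the structural rejection
  # step only nudges food-type and stratum columns)
  sch <- default_trait_schema()
  free <- sch$trait[sch$type == "binary" &
                      !sch$category %in% c("food_type", "foraging_stratum")]
  drawn <- attr(pool, "prevalence")[free]
  emp <- colMeans(as.matrix(pool[free]))
  expect_true(all(abs(emp - drawn) <=
                    4 * sqrt(drawn * (1 - drawn) / nrow(pool)) + 0.02))
})

test_that("site assembly follows the configured rule", {
  cfg <- scenario_config(n_species_pool = 30, seed = 23, sigma_f = 0.05)
  pool <- generate_pool(cfg)
  d <- gower_dissimilarity(pool)

  set.seed(1)
  ab <- assemble_site(pool, "neutral", 10, cfg, d)
  expect_equal(sum(ab > 0), 10)
  expect_true(all(ab[ab > 0] >= 1))
  expect_error(assemble_site(pool, "neutral", 31, cfg, d), "exceeds pool")

  # neutral with a fixed seed is reproducible
  set.seed(5); ab1 <- assemble_site(pool, "neutral", 10, cfg, d)
  set.seed(5); ab2 <- assemble_site(pool, "neutral", 10, cfg, d)
  expect_equal(ab1, ab2)

  # strong filtering picks species near the optimum
  opt <- pool$species_id[1]
  set.seed(2)
  filt_d <- replicate(30, {
    abf <- assemble_site(pool, "filtering", 8, cfg, d, optimum = opt)
    mean(d[names(abf)[abf > 0], opt])
  })
  set.seed(3)
  neut_d <- replicate(30, {
    abn <- assemble_site(pool, "neutral", 8, cfg, d)
    mean(d[names(abn)[abn > 0], opt])
  })
  expect_lt(mean(filt_d), mean(neut_d))
})

test_that("limiting similarity greedily spaces species on a 1-D trait", {
  sch <- mini_schema()
  tr <- tibble::tibble(
    species_id = c("s1", "s2", "s3", "s4"),
    forest_dependency = "medium",
    body_mass = c(1, 2, 10, 11),  # two tight pairs far apart
    invertebrates = 1, fruits = 0, canopy = 1, ground = 0,
    gleaning = 1, mixed_flock = 0
  )
  d <- gower_dissimilarity(tr, sch)
  cfg <- scenario_config(n_species_pool = 4, seed = 1)
  for (s in 1:6) {
    set.seed(s)
    ab <- assemble_site(tr, "limiting_similarity", 2, cfg, d)
    chosen <- names(ab)[ab > 0]
    # whatever the random start, the pair spans the two mass clusters
    expect_true(any(chosen %in% c("s1", "s2")) && any(chosen %in% c("s3", "s4")))
  }
})

test_that("assembly rules shift within-site trait spacing as designed", {
  cfg_n <- scenario_config(n_species_pool = 80, seed = 29,
                           sites = tibble::tibble(landscape = "A",
                                                  habitat = "forest", n = 8L),
                           richness_mean = 15, richness_sd = 1)
  cfg_f <- scenario_config(n_species_pool = 80, seed = 29,
                           sites = cfg_n$sites, richness_mean = 15,
                           richness_sd = 1,
                           assembly = list(forest = "filtering",
                                           agroforestry = "neutral"))
  cfg_l <- scenario_config(n_species_pool = 80, seed = 29,
                           sites = cfg_n$sites, richness_mean = 15,
                           richness_sd = 1,
                           assembly = list(forest = "limiting_similarity",
                                           agroforestry = "neutral"))
  mean_within <- function(cfg) {
    sim <- simulate_landscapes(cfg)
    d <- gower_dissimilarity(sim$traits)
    ab <- abundance_matrix(sim$communities)
    mean(vapply(seq_len(nrow(ab)), function(i) {
      sp <- colnames(ab)[ab[i, ] > 0]
      mean(d[sp, sp][upper.tri(d[sp, sp])])
    }, numeric(1)))
  }
  w_n <- mean_within(cfg_n)
  w_f <- mean_within(cfg_f)
  w_l <- mean_within(cfg_l)
  expect_lt(w_f, w_n)  # filtering clusters traits
  expect_gt(w_l, w_n)  # limiting similarity overdisperses them
})

test_that("landscape generation echoes the configured survey layout", {
  sim <- simulate_landscapes(scenario_config(n_species_pool = 50, seed = 31))
  comm <- sim$communities
  counts <- dplyr::count(comm, landscape, habitat)
  expect_equal(counts$n[counts$landscape == "A" & counts$habitat == "forest"], 12L)
  expect_equal(counts$n[counts$landscape == "A" & counts$habitat == "agroforestry"], 6L)
  expect_equal(counts$n[counts$landscape == "B" & counts$habitat == "forest"], 4L)
  expect_equal(counts$n[counts$landscape == "B" & counts$habitat == "agroforestry"], 4L)
  expect_equal(nrow(comm), 26L)

  # validation holds by construction and spacing is respected
  expect_s3_class(comm, "fda_community")
  for (land in c("A", "B")) {
    xy <- comm[comm$landscape == land, c("coord_x", "coord_y")]
    dm <- stats::dist(as.matrix(xy))
    expect_gte(min(dm), 200)
  }

  # identical seed -> identical simulation
  sim2 <- simulate_landscapes(scenario_config(n_species_pool = 50, seed = 31))
  expect_equal(as.data.frame(sim2$communities), as.data.frame(comm))
  expect_equal(as.data.frame(sim2$traits), as.data.frame(sim$traits))
})
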