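# Small fixtures built in code.

# Minimal schema: body mass + 6 binary traits covering the structural
# categories (2 food types with diet roles, 2 strata, 1 method, 1 flock).
mini_schema <- function() {
  trait_schema(
    trait = c("body_mass", "invertebrates", "fruits", "canopy", "ground",
              "gleaning", "mixed_flock"),
    type = c("continuous", rep("binary", 6)),
    category = c("resource_quantity", "food_type", "food_type",
                 "foraging_stratum", "foraging_stratum", "foraging_method",
                 "mixed_flock"),
    role = c(NA, "invertebrate", "fruit", NA, NA, NA, NA)
  )
}

# Deterministic 4-species table under the minimal schema.
mini_traits <- function() {
  tibble::tibble(
    species_id = c("spA", "spB", "spC", "spD"),
    forest_dependency = c("high", "low", "medium", "high"),
    body_mass = c(10, 100, 55, 10),
    invertebrates = c(1, 0, 1, 1),
    fruits = c(0, 1, 1, 0),
    canopy = c(1, 1, 0, 1),
    ground = c(0, 1, 1, 0),
    gleaning = c(1, 0, 0, 1),
    mixed_flock = c(0, 0, 1, 0)
  )
}

# Companion 3-site community over the 4 species.
mini_community <- function() {
  tibble::tibble(
    site_id = c("s1", "s2", "s3"),
    landscape = "L1",
    habitat = c("forest", "forest", "agroforestry"),
    coord_x = c(0, 500, 1200),
    coord_y = c(0, 400, 100),
    spA = c(3, 0, 1),
    spB = c(2, 5, 0),
    spC = c(0, 1, 4),
    spD = c(1, 0, 2)
  )
}

# Random trait table under the default 26-trait schema; constraints
# satisfied by construction (first food type / stratum forced on when the
# row would otherwise be empty).
random_traits <- function(n, seed = 1) {
  set.seed(seed)
  sch <- default_trait_schema()
  bin <- sch$trait[sch$type == "binary"]
  x <- matrix(stats::rbinom(n * length(bin), 1, 0.4), nrow = n,
              dimnames = list(NULL, bin))
  food <- sch$trait[sch$category == "food_type"]
  strat <- sch$trait[sch$category == "foraging_stratum"]
  x[rowSums(x[, food, drop = FALSE]) == 0, food[1]] <- 1
  x[rowSums(x[, strat, drop = FALSE]) == 0, strat[1]] <- 1
  dplyr::bind_cols(
    tibble::tibble(
      species_id = sprintf("r%03d", seq_len(n)),
      forest_dependency = sample(c("high", "medium", "low"), n, replace = TRUE),
      body_mass = round(stats::runif(n, 2, 2172), 1)
    ),
    tibble::as_tibble(x)
  )
}

# Per-trait arithmetic Gower oracle: explicit double loop over species and
# traits, independent of the package's matrix algebra.
gower_oracle <- function(traits, schema, ranges = NULL) {
  cont <- schema$trait[schema$type == "continuous"]
  bin <- schema$trait[schema$type == "binary"]
  n <- nrow(traits)
  if (is.null(ranges)) {
    ranges <- vapply(cont, function(tr) diff(range(traits[[tr]])), numeric(1))
  }
  d <- matrix(0, n, n, dimnames = list(traits$species_id, traits$species_id))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (tr in cont) {
        acc <- acc + abs(traits[[tr]][i] - traits[[tr]][j]) / ranges[[tr]]
      }
      for (tr in bin) {
        acc <- acc + as.numeric(traits[[tr]][i] != traits[[tr]][j])
      }
      d[i, j] <- acc / (length(cont) + length(bin))
    }
  }
  d
}

# Brute-force minimum spanning tree total length by enumerating all labeled
# spanning trees of K_n via Pruefer sequences (n <= 7).
mst_bruteforce <- function(coords) {
  n <- nrow(coords)
  stopifnot(n >= 2, n <= 7)
  dm <- as.matrix(stats::dist(coords))
  if (n == 2) return(dm[1, 2])
  seqs <- expand.grid(rep(list(seq_len(n)), n - 2))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- as.integer(seqs[r, ])
    edges <- pruefer_decode(pr, n)
    len <- sum(dm[edges])
    if (len < best) best <- len
  }
  best
}

pruefer_decode <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 1L
  pr_left <- pr
  for (v in pr_left) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, v)
    k <- k + 1L
    degree[leaf] <- 0L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[k, ] <- last
  edges
}

# Step-by-step FEve oracle: enumerate all spanning trees for the MST, then
# apply the EW/PEW formula term by term.
feve_oracle <- function(coords, p) {
  n <- nrow(coords)
  dm <- as.matrix(stats::dist(coords))
  # find MST edge set by brute force
  seqs <- expand.grid(rep(list(seq_len(n)), n - 2))
  best <- NULL; best_len <- Inf
  for (r in seq_len(nrow(seqs))) {
    edges <- pruefer_decode(as.integer(seqs[r, ]), n)
    len <- sum(dm[edges])
    if (len < best_len) { best_len <- len; best <- edges }
  }
  ew <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    i <- best[k, 1]; j <- best[k, 2]
    ew[k] <- dm[i, j] / (p[i] + p[j])
  }
  pew <- ew / sum(ew)
  thr <- 1 / (n - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}
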