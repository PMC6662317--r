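#' Gower dissimilarity on mixed binary + continuous traits
#'
#' Pairwise functional distances
#' \eqn{d_{ij} = \frac{1}{T}\sum_k \delta_k(i,j)} with equal weight per
#' trait: for a binary trait \eqn{\delta_k = |x_{ik} - x_{jk}|} (symmetric
#' mismatch — shared absence counts as similarity) and for a continuous
#' trait \eqn{\delta_k = |x_{ik} - x_{jk}| / \mathrm{range}_k}, the range
#' taken over the regional pool. Distances lie in \[0, 1\].
#'
#' The continuous-trait range is computed once on the full pool and reused
#' for every subset (pass `ranges` when computing distances for a subgroup),
#' so subgroup distances stay comparable across groups. Distances for a
#' species subset therefore equal the corresponding submatrix of the pool
#' matrix.
#'
#' @param traits an `fda_traits` table (or any data frame with the schema's
#'   trait columns plus `species_id`).
#' @param schema the [trait_schema()].
#' @param ranges optional named vector of pool ranges for the continuous
#'   traits; defaults to ranges observed in `traits`.
#' @param binary `"symmetric"` (default) or `"asymmetric"`; the asymmetric
#'   variant drops double-zero binary traits from each pair's denominator
#'   (Jaccard-style).
#' @param log_mass if `TRUE`, continuous traits are log10-transformed before
#'   ranging (off by default; results differ).
#' @return A symmetric numeric matrix with species ids as dimnames, classed
#'   `fda_dissim`, with attribute `ranges`.
#' @export
#' @examples
#' pool <- generate_pool(scenario_config(n_species_pool = 10, seed = 1))
#' d <- gower_dissimilarity(pool)
#' range(d)
gower_dissimilarity <- function(traits, schema = default_trait_schema(),
                                ranges = NULL,
                                binary = c("symmetric", "asymmetric"),
                                log_mass = FALSE) {
  binary <- match.arg(binary)
  if (nrow(traits) < 2L) rlang::abort("Need at least 2 species.")
  cont <- schema_traits(schema, type = "continuous")
  bin <- schema_traits(schema, type = "binary")
  sp <- traits$species_id
  n_tr <- length(cont) + length(bin)

  xc <- as.matrix(traits[cont])
  if (log_mass && length(cont)) xc <- log10(xc)
  if (is.null(ranges)) {
    ranges <- apply(xc, 2, function(v) diff(range(v)))
    names(ranges) <- cont
  }
  zero <- ranges[cont] <= 0
  if (any(zero)) {
    rlang::abort(sprintf(
      "Continuous trait '%s' has zero range across the pool.",
      cont[zero][1]
    ))
  }
  xc <- sweep(xc, 2, ranges[cont], "/")
  xb <- as.matrix(traits[bin])

  # sum of per-trait scaled absolute differences = Manhattan distance
  num <- as.matrix(stats::dist(cbind(xc, xb), method = "manhattan"))
  if (binary == "symmetric") {
    d <- num / n_tr
  } else {
    zz <- (1 - xb) %*% t(1 - xb)  # double-zero binary counts per pair
    denom <- n_tr - zz
    denom[denom <= 0] <- 1
    d <- num / denom
  }
  dimnames(d) <- list(sp, sp)
  diag(d) <- 0
  identical_pairs <- sum(d[upper.tri(d)] == 0)
  if (identical_pairs > 0) {
    rlang::inform(sprintf(
      "%d species pair(s) are functionally identical (d = 0).", identical_pairs
    ))
  }
  structure(d, ranges = ranges, binary = binary, class = c("fda_dissim", "matrix"))
}

#' Principal coordinates of a dissimilarity matrix with Cailliez correction
#'
#' Embeds species in a Euclidean trait space whose pairwise distances
#' reproduce the (corrected) dissimilarities. When the input matrix is not
#' Euclidean some principal-coordinate eigenvalues are negative; the
#' Cailliez correction adds the smallest constant `c` to every off-diagonal
#' dissimilarity that makes the matrix embeddable, removing the negative
#' eigenvalues. All axes with eigenvalue above `tol` are retained, so the
#' corrected geometry is preserved exactly (up to numerical tolerance).
#'
#' @param d an `fda_dissim` matrix (or any symmetric distance matrix with
#'   dimnames).
#' @param tol eigenvalue tolerance; axes with eigenvalue `> tol` are kept.
#' @return A list of class `fda_trait_space`: `coordinates` (species x
#'   axes), `eigenvalues`, `correction` (the additive constant, 0 when the
#'   input was already Euclidean).
#' @export
pcoa_cailliez <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) rlang::abort("Need at least 3 species for principal coordinates.")
  sp <- rownames(d)
  cc <- cailliez_constant(d, tol = tol)
  dc <- d + cc
  diag(dc) <- 0
  e <- double_centered_eigen(dc)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    rlang::abort(sprintf(
      "Cailliez correction failed numerically (smallest eigenvalue %.3g).",
      min(e$values)
    ))
  }
  keep <- which(e$values > tol)
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- sp
  colnames(coords) <- paste0("A", seq_along(keep))
  structure(
    list(coordinates = coords, eigenvalues = e$values[keep], correction = cc),
    class = "fda_trait_space"
  )
}

# Smallest additive constant making d Euclidean (Cailliez 1983): the
# largest real eigenvalue of the 2n x 2n block matrix
#   [ 0   2*W1 ; -I  -4*W2 ]
# with W1 the double-centered -d^2/2 and W2 the double-centered -d/2.
cailliez_constant <- function(d, tol = 1e-8) {
  e0 <- double_centered_eigen(d)
  if (min(e0$values) > -tol * max(1, max(abs(e0$values)))) {
    return(0)  # already Euclidean
  }
  n <- nrow(d)
  w1 <- gower_center(-0.5 * d^2)
  w2 <- gower_center(-0.5 * d)
  big <- rbind(
    cbind(matrix(0, n, n), 2 * w1),
    cbind(-diag(n), -4 * w2)
  )
  ev <- eigen(big, only.values = TRUE)$values
  cc <- max(Re(ev[abs(Im(ev)) < 1e-8]))
  if (!is.finite(cc) || cc < 0) {
    rlang::abort(sprintf(
      "Could not find a valid Cailliez constant (got %.3g).", cc
    ))
  }
  cc
}

gower_center <- function(a) {
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# Eigen-decomposition of the Gower-centered -d^2/2 matrix.
double_centered_eigen <- function(d) {
  g <- gower_center(-0.5 * d^2)
  g <- (g + t(g)) / 2
  eigen(g, symmetric = TRUE)
}

#' UPGMA functional dendrogram
#'
#' Average-linkage agglomerative clustering of the dissimilarity matrix.
#' Species are pre-sorted lexicographically so that ties in the minimal pair
#' distance are broken deterministically; UPGMA merge heights are
#' non-decreasing and the cophenetic distances are ultrametric.
#'
#' @param d symmetric dissimilarity matrix with species dimnames.
#' @return An [stats::hclust] object (method `"average"`).
#' @export
upgma_dendrogram <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) rlang::abort("Need at least 2 species.")
  ord <- order(rownames(d))
  stats::hclust(stats::as.dist(d[ord, ord, drop = FALSE]), method = "average")
}

#' Export a dendrogram to Newick
#'
#' @param hc an [stats::hclust] dendrogram.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Total dendrogram branch length
#'
#' Sum of all branch segments of an agglomerative dendrogram: each merge at
#' height `h` joining subtrees whose own top heights are `h1`, `h2`
#' contributes `(h - h1) + (h - h2)`. This is the branch-length sum
#' "without the root segment" used by the FD index (and equals vegan's
#' tree-height convention).
#'
#' @param hc an [stats::hclust] object.
#' @return Non-negative branch-length sum.
#' @export
branch_length_sum <- function(hc) {
  m <- hc$merge
  h <- hc$height
  total <- 0
  for (i in seq_len(nrow(m))) {
    child_h <- ifelse(m[i, ] < 0, 0, h[pmax(m[i, ], 1)])  # leaves sit at height 0
    total <- total + sum(h[i] - child_h)
  }
  total
}

#' Minimum spanning tree of points in trait space
#'
#' @param coords numeric matrix (points x axes) with rownames.
#' @return A tibble with columns `from`, `to` (point labels) and `length`
#'   (Euclidean edge length); `n - 1` rows.
#' @export
mst_edges <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) rlang::abort("Need at least 2 points.")
  labs <- rownames(coords) %||% as.character(seq_len(n))
  dm <- stats::dist(coords)
  st <- vegan::spantree(dm)
  from <- labs[2:n]
  to <- labs[st$kid]
  tibble::tibble(from = from, to = to, length = as.numeric(st$dist))
}
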