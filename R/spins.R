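# Sphere-rotation ("spin") spatial permutation nulls, component and gene
# significance against the shared spin null, and spatial-topography
# summaries.
#
# Cortical centroids are projected onto a per-hemisphere sphere, rotated by
# a uniform random 3-D rotation (mirrored across hemispheres), and each
# region is reassigned to the nearest rotated region by greedy one-to-one
# matching.  Subcortical regions, which have no spherical geometry, are
# permuted uniformly among themselves.  This preserves spatial
# autocorrelation in the permuted maps, unlike an iid shuffle.

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
.random_rotation <- function() {
  qrm <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qrm)
  Q <- Q %*% diag(sign(diag(qr.R(qrm))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# unit vectors of hemisphere centroids about their own centre
.sphere_units <- function(cent) {
  ctr <- colMeans(cent)
  u <- sweep(cent, 2L, ctr)
  u / sqrt(rowSums(u^2))
}

# greedy one-to-one assignment minimizing pairwise distance.
# D[i, j]: distance from original slot i to rotated region j.
# Returns pi with pi[i] = j, a bijection.
.greedy_assign <- function(D) {
  n <- nrow(D)
  out <- integer(n)
  for (k in seq_len(n)) {
    m <- arrayInd(which.min(D), dim(D))
    out[m[1L]] <- m[2L]
    D[m[1L], ] <- Inf
    D[, m[2L]] <- Inf
  }
  out
}

#' Generate spatial spin permutations
#'
#' @param atlas an `atlas_info` table with cortical centroids on (or
#'   projectable to) per-hemisphere spheres.
#' @param n_perm number of spins (fewer than 100 triggers a warning).
#' @param seed integer seed.
#' @return list of class `spin_set` with `perm` (n_perm x regions integer
#'   matrix; row `s` reorders a map as `map[perm[s, ]]`), `method`,
#'   `cortical` and `subcortical` index vectors.  Every row is a bijection
#'   mapping cortex to cortex and subcortex to subcortex.
#' @export
generate_spins <- function(atlas, n_perm = 1000L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  if (n_perm < 100L) warning("`n_perm` < 100 gives coarse spin p-values")
  idx_L <- which(atlas$tissue == "cortical" & atlas$hemisphere == "L")
  idx_R <- which(atlas$tissue == "cortical" & atlas$hemisphere == "R")
  idx_S <- which(atlas$tissue == "subcortical")
  u_L <- .sphere_units(as.matrix(atlas[idx_L, c("R", "A", "S")]))
  u_R <- .sphere_units(as.matrix(atlas[idx_R, c("R", "A", "S")]))
  mirror <- diag(c(-1, 1, 1))
  n <- nrow(atlas)
  with_seed(seed, {
    perm <- matrix(0L, n_perm, n)
    for (s in seq_len(n_perm)) {
      rot <- .random_rotation()
      rot_R <- mirror %*% rot %*% mirror
      v_L <- u_L %*% t(rot)
      v_R <- u_R %*% t(rot_R)
      a_L <- .greedy_assign(2 - 2 * tcrossprod(u_L, v_L))
      a_R <- .greedy_assign(2 - 2 * tcrossprod(u_R, v_R))
      row <- integer(n)
      row[idx_L] <- idx_L[a_L]
      row[idx_R] <- idx_R[a_R]
      if (length(idx_S) > 0L) row[idx_S] <- idx_S[sample.int(length(idx_S))]
      perm[s, ] <- row
    }
    structure(list(perm = perm, method = "sphere_rotation_greedy",
                   cortical = c(idx_L, idx_R), subcortical = idx_S,
                   seed = seed),
              class = "spin_set")
  })
}

#' PLS spin-null distributions
#'
#' Refits the PLS for every spin of the predictor matrix and collects the
#' null explained variance per component and the null first-component gene
#' weights.  Component and gene significance consume this one shared null.
#'
#' Reordering the rows of `X` by a permutation is algebraically equivalent
#' to fitting the original `X` against the inversely permuted response, so
#' the expression matrix is never copied per spin.
#'
#' @inheritParams pls_fit
#' @param spins a `spin_set` for the same atlas.
#' @return list with `expvar_null` (n_perm x k) and `w1_null` (n_perm x
#'   genes).
#' @export
spin_pls_nulls <- function(X, y, spins, n_components = 1L) {
  X <- as.matrix(X)
  if (inherits(y, "regional_map")) y <- setNames(y$statistic, y$region)
  y <- as.numeric(y)
  if (ncol(spins$perm) != nrow(X)) stop_invalid("spins do not match the atlas size")
  n_perm <- nrow(spins$perm)
  ev <- matrix(NA_real_, n_perm, n_components)
  w1 <- matrix(NA_real_, n_perm, ncol(X))
  for (s in seq_len(n_perm)) {
    inv <- order(spins$perm[s, ])
    fit <- .simpls(X, y[inv], n_components)
    ev[s, seq_len(fit$n_components)] <- fit$expvar
    w1[s, ] <- fit$weights[, 1L]
  }
  list(expvar_null = ev, w1_null = w1)
}

#' Spin-test p-values for PLS components
#'
#' `p_k = (1 + #[null explained variance of component k >= observed]) /
#' (1 + n_perm)` over the spin null.
#'
#' @inheritParams spin_pls_nulls
#' @param nulls optional precomputed [spin_pls_nulls()] result (to share
#'   the null with [gene_significance()]).
#' @return list with `p` (per component), `expvar` (observed), `nulls`.
#' @export
component_significance <- function(X, y, spins, n_components = 1L,
                                   nulls = NULL) {
  fit <- pls_fit(X, y, n_components)
  if (is.null(nulls)) nulls <- spin_pls_nulls(X, y, spins, n_components)
  n_perm <- nrow(nulls$expvar_null)
  k <- fit$n_components
  p <- vapply(seq_len(k), function(j) {
    (1 + sum(nulls$expvar_null[, j] >= fit$expvar[j], na.rm = TRUE)) / (1 + n_perm)
  }, numeric(1))
  list(p = p, expvar = fit$expvar, nulls = nulls)
}

#' One-sided FWE q-values for gene weights against the spin null
#'
#' For each spin, the 95th and 5th percentiles of that spin's weight
#' distribution are computed (linear interpolation).  A gene's q is the
#' proportion of spins in which its observed weight fails to strictly
#' exceed the 95th percentile (upweighted side) or fall strictly below the
#' 5th (downweighted side); the side is chosen by the sign of the observed
#' weight.  Genes with q < 0.05 are flagged significant.
#'
#' @param observed numeric vector of observed first-component gene weights
#'   (named by gene).
#' @param null_weights spins x genes matrix of null weights (from
#'   [spin_pls_nulls()], the same spin set used for component significance).
#' @return `data.frame`: `gene`, `weight`, `q_up`, `q_down`, `direction`,
#'   `q`, `significant`.
#' @export
gene_significance <- function(observed, null_weights) {
  null_weights <- as.matrix(null_weights)
  if (nrow(null_weights) < 20L) {
    stop_invalid("fewer than 20 permutations: percentiles unstable")
  }
  if (ncol(null_weights) != length(observed)) {
    stop_invalid("`observed` and `null_weights` gene counts differ")
  }
  p95 <- apply(null_weights, 1L, quantile, probs = 0.95, type = 7, names = FALSE)
  p05 <- apply(null_weights, 1L, quantile, probs = 0.05, type = 7, names = FALSE)
  q_up <- colMeans(!outer(p95, observed, function(a, b) b > a))
  q_down <- colMeans(!outer(p05, observed, function(a, b) b < a))
  direction <- ifelse(observed >= 0, "upweighted", "downweighted")
  q <- ifelse(direction == "upweighted", q_up, q_down)
  data.frame(gene = if (is.null(names(observed))) seq_along(observed) else names(observed),
             weight = unname(observed), q_up = q_up, q_down = q_down,
             direction = direction, q = q, significant = q < 0.05,
             stringsAsFactors = FALSE)
}

#' Spatial topography of a regional map
#'
#' Spearman correlations of a per-region vector against the centroid
#' coordinates (R: left to right, A: posterior to anterior, S: inferior to
#' superior), with p-values.
#'
#' @param v per-region numeric vector.
#' @param atlas an `atlas_info` table.
#' @return `data.frame`: `axis`, `rho`, `p`.
#' @export
spatial_topography <- function(v, atlas) {
  if (length(v) != nrow(atlas)) stop_invalid("`v` length must equal atlas regions")
  res <- lapply(c("R", "A", "S"), function(ax) {
    ct <- suppressWarnings(
      stats::cor.test(v, atlas[[ax]], method = "spearman", exact = FALSE))
    data.frame(axis = ax, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
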