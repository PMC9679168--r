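# Network-based statistic: edge-wise GLM t-maps, suprathreshold components,
# and component-extent family-wise-error permutation p-values.
#
# Covariates are handled by Freedman-Lane residual permutation: residuals of
# the reduced (nuisance-only) model are permuted and the statistic of the
# full model recomputed, with one shared permutation applied to every edge
# per iteration (required for family-wise-error validity).  The per-edge t
# is computed through the Frisch-Waugh-Lovell identity, which lets all
# permutations be evaluated with two large matrix products.

# Core engine.  Y: subjects x edges; Z: nuisance design incl. intercept;
# x: contrast column; perms: n_perm x n matrix of permutation vectors.
# Returns observed and permuted t statistics for the contrast coefficient.
fl_perm_t <- function(Y, Z, x, perms, chunk = 100L) {
  n <- nrow(Y)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) stop_invalid("nuisance design is rank deficient")
  U <- qr.Q(qrZ)[, seq_len(qrZ$rank), drop = FALSE]
  xt <- x - U %*% crossprod(U, x)
  xx <- sum(xt^2)
  if (xx < 1e-10 * max(1, sum(x^2))) {
    stop_invalid("contrast column is collinear with the covariates")
  }
  Yt <- Y - U %*% crossprod(U, Y)
  cs <- colSums(Yt^2)
  # edges whose variance is fully absorbed by the nuisance model carry no
  # testable signal; without this guard their t would be roundoff noise
  degenerate <- cs <= 1e-12 * pmax(colSums(Y^2), 1e-300)
  q <- ncol(U)
  df <- n - q - 1L
  if (df < 1L) stop_invalid("not enough subjects for the design")
  num <- drop(crossprod(xt, Yt))
  rss <- pmax(cs - num^2 / xx, 1e-300)
  t_obs <- num * sqrt(df / (xx * rss))
  t_obs[degenerate] <- 0
  n_perm <- nrow(perms)
  E <- ncol(Y)
  t_perm <- matrix(0, n_perm, E)
  block <- q + 1L
  for (start in seq.int(1L, n_perm, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_perm)
    W <- matrix(0, n, block * length(idx))
    for (k in seq_along(idx)) {
      pr <- perms[idx[k], ]
      W[, (k - 1L) * block + 1L] <- xt[pr]
      W[, (k - 1L) * block + 1L + seq_len(q)] <- U[pr, ]
    }
    CP <- crossprod(W, Yt)                       # (block*len) x E
    for (k in seq_along(idx)) {
      r0 <- (k - 1L) * block
      numv <- CP[r0 + 1L, ]
      projsq <- if (q == 1L) CP[r0 + 2L, ]^2 else
        colSums(CP[r0 + 1L + seq_len(q), , drop = FALSE]^2)
      rssp <- pmax(cs - projsq - numv^2 / xx, 1e-300)
      tp <- numv * sqrt(df / (xx * rssp))
      tp[degenerate] <- 0
      t_perm[idx[k], ] <- tp
    }
  }
  list(t_obs = t_obs, t_perm = t_perm, df = df)
}

#' Edge-wise GLM t-statistic map
#'
#' Fits, for every connectome edge, an ordinary-least-squares model of edge
#' weight on the design columns and returns the t statistic of the contrast
#' coefficient as a symmetric matrix.
#'
#' @param connectomes per-subject list of connectomes (or lists holding a
#'   `functional` element, selected by `modality`).
#' @param design `data.frame` of numeric covariates, rows aligned with
#'   subjects; an intercept is added automatically.
#' @param contrast name of the design column to test.
#' @param modality modality selected when subjects hold several.
#' @return list of class `edge_stat_map` with `tmap` (symmetric matrix,
#'   zero diagonal), `contrast` and `df`.
#' @export
edge_glm_tmap <- function(connectomes, design, contrast, modality = "functional") {
  Y <- stack_edges(connectomes, modality)
  des <- .check_design(design, contrast, n = nrow(Y))
  fl <- fl_perm_t(Y, des$Z, des$x,
                  perms = matrix(seq_len(nrow(Y)), nrow = 1L))
  n <- (1 + sqrt(1 + 8 * ncol(Y))) / 2
  rn <- rownames(as.matrix(unclass(
    if (is.list(connectomes[[1]])) connectomes[[1]][[modality]] else connectomes[[1]]
  )))
  tmap <- ut_unvec(fl$t_obs, as.integer(n), dimnames = list(rn, rn))
  structure(list(tmap = tmap, contrast = contrast, df = fl$df),
            class = "edge_stat_map")
}

# Validate a design data.frame; returns Z (nuisance + intercept) and x.
.check_design <- function(design, contrast, n) {
  design <- as.data.frame(design)
  if (nrow(design) != n) stop_invalid("design rows must match subjects")
  if (!contrast %in% names(design)) {
    stop_invalid(sprintf("contrast column '%s' not in design", contrast))
  }
  if (n <= ncol(design) + 1L) {
    stop_invalid("need more subjects than design columns")
  }
  X <- cbind(intercept = 1, as.matrix(design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_invalid("design is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", "))
  }
  keep <- setdiff(colnames(X), contrast)
  list(Z = X[, keep, drop = FALSE], x = X[, contrast])
}

#' Connected components of the suprathreshold graph
#'
#' Edges whose statistic strictly exceeds `t_threshold` form a graph; its
#' node-connected components are returned, each as an edge set.  Ties at the
#' threshold are excluded (strict `>`).
#'
#' @param stat an `edge_stat_map` or a symmetric statistic matrix.
#' @param t_threshold primary threshold (the analyses in this package
#'   default to 3.1).
#' @return list of 2-column integer edge matrices (1-based indices, i < j),
#'   each with a `t` attribute holding the edge statistics; empty list if no
#'   edge survives.
#' @export
suprathreshold_components <- function(stat, t_threshold = 3.1) {
  tmap <- if (inherits(stat, "edge_stat_map")) stat$tmap else as.matrix(stat)
  if (any(!is.finite(tmap[upper.tri(tmap)]))) stop_invalid("t map must be finite")
  sel <- which(upper.tri(tmap) & tmap > t_threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(list())
  comp <- .edge_components(sel)
  lapply(comp, function(e) {
    colnames(e) <- c("i", "j")
    attr(e, "t") <- tmap[e]
    e
  })
}

# Split an edge list into node-connected components (igraph backend).
.edge_components <- function(edges) {
  verts <- sort(unique(as.vector(edges[, 1:2])))
  g <- igraph::graph_from_edgelist(
    cbind(match(edges[, 1], verts), match(edges[, 2], verts)),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  edge_memb <- memb[match(edges[, 1], verts)]
  lapply(split(seq_len(nrow(edges)), edge_memb),
         function(ii) edges[ii, , drop = FALSE])
}

# Max component size (edge count) of a suprathreshold t vector over the
# upper-triangle edge list `edges` (2-column matrix).
.max_component_size <- function(tvec, edges, thr) {
  sel <- tvec > thr
  if (!any(sel)) return(0L)
  e <- edges[sel, , drop = FALSE]
  verts <- sort(unique(as.vector(e)))
  g <- igraph::graph_from_edgelist(
    cbind(match(e[, 1], verts), match(e[, 2], verts)), directed = FALSE)
  memb <- igraph::components(g)$membership
  max(tabulate(memb[match(e[, 1], verts)]))
}

#' Network-based statistic test
#'
#' Edge-wise GLM t statistics, primary thresholding, connected components,
#' and component-level family-wise-error permutation p-values based on the
#' maximum component extent (edge count) across permutations:
#' `fwe_p = (1 + #[max perm size >= observed size]) / (1 + n_perm)`.
#' One-sided tests are run per direction; use `direction = "neg"` to test
#' the negative contrast.
#'
#' @inheritParams edge_glm_tmap
#' @param direction "pos" tests positive contrast coefficients, "neg"
#'   negative ones.
#' @param t_threshold primary threshold (default 3.1).
#' @param n_perm number of permutations (default 5000); fewer than 100
#'   triggers a warning, fewer than 10 an error.
#' @param seed integer seed for the shared permutation stream.
#' @return list of class `nbs_result`: `components` (edge sets),
#'   `component_size`, `fwe_p`, `tmap`, `t_threshold`, `n_perm`,
#'   `direction`, `seed`, `perm_max_size`.
#' @export
nbs_test <- function(connectomes, design, contrast, direction = c("pos", "neg"),
                     t_threshold = 3.1, n_perm = 5000L, seed = 1L,
                     modality = "functional") {
  direction <- match.arg(direction)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  if (n_perm < 10L) stop_invalid("`n_perm` < 10 is not interpretable")
  if (n_perm < 100L) warning("`n_perm` < 100 gives coarse p-values")
  Y <- stack_edges(connectomes, modality)
  des <- .check_design(design, contrast, n = nrow(Y))
  perms <- with_seed(seed, t(replicate(n_perm, sample.int(nrow(Y)))))
  fl <- fl_perm_t(Y, des$Z, des$x, perms)
  sgn <- if (direction == "pos") 1 else -1
  t_obs <- sgn * fl$t_obs
  n <- (1 + sqrt(1 + 8 * ncol(Y))) / 2
  edges <- ut_edges(as.integer(n))
  rn <- rownames(as.matrix(unclass(
    if (is.list(connectomes[[1]])) connectomes[[1]][[modality]] else connectomes[[1]]
  )))
  tmap <- ut_unvec(t_obs, as.integer(n), dimnames = list(rn, rn))
  comps <- suprathreshold_components(tmap, t_threshold)
  perm_max <- vapply(seq_len(n_perm), function(p) {
    .max_component_size(sgn * fl$t_perm[p, ], edges, t_threshold)
  }, integer(1))
  sizes <- vapply(comps, nrow, integer(1))
  fwe_p <- vapply(sizes, function(s) (1 + sum(perm_max >= s)) / (1 + n_perm),
                  numeric(1))
  structure(list(components = comps, component_size = sizes, fwe_p = fwe_p,
                 tmap = tmap, t_threshold = t_threshold, n_perm = n_perm,
                 direction = direction, seed = seed, df = fl$df,
                 perm_max_size = perm_max),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> direction=%s t>%.3g, %d permutations\n",
              x$direction, x$t_threshold, x$n_perm))
  if (length(x$component_size) == 0L) {
    cat("  no suprathreshold components\n")
  } else {
    for (k in order(x$fwe_p)) {
      cat(sprintf("  component %d: %d edges, FWE p = %.4g\n",
                  k, x$component_size[k], x$fwe_p[k]))
    }
  }
  invisible(x)
}

#' Classify subnetwork connections by anatomy
#'
#' Each edge is assigned exactly one class: cortico-striatal if exactly one
#' endpoint is subcortical, otherwise interhemispheric if the endpoint
#' hemispheres differ, otherwise intrahemispheric.
#'
#' @param component 2-column integer edge matrix (1-based atlas row indices).
#' @param atlas an `atlas_info` table.
#' @return list with `counts`, `proportions` (named, summing to 1) and the
#'   per-edge `class` vector.
#' @export
classify_connections <- function(component, atlas) {
  component <- as.matrix(component)
  if (any(component < 1L) || any(component > nrow(atlas))) {
    stop_invalid("component references regions outside the atlas")
  }
  sub1 <- atlas$tissue[component[, 1]] == "subcortical"
  sub2 <- atlas$tissue[component[, 2]] == "subcortical"
  hemi_diff <- atlas$hemisphere[component[, 1]] != atlas$hemisphere[component[, 2]]
  cls <- ifelse(xor(sub1, sub2), "cortico-striatal",
                ifelse(hemi_diff, "interhemispheric", "intrahemispheric"))
  lev <- c("cortico-striatal", "interhemispheric", "intrahemispheric")
  counts <- table(factor(cls, levels = lev))
  list(counts = counts, proportions = counts / sum(counts), class = cls)
}
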