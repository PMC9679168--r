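# Connectome container, IO, summaries and the density permutation test.

#' Construct a connectome
#'
#' A connectome is a square symmetric weighted matrix over atlas regions.
#' Matrices that are asymmetric beyond `tol` (e.g. from text-file
#' round-trips) are symmetrized by averaging the two halves with a warning;
#' the diagonal is forced to zero.  Structural weights must be nonnegative.
#'
#' @param m square numeric matrix.
#' @param modality one of "structural", "functional", "constrained".
#' @param roi_names optional region names (defaults to existing dimnames).
#' @param tol symmetry tolerance.
#' @return matrix of class `connectome` with a `modality` attribute.
#' @export
as_connectome <- function(m, modality = c("functional", "structural", "constrained"),
                          roi_names = NULL, tol = 1e-9) {
  modality <- match.arg(modality)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_invalid("connectome matrix must be square")
  if (!is.null(roi_names)) dimnames(m) <- list(roi_names, roi_names)
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    warning(sprintf("matrix asymmetric (max |m - t(m)| = %.3g); symmetrizing by averaging", asym))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (modality == "structural" && any(m < 0)) {
    stop_invalid("structural weights must be nonnegative")
  }
  structure(m, class = c("connectome", "matrix"), modality = modality)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s, %d regions, density %.4g\n",
              attr(x, "modality"), nrow(x), connectome_density(x)))
  invisible(x)
}

#' Read / write a connectome as TSV
#'
#' Square tab-separated matrix with region names as header row and first
#' column.  If an atlas is supplied the region order is validated against it.
#'
#' @param path file path.
#' @param modality connectome modality.
#' @param atlas optional `atlas_info` for region-order validation.
#' @return [as_connectome()] object.
#' @export
read_connectome_tsv <- function(path, modality = "functional", atlas = NULL) {
  m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
  if (!is.null(atlas) && !identical(rownames(m), atlas$name)) {
    stop_invalid("region order in ", path, " does not match the atlas")
  }
  as_connectome(m, modality)
}

#' @rdname read_connectome_tsv
#' @param c a connectome.
#' @export
write_connectome_tsv <- function(c, path) {
  write.table(as.matrix(unclass(c)), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Constrain a functional connectome by structural support
#'
#' Keeps a functional weight only where the structural matrix has a positive
#' weight (multiplication by the binarized structural matrix); all other
#' edges are set to zero.
#'
#' @param functional,structural connectomes with identical shape and region
#'   order.
#' @return a `connectome` with modality "constrained".
#' @export
constrain_by_structure <- function(functional, structural) {
  if (!identical(dim(functional), dim(structural)) ||
      !identical(rownames(functional), rownames(structural))) {
    stop_invalid("functional and structural connectomes must share shape and region order")
  }
  m <- unclass(functional) * (unclass(structural) > 0)
  as_connectome(m, "constrained")
}

#' Connectome density
#'
#' Sum of all weighted connections, each undirected edge counted once
#' (upper-triangle sum).
#'
#' @param c a connectome.
#' @return scalar density.
#' @export
connectome_density <- function(c) sum(ut_vec(as.matrix(unclass(c))))

#' Node strength
#'
#' Per-region sum of edge weights, the graph-theory strength metric used as
#' the regional summary of functional connectivity.
#'
#' @param c a connectome.
#' @return named numeric vector, one value per region.
#' @export
node_strength <- function(c) rowSums(as.matrix(unclass(c)))

# Stack one modality of a per-subject connectome list into a subjects x edges
# matrix of upper-triangle weights.
stack_edges <- function(connectomes, modality = "functional") {
  mats <- lapply(connectomes, function(s) {
    m <- if (is.list(s) && !is.null(s[[modality]])) s[[modality]] else s
    ut_vec(as.matrix(unclass(m)))
  })
  do.call(rbind, mats)
}

#' Permutation test for a group difference in connectome density
#'
#' Fits density ~ group + age + sex by ordinary least squares and tests the
#' group coefficient with a two-tailed permutation test.  Covariates are
#' respected by Freedman-Lane residual permutation: the reduced
#' (covariates-only) model residuals are permuted and the full model refit.
#'
#' @param connectomes per-subject list of connectomes (or of lists holding a
#'   `functional`/`structural` element, selected by `modality`).
#' @param cohort `cohort_table` aligned with `connectomes`.
#' @param modality which modality to summarize when subjects hold both.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `t_obs`, `p`, `densities`, `n_perm`.
#' @export
density_group_test <- function(connectomes, cohort, modality = "functional",
                               n_perm = 5000L, seed = 1L) {
  if (length(connectomes) != nrow(cohort)) {
    stop_invalid("`connectomes` and `cohort` must align")
  }
  tab <- table(cohort$group)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop_invalid("need at least 2 subjects in each group")
  }
  dens <- vapply(connectomes, function(s) {
    m <- if (is.list(s) && !is.null(s[[modality]])) s[[modality]] else s
    connectome_density(m)
  }, numeric(1))
  des <- build_design(cohort, contrast = "group")
  perms <- with_seed(seed, t(replicate(n_perm, sample.int(nrow(cohort)))))
  fl <- fl_perm_t(matrix(dens, ncol = 1L), des$Z, des$x, perms)
  p <- (1 + sum(abs(fl$t_perm[, 1]) >= abs(fl$t_obs[1]))) / (1 + n_perm)
  list(t_obs = fl$t_obs[1], p = p, densities = dens, n_perm = n_perm)
}

# Design pieces for permutation GLMs: Z = intercept + nuisance covariates,
# x = contrast column.  Sex coded 0/1 (M = 1), group 0/1 (carrier = 1).
build_design <- function(cohort, contrast = c("group", "nfl"),
                         covariates = c("age", "sex")) {
  contrast <- match.arg(contrast)
  sex01 <- as.numeric(cohort$sex == "M")
  grp01 <- as.numeric(cohort$group == "carrier")
  cols <- list(age = cohort$age, sex = sex01)
  Z <- cbind(intercept = 1, do.call(cbind, cols[covariates]))
  x <- switch(contrast, group = grp01, nfl = cohort$csf_nfl)
  if (anyNA(x)) stop_invalid("contrast variable has missing values; drop those subjects first")
  list(Z = Z, x = x, contrast = contrast)
}
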