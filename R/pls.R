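# Probe collapsing, expression normalization, partial least squares
# regression of the region x gene matrix onto a regional map, and bootstrap
# gene ranking.
#
# The PLS is a SIMPLS-style two-block regression with deflation (de Jong
# 1993).  For a univariate response this reports, per component, a
# unit-norm gene weight vector, orthonormal region scores, and the percent
# of response variance explained; components are oriented so their region
# scores correlate positively with the response.

#' Collapse probe-level expression to one probe per gene
#'
#' Drops probes that are above background in no more than 50% of samples,
#' then keeps, per gene, the surviving probe with the highest mean
#' intensity (exact ties broken by the lexicographically smaller probe id).
#' Genes with no surviving probe are excluded.
#'
#' @param probes `data.frame` with columns `probe_id`, `gene`, and one
#'   numeric column per sample.
#' @param above_background logical matrix (probes x samples) aligned with
#'   the sample columns of `probes`.
#' @return gene x sample numeric matrix.
#' @export
collapse_probes <- function(probes, above_background) {
  if (nrow(probes) == 0L) stop_invalid("empty probe table")
  sample_cols <- setdiff(names(probes), c("probe_id", "gene"))
  intensity <- as.matrix(probes[, sample_cols, drop = FALSE])
  ab <- as.matrix(above_background)
  if (!all(dim(ab) == dim(intensity))) {
    stop_invalid("`above_background` must match the probe intensity columns")
  }
  keep <- rowMeans(ab) > 0.5
  if (!any(keep)) {
    warning("no probe above background in over 50% of samples; empty result")
    return(matrix(numeric(0), 0L, length(sample_cols),
                  dimnames = list(NULL, sample_cols)))
  }
  probes <- probes[keep, , drop = FALSE]
  intensity <- intensity[keep, , drop = FALSE]
  mu <- rowMeans(intensity)
  ord <- order(probes$gene, -mu, probes$probe_id)
  first <- !duplicated(probes$gene[ord])
  pick <- ord[first]
  out <- intensity[pick, , drop = FALSE]
  rownames(out) <- probes$gene[pick]
  out
}

#' Normalize a region-by-gene expression matrix
#'
#' Z-scores every gene column across regions (mean 0, SD 1); constant genes
#' are dropped with a warning.  Normalization preserves each gene's
#' regional ranking.
#'
#' @param m regions x genes numeric matrix.
#' @return normalized matrix (possibly fewer columns).
#' @export
normalize_expression <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop_invalid("need at least 3 regions")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene column(s)", sum(sds == 0)))
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# SIMPLS with a univariate response.  X: n x p (columns centred/scaled
# upstream); y centred internally, never rescaled.
.simpls <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  y <- y - mean(y)
  ssy <- sum(y^2)
  if (ssy == 0) stop_invalid("response is constant")
  s <- crossprod(X, y)
  W <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  V <- matrix(0, p, ncomp)
  qvec <- numeric(ncomp)
  k_done <- 0L
  for (k in seq_len(ncomp)) {
    if (sqrt(sum(s^2)) < 1e-12 * ssy) break
    r <- s
    t <- drop(X %*% r)
    t <- t - mean(t)
    tn <- sqrt(sum(t^2))
    if (tn < 1e-12) break
    t <- t / tn
    r <- r / tn
    q <- sum(y * t)
    if (q < 0) { r <- -r; t <- -t; q <- -q }   # scores correlate + with y
    pl <- crossprod(X, t)
    v <- pl
    if (k > 1L) {
      Vk <- V[, seq_len(k - 1L), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, pl)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    W[, k] <- r
    Tm[, k] <- t
    V[, k] <- v
    qvec[k] <- q
    k_done <- k
  }
  if (k_done == 0L) stop_invalid("response is orthogonal to the predictors")
  seqk <- seq_len(k_done)
  wn <- sqrt(colSums(W[, seqk, drop = FALSE]^2))
  list(weights = sweep(W[, seqk, drop = FALSE], 2L, wn, `/`),
       scores = Tm[, seqk, drop = FALSE],
       expvar = 100 * qvec[seqk]^2 / ssy,
       n_components = k_done)
}

#' Partial least squares regression of a regional map onto gene expression
#'
#' Regresses the centred response map on the region x gene predictor block
#' and reports, per component, a unit-norm gene weight vector, orthonormal
#' region scores, and the percent of response variance explained.
#'
#' @param X regions x genes matrix, gene columns z-scored (see
#'   [normalize_expression()]); rownames are region names.
#' @param y per-region response (named vector or `regional_map` statistic
#'   column); region order must match `X`.
#' @param n_components number of components (at most regions - 1).
#' @return list of class `pls_result`: `weights` (genes x k), `scores`
#'   (regions x k), `expvar` (percent per component), `n_components`,
#'   `genes`.
#' @export
pls_fit <- function(X, y, n_components = 5L) {
  X <- as.matrix(X)
  if (inherits(y, "regional_map")) {
    y <- setNames(y$statistic, y$region)
  }
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!identical(names(y), rownames(X))) {
      stop_invalid("region labels of `X` and `y` are misaligned")
    }
  }
  if (length(y) != nrow(X)) stop_invalid("`y` length must equal nrow(X)")
  n_components <- check_count(n_components, "n_components", min = 1L)
  if (n_components > nrow(X) - 1L) {
    stop_invalid("`n_components` must be at most regions - 1")
  }
  fit <- .simpls(X, as.numeric(y), n_components)
  structure(list(weights = `rownames<-`(fit$weights, colnames(X)),
                 scores = `rownames<-`(fit$scores, rownames(X)),
                 expvar = fit$expvar, n_components = fit$n_components,
                 genes = colnames(X)),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d component(s)\n", x$n_components))
  cat(sprintf("  component %d: %.2f%% of response variance\n",
              seq_len(x$n_components), x$expvar), sep = "")
  invisible(x)
}

#' Bootstrap-normalized gene ranking for the first PLS component
#'
#' Resamples regions (the sampling units of the map) with replacement,
#' refits the first component, aligns each bootstrap weight vector's sign
#' to the original, and normalizes each original gene weight by its
#' bootstrap standard deviation (Z).  Genes are ranked by decreasing Z;
#' direction splits at Z = 0.
#'
#' @inheritParams pls_fit
#' @param n_boot number of bootstrap resamples (>= 2; >= 100 recommended).
#' @param seed integer seed; fixed seeds give bit-reproducible Z.
#' @return `data.frame` of class `ranked_gene_list`, ordered by rank:
#'   `gene`, `weight` (original PLS1 weight), `z`, `rank`, `direction`.
#' @export
bootstrap_gene_ranking <- function(X, y, n_boot = 1000L, seed = 1L) {
  n_boot <- check_count(n_boot, "n_boot", min = 0L)
  if (n_boot < 2L) stop_invalid("`n_boot` must be >= 2 (bootstrap SD undefined)")
  if (n_boot < 100L) warning("`n_boot` < 100 gives unstable Z")
  X <- as.matrix(X)
  if (inherits(y, "regional_map")) y <- setNames(y$statistic, y$region)
  y <- as.numeric(y)
  w0 <- pls_fit(X, y, 1L)$weights[, 1L]
  n <- nrow(X)
  WB <- with_seed(seed, {
    out <- matrix(NA_real_, length(w0), n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (sd(y[idx]) > 0) break
      }
      wb <- .simpls(X[idx, , drop = FALSE], y[idx], 1L)$weights[, 1L]
      if (sum(wb * w0) < 0) wb <- -wb
      out[, b] <- wb
    }
    out
  })
  sdb <- apply(WB, 1L, sd)
  z <- w0 / pmax(sdb, 1e-12)
  ord <- order(-z, names(w0))
  out <- data.frame(gene = names(w0)[ord], weight = unname(w0[ord]),
                    z = unname(z[ord]), rank = seq_along(ord),
                    direction = ifelse(z[ord] >= 0, "upweighted", "downweighted"),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}
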