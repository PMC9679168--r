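# Per-region response maps: partial Spearman correlations of node strength
# with the biomarker, group-by-biomarker interaction estimates, FDR control,
# and t-tests from printed summary statistics.

#' Pooled two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t with df = n1 + n2 - 2, computed from group
#' sizes, means and SDs (for reproducing tests reported only as printed
#' summaries).  The statistic is `(mean2 - mean1) / se`, so it is
#' antisymmetric under swapping the groups.
#'
#' @param n1,mean1,sd1 first group size, mean, SD.
#' @param n2,mean2,sd2 second group size, mean, SD.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
pooled_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop_invalid("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_invalid("SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean2 - mean1) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y` (midranks for ties), residualizes both on the
#' covariates (with intercept), and returns the Pearson correlation of the
#' residuals.  With no covariates this equals the plain Spearman rho.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return partial rho in \[-1, 1\].
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  n <- length(x)
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (length(y) != n || (!is.null(covariates) && nrow(as.matrix(covariates)) != n)) {
    stop_invalid("`x`, `y` and `covariates` must have matching lengths")
  }
  if (n < ncov + 3L) stop_invalid("too few observations for the covariate count")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values must be dropped upstream")
  rx <- midrank(x); ry <- midrank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop_invalid("correlation undefined: constant ranks")
  }
  if (ncov == 0L) return(cor(rx, ry))
  Q <- qr.Q(qr(cbind(1, as.matrix(covariates))))
  ex <- rx - Q %*% crossprod(Q, rx)
  ey <- ry - Q %*% crossprod(Q, ry)
  # ranks fully absorbed by the covariates leave nothing to correlate
  if (sum(ex^2) <= 1e-10 * sum((rx - mean(rx))^2) ||
      sum(ey^2) <= 1e-10 * sum((ry - mean(ry))^2)) {
    return(0)
  }
  drop(crossprod(ex, ey) / sqrt(sum(ex^2) * sum(ey^2)))
}

# Vectorized partial Spearman of each column of `Y` against `x` given
# covariates; returns rho and t-approximation p-values.
.partial_spearman_map <- function(Y, x, covariates) {
  n <- nrow(Y)
  RY <- apply(Y, 2L, midrank)
  rx <- midrank(x)
  Q <- qr.Q(qr(cbind(1, as.matrix(covariates))))
  EY <- RY - Q %*% crossprod(Q, RY)
  ex <- rx - Q %*% crossprod(Q, rx)
  ssy <- colSums(EY^2)
  tot <- colSums(sweep(RY, 2L, colMeans(RY))^2)
  rho <- drop(crossprod(ex, EY)) / sqrt(sum(ex^2) * pmax(ssy, 1e-300))
  rho[ssy <= 1e-10 * pmax(tot, 1e-300)] <- 0
  df <- n - 2L - ncol(as.matrix(covariates))
  tt <- rho * sqrt(df / pmax(1 - rho^2, 1e-12))
  list(rho = rho, p = 2 * pt(-abs(tt), df), df = df, ex = ex, EY = EY, ssy = ssy)
}

#' Regional biomarker association map
#'
#' For each region, the partial Spearman correlation of node strength with
#' the biomarker controlling for age and sex, computed over one group
#' (carriers by default, matching the primary analysis; controls or the
#' whole cohort are available as negative controls).  P-values use the
#' t-approximation for partial rank correlation (a permutation option is
#' provided); q-values are Benjamini-Hochberg across regions.
#'
#' @param strengths subjects x regions matrix of node strengths.
#' @param cohort `cohort_table` aligned with `strengths` rows.
#' @param group "carrier", "control" or "all".
#' @param p_method "t" (t-approximation) or "permutation".
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param seed seed for the permutation option.
#' @return `data.frame` of class `regional_map` (columns `region`,
#'   `statistic`, `p`, `q`) with attribute `map_kind = "partial_correlation"`.
#' @export
roi_association_map <- function(strengths, cohort, group = "carrier",
                                p_method = c("t", "permutation"),
                                n_perm = 999L, seed = 1L) {
  p_method <- match.arg(p_method)
  keep <- !is.na(cohort$csf_nfl) &
    if (group == "all") TRUE else cohort$group == group
  if (sum(keep) < 10L) warning("fewer than 10 usable subjects for the association map")
  Y <- strengths[keep, , drop = FALSE]
  cov <- cbind(age = cohort$age[keep], sex = as.numeric(cohort$sex[keep] == "M"))
  res <- .partial_spearman_map(Y, cohort$csf_nfl[keep], cov)
  p <- res$p
  if (p_method == "permutation") {
    p <- with_seed(seed, {
      exceed <- rep(1, ncol(Y))
      for (b in seq_len(n_perm)) {
        exb <- res$ex[sample.int(nrow(Y))]
        rhob <- drop(crossprod(exb, res$EY)) / sqrt(sum(exb^2) * res$ssy)
        exceed <- exceed + (abs(rhob) >= abs(res$rho))
      }
      exceed / (1 + n_perm)
    })
  }
  out <- data.frame(region = colnames(strengths), statistic = res$rho,
                    p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
  attr(out, "map_kind") <- "partial_correlation"
  class(out) <- c("regional_map", "data.frame")
  out
}

#' Regional group-by-biomarker interaction map
#'
#' Per-region ordinary-least-squares fit of node strength on intercept, age,
#' sex, group, biomarker and group x biomarker; the interaction coefficient
#' is the map statistic (strength units per pg/ml), its t statistic gives
#' the p-value, and q-values are Benjamini-Hochberg across regions.
#'
#' @inheritParams roi_association_map
#' @return `data.frame` of class `regional_map` with attribute
#'   `map_kind = "interaction"`.
#' @export
roi_interaction_map <- function(strengths, cohort) {
  keep <- !is.na(cohort$csf_nfl)
  Y <- strengths[keep, , drop = FALSE]
  co <- cohort[keep, , drop = FALSE]
  for (g in c("control", "carrier")) {
    if (sum(co$group == g) < 2L || sd(co$csf_nfl[co$group == g]) == 0) {
      stop_invalid("both groups need varying biomarker values")
    }
  }
  grp <- as.numeric(co$group == "carrier")
  X <- cbind(intercept = 1, age = co$age, sex = as.numeric(co$sex == "M"),
             group = grp, nfl = co$csf_nfl, group_nfl = grp * co$csf_nfl)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_invalid("singular interaction design")
  XtXi <- chol2inv(qr.R(qrX))
  B <- qr.coef(qrX, Y)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  j <- which(colnames(X) == "group_nfl")
  se <- sqrt(sigma2 * XtXi[j, j])
  beta <- B[j, ]
  tt <- ifelse(se > 0, beta / se, 0)
  p <- 2 * pt(-abs(tt), df)
  beta[se == 0] <- 0
  out <- data.frame(region = colnames(strengths), statistic = beta,
                    p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
  attr(out, "map_kind") <- "interaction"
  class(out) <- c("regional_map", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Write a regional map as TSV
#'
#' @param map a `regional_map`.
#' @param path output path.
#' @export
write_regional_map_tsv <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
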