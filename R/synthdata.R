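# Seeded generators for atlases, cohorts, connectomes, expression matrices
# and cell-type references.  These emulate the statistical structure the
# downstream analyses assume (two-group cohort with a skewed biomarker,
# connectomes with an optional biomarker-coupled subnetwork, spatially
# autocorrelated expression maps), so every stage can be exercised and
# validated offline.

.network_labels <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn",
                     "Limbic", "Cont", "Default")

.cell_type_labels <- c("Glutamatergic", "GABAergic", "Astrocyte",
                       "Microglia", "Oligodendrocyte", "OPC",
                       "Endothelial", "Pericyte", "VLMC")

#' Generate a synthetic brain atlas
#'
#' Builds a labelled parcellation of cortical plus subcortical regions with
#' 3-D centroids in mm (R: left to right, A: posterior to anterior,
#' S: inferior to superior).  Cortical centroids are sampled uniformly on a
#' per-hemisphere sphere (so they are exactly projectable for spin tests);
#' subcortical centroids sit near the midline interior.  Network labels are
#' assigned cyclically from a fixed resting-state-style label set.
#'
#' @param n_cortical even number of cortical regions, split equally across
#'   hemispheres (the analyses in this package use 100 or 500).
#' @param n_subcortical number of subcortical (striatal) regions.
#' @param seed integer seed; identical seeds give identical atlases.
#' @return A `data.frame` of class `atlas_info` with columns `roi_id`
#'   (0-based, contiguous), `name`, `hemisphere` ("L"/"R"), `tissue`
#'   ("cortical"/"subcortical"), `network`, and centroid coordinates
#'   `R`, `A`, `S`.
#' @export
generate_atlas <- function(n_cortical = 100, n_subcortical = 14, seed = 1L) {
  n_cortical <- check_count(n_cortical, "n_cortical", min = 2L)
  n_subcortical <- check_count(n_subcortical, "n_subcortical", min = 0L)
  if (n_cortical %% 2L != 0L) {
    stop_invalid("`n_cortical` must be even (regions are split across hemispheres)")
  }
  n_hemi <- n_cortical %/% 2L
  with_seed(seed, {
    sphere <- function(n, center) {
      u <- matrix(rnorm(3L * n), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      sweep(55 * u, 2L, center, `+`)
    }
    cent_L <- sphere(n_hemi, c(-35, -20, 20))
    cent_R <- sphere(n_hemi, c(35, -20, 20))
    sub_hemi <- rep(c("L", "R"), length.out = n_subcortical)
    cent_S <- cbind(
      R = ifelse(sub_hemi == "L", -1, 1) * runif(n_subcortical, 8, 16),
      A = runif(n_subcortical, -5, 20),
      S = runif(n_subcortical, -10, 12)
    )
    hemi <- c(rep("L", n_hemi), rep("R", n_hemi), sub_hemi)
    tissue <- c(rep("cortical", n_cortical), rep("subcortical", n_subcortical))
    network <- c(
      rep_len(.network_labels, n_hemi),
      rep_len(.network_labels, n_hemi),
      if (n_subcortical > 0L) rep_len(.network_labels, n_subcortical) else character(0)
    )
    coords <- rbind(cent_L, cent_R,
                    if (n_subcortical > 0L) cent_S else NULL)
    colnames(coords) <- c("R", "A", "S")
    idx_within <- c(seq_len(n_hemi), seq_len(n_hemi), seq_len(n_subcortical))
    name <- sprintf("%s_%s_%s_%03d",
                    ifelse(tissue == "cortical", "ctx", "str"),
                    hemi, network, idx_within)
    atlas <- data.frame(
      roi_id = seq_len(n_cortical + n_subcortical) - 1L,
      name = name, hemisphere = hemi, tissue = tissue, network = network,
      R = coords[, "R"], A = coords[, "A"], S = coords[, "S"],
      stringsAsFactors = FALSE
    )
    stopifnot(!anyDuplicated(atlas$name))
    class(atlas) <- c("atlas_info", "data.frame")
    atlas
  })
}

#' Generate a synthetic two-group cohort
#'
#' Draws a control/carrier cohort with CSF biomarker levels (pg/ml) from
#' zero-truncated normal distributions (values are redrawn until positive,
#' since concentrations cannot be negative), and ages and sexes balanced
#' across groups.
#'
#' @param n_control,n_carrier group sizes.
#' @param nfl_params list with elements `control` and `carrier`, each
#'   `c(mean, sd)` in pg/ml.  Defaults are the study conditions this package
#'   emulates: controls mean 354, SD 261; carriers mean 767, SD 585.
#' @param age_params `c(mean, sd)` in years, shared by both groups.
#' @param prop_missing_nfl proportion of subjects with missing biomarker
#'   values (excluded from biomarker analyses downstream).
#' @param seed integer seed.
#' @return A `data.frame` of class `cohort_table` with columns `subject_id`,
#'   `group` ("control"/"carrier"), `age`, `sex` ("F"/"M"), `csf_nfl`.
#' @export
generate_cohort <- function(n_control = 41, n_carrier = 46,
                            nfl_params = list(control = c(mean = 354, sd = 261),
                                              carrier = c(mean = 767, sd = 585)),
                            age_params = c(mean = 29, sd = 5.65),
                            prop_missing_nfl = 0, seed = 1L) {
  n_control <- check_count(n_control, "n_control")
  n_carrier <- check_count(n_carrier, "n_carrier")
  for (g in c("control", "carrier")) {
    if (!all(c("mean", "sd") %in% names(nfl_params[[g]])) ||
        nfl_params[[g]][["sd"]] <= 0) {
      stop_invalid("`nfl_params` must give a positive sd for each group")
    }
  }
  with_seed(seed, {
    rtrunc_pos <- function(n, mean, sd) {
      x <- rnorm(n, mean, sd)
      while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
      x
    }
    draw_group <- function(n, group) {
      if (n == 0L) return(NULL)
      p <- nfl_params[[group]]
      data.frame(
        group = group,
        age = rnorm(n, age_params[["mean"]], age_params[["sd"]]),
        sex = rep_len(c("F", "M"), n),
        csf_nfl = rtrunc_pos(n, p[["mean"]], p[["sd"]]),
        stringsAsFactors = FALSE
      )
    }
    cohort <- rbind(draw_group(n_control, "control"),
                    draw_group(n_carrier, "carrier"))
    cohort$subject_id <- sprintf("sub-%03d", seq_len(nrow(cohort)))
    if (prop_missing_nfl > 0) {
      miss <- sample.int(nrow(cohort), round(prop_missing_nfl * nrow(cohort)))
      cohort$csf_nfl[miss] <- NA_real_
    }
    cohort <- cohort[, c("subject_id", "group", "age", "sex", "csf_nfl")]
    class(cohort) <- c("cohort_table", "data.frame")
    cohort
  })
}

#' Specify planted effects for the synthetic generators
#'
#' Collects the parameters that control what structure is planted into
#' synthetic connectomes and expression matrices.
#'
#' @param planted_edges 2-column integer matrix of region pairs (1-based
#'   matrix indices) forming the biomarker-coupled subnetwork, or `NULL`.
#' @param coupling slope of functional edge weight per pg/ml of the
#'   biomarker on planted edges.
#' @param coupling_group `"carrier"` (coupling acts in carriers only,
#'   centred at the carrier mean) or `"all"` (whole cohort, centred at the
#'   cohort mean).  Both are exposed because neither is asserted as the
#'   generative truth.
#' @param edge_noise_sd additional noise SD on planted edges (weight units).
#' @param expression_autocorr_length length-scale (mm) of the
#'   squared-exponential spatial kernel used for gene expression maps.
#' @param n_planted_genes number of genes tracking the response map.
#' @param planted_gene_effect target correlation of planted-gene expression
#'   with the response map, in \[0, 1\].
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(planted_edges = NULL, coupling = 0,
                        coupling_group = c("carrier", "all"),
                        edge_noise_sd = 0.05,
                        expression_autocorr_length = 20,
                        n_planted_genes = 0L, planted_gene_effect = 0) {
  coupling_group <- match.arg(coupling_group)
  if (!is.finite(coupling) || !is.finite(edge_noise_sd) || edge_noise_sd < 0) {
    stop_invalid("`coupling` must be finite and `edge_noise_sd` finite and >= 0")
  }
  if (expression_autocorr_length < 0) {
    stop_invalid("`expression_autocorr_length` must be >= 0")
  }
  if (abs(planted_gene_effect) > 1) {
    stop_invalid("`planted_gene_effect` must lie in [-1, 1]")
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (ncol(planted_edges) != 2L || any(planted_edges[, 1] == planted_edges[, 2])) {
      stop_invalid("`planted_edges` must be a 2-column matrix of distinct region pairs")
    }
  }
  structure(list(planted_edges = planted_edges, coupling = coupling,
                 coupling_group = coupling_group, edge_noise_sd = edge_noise_sd,
                 expression_autocorr_length = expression_autocorr_length,
                 n_planted_genes = check_count(n_planted_genes, "n_planted_genes"),
                 planted_gene_effect = planted_gene_effect),
            class = "effect_spec")
}

#' Sample a connected subnetwork of atlas regions
#'
#' Grows a connected edge set by preferentially attaching new edges to
#' regions already in the subnetwork; used to define planted
#' biomarker-coupled subnetworks that the network-based statistic should
#' recover as a single component.
#'
#' @param atlas an `atlas_info` table.
#' @param n_edges number of edges.
#' @param tissue tissue type(s) to draw regions from.
#' @param seed integer seed.
#' @return 2-column integer matrix of edges (1-based matrix indices, i < j).
#' @export
plant_subnetwork <- function(atlas, n_edges = 20L, tissue = "cortical", seed = 1L) {
  n_edges <- check_count(n_edges, "n_edges", min = 1L)
  pool <- which(atlas$tissue %in% tissue)
  if (length(pool) < 3L) stop_invalid("not enough regions in the requested tissue")
  with_seed(seed, {
    nodes <- sample(pool, 1L)
    edges <- matrix(integer(0), 0L, 2L)
    seen <- character(0)
    while (nrow(edges) < n_edges) {
      a <- nodes[sample.int(length(nodes), 1L)]
      b <- if (runif(1) < 0.7 || length(nodes) < 3L) {
        sample(setdiff(pool, nodes), 1L)
      } else {
        sample(setdiff(nodes, a), 1L)
      }
      key <- paste(min(a, b), max(a, b))
      if (key %in% seen) next
      seen <- c(seen, key)
      edges <- rbind(edges, c(min(a, b), max(a, b)))
      nodes <- union(nodes, b)
    }
    colnames(edges) <- c("i", "j")
    edges
  })
}

#' Generate synthetic structural and functional connectomes
#'
#' Structural weights are nonnegative with a distance-decaying expectation;
#' functional baseline weights are correlation-like (tanh of a Gaussian
#' field shared across subjects plus subject noise).  On planted edges the
#' functional weight additionally carries `coupling * (NfL - group mean)`
#' plus noise, so the planted subnetwork covaries with the biomarker.
#'
#' @param cohort a `cohort_table`.
#' @param atlas an `atlas_info` table.
#' @param effect an [effect_spec()].
#' @param seed integer seed.
#' @return Named list (by `subject_id`) of lists with elements `functional`
#'   and `structural`, each a connectome (see [as_connectome()]).
#' @export
generate_connectomes <- function(cohort, atlas, effect = effect_spec(), seed = 1L) {
  n <- nrow(atlas)
  if (!is.null(effect$planted_edges) && any(effect$planted_edges > n)) {
    stop_invalid("`planted_edges` reference regions outside the atlas")
  }
  if (effect$coupling != 0 && anyNA(cohort$csf_nfl)) {
    stop_invalid("cohort has missing biomarker values but `coupling` != 0")
  }
  edges <- ut_edges(n)
  n_e <- nrow(edges)
  cent <- as.matrix(atlas[, c("R", "A", "S")])
  D <- as.matrix(stats::dist(cent))
  d_e <- D[upper.tri(D)]
  dn <- list(atlas$name, atlas$name)
  planted_idx <- integer(0)
  if (!is.null(effect$planted_edges)) {
    pe <- effect$planted_edges
    key_all <- paste(edges[, 1], edges[, 2])
    planted_idx <- match(paste(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2])), key_all)
  }
  with_seed(seed, {
    base_str <- exp(-d_e / 40)
    g0 <- rnorm(n_e, 0, 0.5)                 # shared functional field
    nfl <- cohort$csf_nfl
    centred <- switch(effect$coupling_group,
      carrier = ifelse(cohort$group == "carrier",
                       nfl - mean(nfl[cohort$group == "carrier"]), 0),
      all = nfl - mean(nfl))
    out <- vector("list", nrow(cohort))
    names(out) <- cohort$subject_id
    for (s in seq_len(nrow(cohort))) {
      w_str <- base_str * exp(rnorm(n_e, 0, 0.3))
      w_fun <- tanh(g0 + rnorm(n_e, 0, 0.35))
      if (length(planted_idx) > 0L && effect$coupling != 0) {
        w_fun[planted_idx] <- w_fun[planted_idx] +
          effect$coupling * centred[s] +
          rnorm(length(planted_idx), 0, effect$edge_noise_sd)
      }
      out[[s]] <- list(
        functional = as_connectome(ut_unvec(w_fun, n, dn), "functional"),
        structural = as_connectome(ut_unvec(w_str, n, dn), "structural")
      )
    }
    out
  })
}

# Cholesky factor of the squared-exponential kernel over centroids
.spatial_chol <- function(atlas, length_scale) {
  n <- nrow(atlas)
  if (length_scale <= 0) return(diag(n))
  D <- as.matrix(stats::dist(as.matrix(atlas[, c("R", "A", "S")])))
  K <- exp(-D^2 / (2 * length_scale^2))
  chol(K + diag(1e-6, n))
}

#' Generate a spatially smooth map over atlas regions
#'
#' One draw from a zero-mean Gaussian process over region centroids with a
#' squared-exponential kernel; used as a response map for planted-gene
#' simulations.
#'
#' @param atlas an `atlas_info` table.
#' @param autocorr_length kernel length-scale in mm (0 gives iid noise).
#' @param seed integer seed.
#' @return numeric vector, one value per region, named by region.
#' @export
generate_smooth_map <- function(atlas, autocorr_length = 20, seed = 1L) {
  L <- .spatial_chol(atlas, autocorr_length)
  with_seed(seed, {
    v <- drop(t(L) %*% rnorm(nrow(atlas)))
    names(v) <- atlas$name
    v
  })
}

#' Generate a synthetic region-by-gene expression matrix
#'
#' Non-planted genes are independent draws from a spatial Gaussian process
#' over region centroids (squared-exponential kernel with length-scale
#' `effect$expression_autocorr_length`); planted genes are mixtures
#' `rho * response_map + sqrt(1 - rho^2) * GP` with `rho =
#' effect$planted_gene_effect`, so they track the response map at the
#' requested correlation while staying spatially smooth.  Per-gene
#' transcript length and GC fraction are drawn from broad positive
#' distributions for use by the cell-type enrichment bootstrap.
#'
#' @param atlas an `atlas_info` table.
#' @param n_genes number of genes.
#' @param effect an [effect_spec()].
#' @param response_map per-region vector the planted genes should track
#'   (required when `effect$n_planted_genes > 0`).
#' @param seed integer seed.
#' @return list with `expression` (regions x genes matrix, dimnames set) and
#'   `meta` (`data.frame`: gene, transcript_length, gc, planted).
#' @export
generate_expression <- function(atlas, n_genes = 2000L, effect = effect_spec(),
                                response_map = NULL, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  if (n_genes < effect$n_planted_genes) {
    stop_invalid("`n_genes` is smaller than the number of planted genes")
  }
  n <- nrow(atlas)
  if (effect$n_planted_genes > 0L) {
    if (is.null(response_map) || length(response_map) != n) {
      stop_invalid("`response_map` of length nrow(atlas) required for planted genes")
    }
  }
  L <- .spatial_chol(atlas, effect$expression_autocorr_length)
  with_seed(seed, {
    Z <- matrix(rnorm(n * n_genes), n, n_genes)
    X <- crossprod(L, Z)                       # each column a GP draw
    genes <- sprintf("g%05d", seq_len(n_genes))
    planted <- rep(FALSE, n_genes)
    if (effect$n_planted_genes > 0L) {
      pick <- sample.int(n_genes, effect$n_planted_genes)
      planted[pick] <- TRUE
      rho <- effect$planted_gene_effect
      ym <- as.numeric(scale(response_map))
      for (g in pick) {
        X[, g] <- rho * ym + sqrt(1 - rho^2) * as.numeric(scale(X[, g]))
      }
    }
    gene_mean <- rnorm(n_genes, 8, 2)
    gene_sd <- runif(n_genes, 0.5, 2)
    expr <- sweep(sweep(X, 2L, gene_sd, `*`), 2L, gene_mean, `+`)
    dimnames(expr) <- list(atlas$name, genes)
    meta <- data.frame(
      gene = genes,
      transcript_length = round(rlnorm(n_genes, log(2500), 0.8)) + 200,
      gc = rbeta(n_genes, 9, 11),
      planted = planted,
      stringsAsFactors = FALSE
    )
    list(expression = expr, meta = meta)
  })
}

#' Generate a synthetic cell-type mean-expression reference
#'
#' Assigns marker genes to each cell type and elevates their mean expression
#' in that type, so the derived specificity matrix recovers the markers.
#'
#' @param meta gene metadata as returned by [generate_expression()].
#' @param cell_types character vector of unique cell-type labels; defaults
#'   to nine major classes (glutamatergic, GABAergic, astrocyte, microglia,
#'   oligodendrocyte, OPC, endothelial, pericyte, VLMC).
#' @param n_markers_per_type markers per cell type.
#' @param marker_fold fold elevation of marker expression in the assigned
#'   type (1 gives no elevation, i.e. a null reference).
#' @param marker_pools optional named list (cell type -> gene vector):
#'   markers for those types are drawn from the given pool where possible.
#'   Lets a simulated study couple, e.g., response-tracking genes to one
#'   neuronal class so the enrichment stage has a recoverable signal.
#' @param seed integer seed.
#' @return cell-type x gene matrix of nonnegative mean expression with a
#'   `markers` attribute (`data.frame`: gene, cell_type).
#' @export
generate_celltype_reference <- function(meta, cell_types = .cell_type_labels,
                                        n_markers_per_type = 25L,
                                        marker_fold = 5, marker_pools = NULL,
                                        seed = 1L) {
  if (anyDuplicated(cell_types)) stop_invalid("cell-type labels must be unique")
  n_markers_per_type <- check_count(n_markers_per_type, "n_markers_per_type")
  genes <- meta$gene
  if (n_markers_per_type * length(cell_types) > length(genes)) {
    stop_invalid("not enough genes for the requested number of markers")
  }
  with_seed(seed, {
    ref <- matrix(rlnorm(length(cell_types) * length(genes), 1, 0.5),
                  nrow = length(cell_types),
                  dimnames = list(cell_types, genes))
    available <- genes
    marker_genes <- character(0)
    marker_type <- character(0)
    for (ct in cell_types) {
      pool <- intersect(marker_pools[[ct]] %||% character(0), available)
      take <- if (length(pool) >= n_markers_per_type) {
        sample(pool, n_markers_per_type)
      } else {
        c(pool, sample(setdiff(available, pool),
                       n_markers_per_type - length(pool)))
      }
      marker_genes <- c(marker_genes, take)
      marker_type <- c(marker_type, rep(ct, n_markers_per_type))
      available <- setdiff(available, take)
    }
    # elevate each marker to marker_fold times its mean expression in the
    # other types, so marker specificity is fold / (fold + K - 1) by
    # construction (uniform 1/K when marker_fold = 1)
    for (k in seq_along(marker_genes)) {
      others <- setdiff(cell_types, marker_type[k])
      ref[marker_type[k], marker_genes[k]] <-
        marker_fold * mean(ref[others, marker_genes[k]])
    }
    attr(ref, "markers") <- data.frame(gene = marker_genes,
                                       cell_type = marker_type,
                                       stringsAsFactors = FALSE)
    ref
  })
}
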