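# End-to-end orchestration: configuration, the biomarker subgroup split,
# and a deterministic multi-stage run with a machine-readable manifest.

#' Default run configuration
#'
#' Returns the nested configuration the pipeline consumes.  The `synth`
#' block holds the generator parameters (defaults are the study conditions
#' this package emulates: 100 + 14 regions, 41 controls + 46 carriers,
#' biomarker means/SDs 354/261 and 767/585 pg/ml); `params` holds the
#' per-stage analysis parameters (primary threshold 3.1; permutation and
#' bootstrap counts at demonstration scale — raise them for full runs);
#' `stages` toggles stages; `demographics` carries printed group summaries
#' reproduced via [pooled_t_from_summary()].
#'
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synth = list(
      n_cortical = 100L, n_subcortical = 14L,
      n_control = 41L, n_carrier = 46L,
      nfl_control = list(mean = 354, sd = 261),
      nfl_carrier = list(mean = 767, sd = 585),
      n_genes = 2000L,
      n_planted_edges = 20L, coupling = 0.002, coupling_group = "carrier",
      edge_noise_sd = 0.05,
      expression_autocorr_length = 20,
      n_planted_genes = 100L, planted_gene_effect = 0.8
    ),
    stages = list(connectome = TRUE, nbs = TRUE, maps = TRUE,
                  pls = TRUE, enrich = TRUE),
    params = list(
      t_threshold = 3.1, n_perm_nbs = 1000L, n_perm_density = 1000L,
      n_spins = 500L, n_components = 5L, n_boot_pls = 500L,
      n_boot_ewce = 5000L, n_perm_candidate = 5000L,
      nfl_split_percentile = 95, target_pct = 10
    ),
    demographics = list(
      nfl = list(n1 = 41, mean1 = 354, sd1 = 261,
                 n2 = 46, mean2 = 767, sd2 = 585),
      age = list(n1 = 41, mean1 = 28.61, sd1 = 5.68,
                 n2 = 46, mean2 = 29.46, sd2 = 5.62)
    )
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip unchanged through file.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config(cfg$seed %||% 1L))
  for (blk in intersect(names(base), names(cfg))) {
    if (is.list(base[[blk]])) {
      for (k in names(cfg[[blk]])) base[[blk]][[k]] <- cfg[[blk]][[k]]
    } else {
      base[[blk]] <- cfg[[blk]]
    }
  }
  structure(base, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split carriers into biomarker subgroups at a control percentile
#'
#' The threshold is the stated percentile of the control biomarker values
#' (linear interpolation); carriers strictly below it are labelled "low",
#' the rest "high" (mirroring a pathological-threshold split at the 95th
#' percentile of controls).
#'
#' @param cohort a `cohort_table`.
#' @param percentile percentile of control values, in (0, 100\].
#' @return the cohort with an `nfl_subgroup` column (NA for controls) and a
#'   `threshold` attribute.
#' @export
split_by_nfl_percentile <- function(cohort, percentile = 95) {
  ctrl <- cohort$csf_nfl[cohort$group == "control" & !is.na(cohort$csf_nfl)]
  if (length(ctrl) == 0L) stop_invalid("no controls with biomarker values")
  thr <- unname(quantile(ctrl, percentile / 100, type = 7))
  sub <- rep(NA_character_, nrow(cohort))
  carrier <- cohort$group == "carrier" & !is.na(cohort$csf_nfl)
  sub[carrier] <- ifelse(cohort$csf_nfl[carrier] < thr, "low", "high")
  cohort$nfl_subgroup <- sub
  attr(cohort, "threshold") <- thr
  cohort
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in order — synthetic data, connectome summaries and
#' density tests, network-based statistic on the biomarker contrast,
#' regional association map, PLS with spin nulls and bootstrap gene
#' ranking, and enrichment analyses — writing stage outputs and a JSON
#' manifest with seeds, parameters and headline numbers to `out_dir`.
#' Re-running with the same configuration reproduces the manifest
#' bit-for-bit.  A stage failure aborts with the stage name.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param annotation optional named list of term gene sets for
#'   over-representation (e.g. [read_gmt()]); skipped when `NULL`.
#' @return invisibly, a list with all stage objects and the manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         annotation = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  sy <- config$synth
  pa <- config$params
  manifest <- list(package = "connectogene",
                   version = as.character(packageVersion("connectogene")),
                   seed = seed, synth = sy, params = pa)
  res <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## --- synthetic data ------------------------------------------------
  res$atlas <- run_stage("synth", {
    generate_atlas(sy$n_cortical, sy$n_subcortical, seed = derive_seed(seed, "atlas"))
  })
  res$cohort <- run_stage("synth", {
    generate_cohort(sy$n_control, sy$n_carrier,
                    nfl_params = list(control = sy$nfl_control,
                                      carrier = sy$nfl_carrier),
                    seed = derive_seed(seed, "cohort"))
  })
  planted_edges <- run_stage("synth", {
    if (sy$n_planted_edges > 0L) {
      plant_subnetwork(res$atlas, sy$n_planted_edges,
                       seed = derive_seed(seed, "edges"))
    } else NULL
  })
  effect <- effect_spec(planted_edges = planted_edges, coupling = sy$coupling,
                        coupling_group = sy$coupling_group,
                        edge_noise_sd = sy$edge_noise_sd,
                        expression_autocorr_length = sy$expression_autocorr_length,
                        n_planted_genes = sy$n_planted_genes,
                        planted_gene_effect = sy$planted_gene_effect)
  res$connectomes <- run_stage("synth", {
    generate_connectomes(res$cohort, res$atlas, effect,
                         seed = derive_seed(seed, "connectomes"))
  })
  write_atlas_tsv(res$atlas, file.path(out_dir, "atlas.tsv"))
  write_cohort_tsv(res$cohort, file.path(out_dir, "cohort.tsv"))

  ## --- demographics from printed summaries ---------------------------
  manifest$demographics <- lapply(config$demographics, function(d) {
    r <- do.call(pooled_t_from_summary, d)
    list(t = r$t, df = r$df, p = r$p)
  })

  ## --- subgroup split -------------------------------------------------
  res$cohort <- split_by_nfl_percentile(res$cohort, pa$nfl_split_percentile)
  manifest$nfl_split <- list(
    percentile = pa$nfl_split_percentile,
    threshold = attr(res$cohort, "threshold"),
    n_low = sum(res$cohort$nfl_subgroup == "low", na.rm = TRUE),
    n_high = sum(res$cohort$nfl_subgroup == "high", na.rm = TRUE))

  ## --- connectome summaries -------------------------------------------
  if (isTRUE(config$stages$connectome)) {
    manifest$density <- run_stage("connectome", {
      lapply(setNames(nm = c("functional", "structural")), function(mod) {
        dt <- density_group_test(res$connectomes, res$cohort, modality = mod,
                                 n_perm = pa$n_perm_density,
                                 seed = derive_seed(seed, paste0("density_", mod)))
        list(t = dt$t_obs, p = dt$p, mean_density = mean(dt$densities))
      })
    })
  }

  ## --- network-based statistic ----------------------------------------
  if (isTRUE(config$stages$nbs)) {
    res$nbs <- run_stage("nbs", {
      carriers <- res$cohort$group == "carrier" & !is.na(res$cohort$csf_nfl)
      design <- data.frame(age = res$cohort$age[carriers],
                           sex = as.numeric(res$cohort$sex[carriers] == "M"),
                           nfl = res$cohort$csf_nfl[carriers])
      nbs_test(res$connectomes[carriers], design, contrast = "nfl",
               direction = "pos", t_threshold = pa$t_threshold,
               n_perm = pa$n_perm_nbs, seed = derive_seed(seed, "nbs"))
    })
    manifest$nbs <- list(
      n_components = length(res$nbs$component_size),
      min_fwe_p = if (length(res$nbs$fwe_p)) min(res$nbs$fwe_p) else NA,
      largest_component_edges = if (length(res$nbs$component_size))
        max(res$nbs$component_size) else 0L)
    if (length(res$nbs$component_size) > 0L) {
      best <- res$nbs$components[[which.min(res$nbs$fwe_p)]]
      cls <- classify_connections(best, res$atlas)
      manifest$nbs$class_proportions <- as.list(round(cls$proportions, 4))
      if (!is.null(planted_edges)) {
        manifest$nbs$jaccard_planted <- edge_jaccard(best, planted_edges)
      }
      tab <- data.frame(region_a = res$atlas$name[best[, 1]],
                        region_b = res$atlas$name[best[, 2]],
                        t = attr(best, "t"))
      write.table(tab, file.path(out_dir, "nbs_component.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  ## --- regional maps ----------------------------------------------------
  if (isTRUE(config$stages$maps)) {
    res$map <- run_stage("maps", {
      strengths <- t(vapply(res$connectomes,
                            function(s) node_strength(s$functional),
                            numeric(nrow(res$atlas))))
      colnames(strengths) <- res$atlas$name
      roi_association_map(strengths, res$cohort, group = "carrier")
    })
    write_regional_map_tsv(res$map, file.path(out_dir, "regional_map.tsv"))
    manifest$regional_map <- list(
      n_p05 = sum(res$map$p < 0.05), n_q05 = sum(res$map$q < 0.05),
      top_region = res$map$region[which.min(res$map$q)],
      max_abs_rho = max(abs(res$map$statistic)))
  }

  ## --- PLS and gene ranking ---------------------------------------------
  if (isTRUE(config$stages$pls)) {
    if (is.null(res$map)) stop_invalid("stage 'pls' requires the maps stage")
    expr_raw <- run_stage("synth", {
      generate_expression(res$atlas, sy$n_genes, effect,
                          response_map = setNames(res$map$statistic, res$map$region),
                          seed = derive_seed(seed, "expression"))
    })
    res$expression <- normalize_expression(expr_raw$expression)
    res$gene_meta <- expr_raw$meta
    res$pls <- run_stage("pls", {
      spins <- generate_spins(res$atlas, n_perm = pa$n_spins,
                              seed = derive_seed(seed, "spins"))
      nulls <- spin_pls_nulls(res$expression, res$map, spins, pa$n_components)
      comp <- component_significance(res$expression, res$map, spins,
                                     pa$n_components, nulls = nulls)
      ranked <- bootstrap_gene_ranking(res$expression, res$map,
                                       n_boot = pa$n_boot_pls,
                                       seed = derive_seed(seed, "boot"))
      fit <- pls_fit(res$expression, res$map, pa$n_components)
      gsig <- gene_significance(fit$weights[, 1L], nulls$w1_null)
      topo <- spatial_topography(fit$scores[, 1L], res$atlas)
      list(fit = fit, comp = comp, ranked = ranked, gsig = gsig, topo = topo)
    })
    ranked_out <- merge(res$pls$ranked,
                        res$pls$gsig[, c("gene", "q", "significant")],
                        by = "gene", sort = FALSE)
    ranked_out <- ranked_out[order(ranked_out$rank), ]
    write.table(ranked_out, file.path(out_dir, "ranked_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$pls <- list(
      expvar = res$pls$fit$expvar,
      component_p = res$pls$comp$p,
      n_significant_up = sum(res$pls$gsig$significant &
                               res$pls$gsig$direction == "upweighted"),
      n_significant_down = sum(res$pls$gsig$significant &
                                 res$pls$gsig$direction == "downweighted"),
      topography = setNames(as.list(res$pls$topo$rho), res$pls$topo$axis))
    if (any(res$gene_meta$planted)) {
      top_decile <- res$pls$ranked$gene[res$pls$ranked$rank <=
                                          ceiling(0.1 * nrow(res$pls$ranked))]
      planted <- res$gene_meta$gene[res$gene_meta$planted]
      manifest$pls$planted_top_decile_frac <-
        mean(planted %in% top_decile)
    }
  }

  ## --- enrichment --------------------------------------------------------
  if (isTRUE(config$stages$enrich)) {
    if (is.null(res$pls)) {
      message("enrichment stage skipped: PLS stage disabled")
    } else {
      res$enrich <- run_stage("enrich", {
        ranked <- res$pls$ranked
        n_top <- ceiling(pa$target_pct / 100 * nrow(ranked))
        top_genes <- ranked$gene[seq_len(n_top)]
        pools <- if (any(res$gene_meta$planted)) {
          list(Glutamatergic = res$gene_meta$gene[res$gene_meta$planted])
        } else NULL
        ref <- generate_celltype_reference(res$gene_meta, marker_pools = pools,
                                           seed = derive_seed(seed, "celltypes"))
        spec <- specificity_matrix(ref)
        ewce <- ewce_bootstrap(top_genes, spec, res$gene_meta,
                               n_boot = pa$n_boot_ewce,
                               seed = derive_seed(seed, "ewce"))
        cand <- candidate_list_enrichment(
          ranked, res$gene_meta$gene[res$gene_meta$planted],
          n_perm = pa$n_perm_candidate,
          seed = derive_seed(seed, "candidate"), label = "planted_genes")
        ora <- if (!is.null(annotation)) {
          overrepresentation(top_genes, ranked$gene, annotation)
        } else NULL
        list(ewce = ewce, candidate = cand, ora = ora)
      })
      write.table(res$enrich$ewce, file.path(out_dir, "ewce.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$enrichment <- list(
        top_cell_type = res$enrich$ewce$label[1L],
        top_cell_type_p = res$enrich$ewce$p[1L],
        top_cell_type_fold = res$enrich$ewce$fold_change[1L],
        candidate_p = res$enrich$candidate$p)
      if (!is.null(res$enrich$ora)) {
        write.table(res$enrich$ora, file.path(out_dir, "overrepresentation.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
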