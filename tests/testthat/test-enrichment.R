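test_that("over-representation p matches exhaustive enumeration on small universes", {
  set.seed(1)
  for (r in 1:8) {
    background <- sprintf("g%02d", 1:20)
    term <- sample(background, sample(4:10, 1))
    target <- sample(background, 5)
    res <- overrepresentation(target, background, list(T1 = term))
    k <- length(intersect(target, term))
    expect_equal(res$p, enum_hyper_tail(background, term, 5, k),
                 tolerance = 1e-12)
  }
  # term identical to the target within a 2x background
  target <- sprintf("t%d", 1:6)
  background <- c(target, sprintf("b%d", 1:6))
  res <- overrepresentation(target, background, list(hit = target))
  expect_equal(res$p, phyper(5, 6, 6, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p, 1 / choose(12, 6), tolerance = 1e-12)
})

test_that("over-representation drops oversized terms and handles disjoint ones", {
  background <- sprintf("g%04d", 1:1200)
  target <- background[1:20]
  ann <- list(big = background[1:1001],        # > 1000 genes: excluded
              ok = background[1:50],
              disjoint = background[1001:1100])
  res <- overrepresentation(target, background, ann)
  expect_false("big" %in% res$label)
  expect_true(all(c("ok", "disjoint") %in% res$label))
  expect_equal(res$p[res$label == "disjoint"], 1)
  expect_gt(res$fold_change[res$label == "ok"], 1)
  expect_error(overrepresentation(character(0), background, ann), "empty")
  expect_error(overrepresentation("zz", background, ann), "subset")
})

test_that("specificity matrix normalizes rows and flags degenerate genes", {
  ref <- rbind(Astrocyte = c(a = 2, b = 1, c = 0),
               Microglia = c(a = 0, b = 1, c = 0))
  expect_warning(sp <- specificity_matrix(ref), "zero expression")
  expect_equal(unname(sp["a", ]), c(1, 0))
  expect_equal(unname(sp["b", ]), c(0.5, 0.5))
  expect_false("c" %in% rownames(sp))
  # uniform expression over 9 types: specificity 1/9 each
  u <- matrix(3, 9, 4, dimnames = list(paste0("T", 1:9), letters[1:4]))
  expect_equal(unname(specificity_matrix(u)[1, ]), rep(1 / 9, 9))
  set.seed(2)
  rr <- matrix(rexp(50), 5, 10,
               dimnames = list(paste0("T", 1:5), paste0("g", 1:10)))
  expect_equal(unname(rowSums(specificity_matrix(rr))), rep(1, 10))
  expect_error(specificity_matrix(matrix(-1, 2, 2)), "nonnegative")
})

test_that("EWCE bootstrap recovers planted markers and is calibrated on random lists", {
  at <- tiny_atlas()
  ex <- generate_expression(at, 1200, effect_spec(), seed = 3)
  ref <- generate_celltype_reference(ex$meta, n_markers_per_type = 20, seed = 4)
  sp <- specificity_matrix(ref)
  mk <- attr(ref, "markers")
  glut <- mk$gene[mk$cell_type == "Glutamatergic"]
  res <- suppressWarnings(ewce_bootstrap(glut, sp, ex$meta, n_boot = 2000, seed = 5))
  row <- res[res$label == "Glutamatergic", ]
  expect_lt(row$p, 0.05)
  expect_gt(row$fold_change, 1)
  expect_gt(row$sd_from_mean, 2)
  expect_true(all(c("label", "p", "p_adjusted", "fold_change",
                    "sd_from_mean") %in% names(res)))
  # random target lists: mean fold change ~ 1
  set.seed(6)
  folds <- vapply(1:60, function(r) {
    tgt <- sample(ex$meta$gene, 20)
    rr <- suppressWarnings(ewce_bootstrap(tgt, sp, ex$meta, n_boot = 300,
                                          seed = 60 + r))
    mean(rr$fold_change)
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1), 0.05)
  expect_error(ewce_bootstrap(c(glut, "nope"), sp, ex$meta, n_boot = 1000),
               "absent")
  # determinism
  res2 <- suppressWarnings(ewce_bootstrap(glut, sp, ex$meta, n_boot = 2000, seed = 5))
  expect_identical(res, res2)
})

test_that("candidate-list enrichment handles degenerate and relabelled inputs", {
  set.seed(7)
  genes <- sprintf("g%04d", 1:500)
  rk <- data.frame(gene = genes, weight = rnorm(500), z = rnorm(500),
                   rank = 1:500, direction = "upweighted",
                   stringsAsFactors = FALSE)
  class(rk) <- c("ranked_gene_list", "data.frame")
  # candidate = entire ranked list: null sums tie the observed sum exactly
  res_all <- candidate_list_enrichment(rk, genes, n_perm = 200, seed = 8)
  expect_equal(res_all$p, 1)
  # invariance under monotone relabelling of gene identifiers
  res_a <- candidate_list_enrichment(rk, genes[1:40], n_perm = 500, seed = 9)
  rk2 <- rk
  rk2$gene <- sprintf("x%04d", 1:500)
  res_b <- candidate_list_enrichment(rk2, sprintf("x%04d", 1:40),
                                     n_perm = 500, seed = 9)
  expect_equal(res_a$p, res_b$p)
  expect_equal(res_a$observed, res_b$observed)
  # dropped genes are counted; empty intersections error
  expect_message(
    res_d <- candidate_list_enrichment(rk, c(genes[1:10], "absent1", "absent2"),
                                       n_perm = 200, seed = 10),
    "dropped")
  expect_equal(res_d$n_dropped, 2)
  expect_equal(res_d$n_genes, 10)
  expect_error(candidate_list_enrichment(rk, c("q1", "q2"), n_perm = 100),
               "missing")
  # low-side option flips the tail
  res_hi <- candidate_list_enrichment(rk, genes[order(-rk$z)][1:25],
                                      n_perm = 500, seed = 11)
  res_lo <- candidate_list_enrichment(rk, genes[order(-rk$z)][1:25],
                                      n_perm = 500, seed = 11, side = "low")
  expect_lt(res_hi$p, 0.05)
  expect_gt(res_lo$p, 0.9)
})

test_that("GMT and gene-list files round-trip", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("termA\tdesc\tg1\tg2\tg3", "termB\tdesc\tg9"), gmt)
  ann <- read_gmt(gmt)
  expect_equal(ann$termA, c("g1", "g2", "g3"))
  expect_equal(ann$termB, "g9")
  lst <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("BDNF", "", " GRIN1 "), lst)
  expect_equal(read_gene_list(lst), c("BDNF", "GRIN1"))
})
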