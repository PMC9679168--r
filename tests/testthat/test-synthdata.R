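test_that("atlas generation honours counts, hemispheres and determinism", {
  at <- generate_atlas(100, 14, seed = 1)
  expect_equal(nrow(at), 114)
  expect_equal(sum(at$hemisphere == "L" & at$tissue == "cortical"), 50)
  expect_equal(sum(at$hemisphere == "R" & at$tissue == "cortical"), 50)
  expect_equal(sum(at$tissue == "subcortical"), 14)
  expect_equal(at$roi_id, 0:113)
  expect_false(anyDuplicated(at$name) > 0)
  expect_equal(nrow(generate_atlas(500, 14, seed = 1)), 514)
  expect_identical(generate_atlas(100, 14, seed = 3),
                   generate_atlas(100, 14, seed = 3))
  # cortical centroids lie exactly on a common sphere per hemisphere
  # (algebraic least-squares sphere fit leaves no residual)
  for (h in c("L", "R")) {
    cc <- as.matrix(at[at$tissue == "cortical" & at$hemisphere == h,
                       c("R", "A", "S")])
    sol <- qr.solve(cbind(2 * cc, 1), rowSums(cc^2))
    r2 <- sol[4] + sum(sol[1:3]^2)
    expect_lt(max(abs(rowSums(sweep(cc, 2, sol[1:3])^2) - r2)) / r2, 1e-9)
  }
  expect_error(generate_atlas(99, 14), "even")
  expect_error(generate_atlas(-2, 14), "integer")
})

test_that("cohort biomarker draws match the requested group distributions", {
  co <- generate_cohort(41, 46, seed = 7)
  expect_equal(sum(co$group == "control"), 41)
  expect_equal(sum(co$group == "carrier"), 46)
  expect_true(all(co$csf_nfl > 0))
  expect_false(anyDuplicated(co$subject_id) > 0)
  # sample means within 3 standard errors of the generating means
  m_ctrl <- mean(co$csf_nfl[co$group == "control"])
  m_carr <- mean(co$csf_nfl[co$group == "carrier"])
  expect_lt(abs(m_ctrl - 354), 3 * 261 / sqrt(41))
  expect_lt(abs(m_carr - 767), 3 * 585 / sqrt(46))
  only_carr <- generate_cohort(0, 5, seed = 2)
  expect_equal(nrow(only_carr), 5)
  expect_true(all(only_carr$group == "carrier"))
  expect_error(
    generate_cohort(5, 5, nfl_params = list(control = c(mean = 354, sd = 0),
                                            carrier = c(mean = 767, sd = 585))),
    "positive sd")
  expect_identical(generate_cohort(10, 10, seed = 5),
                   generate_cohort(10, 10, seed = 5))
})

test_that("connectomes are symmetric, zero-diagonal and nonnegative where required", {
  at <- tiny_atlas()
  co <- generate_cohort(5, 5, seed = 3)
  cn <- generate_connectomes(co, at, effect_spec(), seed = 4)
  for (s in cn) {
    for (mod in c("functional", "structural")) {
      m <- unclass(s[[mod]])
      expect_equal(max(abs(m - t(m))), 0)
      expect_equal(max(abs(diag(m))), 0)
    }
    expect_true(all(unclass(s$structural) >= 0))
  }
  expect_identical(generate_connectomes(co, at, effect_spec(), seed = 4), cn)
})

test_that("zero coupling leaves functional edges independent of the biomarker", {
  at <- tiny_atlas()
  pe <- plant_subnetwork(at, 5, seed = 1)
  slopes <- vapply(1:100, function(r) {
    co <- generate_cohort(0, 20, seed = 100 + r)
    cn <- generate_connectomes(co, at, effect_spec(planted_edges = pe), seed = 200 + r)
    w <- vapply(cn, function(s) unclass(s$functional)[pe[1, 1], pe[1, 2]], numeric(1))
    unname(coef(lm(w ~ co$csf_nfl))[2])
  }, numeric(1))
  ci <- mean(slopes) + c(-1, 1) * 1.96 * sd(slopes) / 10
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("strong coupling with low noise makes planted edges track the biomarker", {
  at <- tiny_atlas()
  pe <- plant_subnetwork(at, 5, seed = 1)
  co <- generate_cohort(0, 40, seed = 9)
  cn <- generate_connectomes(co, at,
                             effect_spec(planted_edges = pe, coupling = 0.003,
                                         edge_noise_sd = 0.02), seed = 10)
  for (r in seq_len(nrow(pe))) {
    w <- vapply(cn, function(s) unclass(s$functional)[pe[r, 1], pe[r, 2]], numeric(1))
    expect_gt(cor(w, co$csf_nfl), 0.8)
  }
})

test_that("missing biomarker values with nonzero coupling are rejected", {
  at <- tiny_atlas()
  co <- generate_cohort(5, 5, prop_missing_nfl = 0.3, seed = 1)
  pe <- plant_subnetwork(at, 3, seed = 1)
  expect_error(
    generate_connectomes(co, at, effect_spec(planted_edges = pe, coupling = 1e-3)),
    "missing")
  # but fine with coupling = 0
  expect_silent(generate_connectomes(co, at, effect_spec(), seed = 1))
})

test_that("expression spatial autocorrelation follows the kernel length", {
  at <- generate_atlas(100, 14, seed = 1)
  cent <- as.matrix(at[, c("R", "A", "S")])
  D <- as.matrix(dist(cent))
  # nearest-neighbour pairs
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  # no autocorrelation: neighbouring-region correlation ~ 0 across genes
  ex0 <- generate_expression(at, 400,
                             effect_spec(expression_autocorr_length = 0), seed = 2)
  z0 <- scale(ex0$expression)
  r0 <- mean(vapply(seq_len(nrow(at)),
                    function(i) mean(z0[i, ] * z0[nn[i], ]), numeric(1)))
  expect_lt(abs(r0), 0.1)
  # long length-scale: neighbours strongly correlated
  ex1 <- generate_expression(at, 400,
                             effect_spec(expression_autocorr_length = 30), seed = 2)
  z1 <- scale(ex1$expression)
  r1 <- mean(vapply(seq_len(nrow(at)),
                    function(i) mean(z1[i, ] * z1[nn[i], ]), numeric(1)))
  expect_gt(r1, 0.5)
  # metadata sanity
  expect_true(all(is.finite(colMeans(ex1$expression))))
  expect_true(all(apply(ex1$expression, 2, sd) > 0))
  expect_true(all(ex1$meta$gc >= 0 & ex1$meta$gc <= 1))
  expect_true(all(ex1$meta$transcript_length > 0))
})

test_that("planted genes track the response map at the requested effect", {
  at <- generate_atlas(100, 14, seed = 1)
  rmap <- generate_smooth_map(at, 20, seed = 3)
  ex <- generate_expression(at, 500,
                            effect_spec(expression_autocorr_length = 20,
                                        n_planted_genes = 50,
                                        planted_gene_effect = 0.9),
                            response_map = rmap, seed = 4)
  planted <- which(ex$meta$planted)
  rho <- vapply(planted, function(g) {
    abs(cor(ex$expression[, g], rmap, method = "spearman"))
  }, numeric(1))
  expect_gte(median(rho), 0.7)
  expect_error(
    generate_expression(at, 10, effect_spec(n_planted_genes = 20,
                                            planted_gene_effect = 0.5),
                        response_map = rmap),
    "planted")
})

test_that("cell-type reference elevates markers and validates labels", {
  at <- tiny_atlas()
  ex <- generate_expression(at, 300, effect_spec(), seed = 5)
  ref <- generate_celltype_reference(ex$meta, n_markers_per_type = 10, seed = 6)
  expect_true(all(ref >= 0))
  spec <- specificity_matrix(ref)
  mk <- attr(ref, "markers")
  for (r in seq_len(nrow(mk))) {
    expect_gt(spec[mk$gene[r], mk$cell_type[r]], 1 / nrow(ref))
  }
  # no marker elevation: specificity approximately uniform
  ref0 <- generate_celltype_reference(ex$meta, n_markers_per_type = 10,
                                      marker_fold = 1, seed = 6)
  spec0 <- specificity_matrix(ref0)
  expect_lt(max(abs(colMeans(spec0) - 1 / nrow(ref0))), 0.02)
  expect_error(generate_celltype_reference(ex$meta, cell_types = c("A", "A")),
               "unique")
})
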