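test_that("edge GLM t map matches closed-form two-sample t and nulls", {
  n_sub <- 12
  co <- generate_cohort(6, 6, seed = 1)
  grp <- as.numeric(co$group == "carrier")
  # identical matrices for all subjects: t = 0 everywhere
  same <- replicate(n_sub, make_conn(4, rbind(c(1, 2), c(3, 4)), c(1, 0.5)),
                    simplify = FALSE)
  tm0 <- edge_glm_tmap(same, data.frame(group = grp), "group")
  expect_equal(max(abs(tm0$tmap)), 0)
  # single varying edge, two groups, no covariates: equals pooled t
  set.seed(2)
  w <- rnorm(n_sub) + grp * 2
  conns <- lapply(w, function(wi) make_conn(3, rbind(c(1, 2)), wi))
  tm <- edge_glm_tmap(conns, data.frame(group = grp), "group")
  oracle <- pooled_t_from_summary(6, mean(w[grp == 0]), sd(w[grp == 0]),
                                  6, mean(w[grp == 1]), sd(w[grp == 1]))
  expect_equal(tm$tmap[1, 2], oracle$t, tolerance = 1e-10)
  expect_equal(tm$df, oracle$df)  # same residual df: n - 2
  # edge exactly linear in a covariate: contrast t vanishes
  set.seed(3)
  age <- rnorm(n_sub, 30, 5)
  conns_age <- lapply(age, function(a) make_conn(3, rbind(c(1, 2)), 0.1 * a))
  tm_age <- edge_glm_tmap(conns_age, data.frame(group = grp, age = age), "group")
  expect_lt(abs(tm_age$tmap[1, 2]), 1e-6)
  # rank-deficient designs name the collinear columns
  expect_error(
    edge_glm_tmap(conns, data.frame(group = grp, twin = grp), "group"),
    "collinear")
})

test_that("suprathreshold component extraction handles the canonical cases", {
  tm <- matrix(0, 4, 4)
  expect_identical(suprathreshold_components(tm, 3.1), list())
  # chain (1,2), (2,3): one component with 2 edges
  tm1 <- matrix(0, 4, 4)
  tm1[1, 2] <- tm1[2, 1] <- 4
  tm1[2, 3] <- tm1[3, 2] <- 5
  c1 <- suprathreshold_components(tm1, 3.1)
  expect_length(c1, 1)
  expect_equal(nrow(c1[[1]]), 2)
  # disjoint edges (1,2), (3,4): two singleton components
  tm2 <- matrix(0, 4, 4)
  tm2[1, 2] <- tm2[2, 1] <- 4
  tm2[3, 4] <- tm2[4, 3] <- 4
  c2 <- suprathreshold_components(tm2, 3.1)
  expect_length(c2, 2)
  expect_equal(unname(sort(vapply(c2, nrow, integer(1)))), c(1L, 1L))
  # ties at the threshold are excluded (strict >)
  tm3 <- matrix(0, 3, 3)
  tm3[1, 2] <- tm3[2, 1] <- 3.1
  expect_identical(suprathreshold_components(tm3, 3.1), list())
})

test_that("raising the threshold never enlarges any component", {
  set.seed(4)
  for (rep in 1:20) {
    m <- matrix(0, 8, 8)
    m[upper.tri(m)] <- rnorm(28, 2, 1.5)
    m <- m + t(m)
    lo <- suprathreshold_components(m, 2)
    hi <- suprathreshold_components(m, 3)
    lo_edges <- do.call(rbind, lo)
    hi_edges <- do.call(rbind, hi)
    n_lo <- if (is.null(lo_edges)) 0L else nrow(lo_edges)
    n_hi <- if (is.null(hi_edges)) 0L else nrow(hi_edges)
    expect_lte(n_hi, n_lo)
    if (n_hi > 0) {
      keys <- function(e) paste(e[, 1], e[, 2])
      expect_true(all(keys(hi_edges) %in% keys(lo_edges)))
    }
  }
})

test_that("NBS result is invariant to region relabelling", {
  at <- tiny_atlas()
  n <- nrow(at)
  co <- generate_cohort(8, 8, seed = 5)
  pe <- plant_subnetwork(at, 4, seed = 5)
  cn <- generate_connectomes(co, at,
                             effect_spec(planted_edges = pe, coupling = 0.002,
                                         coupling_group = "all"), seed = 6)
  des <- data.frame(age = co$age, sex = as.numeric(co$sex == "M"),
                    nfl = co$csf_nfl)
  set.seed(7)
  perm <- sample(n)
  relabel <- function(s) {
    m <- unclass(s$functional)[perm, perm]
    list(functional = as_connectome(m, "functional"))
  }
  suppressWarnings({
    r1 <- nbs_test(cn, des, "nfl", n_perm = 99, seed = 8)
    r2 <- nbs_test(lapply(cn, relabel), des, "nfl", n_perm = 99, seed = 8)
  })
  expect_equal(sort(r1$component_size), sort(r2$component_size))
  expect_equal(sort(r1$fwe_p), sort(r2$fwe_p))
})

test_that("NBS permutation-count guards fire", {
  at <- tiny_atlas()
  co <- generate_cohort(5, 5, seed = 1)
  cn <- generate_connectomes(co, at, effect_spec(), seed = 2)
  des <- data.frame(group = as.numeric(co$group == "carrier"))
  expect_error(nbs_test(cn, des, "group", n_perm = 5, seed = 1), "n_perm")
  expect_warning(nbs_test(cn, des, "group", n_perm = 50, seed = 1), "coarse")
})

test_that("connection classification is exhaustive and exclusive", {
  at <- generate_atlas(4, 2, seed = 1)
  # rows: 1 = L cortical, 2 = L cortical, 3..4 = R cortical, 5 = L sub, 6 = R sub
  iL <- which(at$tissue == "cortical" & at$hemisphere == "L")
  iR <- which(at$tissue == "cortical" & at$hemisphere == "R")
  iS <- which(at$tissue == "subcortical")
  edges <- rbind(c(iL[1], iL[2]),   # intrahemispheric
                 c(iL[1], iR[1]),   # interhemispheric
                 c(iL[1], iS[1]),   # cortico-striatal
                 c(iS[1], iS[2]))   # subcortical pair, hemispheres differ
  cl <- classify_connections(edges, at)
  expect_equal(cl$class,
               c("intrahemispheric", "interhemispheric",
                 "cortico-striatal", "interhemispheric"))
  expect_equal(sum(cl$proportions), 1)
  expect_error(classify_connections(rbind(c(1, 99)), at), "outside")
})
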