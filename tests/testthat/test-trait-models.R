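two_tip_tt <- function() {
  recs <- tibble::tibble(name = c("A", "B"), fad = c(200, 190),
                         lad = c(199, 188))
  calibrate(read_tree("(A,B);"), recs, method = "mbl", min_duration = 1,
            root_extension = 1)
}

test_that("the BM covariance has shared-path entries and PSD structure", {
  C <- phylo_vcv(two_tip_tt())
  expect_equal(unname(sort(diag(C))), c(1, 11))
  expect_equal(C["A", "B"], 0)

  for (s in 1:4) {
    b <- sim_bundle(seed = 900 + s, n_taxa = 9)
    tt <- calibrate(b$tree, b$records)
    C <- phylo_vcv(tt)
    expect_true(isSymmetric(C))
    expect_true(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
                > -1e-9)
  }
  expect_error(phylo_vcv(two_tip_tt(), "Z"), "not in tree")

  # ultrametric tree: constant diagonal
  um <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  recs <- tibble::tibble(name = c("A", "B", "C"), fad = c(0, 0, 0),
                         lad = c(0, 0, 0))
  ttu <- list(phy = um, node_age = NULL, ranges = recs)
  class(ttu) <- "time_tree"
  expect_equal(unname(diag(phylo_vcv(ttu))), rep(2, 3))
})

test_that("stasis has closed-form estimates and flags zero variance", {
  y <- tibble::tibble(taxon = letters[1:5], value = c(10, 12, 9, 11, 13))
  f <- fit_stasis(y, measurement_sd = 0)
  expect_equal(f$estimates$trait_mean, mean(y$value))
  expect_equal(f$estimates$trait_variance, mean((y$value - mean(y$value))^2))
  # lnL equals the direct density at the estimates
  expect_equal(f$logLik,
               sum(stats::dnorm(y$value, f$estimates$trait_mean,
                                sqrt(f$estimates$trait_variance), log = TRUE)))

  same <- tibble::tibble(taxon = letters[1:4], value = rep(7, 4))
  fd <- fit_stasis(same, 0)
  expect_true(fd$degenerate)
  expect_equal(fd$estimates$trait_mean, 7)
  expect_equal(fd$estimates$trait_variance, 0)
})

test_that("stasis recovers simulated white-noise parameters within 3 SE", {
  set.seed(14)
  y <- tibble::tibble(taxon = paste0("t", 1:200),
                      value = stats::rnorm(200, 1000, 20))
  f <- fit_stasis(y, measurement_sd = 0)
  expect_lt(abs(f$estimates$trait_mean - 1000), 3 * 20 / sqrt(200))
  expect_lt(abs(f$estimates$trait_variance - 400), 3 * 400 * sqrt(2 / 200))
})

test_that("likelihoods match a direct multivariate-normal evaluation", {
  for (s in 1:3) {
    b <- sim_bundle(seed = 910 + s, n_taxa = 6)
    tt <- calibrate(b$tree, b$records)
    cfg <- b$cfg
    cfg$trait_model <- "trend"
    td <- simulate_traits(tt, cfg)
    sd0 <- 30
    C <- phylo_vcv(tt)
    y <- td$value[match(rownames(C), td$taxon)]

    fb <- fit_bm(tt, td, sd0)
    Vb <- fb$estimates$step_variance * C + sd0^2 * diag(6)
    expect_equal(fb$logLik,
                 mvn_logdens(y, rep(fb$estimates$root_state, 6), Vb),
                 tolerance = 1e-8)

    ft <- fit_trend(tt, td, sd0)
    Vt <- ft$estimates$step_variance * C + sd0^2 * diag(6)
    mu <- ft$estimates$root_state + ft$estimates$step_mean * diag(C)
    expect_equal(ft$logLik, mvn_logdens(y, mu, Vt), tolerance = 1e-8)

    # and neither is beaten by an independent full optimisation
    nll <- function(p, trend) {
      mu <- p[1] + (if (trend) p[3] else 0) * diag(C)
      -mvn_logdens(y, mu, exp(p[2]) * C + sd0^2 * diag(6))
    }
    ob <- stats::optim(c(mean(y), log(stats::var(y) / mean(diag(C)))),
                       nll, trend = FALSE, method = "BFGS")
    ot <- stats::optim(c(mean(y), log(stats::var(y) / mean(diag(C))), 0),
                       nll, trend = TRUE, method = "BFGS")
    expect_gte(fb$logLik, -ob$value - 1e-6)
    expect_gte(ft$logLik, -ot$value - 1e-6)
  }
})

test_that("on a star tree with equal depths BM collapses to stasis", {
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  recs <- tibble::tibble(name = c("A", "B", "C", "D", "E"),
                         fad = rep(195, 5), lad = rep(194, 5))
  tt <- calibrate(star, recs, method = "mbl", min_duration = 0,
                  root_extension = 5)
  set.seed(8)
  td <- tibble::tibble(taxon = recs$name, value = rnorm(5, 100, 4))
  fb <- fit_bm(tt, td, 0)
  fs <- fit_stasis(td, 0)
  expect_equal(fb$logLik, fs$logLik, tolerance = 1e-6)
  expect_equal(fb$estimates$step_variance * 5,
               fs$estimates$trait_variance, tolerance = 1e-4)
})

test_that("the trend model is refused on an ultrametric tree", {
  star <- ape::read.tree(text = "((A,B),(C,D));")
  recs <- tibble::tibble(name = c("A", "B", "C", "D"),
                         fad = rep(195, 4), lad = rep(194, 4))
  tt <- calibrate(star, recs, method = "mbl", min_duration = 0,
                  root_extension = 5)
  td <- tibble::tibble(taxon = recs$name, value = c(1, 2, 3, 4))
  expect_error(fit_trend(tt, td, 0), "ultrametric")
})

test_that("BM likelihood is shift-equivariant through the profiled root state", {
  b <- sim_bundle(seed = 920, n_taxa = 8)
  tt <- calibrate(b$tree, b$records)
  cfg <- b$cfg; cfg$trait_model <- "bm"
  td <- simulate_traits(tt, cfg)
  f1 <- fit_bm(tt, td, 10)
  td2 <- td; td2$value <- td$value + 500
  f2 <- fit_bm(tt, td2, 10)
  expect_equal(f2$logLik, f1$logLik, tolerance = 1e-6)
  expect_equal(f2$estimates$root_state, f1$estimates$root_state + 500,
               tolerance = 1e-4)
  expect_equal(f2$estimates$step_variance, f1$estimates$step_variance,
               tolerance = 1e-4)
})

test_that("AICc and Akaike weights follow their definitions", {
  f1 <- paleomacro:::new_trait_fit("bm", 2L, list(a = 1), -10, 20)
  expect_equal(aicc(f1), 20 + 4 + 2 * 2 * 3 / (20 - 3))
  expect_error(aicc(paleomacro:::new_trait_fit("trend", 3L, list(), -1, 4)),
               "undefined")
  f2 <- paleomacro:::new_trait_fit("trend", 3L, list(a = 1),
                                   -(24 + 12 / 17 - 7.5) / 2, 20)
  # equal AICc -> equal weights
  w <- akaike_weights(list(f1, f2))
  expect_equal(unname(w), c(0.5, 0.5), tolerance = 1e-4)
  # a 282-unit AICc gap gives essentially all weight to the better model
  f3 <- paleomacro:::new_trait_fit("bm", 2L, list(), -(2363 - 4 - 12 / 17) / 2, 20)
  f4 <- paleomacro:::new_trait_fit("trend", 3L,
                                   list(), -(2081 - 6 - 24 / 16) / 2, 20)
  w2 <- akaike_weights(list(f3, f4))
  expect_equal(unname(w2[2]), 1, tolerance = 1e-10)
})

test_that("fit_all returns weights summing to one on both scales", {
  b <- sim_bundle(seed = 930, n_taxa = 12)
  tt <- calibrate(b$tree, b$records)
  cfg <- b$cfg; cfg$trait_model <- "trend"
  td <- simulate_traits(tt, cfg)
  td$value <- abs(td$value) + 100
  for (tr in c("none", "ln")) {
    fa <- fit_all(tt, td, measurement_sd = 55, transform = tr)
    expect_equal(sum(fa$weights), 1)
    g <- glance(fa)
    expect_equal(g$model, c("stasis", "bm", "trend"))
    expect_true(all(is.finite(g$aicc)))
  }
  td_small <- td[1:3, ]
  expect_error(fit_all(tt, td_small, 55), "at least 4")
})

test_that("BM-generated data prefer BM over trend in most replicates", {
  wins <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(seed = 3000 + r, n_taxa = 24, trait_model = "bm",
                      step_variance = 20, measurement_sd = 0)
    sim <- simulate_tree_with_ranges(cfg)
    tt <- calibrate(sim$tree, sim$records)
    td <- simulate_traits(tt, cfg)
    fb <- fit_bm(tt, td, 0)
    ft <- fit_trend(tt, td, 0)
    if (fb$aicc < ft$aicc) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.7)
})

test_that("tidy and glance expose estimates in broom shape", {
  b <- sim_bundle(seed = 940, n_taxa = 10)
  tt <- calibrate(b$tree, b$records)
  cfg <- b$cfg
  td <- simulate_traits(tt, cfg)
  fa <- fit_all(tt, td, 55)
  td_tidy <- tidy(fa)
  expect_true(all(c("model", "term", "estimate") %in% names(td_tidy)))
  expect_setequal(unique(td_tidy$model), c("stasis", "bm", "trend"))
  expect_true("step_mean" %in% td_tidy$term[td_tidy$model == "trend"])
})
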