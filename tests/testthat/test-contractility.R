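test_that("elliptical CSA is the mean of per-point ellipse areas", {
  expect_equal(elliptical_csa(rep(50, 3), rep(50, 3)), pi * 25^2)
  expect_equal(elliptical_csa(c(40, 50, 60), c(40, 50, 60)),
               mean(pi * c(20, 25, 30)^2))
  expect_equal(elliptical_csa(c(40, 50, 60), c(40, 50, 60)),
               mean(c(1256.64, 1963.50, 2827.43)), tolerance = 1e-5)
  ## dimensional homogeneity: doubling all inputs quadruples the area
  expect_equal(elliptical_csa(c(80, 100, 120), c(80, 100, 120)),
               4 * elliptical_csa(c(40, 50, 60), c(40, 50, 60)))
  expect_error(elliptical_csa(c(40, -50, 60), c(40, 50, 60)), "positive")
})

test_that("curves normalize to the pCa 4.5 force and stay idempotent", {
  curve <- data.frame(pCa = c(4.5, 6.0), force = c(120, 60))
  norm <- normalize_curve(curve)
  expect_equal(norm$force, c(1, 0.5))
  expect_equal(normalize_curve(norm)$force, norm$force)   # idempotent
  expect_equal(normalize_curve(data.frame(pCa = c(4.5, 5, 6),
                                          force = c(7, 7, 7)))$force,
               rep(1, 3))
  expect_error(normalize_curve(data.frame(pCa = c(5, 6), force = c(1, 2))),
               "pCa 4.5")
})

test_that("noiseless simulated curves equal the Hill closed form", {
  cfg <- fibre_sim_config(n_fibres_per_group = 2L, noise_sd = 0,
                          pca50_true = c(wt = 6.0), nh_true = 2.0)
  sim <- simulate_force_pca(cfg)
  ## equal to the closed form up to the mandatory pCa 4.5 renormalization
  ## (the Hill force at pCa 4.5 is 0.999 for these parameters, so rescaling
  ## to 1 shifts every point by at most one part in a thousand)
  expect_equal(sim$force, hill_force(sim$pCa, 6.0, 2.0), tolerance = 1.1e-3)
  expect_true(all(sim$force[sim$pCa == 4.5] == 1))
  ## at pCa 9 any physiological parameter set is essentially relaxed
  relaxed <- hill_force(9.0, 6.1, 1.0)
  expect_lt(relaxed, 0.002)
  expect_lt(max(sim$force[sim$pCa == 9.0]), 0.002)
})

test_that("the Hill fit recovers noiseless parameters and matches a grid search", {
  grid <- c(9.0, 6.4, 6.2, 6.0, 5.8, 5.6, 5.4, 5.2, 5.0, 4.5)
  curve <- data.frame(pCa = grid, force = hill_force(grid, 6.0, 2.0))
  fit <- fit_hill(curve)
  expect_equal(fit$pca50, 6.0, tolerance = 1e-6)
  expect_equal(fit$nh, 2.0, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-10)
  expect_equal(unname(coef(fit)), c(fit$pca50, fit$nh))
  expect_equal(predict(fit, data.frame(pCa = 6.0)), 0.5, tolerance = 1e-6)

  ## noisy curve: least-squares optimum within one grid cell of the
  ## brute-force grid optimum
  set.seed(12)
  noisy <- data.frame(pCa = grid,
                      force = pmax(hill_force(grid, 5.9, 2.2) +
                                     rnorm(length(grid), 0, 0.03), 0))
  fit <- fit_hill(noisy)
  want <- oracle_hill_grid(noisy)
  expect_lt(abs(fit$pca50 - want["pca50"]), 0.01 + 1e-9)
  expect_lt(abs(fit$nh - want["nh"]), 0.05 + 1e-9)

  expect_error(fit_hill(data.frame(pCa = c(4.5, 6, 9),
                                   force = c(1, 0.5, 0))),
               "at least 4")
})

test_that("pca_at_fraction follows the closed form and orders correctly", {
  fit <- list(pca50 = 6.0, nh = 2.0)
  expect_equal(pca_at_fraction(fit, 0.5)$pCa, 6.0)
  expect_equal(pca_at_fraction(fit, 0.1)$pCa, 6 + log10(9) / 2,
               tolerance = 1e-12)
  d <- pca_at_fraction(fit, c(0.1, 0.2, 0.5))
  expect_true(all(diff(d$pCa) < 0))            # pCa10 > pCa20 > pCa50
  expect_true(all(diff(d$calcium_mM) > 0))     # calcium strictly increasing
  expect_equal(d$calcium_mM, 10^(-d$pCa) * 1000)
  expect_error(pca_at_fraction(fit, 1), "between 0 and 1")
})

test_that("group comparison reproduces the textbook t-test", {
  stats <- data.frame(group = rep(c("a", "b"), each = 3),
                      pca50 = c(1, 2, 3, 4, 5, 6))
  cmp <- compare_groups(stats, metrics = "pca50")
  expect_equal(cmp$t, -3.674, tolerance = 1e-3)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, 2 * pt(-3.674, 4), tolerance = 1e-3)

  ## identical groups: t = 0, p = 1
  same <- data.frame(group = rep(c("a", "b"), each = 3),
                     pca50 = c(1, 2, 3, 1, 2, 3))
  cmp <- compare_groups(same, metrics = "pca50")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)

  expect_error(compare_groups(data.frame(group = c("a", "a", "b"),
                                         pca50 = 1:3), metrics = "pca50"),
               "fewer than 2")
})

test_that("fitted parameters recover the generative values across seeds", {
  err50 <- err_nh <- numeric(0)
  for (seed in 1:25) {
    cfg <- fibre_sim_config(n_fibres_per_group = 4L,
                            pca50_true = c(wt = 5.804), seed = seed)
    fits <- fit_hill_groups(simulate_force_pca(cfg))
    err50 <- c(err50, abs(fits$pca50 - 5.804))
    err_nh <- c(err_nh, abs(fits$nh - 2.0))
  }
  expect_lt(median(err50), 0.03)
  expect_lt(median(err_nh), 0.3)
})

test_that("generative group separation appears in the fitted midpoints", {
  sim <- simulate_force_pca(fibre_sim_config(seed = 21L))
  fits <- fit_hill_groups(sim)
  shift <- mean(fits$pca50[fits$group == "affected"]) -
    mean(fits$pca50[fits$group == "wild_type"])
  expect_equal(shift, 6.056 - 5.804, tolerance = 0.1)
})
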