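obs_example <- c(private_west = 10, private_east = 8, shared = 5, fixed = 2)

test_that("the acceptance rule applies the per-component tolerance", {
  cfg <- rejection_config(epsilon_pct = 25, n_sims = 10)
  # bounds: [7.5, 12.5], [6, 10], [3.75, 6.25], [1.5, 2.5]
  expect_true(accept(c(12, 7, 4, 2), obs_example, cfg))
  expect_false(accept(c(13, 8, 5, 2), obs_example, cfg))
  expect_true(accept(obs_example, obs_example,
                     rejection_config(epsilon_pct = 1e-6)))
  # vectorised over replicates
  sims <- rbind(c(12, 7, 4, 2), c(13, 8, 5, 2), c(10, 8, 5, 2))
  expect_equal(accept(sims, obs_example, cfg), c(TRUE, FALSE, TRUE))
})

test_that("total-sum mode compares the grand total only", {
  cfg <- rejection_config(epsilon_pct = 25, acceptance_mode = "total_sum")
  # total 25, band [18.75, 31.25]
  expect_true(accept(c(0, 0, 0, 19), obs_example, cfg))
  expect_false(accept(c(0, 0, 0, 18), obs_example, cfg))
})

test_that("a zero observed component degenerates to requiring zero", {
  obs0 <- c(private_west = 10, private_east = 8, shared = 5, fixed = 0)
  cfg <- rejection_config(epsilon_pct = 25)
  expect_warning(ok <- accept(c(10, 8, 5, 0), obs0, cfg), "0")
  expect_true(ok)
  expect_warning(ok2 <- accept(c(10, 8, 5, 1), obs0, cfg), "0")
  expect_false(ok2)
})

test_that("acceptance is monotone in epsilon on a shared stream", {
  set.seed(401)
  sims <- matrix(rpois(400 * 4, lambda = c(10, 8, 5, 2)), ncol = 4,
                 byrow = TRUE)
  n_acc <- vapply(c(5, 10, 25, 50, 100), function(eps) {
    sum(accept(sims, obs_example, rejection_config(epsilon_pct = eps)))
  }, 1L)
  expect_true(all(diff(n_acc) >= 0))
})

test_that("the zero-acceptance bound is ln(1/n_sims)", {
  expect_equal(zero_acceptance_bound(1e6), log(1e-6))
  expect_lte(zero_acceptance_bound(1e6), -13.815)
  expect_equal(zero_acceptance_bound(4e4), -10.5966, tolerance = 1e-4)
  expect_equal(zero_acceptance_bound(1), 0)
  expect_error(zero_acceptance_bound(0), "n_sims")
})

test_that("approx_lnL returns ln(accepted / n_sims) and flags bounds", {
  expect_equal(log(30 / 40000), -7.1954, tolerance = 1e-4)
  set.seed(402)
  ds <- generate_dataset(study_design(n_loci = 3, n_west = 6, n_east = 6,
                                      rng_seed = 31))
  obs <- wakeley_hey(lapply(ds$alns, identity))
  p <- ds$truth
  params <- model_params(p$model, p$theta, p$T_gen, p$m, p$tau)
  cfg <- rejection_config(epsilon_pct = 50, n_sims = 400, rng_seed = 9)
  res <- suppressWarnings(
    approx_lnL(obs, params, ds$specs, mu_study(), cfg))
  expect_equal(res$lnL, if (res$n_accepted == 0) log(1 / 400)
                        else log(res$n_accepted / 400))
  expect_identical(res$is_bound, res$n_accepted == 0)
  # bit-reproducible with the same seed
  res2 <- suppressWarnings(
    approx_lnL(obs, params, ds$specs, mu_study(), cfg))
  expect_identical(res$n_accepted, res2$n_accepted)
  # impossible observation: nothing accepted, bound returned
  obs_imp <- c(private_west = 1e6, private_east = 1e6, shared = 1e6,
               fixed = 1e6)
  res3 <- approx_lnL(obs_imp, params, ds$specs, mu_study(), cfg)
  expect_true(res3$is_bound)
  expect_equal(res3$lnL, log(1 / 400))
})

test_that("the study grid has the published axis sizes", {
  g_iso <- grid_spec("isolation")
  expect_length(g_iso$T_gen, 21)
  expect_length(g_iso$theta, 19)
  expect_identical(g_iso$m, 0)
  expect_identical(g_iso$tau, 1)
  g_om <- grid_spec("ongoing_migration")
  expect_length(g_om$m, 20)
  g_sc <- grid_spec("secondary_contact")
  expect_length(g_sc$tau, 10)
})

test_that("grid search covers the grid and its maximum is non-positive", {
  set.seed(403)
  ds <- generate_dataset(study_design(n_loci = 2, n_west = 6, n_east = 6,
                                      rng_seed = 32))
  obs <- wakeley_hey(ds$alns)
  g <- grid_spec("isolation", T_gen = c(0, 1e6, 2e6),
                 theta = c(0.001, 0.002))
  cfg <- rejection_config(epsilon_pct = 50, n_sims = 120, rng_seed = 5)
  surf <- suppressWarnings(
    grid_search(obs, "isolation", g, ds$specs, mu_study(), cfg))
  expect_equal(nrow(surf), 6)
  expect_lte(max(surf$lnL), 0)
  mle <- surface_mle(surf)
  expect_equal(mle$lnL, max(surf$lnL))
  # deterministic: same master seed, same surface
  surf2 <- suppressWarnings(
    grid_search(obs, "isolation", g, ds$specs, mu_study(), cfg))
  expect_identical(surf$n_accepted, surf2$n_accepted)
  expect_error(grid_search(obs, "ongoing_migration", g, ds$specs,
                           mu_study(), cfg), "grid was built")
})

test_that("model nesting orders maximum likelihoods with shared streams", {
  set.seed(404)
  ds <- generate_dataset(study_design(n_loci = 4, n_west = 8, n_east = 8,
                                      rng_seed = 33))
  obs <- wakeley_hey(ds$alns)
  mu <- mu_study()
  cfg <- rejection_config(epsilon_pct = 40, n_sims = 300, rng_seed = 12)
  theta_ax <- c(0.001, 0.002, 0.005)
  T_ax <- c(4e6, 8.5e6)
  surf_iso <- suppressWarnings(grid_search(
    obs, "isolation", grid_spec("isolation", T_gen = T_ax, theta = theta_ax),
    ds$specs, mu, cfg))
  surf_om <- suppressWarnings(grid_search(
    obs, "ongoing_migration",
    grid_spec("ongoing_migration", T_gen = T_ax, theta = theta_ax,
              m = c(0, 0.7, 2)),
    ds$specs, mu, cfg))
  surf_sc <- suppressWarnings(grid_search(
    obs, "secondary_contact",
    grid_spec("secondary_contact", T_gen = T_ax, theta = theta_ax,
              m = c(0, 0.7, 2), tau = c(0.5, 1)),
    ds$specs, mu, cfg))
  # the nested optimum is contained in the larger grid with the same
  # child seeds, so the ordering is exact, not just in expectation
  expect_gte(max(surf_om$lnL), max(surf_iso$lnL))
  expect_gte(max(surf_sc$lnL), max(surf_om$lnL))
})

test_that("profile CIs keep values within 1.92 lnL of the maximum", {
  surf <- tibble::tibble(
    theta = c(0.001, 0.002, 0.003, 0.004, 0.005),
    T_gen = 1e6, m = 0, tau = 1,
    lnL = c(-12, -9, -8, -9.5, -12))
  ci <- profile_ci(surf, "theta")
  expect_equal(ci$mle, 0.003)
  expect_equal(ci$low, 0.002)
  expect_equal(ci$high, 0.004)
  expect_false(ci$censored_low)
  expect_false(ci$censored_high)

  flat <- dplyr::mutate(surf, lnL = -5)
  ci_flat <- profile_ci(flat, "theta")
  expect_equal(c(ci_flat$low, ci_flat$high), c(0.001, 0.005))
  expect_true(ci_flat$censored_low && ci_flat$censored_high)

  rising <- dplyr::mutate(surf, lnL = seq(-10, -2, length.out = 5))
  ci_r <- profile_ci(rising, "theta")
  expect_true(ci_r$censored_high)
  expect_false(ci_r$censored_low)
})

test_that("surface accessors tidy, glance and write/read round-trip", {
  set.seed(405)
  ds <- generate_dataset(study_design(n_loci = 2, n_west = 6, n_east = 6,
                                      rng_seed = 34))
  obs <- wakeley_hey(ds$alns)
  g <- grid_spec("isolation", T_gen = c(0, 1e6), theta = c(0.002))
  cfg <- rejection_config(epsilon_pct = 50, n_sims = 80, rng_seed = 2)
  surf <- suppressWarnings(
    grid_search(obs, "isolation", g, ds$specs, mu_study(), cfg))
  td <- tidy(surf)
  expect_s3_class(td, "tbl_df")
  gl <- glance(surf)
  expect_equal(gl$max_lnL, max(surf$lnL))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_surface(surf, path)
  back <- read_surface(path)
  expect_equal(back$lnL, surf$lnL)
  p <- autoplot(surf)
  expect_s3_class(p, "ggplot")
})
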