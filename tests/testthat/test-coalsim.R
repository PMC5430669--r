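test_that("coalescent scaling reproduces hand arithmetic", {
  mu <- mu_study()
  p <- model_params("ongoing_migration", theta = 0.002, T_gen = 8.5e6, m = 0.7)
  sc <- coalescent_scaling(p, mu)
  expect_equal(sc$N_e, 0.002 / (4 * 2.69e-9), tolerance = 1e-9)
  expect_equal(sc$N_e, 185873.6, tolerance = 1e-6)
  expect_equal(sc$T_coal, 8.5e6 / (4 * sc$N_e), tolerance = 1e-12)
  expect_equal(sc$T_coal, 11.432, tolerance = 1e-4)
  expect_equal(sc$M_coal, 2.8)
  expect_equal(coalescent_scaling(p, mu, "direct")$M_coal, 0.7)
  p0 <- model_params("isolation", theta = 0.002, T_gen = 8.5e6, m = 0)
  expect_equal(coalescent_scaling(p0, mu)$M_coal, 0)
})

test_that("model parameter invariants are enforced", {
  expect_error(model_params("isolation", theta = 0.01, T_gen = 1e6, m = 0.5),
               "m = 0")
  expect_error(model_params("ongoing_migration", 0.01, 1e6, 1, tau = 0.5),
               "tau")
  expect_error(model_params("isolation", theta = 0, T_gen = 0), "theta")
  expect_silent(model_params("secondary_contact", 0.01, 1e6, 1, tau = 0.4))
})

test_that("panmictic TMRCA for two lineages averages one coalescent unit", {
  set.seed(101)
  p <- panmictic_params()
  spec <- locus_spec("L", 1, 1, n_west = 1, n_east = 1)
  tmrca <- replicate(4000, max(simulate_genealogy(p, spec, mu_study())$time))
  se <- stats::sd(tmrca) / sqrt(length(tmrca))
  expect_lt(abs(mean(tmrca) - 1), 3 * se)
})

test_that("segregating sites match Watterson's expectation", {
  set.seed(102)
  p <- panmictic_params(theta = 1)
  spec <- locus_spec("L", length = 5, scalar = 1, n_west = 5, n_east = 5)
  S <- replicate(3000, sim_n_sites(p, spec, mu_study()))
  a_n <- sum(1 / (1:9))
  se <- stats::sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - 5 * a_n), 3 * se)

  # n = 2, theta_locus = 1: E[S] = 1
  spec2 <- locus_spec("L", length = 1, scalar = 1, n_west = 1, n_east = 1)
  S2 <- replicate(4000, sim_n_sites(p, spec2, mu_study()))
  expect_lt(abs(mean(S2) - 1), 3 * stats::sd(S2) / sqrt(length(S2)))
})

test_that("within-population pairwise diversity per site approaches theta", {
  set.seed(103)
  theta <- 0.01
  p <- panmictic_params(theta)
  L <- 500
  spec <- locus_spec("L", length = L, scalar = 1, n_west = 2, n_east = 0)
  pi_hat <- replicate(2000, sim_n_sites(p, spec, mu_study())) / L
  se <- stats::sd(pi_hat) / sqrt(length(pi_hat))
  expect_lt(abs(mean(pi_hat) - theta), 3 * se)
})

test_that("m = 0 and tau = 1 collapse the models into one another", {
  set.seed(104)
  mu <- mu_study()
  spec <- locus_spec("L", 1, 1, n_west = 4, n_east = 4)
  tm <- function(params) {
    replicate(2500, max(simulate_genealogy(params, spec, mu)$time))
  }
  iso <- model_params("isolation", 0.002, T_gen = 2e6)
  om0 <- model_params("ongoing_migration", 0.002, T_gen = 2e6, m = 0)
  expect_gt(suppressWarnings(stats::ks.test(tm(iso), tm(om0)))$p.value, 0.01)

  om <- model_params("ongoing_migration", 0.002, T_gen = 2e6, m = 1)
  sc1 <- model_params("secondary_contact", 0.002, T_gen = 2e6, m = 1, tau = 1)
  expect_gt(suppressWarnings(stats::ks.test(tm(om), tm(sc1)))$p.value, 0.01)
})

test_that("genealogies are ultrametric and span at least T_coal when split", {
  set.seed(105)
  mu <- mu_study()
  p <- model_params("isolation", 0.002, T_gen = 8.5e6)
  spec <- locus_spec("L", 1, 1, n_west = 3, n_east = 3)
  T_coal <- coalescent_scaling(p, mu)$T_coal
  for (i in 1:20) {
    g <- simulate_genealogy(p, spec, mu)
    n <- g$n_west + g$n_east
    expect_true(all(g$time[seq_len(n)] == 0))
    # parent times never precede child times
    kids <- seq_len(2 * n - 2)
    expect_true(all(g$time[g$parent[kids]] >= g$time[kids]))
    expect_gte(max(g$time), T_coal)
  }
})

test_that("migration shifts fixed differences down and shared sites up", {
  set.seed(106)
  mu <- mu_study()
  spec <- locus_spec("L", length = 300, scalar = 1, n_west = 8, n_east = 8)
  means <- lapply(c(0, 1, 10), function(m) {
    p <- model_params("ongoing_migration", 0.002, T_gen = 8.5e6, m = m)
    colMeans(as.matrix(simulate_wh(p, spec, mu, 1500)))
  })
  fixed <- vapply(means, `[[`, 1.0, "fixed")
  shared <- vapply(means, `[[`, 1.0, "shared")
  expect_true(fixed[1] >= fixed[2] && fixed[2] >= fixed[3])
  expect_true(shared[1] <= shared[2] && shared[2] <= shared[3])
})

test_that("mutation dropping is consistent with the batch path", {
  set.seed(107)
  p <- model_params("ongoing_migration", 0.005, T_gen = 5e6, m = 0.5)
  spec <- locus_spec("L", length = 200, scalar = 1.2, n_west = 6, n_east = 8)
  mu <- mu_study()
  per_site <- replicate(1500, {
    sim <- drop_mutations(simulate_genealogy(p, spec, mu), spec, p)
    vapply(c("private_west", "private_east", "shared", "fixed"),
           function(k) sum(sim$class == k), 1L)
  })
  batch <- colMeans(as.matrix(simulate_wh(p, spec, mu, 1500)))
  for (k in 1:4) {
    se <- stats::sd(per_site[k, ]) / sqrt(ncol(per_site)) +
      stats::sd(as.matrix(simulate_wh(p, spec, mu, 200))[, k]) / sqrt(200)
    expect_lt(abs(mean(per_site[k, ]) - batch[k]), 4 * se + 0.05)
  }
})

test_that("ms-style text renders segregating sites and haplotypes", {
  set.seed(108)
  p <- panmictic_params(theta = 2)
  spec <- locus_spec("L", 5, 1, n_west = 2, n_east = 2)
  sim <- drop_mutations(simulate_genealogy(p, spec, mu_study()), spec, p)
  txt <- as_ms_text(sim)
  expect_match(txt, "^//\n")
  expect_match(txt, paste0("segsites: ", nrow(sim)))
  if (nrow(sim) > 0) {
    expect_match(txt, "positions:")
    lines <- strsplit(txt, "\n")[[1]]
    haps <- lines[grepl("^[01]+$", lines)]
    expect_length(haps, 4)
    expect_true(all(nchar(haps) == nrow(sim)))
  }
})
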