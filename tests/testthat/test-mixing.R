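test_that("single-source log likelihood reduces to the closed normal form", {
  src <- make_source_profiles("CF", d15N_mean = 2, d15N_sd = 1.5,
                              d18O_mean = -1, d18O_sd = 0.8)
  s <- toy_samples()
  sigma <- c(0.4, 0.6)
  got <- mixing_log_likelihood(1, sigma, s, src)
  want <- sum(dnorm(s$d15N_NO3, 2, sqrt(1.5^2 + 0.4^2), log = TRUE)) +
    sum(dnorm(s$d18O_NO3, -1, sqrt(0.8^2 + 0.6^2), log = TRUE))
  expect_equal(got, want)
})

test_that("likelihood is constant in P when all sources are identical", {
  src <- make_source_profiles(c("a", "b", "c"),
                              d15N_mean = rep(5, 3), d15N_sd = rep(0, 3),
                              d18O_mean = rep(2, 3), d18O_sd = rep(0, 3))
  s <- toy_samples()
  vals <- sapply(list(c(1, 0, 0) + 0, c(0.2, 0.3, 0.5), c(1, 1, 1) / 3),
                 function(p) mixing_log_likelihood(p, c(1, 1), s, src))
  expect_equal(vals[1], vals[2])
  expect_equal(vals[2], vals[3])
})

test_that("marginal likelihood matches numerical convolution of the latent normals", {
  set.seed(9)
  src <- make_source_profiles(c("X", "Y"),
                              d15N_mean = c(1, 12), d15N_sd = c(1.2, 2.1),
                              d18O_mean = c(-3, 6), d18O_sd = c(0.9, 1.7),
                              d15N_frac_mean = c(0.5, -0.3), d15N_frac_sd = c(0.4, 0.6),
                              d18O_frac_mean = c(0.2, 0.1), d18O_frac_sd = c(0.3, 0.5))
  s <- data.frame(sample_id = c("a", "b", "c"), water_type = "surface",
                  d15N_NO3 = c(4.1, 6.8, 5.2), d18O_NO3 = c(0.5, 2.2, 1.4))
  P <- c(0.6, 0.4); sigma <- c(0.5, 0.7)
  got <- mixing_log_likelihood(P, sigma, s, src)
  ref <- 0
  for (j in seq_along(default_tracers())) {
    tr <- default_tracers()[j]
    sub <- src[src$tracer == tr, ]
    ref <- ref + sum(convolved_mixture_logpdf(
      s[[tr]], P, sub$mean, sub$sd, sub$frac_mean, sub$frac_sd, sigma[j]))
  }
  expect_equal(got, ref, tolerance = 1e-4)
})

test_that("the prior is flat over the simplex interior and proper in sigma", {
  # Dirichlet(1,..,1): interior log-prior differences depend only on sigma
  p1 <- c(0.2, 0.3, 0.4, 0.1); p2 <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(mixing_log_prior(p1, 1), mixing_log_prior(p2, 1))
  expect_lt(mixing_log_prior(p1, 1e6), mixing_log_prior(p1, 1) - 100)
  expect_identical(mixing_log_prior(c(0, 0.5, 0.5, 0), 1), -Inf)
  # independent recomputation of the full density at a random point
  set.seed(4)
  sg <- c(1.3, 0.6)
  want <- lgamma(4) + sum(0 * log(p1)) +
    sum(dnorm(sg, 0, 20, log = TRUE) + log(2))
  expect_equal(mixing_log_prior(p1, sg), want)
})

test_that("prior draws put mean 1/K mass on each source", {
  set.seed(123)
  K <- 4; n <- 1e5
  e <- matrix(rexp(n * K), n, K)
  P <- e / rowSums(e)          # uniform on the simplex
  se <- apply(P, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(P) - 1 / K) < 3 * se))
})

test_that("degenerate one-source fits return proportion one exactly", {
  src <- make_source_profiles("CF", d15N_mean = 5, d15N_sd = 1,
                              d18O_mean = 2, d18O_sd = 1)
  post <- fit_mixing_model(toy_samples(), src, mcmc = quick_mcmc())
  expect_true(all(post$draws_P == 1))
  expect_true(all(post$draws_sigma > 0))
  sm <- summarize_posterior(post)
  expect_equal(sm$mean_pct, 100.0)
  expect_equal(sm$sd_pct, 0.0)
})

test_that("symmetric two-source problems give symmetric posteriors", {
  src <- make_source_profiles(c("L", "R"),
                              d15N_mean = c(5, 5), d15N_sd = c(1, 1),
                              d18O_mean = c(2, 2), d18O_sd = c(1, 1))
  post <- suppressWarnings(
    fit_mixing_model(toy_samples(), src, mcmc = quick_mcmc(seed = 2))
  )
  pm <- colMeans(post$draws_P)
  mcse <- apply(post$draws_P, 2, sd) / sqrt(nrow(post$draws_P) / 20)
  expect_true(all(abs(pm - 0.5) < 3 * pmax(mcse, 0.02)))
})

test_that("every retained draw lies on the simplex to 1e-12", {
  ds <- generate_basin_scenario(3)
  ids <- ds$truth$per_sample$sample_id[ds$truth$per_sample$group == "B"]
  post <- suppressWarnings(fit_mixing_model(
    ds$samples[ds$samples$sample_id %in% ids, ], basin_source_profiles(),
    mcmc = quick_mcmc(seed = 3)))
  expect_true(all(abs(rowSums(post$draws_P) - 1) < 1e-12))
  expect_true(all(post$draws_P >= 0))
  expect_true(all(post$draws_sigma > 0))
})

test_that("a well-separated two-source mix is recovered within 0.10", {
  src <- make_source_profiles(c("lo", "hi"),
                              d15N_mean = c(0, 20), d15N_sd = c(0.5, 0.5),
                              d18O_mean = c(0, 20), d18O_sd = c(0.5, 0.5))
  set.seed(31)
  n <- 60
  s <- data.frame(sample_id = sprintf("m%02d", 1:n), water_type = "surface",
                  d15N_NO3 = 0.7 * 0 + 0.3 * 20 + rnorm(n, 0, 0.8),
                  d18O_NO3 = 0.7 * 0 + 0.3 * 20 + rnorm(n, 0, 0.8))
  post <- suppressWarnings(fit_mixing_model(
    s, src, mcmc = quick_mcmc(seed = 31, n_iter = 8000, n_burn = 4000)))
  pm <- colMeans(post$draws_P)
  expect_lt(abs(pm[["lo"]] - 0.7), 0.10)
  expect_lt(abs(pm[["hi"]] - 0.3), 0.10)
})

test_that("posterior summaries recompute from the stored draws", {
  ds <- generate_basin_scenario(4)
  ids <- ds$truth$per_sample$sample_id[ds$truth$per_sample$group == "D"]
  post <- suppressWarnings(fit_mixing_model(
    ds$samples[ds$samples$sample_id %in% ids, ], basin_source_profiles(),
    mcmc = quick_mcmc(seed = 4), group_label = "D"))
  sm <- summarize_posterior(post)
  expect_equal(sm$source, c("CF", "MS", "NP", "SN"))
  for (r in seq_len(nrow(sm))) {
    col <- post$draws_P[, sm$source[r]]
    expect_equal(sm$mean_pct[r], round(sum(col) / length(col) * 100, 1))
    expect_equal(sm$sd_pct[r],
                 round(sqrt(sum((col - mean(col))^2) / (length(col) - 1)) * 100, 1))
  }
  expect_lt(abs(sum(sm$mean_pct) - 100), 0.5)
})

test_that("identical configuration reproduces draws bit for bit", {
  src <- toy_sources()
  p1 <- suppressWarnings(fit_mixing_model(toy_samples(), src, mcmc = quick_mcmc(seed = 8)))
  p2 <- suppressWarnings(fit_mixing_model(toy_samples(), src, mcmc = quick_mcmc(seed = 8)))
  expect_identical(p1$draws_P, p2$draws_P)
  expect_identical(p1$draws_sigma, p2$draws_sigma)
  p3 <- suppressWarnings(fit_mixing_model(toy_samples(), src, mcmc = quick_mcmc(seed = 9)))
  expect_false(identical(p1$draws_P, p3$draws_P))
})

test_that("split-Rhat flags disjoint chains and passes identical ones", {
  set.seed(5)
  base <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  same <- convergence_diagnostics(list(base, base))
  expect_true(all(abs(same - 1) < 0.01))

  far <- convergence_diagnostics(list(base, base + 100))
  expect_true(all(far > 10))

  expect_error(convergence_diagnostics(list(base)), ">= 2 chains")
  expect_error(convergence_diagnostics(list(base[1:5, ], base[1:5, ])), ">= 10")

  # agreement with an independently coded split-Rhat on mixed chains
  chains <- lapply(1:3, function(i) {
    set.seed(50 + i)
    matrix(rnorm(300, mean = 0.05 * i), 150, 2)
  })
  got <- convergence_diagnostics(chains)
  for (jp in 1:2) {
    ref <- reference_split_rhat(lapply(chains, function(m) m[, jp]))
    expect_equal(unname(got[jp]), ref, tolerance = 1e-12)
  }
})

test_that("the convergence gate withholds the summary but keeps draws", {
  # force non-convergence: absurdly tiny chains on a hard posterior
  ds <- generate_basin_scenario(6)
  ids <- ds$truth$per_sample$sample_id[ds$truth$per_sample$group == "A"]
  expect_warning(
    post <- fit_mixing_model(ds$samples[ds$samples$sample_id %in% ids, ],
                             basin_source_profiles(),
                             mcmc = mcmc_config(n_chains = 2, n_iter = 300,
                                                n_burn = 100, thin = 1,
                                                rng_seed = 1,
                                                rhat_threshold = 1.001)),
    "withheld")
  expect_null(post$summary)
  expect_gt(nrow(post$draws_P), 0)
  expect_s3_class(summarize_posterior(post), "data.frame")
})
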