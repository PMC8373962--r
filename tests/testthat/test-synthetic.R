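zero_noise_spec <- function(p = c(CF = 0.25, MS = 0.75), n = 8, seed = 1) {
  src <- make_source_profiles(names(p),
                              d15N_mean = c(0, 20), d15N_sd = c(0, 0),
                              d18O_mean = c(-2, 8), d18O_sd = c(0, 0))
  synthetic_spec(
    sources = src,
    groups = list(list(label = "G", water_type = "ground", n = n, p = p,
                       no3_meanlog = log(5), no3_sdlog = 0)),
    sigma = c(d15N_NO3 = 0, d18O_NO3 = 0),
    rng_seed = seed
  )
}

test_that("the noise-free limit reproduces the mixture mean exactly", {
  ds <- generate_mixture_samples(zero_noise_spec())
  expect_equal(ds$samples$d15N_NO3, rep(0.25 * 0 + 0.75 * 20, 8))
  expect_equal(ds$samples$d18O_NO3, rep(0.25 * -2 + 0.75 * 8, 8))
})

test_that("generation is deterministic under the seed", {
  a <- generate_mixture_samples(zero_noise_spec(seed = 7))
  b <- generate_mixture_samples(zero_noise_spec(seed = 7))
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$per_sample, b$truth$per_sample)
})

test_that("generated moments converge to the marginalized closed form", {
  p <- c(CF = 0.3, MS = 0.2, NP = 0.1, SN = 0.4)
  src <- basin_source_profiles()
  spec <- synthetic_spec(
    sources = src,
    groups = list(list(label = "G", water_type = "ground", n = 10000, p = p,
                       no3_meanlog = log(5), no3_sdlog = 0.2)),
    sigma = c(d15N_NO3 = 0.5, d18O_NO3 = 0.5), rng_seed = 99
  )
  ds <- generate_mixture_samples(spec)
  for (tr in default_tracers()) {
    sub <- src[src$tracer == tr, ]
    pp <- p[sub$source_id]
    mu <- sum(pp * (sub$mean + sub$frac_mean))
    v <- sum(pp^2 * (sub$sd^2 + sub$frac_sd^2)) + 0.25
    x <- ds$samples[[tr]]
    expect_lt(abs(mean(x) - mu), 3 * sqrt(v / 10000))
    expect_lt(abs(var(x) - v) / v, 0.05)
  }
})

test_that("the Rayleigh step preserves ids and touches only the pool it should", {
  spec <- zero_noise_spec(n = 10, seed = 3)
  ds <- generate_mixture_samples(spec)

  unchanged <- apply_rayleigh_denitrification(ds, eps = -5, f_range = c(1, 1))
  expect_equal(unchanged$samples$no3, ds$samples$no3)
  expect_equal(unchanged$samples$d15N_NO3, ds$samples$d15N_NO3)

  denit <- apply_rayleigh_denitrification(ds, eps = -5, f_range = c(0.2, 1))
  expect_identical(denit$samples$sample_id, ds$samples$sample_id)
  expect_identical(denit$samples$tn, ds$samples$tn)
  expect_identical(denit$samples$cond, ds$samples$cond)
  expect_true(all(denit$truth$per_sample$f >= 0.2 &
                    denit$truth$per_sample$f <= 1))
  # exact affine relation in the noise-free limit
  r <- cor(denit$samples$d15N_NO3, log(denit$samples$no3))
  expect_equal(r, -1)
  # 2:1 N:O enrichment convention
  d15_shift <- denit$samples$d15N_NO3 - ds$samples$d15N_NO3
  d18_shift <- denit$samples$d18O_NO3 - ds$samples$d18O_NO3
  expect_equal(d15_shift, 2 * d18_shift)

  expect_error(apply_rayleigh_denitrification(ds, eps = 0, f_range = c(0.5, 1)),
               "nonzero")
  expect_error(apply_rayleigh_denitrification(ds, eps = -5, f_range = c(0, 1)),
               "0, 1")
})

test_that("the basin scenario regenerates byte-identically under one seed", {
  a <- generate_basin_scenario(12)
  b <- generate_basin_scenario(12)
  expect_identical(a, b)
  expect_false(identical(a$samples, generate_basin_scenario(13)$samples))

  expect_equal(nrow(a$samples), 62)
  expect_equal(sum(a$samples$water_type == "surface"), 29)
  expect_equal(sum(a$samples$water_type == "ground"), 33)
  expect_equal(a$truth$true_p$D[["MS"]], 0.8)
  expect_equal(sum(a$truth$per_sample$f < 1), 6)
  expect_setequal(a$truth$denitrification$sample_ids,
                  a$samples$sample_id[a$samples$region == "DDKd_low"])
})

test_that("clustering the scenario's surface samples recovers the generating groups", {
  ds <- generate_basin_scenario(12)
  cl <- cluster_water_samples(ds$samples)
  truth <- ds$truth$per_sample$group[match(names(cl$surface$assignments),
                                           ds$truth$per_sample$sample_id)]
  expect_gte(rand_index(cl$surface$assignments, truth), 0.9)
})

test_that("the denitrified demo series triggers the screen under noise", {
  hits <- 0
  for (i in 1:10) {
    ds <- generate_rayleigh_demo(700 + i)
    out <- denitrification_assessment(ds$samples)
    a <- out[out$pair == "d15N_vs_lnNO3", ]
    if (a$interpretation == "denitrification_signal") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("moment-matched synthesis honours the packaged summary table", {
  summ <- basin_reference_summary()
  expect_equal(nrow(summ), 7)
  expect_equal(sum(summ$n), 62)
  s <- generate_from_summary(1)
  expect_equal(nrow(s), 62)
  expect_identical(nrow(validate_dataset(s, basin_source_profiles())), 0L)
  # region means land near the table's means (3 SE check on a large redraw)
  big <- summ; big$n <- big$n * 50
  sb <- generate_from_summary(2, summary = big)
  for (r in seq_len(nrow(summ))) {
    sub <- sb[sb$region == summ$region[r], ]
    se <- summ$d15N_sd[r] / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$d15N_NO3) - summ$d15N_mean[r]), 3 * se)
    se_no3 <- summ$no3_sd[r] / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$no3) - summ$no3_mean[r]), 4 * se_no3)
  }
})
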