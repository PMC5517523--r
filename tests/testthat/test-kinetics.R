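test_that("all three rate laws vanish at t = 0 and obey their limits", {
  expect_equal(kinetic_response("linear", list(k_cat = 4), 0), 0)
  expect_equal(
    kinetic_response("burst", list(A = 0.8, k_burst = 20, k_cat = 0.5), 0), 0
  )
  expect_equal(
    kinetic_response("single_exponential", list(A = 0.9, k_obs = 3), 0), 0
  )
  # exponential asymptote -> amplitude
  expect_equal(
    kinetic_response("single_exponential", list(A = 0.9, k_obs = 3), 1e6), 0.9
  )
  expect_error(kinetic_response("linear", list(k_cat = -1), 1), "positive")
  expect_error(
    kinetic_response("burst", list(A = -0.1, k_burst = 1, k_cat = 1), 1),
    "non-negative"
  )
  expect_error(kinetic_response("linear", list(), 1), "k_cat")
})

test_that("a zero-amplitude burst is exactly the linear model", {
  t <- seq(0, 5, by = 0.01)
  burst0 <- kinetic_response("burst", list(A = 0, k_burst = 7, k_cat = 2), t)
  lin <- kinetic_response("linear", list(k_cat = 2), t)
  expect_lt(max(abs(burst0 - lin)), 1e-12)
})

test_that("simulated traces are seed-deterministic tibbles", {
  t <- seq(0.01, 1, by = 0.01)
  tr1 <- simulate_trace("linear", list(k_cat = 4), t, noise_sd = 0.05,
    seed = 7)
  tr2 <- simulate_trace("linear", list(k_cat = 4), t, noise_sd = 0.05,
    seed = 7)
  expect_identical(tr1$response, tr2$response)
  tr3 <- simulate_trace("linear", list(k_cat = 4), t, noise_sd = 0.05,
    seed = 8)
  expect_false(identical(tr1$response, tr3$response))
  expect_error(
    simulate_trace("linear", list(k_cat = 4), c(0.2, 0.1)),
    "unsorted|strictly|TRUE"
  )
})

test_that("noise-free round trips recover parameters to high precision", {
  t <- seq(0.005, 2, length.out = 80)
  tr_lin <- simulate_trace("linear", list(k_cat = 4), t)
  fl <- fit_trace(tr_lin, "linear")
  expect_equal(unname(fl$parameters["k_cat"]), 4, tolerance = 1e-8)

  truth <- c(A = 0.8, k_burst = 20, k_cat = 0.5)
  tr_b <- simulate_trace("burst", as.list(truth), t)
  fb <- fit_trace(tr_b, "burst")
  expect_equal(unname(fb$parameters[names(truth)]), unname(truth),
    tolerance = 1e-4)

  tr_e <- simulate_trace("single_exponential", list(A = 0.9, k_obs = 12), t)
  fe <- fit_trace(tr_e, "single_exponential")
  expect_equal(unname(fe$parameters[c("A", "k_obs")]), c(0.9, 12),
    tolerance = 1e-5)
})

test_that("noisy exponential estimates are unbiased within 5%", {
  t <- seq(0.02, 1.5, length.out = 30)
  truth <- list(A = 0.85, k_obs = 6)
  ests <- vapply(1:200, function(i) {
    tr <- simulate_trace("single_exponential", truth, t, noise_sd = 0.02,
      seed = 1000 + i)
    fit_trace(tr, "single_exponential")$parameters[["k_obs"]]
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth$k_obs) / truth$k_obs, 0.05)
})

test_that("rate estimates rescale consistently with the time unit", {
  t <- seq(0.005, 2, length.out = 60)
  tr <- simulate_trace("burst", list(A = 0.7, k_burst = 15, k_cat = 1), t)
  fs <- fit_trace(tr, "burst")
  tr_ms <- tr
  tr_ms$time <- tr$time * 1000 # seconds -> milliseconds
  fms <- fit_trace(tr_ms, "burst")
  expect_equal(fms$parameters[["k_burst"]] * 1000,
    fs$parameters[["k_burst"]],
    tolerance = 1e-4)
  expect_equal(fms$parameters[["k_cat"]] * 1000, fs$parameters[["k_cat"]],
    tolerance = 1e-4)
  expect_equal(fms$parameters[["A"]], fs$parameters[["A"]], tolerance = 1e-4)
})

test_that("model comparison prefers the generating model", {
  t <- seq(0.01, 2, length.out = 50)
  lin <- simulate_trace("linear", list(k_cat = 2), t, noise_sd = 0.02,
    seed = 61)
  expect_equal(compare_models(lin)$preferred, "linear")

  bur <- simulate_trace("burst", list(A = 1, k_burst = 25, k_cat = 0.5), t,
    noise_sd = 0.02, seed = 62)
  cmp <- compare_models(bur)
  expect_equal(cmp$preferred, "burst")
  expect_gt(cmp$burst$parameters[["A"]], 2 * cmp$burst$se[["A"]])

  # burst-generated with A = 0 is the nested null: linear wins
  null_b <- simulate_trace("burst", list(A = 0, k_burst = 25, k_cat = 2), t,
    noise_sd = 0.02, seed = 63)
  expect_equal(compare_models(null_b)$preferred, "linear")
})

test_that("fits report curvature standard errors and residual norms", {
  t <- seq(0.01, 2, length.out = 50)
  tr <- simulate_trace("burst", list(A = 0.8, k_burst = 10, k_cat = 1), t,
    noise_sd = 0.03, seed = 64)
  fit <- fit_trace(tr, "burst")
  expect_true(all(fit$se >= 0))
  expect_gt(fit$residual_norm, 0)
  td <- tidy(fit)
  expect_equal(td$term, c("A", "k_burst", "k_cat"))
  expect_equal(glance(fit)$model, "burst")
  expect_error(fit_trace(tr[1:2, ], "burst"), "at least")
})

test_that("traces round-trip through two-column delimited text", {
  tr <- simulate_trace("linear", list(k_cat = 3), seq(0.1, 1, 0.1),
    noise_sd = 0.01, seed = 65)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$time, tr$time)
  expect_equal(back$response, tr$response)
})
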