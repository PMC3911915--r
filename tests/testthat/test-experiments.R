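test_that("control Y-tree runs are symmetric and reruns are bit-identical", {
  prot <- y_competition_protocol(params = transport_params(dt = 5),
                                 perturb_time = 1800, readout_after = 3600,
                                 multiplier = 1, dt = 5)
  res1 <- run_simulation(prot)
  res2 <- run_simulation(prot)
  expect_identical(res1$lengths, res2$lengths)
  expect_identical(res1$conc, res2$conc)
  expect_identical(res1$lengths[, "gc1"], res1$lengths[, "gc2"])
  expect_true(all(diff(res1$times) > 0))
})

test_that("halving the time step changes final lengths by under 0.5%", {
  final_at <- function(dt) {
    prot <- y_competition_protocol(params = transport_params(v = 0, dt = dt),
                                   perturb_time = 3600,
                                   readout_after = 5 * 3600,
                                   multiplier = 1.5, dt = dt)
    res <- run_simulation(prot)
    res$lengths[nrow(res$lengths), ]
  }
  a <- final_at(5)
  b <- final_at(2.5)
  expect_lt(max(abs(a / b - 1)), 0.005)
})

test_that("replay error measure matches its closed forms", {
  t <- seq(0, 3600, by = 600)
  obs <- growth_trace(t, rep(10e-6, length(t)))
  expect_equal(error_measure(obs, obs), 0)
  # constant offset delta over N samples -> delta * sqrt(N)
  sim <- growth_trace(t, rep(12e-6, length(t)))
  expect_equal(error_measure(sim, obs), 2e-6 * sqrt(length(t)))
  # deviations (3, 4) um -> 5 um
  obs2 <- growth_trace(c(0, 600), c(10e-6, 10e-6))
  sim2 <- growth_trace(c(0, 600), c(13e-6, 14e-6))
  expect_equal(error_measure(sim2, obs2), 5e-6)
  expect_error(error_measure(sim2, growth_trace(numeric(0), numeric(0))))
})

test_that("synthetic culture-like traces have staggered onsets and are seed-deterministic", {
  tr1 <- make_synthetic_traces(seed = 7)
  tr2 <- make_synthetic_traces(seed = 7)
  expect_identical(tr1, tr2)
  expect_false(identical(tr1, make_synthetic_traces(seed = 8)))
  onsets <- trace_onsets(tr1)
  expect_equal(unname(onsets), min_to_s(c(0, 980, 1650)))
  # first two grow then stall; the third shows a late growth spurt
  g3 <- tr1$gc3
  early <- diff(range(g3$lengths[g3$times <= min_to_s(2300)]))
  spurt <- max(g3$lengths) - g3$lengths[max(which(g3$times <= min_to_s(2300)))]
  expect_gt(spurt, 3 * early)
})

test_that("growth-trace files round-trip through the two-column text format", {
  tr <- make_synthetic_traces(seed = 3)$gc2
  f <- withr::local_tempfile(fileext = ".txt")
  write_growth_trace(tr, f)
  back <- read_growth_trace(f)
  # the text format keeps 6 decimals in minutes/um
  expect_equal(back$times, tr$times, tolerance = 1e-8)
  expect_equal(back$lengths, tr$lengths, tolerance = 1e-6)
})

test_that("model-generated traces replay consistently in full forced mode", {
  p <- transport_params(dt = 10)
  traces <- make_synthetic_traces(template = "model-generated", params = p,
                                  duration = 7200, sample_interval = 600)
  tree <- build_star_tree(3)
  prot <- protocol(tree, params = p, duration = 7200, dt = 10,
                   output_interval = 600, forced = traces)
  res <- run_simulation(prot)
  expect_true(all(res$lengths >= 0))
  expect_true(all(res$conc >= 0))
  # replayed lengths track the generating run closely
  for (gc in names(traces)) {
    expect_lt(max(abs(res$lengths[, gc] - traces[[gc]]$lengths)), 1e-7)
  }
})

test_that("the retraction statistic is zero without retraction and errors without growth", {
  prot <- y_competition_protocol(params = transport_params(dt = 5),
                                 perturb_time = 600, readout_after = 3000,
                                 multiplier = 1, dt = 5)
  res <- run_simulation(prot)
  expect_equal(total_relative_retraction(res, res, "gc1"), 0)
  shrunk <- res
  shrunk$lengths[nrow(shrunk$lengths), "gc1"] <- shrunk$lengths[1, "gc1"]
  expect_error(total_relative_retraction(res, shrunk, "gc1"), "did not grow")
})

test_that("a one-point grid search returns that point", {
  p <- transport_params(dt = 10)
  traces <- make_synthetic_traces(template = "model-generated", params = p,
                                  duration = 7200, sample_interval = 600)
  spec <- grid_search_spec(D_range = c(p$D, p$D), v_range = c(p$v, p$v),
                           b_range = c(p$b, p$b),
                           C_soma_range = c(p$C_soma, p$C_soma),
                           n_points = 1, free_gc = "gc3", traces = traces)
  expect_equal(nrow(spec$grid), 1L)
  fit <- grid_search_fit(spec, build_star_tree(3), params = p, dt = 10)
  expect_equal(fit$D, p$D)
  expect_lt(fit$error_m, 1e-7)
})
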