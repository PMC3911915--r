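test_that("elongation law reproduces its calibration anchors", {
  p <- transport_params()
  # 0.033 mm/h at 10 uM
  expect_equal(signif(ms_to_mmh(elongation_rate(uM_to_molm3(10), p)), 2),
               0.033)
  # exact zero crossing at q/p (about 5 uM)
  czero <- p$q / p$p
  expect_equal(round(molm3_to_uM(czero)), 5)
  expect_equal(elongation_rate(czero, p), 0, tolerance = 1e-20)
  # pure retraction at zero concentration
  expect_equal(elongation_rate(0, p), -p$q)
  # the multiplier scales polymerization only
  expect_equal(elongation_rate(czero, p, multiplier = 1.5), 0.5 * p$p * czero)
})

test_that("free growth consumes X per metre and leaves the growth cone size fixed", {
  p <- transport_params()
  tr <- set_concentration(build_y_tree(y_tree_spec(50e-6, 10e-6)),
                          uM_to_molm3(10))
  gc <- growth_cones(tr)[["gc1"]]
  sh <- tr$parent[gc]
  q_gc <- tr$Q[gc]
  len_sh <- tr$length[sh]
  len_gc <- tr$length[gc]
  out <- grow_step(tr, "gc1", p, dt = 10)
  dl <- attr(out, "dl")
  expect_equal(dl, elongation_rate(uM_to_molm3(10), p) * 10)
  expect_equal(out$length[sh] - len_sh, dl)
  expect_equal(out$length[gc], len_gc)           # growth cone size constant
  expect_equal(q_gc - out$Q[gc], p$X * dl)       # tubulin ledger
  expect_false(attr(out, "capped"))
})

test_that("no growth and no consumption exactly at the zero-crossing concentration", {
  p <- transport_params()
  tr <- set_concentration(build_y_tree(y_tree_spec(50e-6, 10e-6)), p$q / p$p)
  out <- grow_step(tr, "gc1", p, dt = 100)
  expect_equal(attr(out, "dl"), 0, tolerance = 1e-22)
  expect_equal(out$length, tr$length, tolerance = 1e-15)
  expect_equal(out$Q, tr$Q, tolerance = 1e-15)
})

test_that("retraction releases exactly what an equal elongation consumes", {
  p <- transport_params()
  tr <- set_concentration(build_y_tree(y_tree_spec(50e-6, 20e-6)),
                          uM_to_molm3(5.5))
  gc <- growth_cones(tr)[["gc1"]]
  q0 <- tr$Q[gc]
  l0 <- path_distance(tr, 1L, gc)
  # forced down 2 um, then back up
  tr2 <- forced_growth_step(tr, gc, growth_trace(c(0, 600), c(l0, l0 - 2e-6)),
                            600, p)
  expect_equal(tr2$Q[growth_cones(tr2)[["gc1"]]] - q0, p$X * 2e-6)  # 8e-20 mol
  tr3 <- forced_growth_step(tr2, growth_cones(tr2)[["gc1"]],
                            growth_trace(c(0, 600), c(l0 - 2e-6, l0)), 600, p)
  expect_equal(tr3$Q[growth_cones(tr3)[["gc1"]]], q0, tolerance = 1e-15)
  expect_equal(path_distance(tr3, 1L, growth_cones(tr3)[["gc1"]]), l0)
})

test_that("forced growth is skipped when the growth cone lacks tubulin", {
  p <- transport_params()
  tr <- set_concentration(build_y_tree(y_tree_spec(50e-6, 10e-6)),
                          uM_to_molm3(5.5))
  gc <- growth_cones(tr)[["gc1"]]
  l0 <- path_distance(tr, 1L, gc)
  # demanding +5 um needs 2e-19 mol, far above the ~4e-21 mol in the cone
  out <- forced_growth_step(tr, gc, growth_trace(c(0, 60), c(l0, l0 + 5e-6)),
                            60, p)
  expect_equal(out$length, tr$length)
  expect_equal(out$Q, tr$Q)
  expect_true(attr(out, "capped"))
  # a flat trace is a no-op
  out2 <- forced_growth_step(tr, gc, growth_trace(c(0, 60), c(l0, l0)), 60, p)
  expect_equal(out2$length, tr$length)
  expect_false(attr(out2, "capped"))
})

test_that("free elongation is capped so the growth-cone quantity stays non-negative", {
  p <- transport_params()
  tr <- set_concentration(build_y_tree(y_tree_spec(50e-6, 10e-6)),
                          uM_to_molm3(10))
  out <- grow_step(tr, "gc1", p, dt = 100, multiplier = 1e6)
  gc <- growth_cones(out)[["gc1"]]
  expect_true(attr(out, "capped"))
  expect_gte(out$Q[gc], 0)
  expect_equal(attr(out, "dl"),
               tr$Q[growth_cones(tr)[["gc1"]]] / p$X)
})

test_that("a neurite clamps at its minimum length instead of vanishing", {
  p <- transport_params()
  tr <- set_concentration(build_star_tree(1, neurite_length = 2e-6), 0)
  gc <- growth_cones(tr)[["gc1"]]
  l0 <- path_distance(tr, 1L, gc)
  for (i in 1:500) {
    tr <- grow_step(tr, "gc1", p, dt = 100)
    tr <- remesh(tr, p$l_split, p$l_merge)
  }
  gc <- growth_cones(tr)[["gc1"]]
  lmin <- path_distance(tr, 1L, gc)
  expect_gte(lmin, p$l_merge + p$gc_length - 1e-12)
  expect_lte(lmin, l0)
  expect_silent(validate_tree(tr))
})

test_that("perturbation events replace one multiplier and leave the rest", {
  mult <- c(gc1 = 1, gc2 = 1)
  mult <- apply_perturbation(mult, perturbation_event(36000, "gc1", 1.5))
  expect_equal(mult, c(gc1 = 1.5, gc2 = 1))
  mult <- apply_perturbation(mult, perturbation_event(0, "gc2", 2))
  expect_equal(mult, c(gc1 = 1.5, gc2 = 2))
  # re-applying the current value is a no-op
  expect_equal(apply_perturbation(mult, perturbation_event(0, "gc2", 2)), mult)
  expect_error(apply_perturbation(mult, perturbation_event(0, "gc9", 2)),
               "unknown growth cone")
})
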