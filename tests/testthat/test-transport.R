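test_that("diffusive flux follows Fick's law and is antisymmetric", {
  A <- pi * (1e-6)^2 / 4
  expect_equal(diffusive_flux(5e-3, 5e-3, A, 1e-6, 1e-11), 0)
  # hand unit calculation: D*A*dC/d with a 1 um interface over 1 um
  expect_equal(diffusive_flux(5.5e-3, 0, A, 1e-6, 1e-11), -4.32e-20,
               tolerance = 1e-3)
  set.seed(1)
  for (k in 1:20) {
    ci <- runif(1, 0, 1e-2)
    cj <- runif(1, 0, 1e-2)
    expect_equal(diffusive_flux(ci, cj, A, 1e-6, 1e-11),
                 -diffusive_flux(cj, ci, A, 1e-6, 1e-11))
  }
  expect_error(diffusive_flux(1e-3, 2e-3, A, 0, 1e-11), "degenerate")
})

test_that("advective flux is the upwind donor-cell form and linear in f and v", {
  A <- pi * (1e-6)^2 / 4
  expect_equal(advective_flux(5.5e-3, A, 6e-3, 0), 0)
  expect_equal(advective_flux(5.5e-3, A, 0, 440e-9), 0)
  # hand unit calculation: f*v*C*A
  expect_equal(advective_flux(5.5e-3, A, 6e-3, 440e-9), 1.14e-23,
               tolerance = 1e-3)
  expect_equal(advective_flux(5.5e-3, A, 2 * 6e-3, 440e-9),
               2 * advective_flux(5.5e-3, A, 6e-3, 440e-9))
})

test_that("a sealed system equilibrates and conserves mass exactly", {
  p <- transport_params(v = 0, b = 0)
  tree <- mk_cable(10e-6)
  # unequal initial concentrations
  tree$Q <- seq_along(tree$Q) * 1e-20
  q0 <- total_tubulin(tree)
  for (i in 1:2000) tree <- transport_step(tree, p, dt = 1, clamp_soma = FALSE)
  expect_equal(total_tubulin(tree), q0, tolerance = 1e-12)
  conc <- concentrations(tree)
  expect_lt(diff(range(conc)) / mean(conc), 1e-6)
})

test_that("implicit and explicit integrators agree as dt shrinks", {
  p <- transport_params()
  for (seed in 1:2) {
    tree <- random_tree(seed)
    tree <- set_concentration(tree, p$C_soma)
    set.seed(seed)
    tree$Q <- tree$Q * runif(n_compartments(tree), 0.5, 1.5)
    a <- b <- tree
    for (i in 1:200) {
      a <- transport_step(a, p, dt = 0.01, method = "implicit")
      b <- transport_step(b, p, dt = 0.01, method = "explicit")
    }
    expect_equal(a$Q, b$Q, tolerance = 1e-6)
  }
})

test_that("active transport accumulates tubulin distally in a sealed cable", {
  # strong transport so the distal pile-up is visible on a 10 um cable
  # (e-folding length D/(f*v) ~ 38 um)
  p <- transport_params(v = 4.4e-5, b = 0)
  tree <- mk_cable(10e-6)
  tree <- set_concentration(tree, 5e-3)
  for (i in 1:5000) tree <- transport_step(tree, p, dt = 1, clamp_soma = FALSE)
  conc <- concentrations(tree)
  tip <- growth_cones(tree)[[1]]
  expect_gt(conc[tip], conc[2] * 1.05)
})

test_that("steady state on a clamped cable matches the cosh closed form", {
  # strong decay so the profile is far from flat (lambda = 50 um on 100 um)
  p <- transport_params(v = 0, b = 4e-3)
  tree <- set_concentration(mk_cable(100e-6, soma_d = 0.2e-6), p$C_soma)
  for (i in 1:600) tree <- transport_step(tree, p, dt = 100)
  pr <- tree_profile(tree)[-1, ]
  x <- um_to_m(pr$path_um - pr$length_um / 2)
  exact <- steady_state_profile(x, 100e-6, p)
  expect_lt(max(abs(uM_to_molm3(pr$conc_uM) - exact) / exact), 0.01)
  # closed-form limiting cases
  expect_equal(steady_state_profile(c(0, 5e-5), 1e-4,
                                    transport_params(b = 0)),
               rep(transport_params()$C_soma, 2))
  expect_equal(steady_state_profile(0, 1e-4, p), p$C_soma)
})

test_that("halving the mesh size leaves the steady tip concentration within 0.5%", {
  p <- transport_params(v = 0, b = 4e-3)
  tips <- vapply(c(2.5e-6, 1.25e-6), function(piece) {
    tree <- set_concentration(mk_cable(100e-6, soma_d = 0.2e-6, piece = piece),
                              p$C_soma)
    for (i in 1:600) tree <- transport_step(tree, p, dt = 100)
    concentrations(tree)[growth_cones(tree)[[1]]]
  }, numeric(1))
  expect_lt(abs(tips[2] / tips[1] - 1), 0.005)
})

test_that("the per-step mass ledger closes: production - decay - consumption = dQ", {
  prot <- y_competition_protocol(params = transport_params(dt = 5),
                                 perturb_time = 3600, readout_after = 3600,
                                 multiplier = 1.5, dt = 5)
  res <- run_simulation(prot)
  scale <- max(abs(res$ledger[c("produced", "decayed", "consumed")]))
  expect_lt(abs(res$ledger[["residual"]]) / scale, 1e-9)
})

test_that("mirror compartments of a control Y-tree stay exactly symmetric", {
  prot <- y_competition_protocol(params = transport_params(dt = 5),
                                 perturb_time = 1800, readout_after = 5400,
                                 multiplier = 1, dt = 5)
  res <- run_simulation(prot)
  expect_identical(res$lengths[, "gc1"], res$lengths[, "gc2"])
  expect_identical(res$conc[, "gc1"], res$conc[, "gc2"])
})
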