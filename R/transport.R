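# Tubulin transport on the compartment tree: diffusion, anterograde active
# transport, first-order decay, and the clamped soma source, discretized as
# a conservative finite-volume scheme. The default integrator is backward
# Euler on the linear transport operator (unconditionally stable; the tree
# structure lets the sparse system be solved in O(n) without fill-in). An
# explicit Euler mode with a positivity check is kept for cross-validation.

#' Transport and growth model parameters
#'
#' Returns the full parameter set with literature-calibrated defaults:
#' diffusion constant `D` = 1e-11 m^2/s, active-transport bound fraction
#' `f` = 6e-3 carried at speed `v` = 440 nm/s, decay `b` = 5.67e-7 1/s,
#' tubulin cost per unit length `X` = 4e-14 mol/m (1640 dimers/um across
#' ~15 microtubules), polymerization rate `p` = 1.83e-6 m/(s*mM) and
#' depolymerization rate `q` = 9.17e-9 m/s (chosen so elongation is zero at
#' 5 uM and 0.033 mm/h at 10 uM), and a clamped soma concentration
#' `C_soma` = 5.5 uM. Since 1 mM = 1 mol/m^3, `p` applies directly to
#' concentrations held in mol/m^3.
#'
#' @param D tubulin diffusion constant, m^2/s.
#' @param f fraction of compartmental tubulin bound to active transport.
#' @param v active transport speed, m/s (anterograde).
#' @param b tubulin decay rate, 1/s.
#' @param X tubulin quantity consumed per unit neurite length, mol/m.
#' @param p polymerization rate, m/(s*mM).
#' @param q depolymerization rate, m/s (concentration-independent).
#' @param C_soma clamped soma concentration, mol/m^3 (5.5e-3 = 5.5 uM).
#' @param dt integration time step, s.
#' @param l_split compartment split threshold, m.
#' @param l_merge compartment merge threshold, m.
#' @param gc_length growth-cone compartment length, m (constant during growth).
#' @param interface_area how to pick the cross-section area between
#'   unequal-diameter neighbours: that of the distal compartment (default;
#'   flux limited by the narrower child at tapering branch points) or the
#'   mean of the two.
#' @return a list of class `transport_params`.
#' @export
transport_params <- function(D = 1e-11, f = 6e-3, v = 440e-9, b = 5.67e-7,
                             X = 4e-14, p = 1.83e-6, q = 9.17e-9,
                             C_soma = 5.5e-3, dt = 1,
                             l_split = 2.5e-6, l_merge = 0.5e-6,
                             gc_length = 1e-6,
                             interface_area = c("distal", "mean")) {
  interface_area <- match.arg(interface_area)
  for (nm in c("D", "f", "v", "b", "X", "p", "q", "C_soma", "dt",
               "l_split", "l_merge", "gc_length")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0) {
      stop("parameter ", nm, " must be a single non-negative number")
    }
  }
  if (f > 1) stop("the bound fraction f cannot exceed 1")
  if (dt <= 0) stop("dt must be positive")
  if (l_merge >= l_split) stop("l_merge must be smaller than l_split")
  structure(list(D = D, f = f, v = v, b = b, X = X, p = p, q = q,
                 C_soma = C_soma, dt = dt, l_split = l_split,
                 l_merge = l_merge, gc_length = gc_length,
                 interface_area = interface_area),
            class = "transport_params")
}

#' Diffusive flux between two neighbouring compartments
#'
#' Fick's law across the shared interface: `D * A * (C_j - C_i) / d`,
#' positive into compartment i. Antisymmetric under exchange of i and j.
#'
#' @param c_i,c_j concentrations of the two compartments, mol/m^3.
#' @param area interface cross-sectional area, m^2.
#' @param d distance between compartment centres, m.
#' @param D diffusion constant, m^2/s.
#' @return flux in mol/s (signed, positive into i).
#' @export
diffusive_flux <- function(c_i, c_j, area, d, D) {
  if (any(d <= 0)) stop("degenerate geometry: centre distance must be positive")
  D * area * (c_j - c_i) / d
}

#' Anterograde advective flux out of a compartment
#'
#' The fraction `f` of the donor (proximal) compartment's tubulin is carried
#' at speed `v` across the distal interface: `f * v * c * A` (upwind,
#' donor-cell form).
#'
#' @param c_prox donor (proximal) compartment concentration, mol/m^3.
#' @param area interface cross-sectional area, m^2.
#' @param f bound fraction.
#' @param v transport speed, m/s.
#' @return flux in mol/s (anterograde, soma to tip).
#' @export
advective_flux <- function(c_prox, area, f, v) {
  f * v * c_prox * area
}

# per-compartment coupling coefficients with the parent:
#   g[i]  diffusive exchange, m^3/s
#   adv[i] advective donor coefficient, m^3/s
# Interface area follows params$interface_area; the centre distance to the
# soma uses the soma radius as the soma's half-length.
transport_coefficients <- function(tree, params) {
  area <- compartment_areas(tree)
  half <- tree$length / 2
  half[1] <- tree$diam[1] / 2 # soma: centre-to-surface = radius
  p_idx <- tree$parent
  p_idx[1] <- 1L # self-reference, rows for the root are zeroed below
  a_int <- if (params$interface_area == "distal") area else
    (area + area[p_idx]) / 2
  d <- half + half[p_idx]
  g <- params$D * a_int / d
  # advection splits between children proportionally to their cross-sections
  # automatically, because each child's coefficient uses its own area
  adv <- params$f * params$v * a_int
  g[1] <- 0
  adv[1] <- 0
  list(g = g, adv = adv)
}

#' Advance tubulin transport by one time step
#'
#' Updates every compartment's tubulin quantity by the net diffusive and
#' advective exchange with its neighbours minus first-order decay, holding
#' the soma at its clamped concentration (Dirichlet condition). The implicit
#' method is unconditionally stable and positivity-preserving; the explicit
#' method is a plain forward-Euler update used for cross-validation and
#' stops with an error if the step is unstable.
#'
#' The returned tree carries a `"ledger"` attribute with the tubulin mass
#' injected by the soma clamp (`produced`, mol) and lost to decay
#' (`decayed`, mol) during the step, both evaluated at the end-of-step
#' state consistently with the implicit update.
#'
#' @param tree a `neurite_tree`.
#' @param params a [transport_params()] object.
#' @param dt time step, s (defaults to `params$dt`).
#' @param clamp_soma hold the soma at `params$C_soma` (the model's source).
#'   With `FALSE` the system is sealed (used for conservation audits).
#' @param method `"implicit"` (backward Euler, default) or `"explicit"`.
#' @return the tree with updated quantities.
#' @export
transport_step <- function(tree, params, dt = params$dt, clamp_soma = TRUE,
                           method = c("implicit", "explicit")) {
  method <- match.arg(method)
  co <- transport_coefficients(tree, params)
  vol <- compartment_volumes(tree)
  root_value <- params$C_soma * vol[1]
  if (clamp_soma) tree$Q[1] <- root_value
  if (method == "implicit") {
    par0 <- tree$parent - 1L
    par0[1] <- -1L
    qnew <- be_transport_step(par0, co$g, co$adv, vol, params$b, dt, tree$Q,
                              clamp_soma, root_value)
  } else {
    qnew <- explicit_transport_step(tree, co, vol, params$b, dt,
                                    clamp_soma, root_value)
  }
  if (any(qnew < -1e-12 * max(qnew))) {
    stop("transport step produced negative tubulin quantities; reduce dt")
  }
  ledger <- transport_ledger(tree, co, vol, qnew, params, dt, clamp_soma)
  if (any(qnew < 0)) qnew <- pmax(qnew, 0)
  tree$Q <- qnew
  attr(tree, "ledger") <- ledger
  tree
}

# forward-Euler reference update (donor-cell advection, same coefficients)
explicit_transport_step <- function(tree, co, vol, b, dt, clamp_soma,
                                    root_value) {
  n <- n_compartments(tree)
  conc <- tree$Q / vol
  dQ <- -b * tree$Q
  if (clamp_soma) dQ[1] <- 0
  i <- which(!is.na(tree$parent))
  p <- tree$parent[i]
  f_diff <- co$g[i] * (conc[p] - conc[i])   # into child from parent
  f_adv <- co$adv[i] * conc[p]
  dQ[i] <- dQ[i] + f_diff + f_adv
  out <- rowsum(f_diff + f_adv, p)          # leaves the parent
  pj <- as.integer(rownames(out))
  dQ[pj] <- dQ[pj] - out[, 1]
  qnew <- tree$Q + dt * dQ
  if (clamp_soma) qnew[1] <- root_value
  if (any(qnew < 0)) {
    stop("explicit transport step unstable (negative quantity); reduce dt")
  }
  qnew
}

# production (soma injection) and decay over the step, evaluated at the
# end-of-step concentrations so the mass ledger closes with backward Euler
transport_ledger <- function(tree, co, vol, qnew, params, dt, clamp_soma) {
  cnew <- qnew / vol
  decayed <- params$b * dt * sum(qnew[-1])
  produced <- 0
  if (clamp_soma) {
    kids <- which(!is.na(tree$parent) & tree$parent == 1L)
    produced <- dt * sum(co$g[kids] * (cnew[1] - cnew[kids]) +
                           co$adv[kids] * cnew[1])
  } else {
    decayed <- decayed + params$b * dt * qnew[1]
  }
  c(produced = produced, decayed = decayed)
}

#' Closed-form steady-state concentration profile of a sealed cable
#'
#' For an unbranched neurite of length `L` with a clamped proximal
#' concentration, a sealed distal tip, pure diffusion (`v = 0`) and decay
#' `b`, the steady state is
#' `C(x) = C_soma * cosh((L - x)/lambda) / cosh(L/lambda)` with
#' `lambda = sqrt(D/b)`. Serves as the analytic oracle for the transport
#' solver. With `b = 0` the profile is uniform at `C_soma`.
#'
#' @param x positions along the cable from the clamped end, m.
#' @param L cable length, m.
#' @param params a [transport_params()] object (uses `D`, `b`, `C_soma`).
#' @return concentrations at `x`, mol/m^3.
#' @export
steady_state_profile <- function(x, L, params) {
  stopifnot(all(x >= 0), all(x <= L + 1e-12))
  if (params$b == 0) return(rep(params$C_soma, length(x)))
  lambda <- sqrt(params$D / params$b)
  params$C_soma * cosh((L - x) / lambda) / cosh(L / lambda)
}
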