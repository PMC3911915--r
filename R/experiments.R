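# Competition experiments: Y-tree perturbation protocols and parameter
# sweeps, the complex-tree total-relative-retraction statistic, the replay
# fitting error, and exhaustive grid-search fitting of transport parameters
# to observed growth-cone traces.

#' Y-tree perturbation protocol
#'
#' The canonical simple-morphology competition experiment: a Y-shaped neuron
#' grows freely for `perturb_time`, then one growth cone's polymerization
#' rate is multiplied by `multiplier` and the simulation continues for
#' `readout_after` more. With `multiplier = 1` this is the control run.
#'
#' @param d_a,d_b Y-tree geometry, m (trunk and daughter lengths).
#' @param params a [transport_params()] object.
#' @param perturb_time time of the perturbation, s.
#' @param readout_after simulated time after the perturbation, s.
#' @param multiplier polymerization multiplier applied to `"gc1"`.
#' @param dt time step, s.
#' @param diameter neurite diameter, m.
#' @param output_interval recording interval, s.
#' @return a [protocol()].
#' @export
y_competition_protocol <- function(d_a = 50e-6, d_b = 10e-6,
                                   params = transport_params(),
                                   perturb_time = 10 * 3600,
                                   readout_after = 30 * 3600,
                                   multiplier = 1.5, dt = params$dt,
                                   diameter = 1e-6, output_interval = 600) {
  tree <- build_y_tree(y_tree_spec(d_a, d_b, diameter),
                       gc_length = params$gc_length)
  events <- if (multiplier != 1) {
    list(perturbation_event(perturb_time, "gc1", multiplier))
  } else {
    list()
  }
  protocol(tree, params = params, duration = perturb_time + readout_after,
           dt = dt, output_interval = output_interval, events = events)
}

# value of a result's length curve at (or nearest below) time t, per gc
lengths_at <- function(res, t) {
  i <- max(which(res$times <= t + 1e-6))
  res$lengths[i, ]
}

#' Parameter / geometry sweep of the Y-tree competition experiment
#'
#' Runs the perturbation protocol over a grid along one axis and reports,
#' per grid point, the modified (`gc1`) and neighbouring (`gc2`)
#' soma-to-growth-cone path lengths at the read-out time and the
#' neighbour's length change since the perturbation (negative = retraction).
#'
#' Axes: `"D"` (diffusion constant, m^2/s), `"v"` (active transport speed,
#' m/s), or `"geometry"` (a data.frame grid with columns `d_a`, `d_b`, m).
#' A failing grid point is recorded with `NA` read-outs and the sweep
#' continues.
#'
#' @param axis sweep axis.
#' @param values numeric vector (`"D"`, `"v"`) or data.frame (`"geometry"`).
#' @param d_a,d_b base Y-tree geometry, m.
#' @param params base parameters.
#' @param perturb_time,readout_after,multiplier,dt protocol settings
#'   (see [y_competition_protocol()]).
#' @return a data.frame, one row per grid point, with `len_mod_um`,
#'   `len_neigh_um`, `neigh_change_um` at read-out.
#' @export
competition_sweep <- function(axis = c("D", "v", "geometry"), values,
                              d_a = 50e-6, d_b = 10e-6,
                              params = transport_params(),
                              perturb_time = 10 * 3600,
                              readout_after = 30 * 3600,
                              multiplier = 1.5, dt = params$dt) {
  axis <- match.arg(axis)
  grid <- if (axis == "geometry") {
    stopifnot(is.data.frame(values), all(c("d_a", "d_b") %in% names(values)))
    values
  } else {
    data.frame(value = values)
  }
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    pk <- params
    da <- d_a
    db <- d_b
    if (axis == "D") pk$D <- grid$value[k]
    if (axis == "v") pk$v <- grid$value[k]
    if (axis == "geometry") {
      da <- grid$d_a[k]
      db <- grid$d_b[k]
    }
    out <- data.frame(grid[k, , drop = FALSE],
                      len_mod_um = NA_real_, len_neigh_um = NA_real_,
                      neigh_change_um = NA_real_)
    res <- tryCatch({
      prot <- y_competition_protocol(da, db, pk, perturb_time, readout_after,
                                     multiplier, dt)
      run_simulation(prot)
    }, error = function(e) {
      warning("sweep point ", k, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      at_perturb <- lengths_at(res, perturb_time)
      final <- lengths_at(res, perturb_time + readout_after)
      out$len_mod_um <- m_to_um(final[["gc1"]])
      out$len_neigh_um <- m_to_um(final[["gc2"]])
      out$neigh_change_um <- m_to_um(final[["gc2"]] - at_perturb[["gc2"]])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total relative retraction: the complex-tree competition statistic
#'
#' Sum over all non-modified growth cones of their retraction relative to
#' the control run at the same horizon (negative retraction, i.e. extra
#' growth, contributes zero), divided by the growth of the modified growth
#' cone over the perturbed run.
#'
#' @param control a `simulation_result` of the unperturbed run.
#' @param perturbed a `simulation_result` of the same tree and horizon with
#'   one growth cone's polymerization rate increased.
#' @param modified_gc label of the modified growth cone.
#' @return dimensionless non-negative statistic.
#' @export
total_relative_retraction <- function(control, perturbed, modified_gc) {
  labels <- colnames(control$lengths)
  stopifnot(identical(labels, colnames(perturbed$lengths)))
  if (!modified_gc %in% labels) stop("unknown growth cone: ", modified_gc)
  nt <- nrow(perturbed$lengths)
  growth <- perturbed$lengths[nt, modified_gc] - perturbed$lengths[1, modified_gc]
  if (growth <= 0) {
    stop("undefined statistic: the modified growth cone did not grow")
  }
  others <- setdiff(labels, modified_gc)
  retraction <- pmax(control$lengths[nrow(control$lengths), others] -
                       perturbed$lengths[nt, others], 0)
  unname(sum(retraction) / growth)
}

#' Replay fitting error between a simulated and an observed trace
#'
#' The square root of the summed squared deviation of the simulated
#' soma-to-growth-cone path length from the observed one, over the observed
#' sample times (simulated lengths are linearly interpolated).
#'
#' @param simulated a [growth_trace()] produced by the model.
#' @param observed a [growth_trace()] of observations.
#' @return error in m.
#' @export
error_measure <- function(simulated, observed) {
  if (length(observed$times) == 0) stop("empty observed trace")
  sim_at <- trace_interp(simulated, observed$times)
  sqrt(sum((sim_at - observed$lengths)^2))
}

# log-spaced grid; a zero lower bound contributes the point 0 and the rest
# of the axis is log-spaced over the top two decades
log_grid <- function(lo, hi, n) {
  if (n == 1) return(hi)
  if (lo <= 0) {
    if (n == 2) return(c(0, hi))
    return(c(0, exp(seq(log(hi / 100), log(hi), length.out = n - 1))))
  }
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Grid specification for exhaustive parameter fitting
#'
#' Default ranges follow the replay-fitting search space: `D` in
#' \[1e-13, 0.5e-10\] m^2/s, `v` in \[0, 440e-7\] m/s, `b` in
#' \[5.67e-7, 5.67e-4\] 1/s, and `C_soma` in \[5.5, 50\] uM. `D`, `v`
#' and `b` axes are log-spaced (with 0 kept as the first `v` point),
#' `C_soma` is linear.
#'
#' @param D_range,v_range,b_range,C_soma_range axis ranges (SI units;
#'   `C_soma_range` in mol/m^3).
#' @param n_points points per axis (>= 2 for a swept axis; scalar or
#'   per-axis vector of length 4).
#' @param free_gc label of the growth cone left free during fitting.
#' @param traces named list of observed [growth_trace()] objects for all
#'   growth cones (the non-free ones are replayed in forced mode).
#' @return a list of class `grid_search_spec` with the expanded `grid`.
#' @export
grid_search_spec <- function(D_range = c(1e-13, 0.5e-10),
                             v_range = c(0, 440e-7),
                             b_range = c(5.67e-7, 5.67e-4),
                             C_soma_range = c(5.5e-3, 50e-3),
                             n_points = 3, free_gc, traces) {
  n_points <- rep(n_points, length.out = 4)
  stopifnot(all(n_points >= 1), free_gc %in% names(traces))
  grid <- expand.grid(
    D = log_grid(D_range[1], D_range[2], n_points[1]),
    v = log_grid(v_range[1], v_range[2], n_points[2]),
    b = log_grid(b_range[1], b_range[2], n_points[3]),
    C_soma = seq(C_soma_range[1], C_soma_range[2], length.out = n_points[4]),
    KEEP.OUT.ATTRS = FALSE
  )
  structure(list(grid = grid, free_gc = free_gc, traces = traces),
            class = "grid_search_spec")
}

#' Exhaustive grid-search fit of transport parameters to observed traces
#'
#' For every point of the grid, the model is run in forced-growth replay
#' mode: all growth cones except `free_gc` are forced to follow their
#' observed traces, the free one is governed by the model, and the replay
#' error ([error_measure()]) of the free growth cone against its observed
#' trace is recorded. Grid points are independent and evaluated in
#' deterministic grid order; a failing point is recorded with infinite
#' error. Rows are returned sorted by error, best first.
#'
#' @param spec a [grid_search_spec()].
#' @param tree starting morphology (must carry all trace growth cones).
#' @param params base parameters; each grid point overrides `D`, `v`, `b`
#'   and `C_soma`.
#' @param duration replay duration, s (default: the free trace's support).
#' @param dt time step, s.
#' @param max_points safety cap on the grid size.
#' @return a data.frame with columns `D`, `v`, `b`, `C_soma`,
#'   `error_m`, `error_um`, sorted by error.
#' @export
grid_search_fit <- function(spec, tree, params = transport_params(),
                            duration = NULL, dt = params$dt,
                            max_points = 2000) {
  stopifnot(inherits(spec, "grid_search_spec"))
  if (nrow(spec$grid) > max_points) {
    stop("grid has ", nrow(spec$grid), " points, above the cap of ", max_points)
  }
  obs <- spec$traces[[spec$free_gc]]
  if (is.null(duration)) duration <- max(obs$times)
  forced <- spec$traces[setdiff(names(spec$traces), spec$free_gc)]
  errors <- vapply(seq_len(nrow(spec$grid)), function(k) {
    pk <- params
    pk$D <- spec$grid$D[k]
    pk$v <- spec$grid$v[k]
    pk$b <- spec$grid$b[k]
    pk$C_soma <- spec$grid$C_soma[k]
    tryCatch({
      prot <- protocol(tree, params = pk, duration = duration, dt = dt,
                       output_interval = min(diff(obs$times)),
                       forced = forced)
      res <- run_simulation(prot)
      error_measure(result_trace(res, spec$free_gc), obs)
    }, error = function(e) Inf)
  }, numeric(1))
  out <- cbind(spec$grid, error_m = errors, error_um = m_to_um(errors))
  out <- out[order(out$error_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}
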