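# Simulation driver: a protocol bundles the morphology, parameters,
# perturbation events and forced traces; run_simulation advances the model
# with operator splitting (implicit transport -> growth -> remesh -> record)
# and returns per-growth-cone time series plus a mass ledger.

#' Simulation protocol
#'
#' @param tree the starting morphology, a `neurite_tree`.
#' @param params a [transport_params()] object.
#' @param duration total simulated time, s.
#' @param dt time step, s (defaults to `params$dt`).
#' @param output_interval recording interval, s (must not exceed `duration`).
#' @param events list of [perturbation_event()] objects.
#' @param forced named list of [growth_trace()] objects; the named growth
#'   cones are replayed in forced mode, all others grow freely.
#' @param init_conc initial tubulin concentration everywhere, mol/m^3
#'   (default: the soma concentration, i.e. the tree starts equilibrated
#'   with the source).
#' @param clamp_soma hold the soma at `params$C_soma` (default TRUE).
#' @param record_snapshots also record full per-compartment concentration
#'   profiles at every output time.
#' @return a list of class `protocol`.
#' @export
protocol <- function(tree, params = transport_params(), duration,
                     dt = params$dt, output_interval = 600,
                     events = list(), forced = list(),
                     init_conc = params$C_soma, clamp_soma = TRUE,
                     record_snapshots = FALSE) {
  stopifnot(inherits(tree, "neurite_tree"), inherits(params, "transport_params"),
            duration > 0, dt > 0, output_interval <= duration)
  if (inherits(events, "perturbation_event")) events <- list(events)
  labels <- names(growth_cones(tree))
  for (ev in events) {
    if (!ev$gc %in% labels) stop("perturbation targets unknown growth cone: ", ev$gc)
  }
  if (length(forced) && !all(names(forced) %in% labels)) {
    stop("forced traces reference unknown growth cones")
  }
  structure(list(tree = tree, params = params, duration = duration, dt = dt,
                 output_interval = output_interval, events = events,
                 forced = forced, init_conc = init_conc,
                 clamp_soma = clamp_soma,
                 record_snapshots = record_snapshots),
            class = "protocol")
}

#' Run a simulation protocol
#'
#' Deterministic given the protocol: the same protocol reproduces the same
#' result bit for bit. Each step applies, in order: pending perturbation
#' events, one implicit transport step (soma clamped), one growth step per
#' growth cone (free kinetics or forced replay), and remeshing; the state is
#' recorded on the output grid.
#'
#' @param prot a [protocol()].
#' @return a list of class `simulation_result` with elements `times` (s),
#'   `lengths` and `conc` (time x growth-cone matrices: soma-to-growth-cone
#'   path length in m and growth-cone concentration in mol/m^3), `tree`
#'   (final morphology), `ledger` (cumulative produced / decayed / consumed
#'   tubulin in mol and the residual of the mass balance), and `events`
#'   (counts of capped growth steps and remesh operations). With
#'   `record_snapshots`, `snapshots` holds per-output-time data frames of
#'   compartment path positions and concentrations.
#' @export
run_simulation <- function(prot) {
  params <- prot$params
  dt <- prot$dt
  tree <- set_concentration(prot$tree, prot$init_conc)
  if (prot$clamp_soma) tree$Q[1] <- params$C_soma * compartment_volumes(tree)[1]

  gcs <- growth_cones(tree)
  labels <- names(gcs)
  mult <- setNames(rep(1, length(gcs)), labels)
  pending <- prot$events[order(vapply(prot$events, `[[`, numeric(1), "time"))]

  n_steps <- max(1L, round(prot$duration / dt))
  rec_every <- max(1L, round(prot$output_interval / dt))
  n_rec <- floor(n_steps / rec_every) + 1L
  times <- numeric(n_rec)
  lengths <- matrix(NA_real_, n_rec, length(labels),
                    dimnames = list(NULL, labels))
  conc <- matrix(NA_real_, n_rec, length(labels),
                 dimnames = list(NULL, labels))
  snapshots <- if (prot$record_snapshots) vector("list", n_rec) else NULL

  q0 <- total_tubulin(tree)
  produced <- decayed <- consumed <- 0
  capped_events <- 0L
  remesh_splits <- remesh_merges <- 0L

  record <- function(slot, t) {
    times[slot] <<- t
    gc_now <- growth_cones(tree)
    vols <- compartment_volumes(tree)
    for (lab in labels) {
      i <- gc_now[[lab]]
      lengths[slot, lab] <<- path_distance(tree, 1L, i)
      conc[slot, lab] <<- tree$Q[i] / vols[i]
    }
    if (prot$record_snapshots) snapshots[[slot]] <<- tree_profile(tree)
  }
  record(1L, 0)

  for (s in seq_len(n_steps)) {
    t0 <- (s - 1) * dt
    while (length(pending) && pending[[1]]$time <= t0 + 1e-9) {
      mult <- apply_perturbation(mult, pending[[1]])
      pending <- pending[-1]
    }
    tree <- transport_step(tree, params, dt, clamp_soma = prot$clamp_soma)
    led <- attr(tree, "ledger")
    produced <- produced + led[["produced"]]
    decayed <- decayed + led[["decayed"]]
    gc_now <- growth_cones(tree)
    for (lab in labels) {
      if (lab %in% names(prot$forced)) {
        tree <- forced_growth_step(tree, gc_now[[lab]], prot$forced[[lab]],
                                   t0 + dt, params)
      } else {
        tree <- grow_step(tree, gc_now[[lab]], params, dt, mult[[lab]])
      }
      consumed <- consumed + attr(tree, "consumed")
      if (attr(tree, "capped")) capped_events <- capped_events + 1L
    }
    tree <- remesh(tree, params$l_split, params$l_merge)
    ev <- attr(tree, "remesh_events")
    remesh_splits <- remesh_splits + ev[["splits"]]
    remesh_merges <- remesh_merges + ev[["merges"]]
    if (s %% rec_every == 0L) record(s %/% rec_every + 1L, s * dt)
  }

  residual <- (total_tubulin(tree) - q0) - (produced - decayed - consumed)
  structure(list(
    times = times, lengths = lengths, conc = conc, tree = tree,
    ledger = c(produced = produced, decayed = decayed, consumed = consumed,
               residual = residual),
    events = c(capped = capped_events, splits = remesh_splits,
               merges = remesh_merges),
    protocol = prot
  ), class = "simulation_result")
}

#' Per-compartment path positions and concentrations
#'
#' One row per compartment: distal-end path distance to the soma (um),
#' length, diameter, kind, growth-cone label, and tubulin concentration
#' (uM). Together with the parent column this is a dendrogram-ready table
#' (branch intervals plus mean concentration per compartment).
#'
#' @param tree a `neurite_tree`.
#' @return a data.frame.
#' @export
tree_profile <- function(tree) {
  n <- n_compartments(tree)
  pos <- vapply(seq_len(n), function(i) path_distance(tree, 1L, i), numeric(1))
  data.frame(
    compartment = seq_len(n),
    parent = tree$parent,
    kind = tree$kind,
    growth_cone = tree$gc_label,
    path_um = m_to_um(pos),
    length_um = m_to_um(tree$length),
    diam_um = m_to_um(tree$diam),
    conc_uM = molm3_to_uM(concentrations(tree))
  )
}

#' Tidy long-format table of a simulation result
#'
#' @param res a `simulation_result`.
#' @return a data.frame with columns `time_h`, `growth_cone`,
#'   `path_length_um`, `conc_uM`.
#' @export
result_table <- function(res) {
  labels <- colnames(res$lengths)
  do.call(rbind, lapply(labels, function(lab) {
    data.frame(time_h = res$times / 3600, growth_cone = lab,
               path_length_um = m_to_um(res$lengths[, lab]),
               conc_uM = molm3_to_uM(res$conc[, lab]))
  }))
}

#' Extract one growth cone's simulated trace from a result
#' @param res a `simulation_result`.
#' @param gc growth-cone label.
#' @return a [growth_trace()].
#' @export
result_trace <- function(res, gc) {
  if (!gc %in% colnames(res$lengths)) stop("unknown growth cone: ", gc)
  growth_trace(res$times, res$lengths[, gc])
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", nrow(x$lengths), " samples over ",
      signif(max(x$times) / 3600, 4), " h, ", ncol(x$lengths),
      " growth cones\n", sep = "")
  fin <- signif(m_to_um(x$lengths[nrow(x$lengths), ]), 4)
  cat("  final path lengths (um): ",
      paste0(colnames(x$lengths), "=", fin, collapse = ", "), "\n", sep = "")
  cat("  events: ", paste0(names(x$events), "=", x$events, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
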