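# Growth-cone kinetics: tubulin concentration in the growth-cone compartment
# sets the elongation rate; elongation consumes tubulin (X per unit length)
# and retraction releases it back into the growth cone. The growth cone
# itself keeps a constant size; the unique shaft compartment directly
# proximal to it (the "elongating compartment") absorbs all length changes,
# and remeshing keeps the mesh within bounds afterwards.

#' Neurite elongation rate from growth-cone tubulin concentration
#'
#' `dL/dt = multiplier * p * C - q`. Polymerization is proportional to the
#' free-tubulin concentration; depolymerization `q` is concentration
#' independent (disassembly from existing microtubules). Negative values
#' mean retraction. With the default parameters the rate is zero at
#' `q/p` (about 5 uM) and 0.033 mm/h at 10 uM.
#'
#' @param conc growth-cone tubulin concentration, mol/m^3.
#' @param params a [transport_params()] object (uses `p`, `q`).
#' @param multiplier polymerization-rate multiplier (1 = unperturbed,
#'   1.5 = +50 percent, 2 = +100 percent).
#' @return elongation rate in m/s (vectorized over `conc`).
#' @export
elongation_rate <- function(conc, params, multiplier = 1) {
  stopifnot(all(conc >= 0), multiplier > 0)
  multiplier * params$p * conc - params$q
}

# index of the elongating compartment for a growth cone; the growth step
# edits this compartment's length, never the growth cone's
elongating_compartment <- function(tree, gc_idx) {
  p <- tree$parent[gc_idx]
  if (is.na(p) || tree$kind[p] != KIND_SHAFT) {
    stop("growth cone ", gc_idx, " has no proximal shaft compartment")
  }
  p
}

# apply a length change dl at a growth cone with tubulin bookkeeping.
# Positive dl consumes X*dl from the growth-cone compartment (capped so the
# quantity never goes negative); negative dl releases X*|dl| back into it.
# Retraction is clamped so the elongating shaft keeps a minimal length:
# the mesh floor if its parent is a plain shaft (the merge then absorbs it),
# or l_merge if its parent is the soma or a branch point (the neurite is
# clamped at minimum length and never vanishes).
apply_length_change <- function(tree, gc_idx, dl, params) {
  sh <- elongating_compartment(tree, gc_idx)
  capped <- FALSE
  if (dl > 0) {
    avail <- tree$Q[gc_idx] / params$X
    if (dl > avail) {
      dl <- avail
      capped <- TRUE
    }
  } else if (dl < 0) {
    p2 <- tree$parent[sh]
    floor_len <- if (tree$kind[p2] == KIND_SHAFT && n_children(tree)[p2] == 1L) {
      0.2 * params$l_merge
    } else {
      params$l_merge
    }
    min_dl <- floor_len - tree$length[sh]
    if (dl < min_dl) {
      dl <- min(min_dl, 0)
      capped <- TRUE
    }
  }
  tree$length[sh] <- tree$length[sh] + dl
  tree$Q[gc_idx] <- max(tree$Q[gc_idx] - params$X * dl, 0)
  list(tree = tree, dl = dl, consumed = params$X * dl, capped = capped)
}

#' Advance one growth cone by one free-growth step
#'
#' The elongation rate is evaluated at the growth-cone compartment's
#' concentration at the start of the step (explicit coupling within the
#' operator split). The length change is applied to the elongating shaft
#' compartment; tubulin `X * dL` is consumed on elongation and released on
#' retraction. Call [remesh()] afterwards to restore mesh bounds.
#'
#' @param tree a `neurite_tree`.
#' @param gc growth-cone label or compartment index.
#' @param params a [transport_params()] object.
#' @param dt time step, s.
#' @param multiplier polymerization-rate multiplier for this growth cone.
#' @return the updated tree; attributes `"dl"` (m, the applied length
#'   change), `"consumed"` (mol, negative on release) and `"capped"`
#'   (logical, whether a positivity or minimum-length guard engaged).
#' @export
grow_step <- function(tree, gc, params, dt, multiplier = 1) {
  gc_idx <- resolve_node(tree, gc)
  if (tree$kind[gc_idx] != KIND_GC) stop("compartment ", gc, " is not a growth cone")
  vol <- pi * tree$diam[gc_idx]^2 / 4 * tree$length[gc_idx]
  conc <- tree$Q[gc_idx] / vol
  dl <- elongation_rate(conc, params, multiplier) * dt
  out <- apply_length_change(tree, gc_idx, dl, params)
  tree <- out$tree
  attr(tree, "dl") <- out$dl
  attr(tree, "consumed") <- out$consumed
  attr(tree, "capped") <- out$capped
  tree
}

#' Advance one growth cone by one forced-growth (replay) step
#'
#' The target neurite length at `t` is linearly interpolated from the
#' observed trace (held constant beyond its last sample). If the requested
#' elongation would need more tubulin than the growth-cone compartment
#' holds, the neurite is not allowed to grow out this step (length
#' unchanged). Retraction is always allowed and releases `X * |dL|`.
#'
#' @param tree a `neurite_tree`.
#' @param gc growth-cone label or compartment index.
#' @param trace a [growth_trace()] of soma-to-growth-cone path lengths.
#' @param t simulation time at the end of the step, s.
#' @param params a [transport_params()] object.
#' @return the updated tree, with the same attributes as [grow_step()].
#' @export
forced_growth_step <- function(tree, gc, trace, t, params) {
  gc_idx <- resolve_node(tree, gc)
  target <- trace_interp(trace, t)
  current <- path_distance(tree, 1L, gc_idx)
  dl <- target - current
  if (dl > 0 && params$X * dl > tree$Q[gc_idx]) {
    attr(tree, "dl") <- 0
    attr(tree, "consumed") <- 0
    attr(tree, "capped") <- TRUE
    return(tree)
  }
  out <- apply_length_change(tree, gc_idx, dl, params)
  tree <- out$tree
  attr(tree, "dl") <- out$dl
  attr(tree, "consumed") <- out$consumed
  attr(tree, "capped") <- out$capped
  tree
}

#' Perturbation event: change a growth cone's polymerization rate
#'
#' @param time simulation time at which the change takes effect, s.
#' @param gc growth-cone label.
#' @param multiplier new polymerization-rate multiplier (1.5 = +50 percent,
#'   2 = +100 percent).
#' @return a list of class `perturbation_event`.
#' @export
perturbation_event <- function(time, gc, multiplier) {
  stopifnot(time >= 0, multiplier > 0)
  structure(list(time = time, gc = gc, multiplier = multiplier),
            class = "perturbation_event")
}

#' Apply a perturbation event to a multiplier state
#'
#' Replaces the target growth cone's polymerization multiplier, leaving all
#' others untouched.
#'
#' @param multipliers named numeric vector of per-growth-cone multipliers.
#' @param event a [perturbation_event()].
#' @return the updated multiplier vector.
#' @export
apply_perturbation <- function(multipliers, event) {
  if (!event$gc %in% names(multipliers)) {
    stop("unknown growth cone in perturbation event: ", event$gc)
  }
  multipliers[[event$gc]] <- event$multiplier
  multipliers
}
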