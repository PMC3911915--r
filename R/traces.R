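# Growth-cone traces: time series of soma-to-growth-cone path length, the
# observable extracted from time-lapse imaging of outgrowing neurons. Used
# both as the target of forced-growth replay and as the reference of the
# fitting error. On disk: two-column whitespace text, time in minutes and
# path length in micrometres, one file per growth cone.

#' Growth-cone path-length trace
#'
#' @param times sample times, s (strictly increasing).
#' @param lengths soma-to-growth-cone path lengths, m (non-negative).
#' @return a list of class `growth_trace`.
#' @export
growth_trace <- function(times, lengths) {
  stopifnot(length(times) == length(lengths), length(times) >= 1)
  if (any(diff(times) <= 0)) stop("trace times must be strictly increasing")
  if (any(lengths < 0)) stop("trace lengths must be non-negative")
  structure(list(times = as.numeric(times), lengths = as.numeric(lengths)),
            class = "growth_trace")
}

# linear interpolation at time t (s); constant beyond the trace support
trace_interp <- function(trace, t) {
  approx(trace$times, trace$lengths, xout = t, rule = 2)$y
}

#' Write a growth trace to a two-column text file (minutes, micrometres)
#' @param trace a [growth_trace()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_growth_trace <- function(trace, path) {
  df <- data.frame(time_minutes = s_to_min(trace$times),
                   path_length_micron = m_to_um(trace$lengths))
  writeLines(c("# time_minutes path_length_micron",
               sprintf("%.6f %.6f", df$time_minutes, df$path_length_micron)),
             path)
  invisible(path)
}

#' Read a growth trace written by [write_growth_trace()]
#' @param path input file path.
#' @return a [growth_trace()].
#' @export
read_growth_trace <- function(path) {
  df <- read.table(path, comment.char = "#", col.names = c("t", "l"))
  growth_trace(min_to_s(df$t), um_to_m(df$l))
}

#' Synthetic three-neurite growth traces
#'
#' Emulates the outgrowth pattern of a developing neuron in culture followed
#' by time-lapse imaging: a first neurite grows out immediately and stalls,
#' a second neurite appears after 980 minutes, grows and stalls, and a third
#' appears after 1650 minutes, initially growing slowly and then exhibiting
#' a late growth spurt. Traces are sampled every 10 minutes over 2940
#' minutes, with small seeded measurement jitter after each onset (lengths
#' before a neurite's onset are exactly its initial stub length). These
#' traces are synthetic stand-ins for hand-tracked movie data.
#'
#' With `template = "model-generated"`, the simulator itself is run on a
#' three-neurite star morphology with all growth cones free, and the true
#' simulated traces are returned (used for parameter-recovery tests); in
#' that case `params` selects the generating parameter set.
#'
#' @param seed integer seed for the jitter (ignored for model-generated).
#' @param template `"fig4-like"` (synthetic culture-like traces) or
#'   `"model-generated"`.
#' @param params a [transport_params()] object (model-generated template).
#' @param duration total trace duration, s.
#' @param sample_interval trace sampling interval, s.
#' @param stub_length initial neurite length, m.
#' @return a named list of three [growth_trace()] objects (`gc1..gc3`).
#' @export
make_synthetic_traces <- function(seed = 1,
                                  template = c("fig4-like", "model-generated"),
                                  params = transport_params(),
                                  duration = min_to_s(2940),
                                  sample_interval = min_to_s(10),
                                  stub_length = 2e-6) {
  template <- match.arg(template)
  if (template == "model-generated") {
    tree <- build_star_tree(3, neurite_length = stub_length)
    prot <- protocol(tree, params = params, duration = duration,
                     output_interval = sample_interval)
    res <- run_simulation(prot)
    return(lapply(setNames(colnames(res$lengths), colnames(res$lengths)),
                  function(gc) growth_trace(res$times, res$lengths[, gc])))
  }
  set.seed(seed)
  tmin <- seq(0, s_to_min(duration), by = s_to_min(sample_interval))
  stub <- m_to_um(stub_length)
  ramp <- function(t, t0, t1, rate) pmin(pmax(t - t0, 0), t1 - t0) * rate
  shape <- list(
    # first neurite: immediate outgrowth, stall after ~900 min
    gc1 = list(onset = 0, um = stub + ramp(tmin, 0, 900, 0.075) +
                 ramp(tmin, 900, 2940, 0.002)),
    # second neurite: onset 980 min, grows until ~1900 min, then stalls
    gc2 = list(onset = 980, um = stub + ramp(tmin, 980, 1900, 0.06) +
                 ramp(tmin, 1900, 2940, 0.001)),
    # third neurite: onset 1650 min, slow start, late growth spurt
    gc3 = list(onset = 1650, um = stub + ramp(tmin, 1650, 2300, 0.01) +
                 ramp(tmin, 2300, 2700, 0.15))
  )
  lapply(shape, function(s) {
    um <- s$um
    after <- tmin > s$onset
    # jitter only after onset; a small floor above the stub keeps the
    # departure from the initial length crisp at the onset sample
    um[after] <- pmax(um[after] + rnorm(sum(after), 0, 0.2), stub + 0.05)
    growth_trace(min_to_s(tmin), um_to_m(um))
  })
}

#' Onset times of a list of traces
#'
#' The time of the last sample before a trace first departs from its
#' initial length by more than `threshold` (i.e., when the neurite starts
#' growing out).
#'
#' @param traces list of [growth_trace()] objects.
#' @param threshold length departure defining the onset, m.
#' @return named numeric vector of onset times, s.
#' @export
trace_onsets <- function(traces, threshold = 1e-8) {
  vapply(traces, function(tr) {
    i <- which(abs(tr$lengths - tr$lengths[1]) > threshold)[1]
    if (is.na(i)) NA_real_ else tr$times[max(i - 1, 1)]
  }, numeric(1))
}
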