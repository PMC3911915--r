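# Run configuration: a structured YAML document mirroring the transport
# parameters and the protocol, with human-facing units (um, hours, uM) at
# the interface and SI units internally. Unknown keys are rejected; every
# physical value is validated.

#' Default run configuration
#'
#' All transport parameters at their literature-calibrated defaults, a
#' Y-tree morphology, and the canonical perturbation protocol (free
#' outgrowth for 10 h, +50 percent polymerization on `gc1`, read-out 30 h
#' later).
#'
#' @return a nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    schema_version = 1L,
    seed = 1L,
    parameters = list(
      D = 1e-11,          # m^2/s
      f = 6e-3,           # fraction bound to active transport
      v = 440e-9,         # m/s
      b = 5.67e-7,        # 1/s
      X = 4e-14,          # mol/m
      p = 1.83e-6,        # m/(s*mM)
      q = 9.17e-9,        # m/s
      C_soma_uM = 5.5,    # uM
      dt_s = 5
    ),
    morphology = list(
      type = "y_tree",    # y_tree | star | fixture | swc
      d_a_um = 50,
      d_b_um = 10,
      diameter_um = 1,
      n_neurites = 3L,
      neurite_length_um = 2,
      swc_path = ""
    ),
    protocol = list(
      duration_h = 40,
      output_interval_s = 600,
      perturbation = list(
        time_h = 10,
        growth_cone = "gc1",
        multiplier = 1.5
      )
    ),
    output_dir = "."
  ), class = "run_config")
}

check_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra)) {
    stop("unknown configuration key", if (length(extra) > 1) "s", ": ",
         paste0(path, extra, collapse = ", "))
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]])) stop("configuration key ", path, nm,
                                    " must be a mapping")
      check_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

require_positive <- function(cfg, keys, section, strict = TRUE) {
  for (nm in keys) {
    val <- cfg[[nm]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val) ||
          (strict && val < 0)) {
      stop("configuration field ", section, ".", nm,
           " must be a single non-negative number")
    }
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML document, merges it onto [default_config()] (so an empty
#' file yields all defaults), rejects unknown keys, and validates every
#' physical value.
#'
#' @param path path to a YAML configuration file, or `NULL` for defaults.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    check_keys(user, cfg)
    cfg <- modifyList(cfg, user)
  }
  require_positive(cfg$parameters,
                   c("D", "f", "v", "b", "X", "p", "q", "C_soma_uM", "dt_s"),
                   "parameters")
  if (cfg$parameters$f > 1) stop("parameters.f cannot exceed 1")
  if (cfg$parameters$dt_s <= 0) stop("parameters.dt_s must be positive")
  if (!cfg$morphology$type %in% c("y_tree", "star", "fixture", "swc")) {
    stop("morphology.type must be one of y_tree, star, fixture, swc")
  }
  require_positive(cfg$morphology,
                   c("d_a_um", "d_b_um", "diameter_um", "neurite_length_um"),
                   "morphology")
  if (cfg$protocol$duration_h <= 0) stop("protocol.duration_h must be positive")
  pert <- cfg$protocol$perturbation
  if (!is.null(pert) && pert$multiplier <= 0) {
    stop("protocol.perturbation.multiplier must be positive")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Transport parameters from a run configuration
#' @param cfg a `run_config`.
#' @return a [transport_params()] object.
#' @export
config_params <- function(cfg) {
  p <- cfg$parameters
  transport_params(D = p$D, f = p$f, v = p$v, b = p$b, X = p$X, p = p$p,
                   q = p$q, C_soma = uM_to_molm3(p$C_soma_uM), dt = p$dt_s)
}

#' Starting morphology from a run configuration
#' @param cfg a `run_config`.
#' @return a `neurite_tree`.
#' @export
config_tree <- function(cfg) {
  m <- cfg$morphology
  switch(m$type,
    y_tree = build_y_tree(y_tree_spec(um_to_m(m$d_a_um), um_to_m(m$d_b_um),
                                      um_to_m(m$diameter_um))),
    star = build_star_tree(m$n_neurites,
                           neurite_length = um_to_m(m$neurite_length_um),
                           neurite_diameter = um_to_m(m$diameter_um)),
    fixture = build_branched_fixture(),
    swc = read_swc(m$swc_path)
  )
}

#' Simulation protocol from a run configuration
#' @param cfg a `run_config`.
#' @return a [protocol()].
#' @export
config_protocol <- function(cfg) {
  params <- config_params(cfg)
  tree <- config_tree(cfg)
  pert <- cfg$protocol$perturbation
  events <- list()
  if (!is.null(pert) && pert$multiplier != 1) {
    events <- list(perturbation_event(h_to_s(pert$time_h), pert$growth_cone,
                                      pert$multiplier))
  }
  protocol(tree, params = params, duration = h_to_s(cfg$protocol$duration_h),
           output_interval = cfg$protocol$output_interval_s, events = events)
}

#' Write a reproducibility manifest next to run artifacts
#'
#' Records the fully resolved configuration, its hash, the seed, the package
#' version and the command, so any artifact can be reproduced from its
#' manifest alone.
#'
#' @param cfg the resolved `run_config`.
#' @param path manifest output path (JSON).
#' @param command the command that produced the artifacts.
#' @return invisibly, the manifest list.
#' @export
write_manifest <- function(cfg, path, command = "simulate") {
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    command = command,
    seed = cfg$seed,
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("neuritecomp"))
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
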