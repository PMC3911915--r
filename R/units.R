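#' Unit conversions
#'
#' Small helpers between SI internal units and the reporting units used on
#' figure axes: micrometres, minutes/hours, micromolar, and mm/h.
#' Concentrations: 1 uM = 1e-3 mol/m^3 (and 1 mM = 1 mol/m^3).
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname units
#' @export
uM_to_molm3 <- function(x) x * 1e-3

#' @rdname units
#' @export
molm3_to_uM <- function(x) x * 1e3

#' @rdname units
#' @export
ms_to_mmh <- function(x) x * 3.6e6

#' @rdname units
#' @export
min_to_s <- function(x) x * 60

#' @rdname units
#' @export
s_to_min <- function(x) x / 60

#' @rdname units
#' @export
h_to_s <- function(x) x * 3600
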