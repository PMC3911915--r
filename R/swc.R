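# SWC import/export. Standard 7-column dialect: id, type, x, y, z, radius,
# parent (-1 for the root). Coordinates are used only for segment lengths
# (the path metric); type codes are preserved on write but only soma (type 1)
# detection is interpreted on read.

#' Read an SWC morphology into a compartment tree
#'
#' All points of type 1 are collapsed into the single soma compartment. The
#' remaining points are grouped into unbranched sections (between branch
#' points and tips), and each section is re-sampled into equal-length
#' compartments no longer than `l_split`, preserving the section's cable
#' length exactly. The distal `gc_length` of every terminal section becomes
#' a constant-size growth-cone compartment. Compartment diameters are taken
#' from the SWC radii, linearly interpolated at compartment midpoints.
#'
#' @param path path to an SWC file.
#' @param l_split maximum compartment length after re-sampling, m.
#' @param gc_length growth-cone compartment length, m.
#' @param unit length unit of the SWC coordinates/radii in m (SWC files are
#'   conventionally in um, hence the default 1e-6).
#' @return a `neurite_tree`; growth cones are labelled `"gc1"`, `"gc2"`, ...
#'   in SWC point order.
#' @export
read_swc <- function(path, l_split = 2.5e-6, gc_length = 1e-6, unit = 1e-6) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  raw <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(trimws(raw), "\\s+")
  bad <- which(lengths(fields) != 7)[1]
  if (!is.na(bad)) {
    stop("malformed SWC line ", lineno[bad], ": expected 7 fields, got ",
         lengths(fields)[bad])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  bad <- which(apply(m, 1, function(r) any(is.na(r))))[1]
  if (!is.na(bad)) stop("malformed SWC line ", lineno[bad], ": non-numeric field")
  swc <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                    x = m[, 3] * unit, y = m[, 4] * unit, z = m[, 5] * unit,
                    radius = m[, 6] * unit, parent = as.integer(m[, 7]))
  if (anyDuplicated(swc$id)) stop("duplicate SWC point id")
  row_of <- setNames(seq_len(nrow(swc)), swc$id)
  if (!any(swc$parent == -1)) stop("SWC has no root point (parent -1)")
  # cycle / dangling-parent check
  for (i in seq_len(nrow(swc))) {
    seen <- 0L
    j <- i
    while (swc$parent[j] != -1) {
      pj <- row_of[as.character(swc$parent[j])]
      if (is.na(pj)) stop("SWC point ", swc$id[j], " references missing parent")
      j <- pj
      seen <- seen + 1L
      if (seen > nrow(swc)) stop("SWC parent links contain a cycle")
    }
  }
  is_soma <- swc$type == 1
  if (!any(is_soma)) stop("SWC contains no soma point (type 1)")
  root_row <- which(swc$parent == -1)[1]
  soma_diameter <- 2 * swc$radius[root_row]
  tree <- new_tree(soma_diameter)

  prow <- row_of[as.character(swc$parent)]
  nkids <- tabulate(prow[!is.na(prow) & !is_soma[pmax(prow, 1)]], nbins = nrow(swc))
  # section start points: non-soma points whose parent is soma (or missing link
  # to a soma point), walked distally until a branch point or a tip
  seglen <- numeric(nrow(swc))
  for (i in seq_len(nrow(swc))) {
    if (is_soma[i] || swc$parent[i] == -1) next
    p <- prow[i]
    seglen[i] <- if (is_soma[p]) 0 else
      sqrt((swc$x[i] - swc$x[p])^2 + (swc$y[i] - swc$y[p])^2 +
             (swc$z[i] - swc$z[p])^2)
  }
  children <- split(seq_len(nrow(swc))[!is.na(prow)], prow[!is.na(prow)])
  kids_of <- function(i) {
    k <- children[[as.character(i)]]
    if (is.null(k)) integer(0) else k[!is_soma[k]]
  }
  starts <- which(!is_soma & is_soma[ifelse(is.na(prow), root_row, prow)])
  counter <- 0L
  # walk one section: points from `start` until tip or branch point
  emit_section <- function(tree, attach_idx, start) {
    pts <- start
    repeat {
      k <- kids_of(tail(pts, 1))
      if (length(k) != 1) break
      pts <- c(pts, k)
    }
    dl <- seglen[pts]
    if (is_soma[prow[start]] || swc$parent[start] == -1) {
      # distance from soma surface: segment from soma centre, minus the radius
      d0 <- sqrt((swc$x[start] - swc$x[root_row])^2 +
                   (swc$y[start] - swc$y[root_row])^2 +
                   (swc$z[start] - swc$z[root_row])^2)
      dl[1] <- max(d0 - soma_diameter / 2, 0)
    }
    cum <- cumsum(dl)
    S <- cum[length(cum)]
    radii <- swc$radius[pts]
    rad_at <- function(s) approx(c(0, cum), c(radii[1], radii), xout = s,
                                 rule = 2)$y
    terminal <- length(kids_of(tail(pts, 1))) == 0
    gc_here <- if (terminal) min(gc_length, S / 2) else 0
    shaft <- S - gc_here
    at <- attach_idx
    if (shaft > 0) {
      n <- max(1L, ceiling(shaft / l_split - 1e-9))
      piece <- shaft / n
      for (j in seq_len(n)) {
        r <- rad_at((j - 0.5) * piece)
        res <- add_compartment(tree, at, piece, 2 * r)
        tree <- res$tree
        at <- res$idx
      }
    }
    if (terminal) {
      counter <<- counter + 1L
      res <- add_compartment(tree, at, gc_here, 2 * rad_at(S - gc_here / 2),
                             kind = KIND_GC,
                             gc_label = paste0("gc", counter))
      tree <- res$tree
    } else {
      for (k in kids_of(tail(pts, 1))) tree <- emit_section(tree, at, k)
    }
    tree
  }
  for (s in starts) tree <- emit_section(tree, 1L, s)
  validate_tree(tree)
  tree
}

#' Write a compartment tree to an SWC file
#'
#' Coordinates are synthesized deterministically (planar layout, one point
#' per compartment at its distal end, branches fanning out at distinct
#' angles), so that segment lengths equal compartment lengths exactly and a
#' round trip through [read_swc()] preserves topology and total cable
#' length.
#'
#' @param tree a `neurite_tree`.
#' @param path output file path.
#' @param unit length unit for the written coordinates in m (default um).
#' @return invisibly, the path.
#' @export
write_swc <- function(tree, path, unit = 1e-6) {
  n <- n_compartments(tree)
  x <- numeric(n); y <- numeric(n)
  ang <- numeric(n)
  nch <- n_children(tree)
  children <- split(which(!is.na(tree$parent)), tree$parent[!is.na(tree$parent)])
  assign_xy <- function(i, a, x0, y0) {
    kids <- children[[as.character(i)]]
    if (is.null(kids)) kids <- integer(0)
    if (length(kids) <= 1) {
      offs <- 0
    } else {
      offs <- seq(-1, 1, length.out = length(kids)) * pi / 5
    }
    for (j in seq_along(kids)) {
      k <- kids[j]
      ak <- a + offs[j]
      x[k] <<- x0 + tree$length[k] * cos(ak)
      y[k] <<- y0 + tree$length[k] * sin(ak)
      ang[k] <<- ak
      assign_xy(k, ak, x[k], y[k])
    }
  }
  # spread the soma's neurites around the circle; put the soma point at origin
  roots <- children[["1"]]
  if (!is.null(roots)) {
    a0 <- seq(0, 2 * pi, length.out = length(roots) + 1)[seq_along(roots)]
    r_soma <- tree$diam[1] / 2
    for (j in seq_along(roots)) {
      k <- roots[j]
      x[k] <- (r_soma + tree$length[k]) * cos(a0[j])
      y[k] <- (r_soma + tree$length[k]) * sin(a0[j])
      ang[k] <- a0[j]
      assign_xy(k, a0[j], x[k], y[k])
    }
  }
  type <- ifelse(tree$kind == KIND_SOMA, 1L, 3L)
  radius <- ifelse(tree$kind == KIND_SOMA, tree$diam / 2, tree$diam / 2)
  out <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                 seq_len(n), type, x / unit, y / unit, 0, radius / unit,
                 ifelse(is.na(tree$parent), -1L, tree$parent))
  writeLines(c("# generated by neuritecomp", out), path)
  invisible(path)
}
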