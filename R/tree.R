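# Compartmental representation of a neuron: a rooted tree of cylindrical
# compartments. The soma is the single root; every neurite terminates in a
# constant-size growth-cone compartment. Stored as parallel vectors so the
# transport solver can address the whole tree at once.

KIND_SOMA <- "soma"
KIND_SHAFT <- "shaft"
KIND_GC <- "growth_cone"

#' Create an empty neuron: a single spherical soma compartment
#'
#' The soma is represented by one compartment whose volume is that of a
#' sphere of the given diameter. Only the clamped soma concentration matters
#' dynamically; the volume choice is cosmetic (it sets the clamped quantity).
#'
#' @param soma_diameter soma diameter in m (default 10 um).
#' @return an object of class `neurite_tree`.
#' @export
new_tree <- function(soma_diameter = 10e-6) {
  stopifnot(soma_diameter > 0)
  structure(list(
    parent   = NA_integer_,
    kind     = KIND_SOMA,
    length   = soma_diameter,     # effective length: center-to-surface = diameter/2
    diam     = soma_diameter,
    Q        = 0,
    gc_label = NA_character_,
    soma_volume = pi / 6 * soma_diameter^3
  ), class = "neurite_tree")
}

#' Number of compartments in a tree
#' @param tree a `neurite_tree`.
#' @return integer count.
#' @export
n_compartments <- function(tree) length(tree$parent)

#' Cross-sectional areas of all compartments (m^2)
#' @param tree a `neurite_tree`.
#' @return numeric vector, one value per compartment.
#' @export
compartment_areas <- function(tree) pi * tree$diam^2 / 4

#' Volumes of all compartments (m^3)
#'
#' Cylindrical (area x length) for shafts and growth cones; the declared
#' sphere-equivalent volume for the soma.
#'
#' @param tree a `neurite_tree`.
#' @return numeric vector, one value per compartment.
#' @export
compartment_volumes <- function(tree) {
  v <- compartment_areas(tree) * tree$length
  v[1] <- tree$soma_volume
  v
}

#' Tubulin concentrations of all compartments (mol/m^3)
#' @param tree a `neurite_tree`.
#' @return numeric vector Q/V per compartment.
#' @export
concentrations <- function(tree) tree$Q / compartment_volumes(tree)

#' Set a uniform tubulin concentration
#' @param tree a `neurite_tree`.
#' @param conc concentration in mol/m^3.
#' @return the tree with Q = conc * V in every compartment.
#' @export
set_concentration <- function(tree, conc) {
  stopifnot(conc >= 0)
  tree$Q <- conc * compartment_volumes(tree)
  tree
}

#' Growth-cone compartments of a tree
#' @param tree a `neurite_tree`.
#' @return named integer vector of compartment indices, names are the
#'   persistent growth-cone labels (stable across remeshing).
#' @export
growth_cones <- function(tree) {
  idx <- which(tree$kind == KIND_GC)
  setNames(idx, tree$gc_label[idx])
}

n_children <- function(tree) {
  tab <- tabulate(tree$parent[!is.na(tree$parent)], nbins = n_compartments(tree))
  tab
}

#' Total cable length of the neuritic tree (m), soma excluded
#' @param tree a `neurite_tree`.
#' @return total neurite length in m.
#' @export
total_cable_length <- function(tree) sum(tree$length[tree$kind != KIND_SOMA])

#' Total tubulin quantity in the tree (mol)
#' @param tree a `neurite_tree`.
#' @return sum of compartmental quantities, mol.
#' @export
total_tubulin <- function(tree) sum(tree$Q)

# append one compartment; returns list(tree, idx)
add_compartment <- function(tree, parent, length, diam, kind = KIND_SHAFT,
                            Q = 0, gc_label = NA_character_) {
  tree$parent <- c(tree$parent, as.integer(parent))
  tree$kind <- c(tree$kind, kind)
  tree$length <- c(tree$length, length)
  tree$diam <- c(tree$diam, diam)
  tree$Q <- c(tree$Q, Q)
  tree$gc_label <- c(tree$gc_label, gc_label)
  list(tree = tree, idx = n_compartments(tree))
}

# append an unbranched run of shaft compartments of total length L,
# cut into equal pieces within [l_merge, l_split]
add_chain <- function(tree, parent, L, diam, l_split = 2.5e-6) {
  stopifnot(L > 0)
  n <- max(1L, ceiling(L / l_split - 1e-9))
  piece <- L / n
  at <- parent
  for (i in seq_len(n)) {
    res <- add_compartment(tree, at, piece, diam)
    tree <- res$tree
    at <- res$idx
  }
  list(tree = tree, idx = at)
}

#' Specification of a simple Y-shaped morphology
#'
#' A soma with a single unbranched trunk of path length `d_a` that splits
#' into two daughter branches of initial length `d_b`, each tipped by a
#' growth cone. `d_b` includes the growth-cone compartment, so the soma to
#' growth-cone path distance is exactly `d_a + d_b`.
#'
#' @param d_a path distance soma to branch point, m.
#' @param d_b initial length of each daughter branch, m.
#' @param neurite_diameter neurite diameter, m (constant along the tree).
#' @return a list of class `y_tree_spec`.
#' @export
y_tree_spec <- function(d_a, d_b, neurite_diameter = 1e-6) {
  stopifnot(d_a > 0, d_b > 0, neurite_diameter > 0)
  structure(list(d_a = d_a, d_b = d_b, neurite_diameter = neurite_diameter),
            class = "y_tree_spec")
}

#' Build a Y-shaped compartment tree
#'
#' @param spec a [y_tree_spec()], or `d_a` in m if given positionally.
#' @param d_b daughter branch length in m (when `spec` is numeric).
#' @param neurite_diameter neurite diameter in m.
#' @param soma_diameter soma diameter in m.
#' @param gc_length growth-cone compartment length in m (fixed during growth).
#' @return a `neurite_tree` with growth cones labelled `"gc1"` and `"gc2"`.
#' @examples
#' tr <- build_y_tree(y_tree_spec(50e-6, 10e-6))
#' path_distance(tr, 1, growth_cones(tr)[["gc1"]])  # 60 um
#' @export
build_y_tree <- function(spec, d_b = NULL, neurite_diameter = 1e-6,
                         soma_diameter = 10e-6, gc_length = 1e-6) {
  if (!inherits(spec, "y_tree_spec")) {
    spec <- y_tree_spec(spec, d_b, neurite_diameter)
  }
  if (spec$d_b <= gc_length + 0.5e-6) {
    stop("d_b must exceed the growth-cone length plus the minimum shaft length")
  }
  tree <- new_tree(soma_diameter)
  trunk <- add_chain(tree, 1L, spec$d_a, spec$neurite_diameter)
  tree <- trunk$tree
  for (lab in c("gc1", "gc2")) {
    br <- add_chain(tree, trunk$idx, spec$d_b - gc_length, spec$neurite_diameter)
    tree <- br$tree
    res <- add_compartment(tree, br$idx, gc_length, spec$neurite_diameter,
                           kind = KIND_GC, gc_label = lab)
    tree <- res$tree
  }
  tree
}

#' Build a star morphology: several unbranched neurites from one soma
#'
#' Used for the developing-neuron replay experiments, where a small number of
#' unbranched neurites grow out of the soma.
#'
#' @param n_neurites number of neurites.
#' @param neurite_length initial length of each neurite in m (including the
#'   growth cone).
#' @param neurite_diameter diameter in m.
#' @param soma_diameter soma diameter in m.
#' @param gc_length growth-cone compartment length in m.
#' @return a `neurite_tree` with growth cones `"gc1"`, `"gc2"`, ...
#' @export
build_star_tree <- function(n_neurites = 3, neurite_length = 2e-6,
                            neurite_diameter = 1e-6, soma_diameter = 10e-6,
                            gc_length = 1e-6) {
  stopifnot(n_neurites >= 1, neurite_length > gc_length + 0.4e-6)
  tree <- new_tree(soma_diameter)
  for (i in seq_len(n_neurites)) {
    br <- add_chain(tree, 1L, neurite_length - gc_length, neurite_diameter)
    tree <- br$tree
    res <- add_compartment(tree, br$idx, gc_length, neurite_diameter,
                           kind = KIND_GC, gc_label = paste0("gc", i))
    tree <- res$tree
  }
  tree
}

# recursive section spec: list(len, diam, children = list(...)); lengths m.
add_section_spec <- function(tree, parent, spec, gc_length, counter) {
  if (length(spec$children) == 0) {
    ch <- add_chain(tree, parent, spec$len - gc_length, spec$diam)
    tree <- ch$tree
    counter$n <- counter$n + 1L
    res <- add_compartment(tree, ch$idx, gc_length, spec$diam,
                           kind = KIND_GC, gc_label = paste0("gc", counter$n))
    return(list(tree = res$tree, counter = counter))
  }
  ch <- add_chain(tree, parent, spec$len, spec$diam)
  tree <- ch$tree
  for (child in spec$children) {
    out <- add_section_spec(tree, ch$idx, child, gc_length, counter)
    tree <- out$tree
    counter <- out$counter
  }
  list(tree = tree, counter = counter)
}

#' Deterministic branched "pyramidal-like" fixture morphology
#'
#' A reproducible branched tree with 8 terminal branches whose soma to
#' growth-cone path distances span 30 to 255 um, with tapering diameters.
#' It stands in for a reconstructed pyramidal-neuron morphology in the
#' complex-tree competition experiments and is labelled synthetic: it is
#' generated in code, not traced from a real cell.
#'
#' @param soma_diameter soma diameter, m.
#' @param gc_length growth-cone compartment length, m.
#' @return a `neurite_tree` with 8 growth cones.
#' @export
build_branched_fixture <- function(soma_diameter = 10e-6, gc_length = 1e-6) {
  um <- 1e-6
  spec <- list(
    # basal-like subtree
    list(len = 40 * um, diam = 1.5 * um, children = list(
      list(len = 15 * um, diam = 1.0 * um, children = list()),
      list(len = 25 * um, diam = 1.0 * um, children = list())
    )),
    list(len = 30 * um, diam = 1.0 * um, children = list()),
    # apical-like trunk
    list(len = 80 * um, diam = 2.0 * um, children = list(
      list(len = 30 * um, diam = 1.0 * um, children = list()),
      list(len = 70 * um, diam = 1.8 * um, children = list(
        list(len = 40 * um, diam = 1.2 * um, children = list(
          list(len = 20 * um, diam = 1.0 * um, children = list()),
          list(len = 35 * um, diam = 1.0 * um, children = list())
        )),
        list(len = 60 * um, diam = 1.2 * um, children = list(
          list(len = 25 * um, diam = 1.0 * um, children = list()),
          list(len = 45 * um, diam = 1.0 * um, children = list())
        ))
      ))
    ))
  )
  tree <- new_tree(soma_diameter)
  counter <- list(n = 0L)
  for (s in spec) {
    out <- add_section_spec(tree, 1L, s, gc_length, counter)
    tree <- out$tree
    counter <- out$counter
  }
  tree
}

resolve_node <- function(tree, node) {
  if (is.character(node)) {
    idx <- which(tree$gc_label == node)
    if (length(idx) != 1) stop("unknown growth-cone label: ", node)
    return(idx)
  }
  node <- as.integer(node)
  if (is.na(node) || node < 1 || node > n_compartments(tree)) {
    stop("unknown compartment id: ", node)
  }
  node
}

# ancestors of a node, from itself up to the root (preallocated walk;
# paths can be thousands of compartments deep in grown trees)
ancestor_chain <- function(tree, node) {
  n <- n_compartments(tree)
  chain <- integer(n)
  parent <- tree$parent
  k <- 0L
  while (!is.na(node)) {
    k <- k + 1L
    if (k > n) stop("parent links contain a cycle")
    chain[k] <- node
    node <- parent[node]
  }
  chain[seq_len(k)]
}

#' Path distance along the neuritic tree (m)
#'
#' Distance measured along the tree between the distal ends of two
#' compartments, with the soma treated as a point at the origin. For a
#' growth cone this is the figure-axis quantity "neurite length from the
#' soma to the growth cone": `path_distance(tree, 1, gc)` on a Y-tree with
#' trunk `d_a` and daughters `d_b` is exactly `d_a + d_b`.
#'
#' @param tree a `neurite_tree`.
#' @param a,b compartment indices or growth-cone labels.
#' @return distance in m; zero iff `a == b`.
#' @export
path_distance <- function(tree, a, b) {
  a <- resolve_node(tree, a)
  b <- resolve_node(tree, b)
  if (a == b) return(0)
  len <- tree$length
  len[1] <- 0 # the soma is the origin point of the path metric
  ca <- ancestor_chain(tree, a)
  cb <- ancestor_chain(tree, b)
  common <- intersect(ca, cb)
  lca <- common[1] # chains are ordered upward; first shared node is the LCA
  da <- sum(len[ca[seq_len(which(ca == lca) - 1)]])
  db <- sum(len[cb[seq_len(which(cb == lca) - 1)]])
  da + db
}

#' Neurite length from the soma to each growth cone (m)
#' @param tree a `neurite_tree`.
#' @return named numeric vector of path distances, one per growth cone.
#' @export
neurite_lengths <- function(tree) {
  gcs <- growth_cones(tree)
  vapply(gcs, function(i) path_distance(tree, 1L, i), numeric(1))
}

#' Validate the structural invariants of a compartment tree
#'
#' Checks: single soma root, acyclic parent links, positive lengths and
#' diameters, non-negative tubulin, every leaf is a growth cone, and (when
#' `check_mesh`) every shaft length within the split/merge bounds.
#'
#' @param tree a `neurite_tree`.
#' @param check_mesh also require shaft lengths in `[l_merge, l_split]`.
#' @param l_split,l_merge mesh bounds in m.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_tree <- function(tree, check_mesh = FALSE,
                          l_split = 2.5e-6, l_merge = 0.5e-6) {
  n <- n_compartments(tree)
  if (sum(is.na(tree$parent)) != 1 || !is.na(tree$parent[1])) {
    stop("tree must have exactly one root")
  }
  if (tree$kind[1] != KIND_SOMA || any(tree$kind[-1] == KIND_SOMA)) {
    stop("the root and only the root must be the soma")
  }
  if (any(tree$length <= 0)) stop("all compartment lengths must be positive")
  if (any(tree$diam <= 0)) stop("all compartment diameters must be positive")
  if (any(tree$Q < 0)) stop("tubulin quantities must be non-negative")
  for (i in seq_len(n)) ancestor_chain(tree, i) # cycle check
  leaves <- setdiff(seq_len(n), tree$parent[!is.na(tree$parent)])
  leaves <- setdiff(leaves, 1L)
  if (!all(tree$kind[leaves] == KIND_GC)) {
    stop("every neurite leaf must be a growth cone")
  }
  if (any(tree$kind == KIND_GC & !(seq_len(n) %in% leaves))) {
    stop("growth cones must be leaves")
  }
  if (check_mesh) {
    sh <- tree$kind == KIND_SHAFT
    if (any(tree$length[sh] > l_split * (1 + 1e-9) |
              tree$length[sh] < l_merge * (1 - 1e-9))) {
      stop("shaft compartment length outside [l_merge, l_split]")
    }
  }
  invisible(TRUE)
}

# remove compartment k, re-attaching its children to `to`; indices shift down
drop_compartment <- function(tree, k, to) {
  tree$parent[!is.na(tree$parent) & tree$parent == k] <- as.integer(to)
  keep <- setdiff(seq_len(n_compartments(tree)), k)
  remap <- integer(n_compartments(tree))
  remap[keep] <- seq_along(keep)
  tree$parent <- ifelse(is.na(tree$parent[keep]), NA_integer_,
                        remap[tree$parent[keep]])
  tree$kind <- tree$kind[keep]
  tree$length <- tree$length[keep]
  tree$diam <- tree$diam[keep]
  tree$Q <- tree$Q[keep]
  tree$gc_label <- tree$gc_label[keep]
  tree
}

#' Remesh the compartment tree after growth or retraction
#'
#' A shaft compartment longer than `l_split` is split into two halves, each
#' receiving half its tubulin quantity. A shaft shorter than `l_merge` is
#' merged into its parent (lengths and quantities summed), except when the
#' parent is the soma or a branch point: then the compartment is left in
#' place (the growth step clamps the neurite at its minimum length, so a
#' neurite can shrink to growth cone plus one minimal shaft but never
#' disappears). Both operations conserve total tubulin and total cable
#' length exactly.
#'
#' @param tree a `neurite_tree`.
#' @param l_split maximum shaft length, m.
#' @param l_merge minimum shaft length, m.
#' @return the remeshed tree; the attribute `"remesh_events"` holds the
#'   number of splits and merges performed.
#' @export
remesh <- function(tree, l_split = 2.5e-6, l_merge = 0.5e-6) {
  splits <- 0L
  merges <- 0L
  # fast path: nothing out of range (the common case in the step loop)
  is_shaft <- tree$kind == KIND_SHAFT
  if (!any(is_shaft & (tree$length > l_split | tree$length < l_merge))) {
    attr(tree, "remesh_events") <- c(splits = 0L, merges = 0L)
    return(tree)
  }
  repeat {
    changed <- FALSE
    repeat {
      cand <- which(tree$kind == KIND_SHAFT & tree$length > l_split)
      if (!length(cand)) break
      for (k in cand) {
        # new proximal half between k's parent and k; k keeps its children
        res <- add_compartment(tree, tree$parent[k], tree$length[k] / 2,
                               tree$diam[k], Q = tree$Q[k] / 2)
        tree <- res$tree
        tree$parent[k] <- res$idx
        tree$length[k] <- tree$length[k] / 2
        tree$Q[k] <- tree$Q[k] / 2
        splits <- splits + 1L
      }
      changed <- TRUE
    }
    repeat {
      nch <- n_children(tree)
      cand <- which(tree$kind == KIND_SHAFT & tree$length < l_merge)
      done <- TRUE
      for (k in cand) {
        p <- tree$parent[k]
        if (tree$kind[p] != KIND_SHAFT || nch[p] != 1L) next # clamped at soma/branch point
        # absorb k into its parent, conserving volume, length and tubulin
        vol <- compartment_volumes(tree)
        newlen <- tree$length[p] + tree$length[k]
        newvol <- vol[p] + vol[k]
        tree$length[p] <- newlen
        tree$diam[p] <- 2 * sqrt(newvol / newlen / pi)
        tree$Q[p] <- tree$Q[p] + tree$Q[k]
        tree <- drop_compartment(tree, k, p)
        merges <- merges + 1L
        done <- FALSE
        changed <- TRUE
        break
      }
      if (done) break
    }
    # a merge can push a compartment above l_split; re-check until stable
    if (!changed || !any(tree$kind == KIND_SHAFT & tree$length > l_split)) break
  }
  attr(tree, "remesh_events") <- c(splits = splits, merges = merges)
  tree
}

#' @export
print.neurite_tree <- function(x, ...) {
  gcs <- growth_cones(x)
  cat("<neurite_tree> ", n_compartments(x), " compartments, ",
      length(gcs), " growth cones\n", sep = "")
  cat("  total cable length: ", signif(m_to_um(total_cable_length(x)), 4),
      " um\n", sep = "")
  if (length(gcs)) {
    d <- signif(m_to_um(neurite_lengths(x)), 4)
    cat("  soma->growth-cone path distances (um): ",
        paste0(names(gcs), "=", d, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
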