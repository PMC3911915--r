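# Fixture builders used across the suite. All fixtures are generated in code.

# unbranched cable: soma + shaft chain + growth-cone tip. A small soma puts
# the clamped boundary close to x = 0, matching the analytic cable setup.
mk_cable <- function(L, diam = 1e-6, soma_d = 10e-6, gc_length = 1e-6,
                     piece = 2.5e-6) {
  tr <- neuritecomp:::add_chain(new_tree(soma_d), 1L, L - gc_length, diam,
                                l_split = piece)
  res <- neuritecomp:::add_compartment(tr$tree, tr$idx, gc_length, diam,
                                       kind = "growth_cone", gc_label = "gc1")
  res$tree
}

# random branched tree with growth-cone tips, deterministic per seed
random_tree <- function(seed) {
  set.seed(seed)
  tree <- mk_cable(runif(1, 20, 50) * 1e-6)
  for (i in seq_len(sample(2:5, 1))) {
    shafts <- which(tree$kind == "shaft")
    at <- if (length(shafts) == 1) shafts else sample(shafts, 1)
    ch <- neuritecomp:::add_chain(tree, at, runif(1, 5, 30) * 1e-6, 1e-6)
    res <- neuritecomp:::add_compartment(ch$tree, ch$idx, 1e-6, 1e-6,
                                         kind = "growth_cone",
                                         gc_label = paste0("rgc", i))
    tree <- res$tree
  }
  tree
}

# minimal 3-point SWC: 10 um radius-5 soma at the origin plus a straight
# 10 um neurite (two 5 um segments measured from the soma surface)
write_three_point_swc <- function(path) {
  writeLines(c(
    "# toy neuron",
    "1 1 0 0 0 5 -1",
    "2 3 10 0 0 0.5 1",
    "3 3 15 0 0 0.5 2"
  ), path)
  path
}
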