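test_that("Y-tree geometry: additivity, symmetry and mesh bounds", {
  tr <- build_y_tree(y_tree_spec(50e-6, 10e-6))
  gcs <- growth_cones(tr)
  expect_named(gcs, c("gc1", "gc2"))
  expect_equal(path_distance(tr, 1L, "gc1"), 60e-6)
  expect_equal(path_distance(tr, 1L, "gc2"), 60e-6)
  expect_equal(path_distance(tr, "gc1", "gc2"), 20e-6)
  expect_equal(total_cable_length(tr), 70e-6)

  # the two daughter subtrees are congruent
  branch_of <- function(g) {
    chain <- neuritecomp:::ancestor_chain(tr, g)
    # nodes strictly distal to the branch point (the common ancestor set)
    common <- Reduce(intersect, lapply(gcs, neuritecomp:::ancestor_chain,
                                       tree = tr))
    setdiff(chain, common)
  }
  b1 <- branch_of(gcs[[1]])
  b2 <- branch_of(gcs[[2]])
  expect_equal(length(b1), length(b2))
  expect_equal(sort(tr$length[b1]), sort(tr$length[b2]))

  sh <- tr$kind == "shaft"
  expect_true(all(tr$length[sh] >= 0.5e-6 & tr$length[sh] <= 2.5e-6))
  expect_silent(validate_tree(tr, check_mesh = TRUE))
})

test_that("path_distance is a tree metric and matches an exhaustive oracle", {
  tr <- build_y_tree(y_tree_spec(100e-6, 25e-6))
  expect_equal(path_distance(tr, 1L, "gc1"), 125e-6)
  expect_equal(path_distance(tr, "gc1", "gc1"), 0)
  expect_error(path_distance(tr, 1L, 9999L), "unknown")

  skip_if_not_installed("igraph")
  for (seed in 1:3) {
    tree <- random_tree(seed)
    n <- n_compartments(tree)
    edges <- cbind(tree$parent[-1], seq_len(n)[-1])
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    w <- tree$length[edges[, 2]] # each edge carries the distal compartment
    dmat <- igraph::distances(g, weights = w)
    pairs <- cbind(sample(n, 6, replace = TRUE), sample(n, 6, replace = TRUE))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]
      b <- pairs[k, 2]
      expect_equal(path_distance(tree, a, b), dmat[a, b], tolerance = 1e-12)
      expect_equal(path_distance(tree, a, b), path_distance(tree, b, a))
    }
  }
})

test_that("remesh splits oversized compartments in half with half the tubulin", {
  tr <- build_y_tree(y_tree_spec(50e-6, 10e-6))
  sh <- which(tr$kind == "shaft")[3]
  tr$length[sh] <- 2.6e-6
  tr$Q[sh] <- 2.6e-18
  out <- remesh(tr)
  expect_equal(attr(out, "remesh_events")[["splits"]], 1L)
  halves <- which(abs(out$length - 1.3e-6) < 1e-12)
  expect_length(halves, 2)
  expect_equal(out$Q[halves], rep(1.3e-18, 2))
  expect_equal(total_tubulin(out), total_tubulin(tr))
  expect_equal(total_cable_length(out), total_cable_length(tr))
})

test_that("remesh merges undersized compartments into their parent", {
  tr <- build_y_tree(y_tree_spec(50e-6, 10e-6))
  # pick a shaft whose parent is a plain shaft
  nch <- neuritecomp:::n_children(tr)
  k <- which(tr$kind == "shaft" & tr$kind[tr$parent] == "shaft" &
               nch[tr$parent] == 1)[2]
  p <- tr$parent[k]
  tr$length[k] <- 0.4e-6
  tr$length[p] <- 1.0e-6
  tr$Q[k] <- 3e-19
  tr$Q[p] <- 5e-19
  out <- remesh(tr)
  expect_equal(attr(out, "remesh_events")[["merges"]], 1L)
  merged <- which(abs(out$length - 1.4e-6) < 1e-12)
  expect_length(merged, 1)
  expect_equal(out$Q[merged], 8e-19)
  expect_equal(n_compartments(out), n_compartments(tr) - 1L)
  expect_equal(total_tubulin(out), total_tubulin(tr))
  expect_equal(total_cable_length(out), total_cable_length(tr))
})

test_that("remesh is the identity on an in-range tree and conserves invariants on random trees", {
  tr <- build_y_tree(y_tree_spec(50e-6, 10e-6))
  out <- remesh(tr)
  expect_equal(sum(attr(out, "remesh_events")), 0)
  expect_equal(out$length, tr$length)

  for (seed in 4:8) {
    tree <- random_tree(seed)
    set.seed(seed + 100)
    sh <- which(tree$kind == "shaft")
    tree$length[sh] <- runif(length(sh), 0.3e-6, 3.5e-6)
    tree$Q <- runif(n_compartments(tree)) * 1e-19
    q0 <- total_tubulin(tree)
    l0 <- total_cable_length(tree)
    out <- remesh(tree)
    expect_equal(total_tubulin(out), q0, tolerance = 1e-14)
    expect_equal(total_cable_length(out), l0, tolerance = 1e-14)
    # every shaft is in range, except sub-minimum ones clamped at the soma
    # or a branch point (where merging would delete topology)
    sh <- which(out$kind == "shaft")
    nch <- neuritecomp:::n_children(out)
    ok <- out$length[sh] <= 2.5e-6 * (1 + 1e-12) &
      (out$length[sh] >= 0.5e-6 * (1 - 1e-12) |
         out$kind[out$parent[sh]] != "shaft" | nch[out$parent[sh]] > 1)
    expect_true(all(ok))
    expect_silent(validate_tree(out))
  }
})

test_that("branched fixture has 8 growth cones spanning a wide range of path distances", {
  tr <- build_branched_fixture()
  gcs <- growth_cones(tr)
  expect_length(gcs, 8)
  d <- neurite_lengths(tr)
  expect_equal(min(d), 30e-6)
  expect_equal(max(d), 255e-6)
  expect_silent(validate_tree(tr, check_mesh = TRUE))
})
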