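test_that("pivot selection honors the side draw and degree eligibility", {
  set.seed(10)
  g <- random_small_graph(8, 20)
  for (i in 1:20) expect_equal(select_pivot(g, p_in = 1)$side, "in")
  for (i in 1:20) expect_equal(select_pivot(g, p_in = 0)$side, "out")

  # only node 3 has in-degree in {1, ..., n-2}: others have 0 or n-1 in-links
  A <- matrix(0, 4, 4)
  A[3, 1] <- 1
  A[1, 2] <- 1; A[1, 3] <- 1; A[1, 4] <- 1 # node 1 has in-degree n-1 = 3
  g <- spatial_digraph(A, matrix(0, 4, 2))
  for (i in 1:10) expect_equal(select_pivot(g, p_in = 1)$node, 3L)

  gc4 <- make_fixture("complete-4") # every degree is n-1
  expect_error(select_pivot(gc4, p_in = 1), class = "adaptrewire_no_eligible_pivot")
  expect_error(select_pivot(gc4, p_in = 0), class = "adaptrewire_no_eligible_pivot")
})

test_that("principle choice partitions the unit interval as distance|wave|functional|random", {
  cfg <- rewiring_config(p_function = 0.4, p_distance = 0.3, p_wave = 0.3)
  pick <- adaptrewire:::.principle_from_r2
  expect_equal(pick(0.10, cfg), "distance")
  expect_equal(pick(0.29, cfg), "distance")
  expect_equal(pick(0.45, cfg), "wave")
  expect_equal(pick(0.95, cfg), "functional")
  cfg2 <- rewiring_config(p_function = 0.5, p_distance = 0.2, p_wave = 0.1)
  expect_equal(pick(0.85, cfg2), "random")
  set.seed(1)
  cfg3 <- rewiring_config(p_function = 0, p_distance = 1)
  for (i in 1:10) expect_equal(choose_principle(cfg3), "distance")
  expect_error(rewiring_config(p_function = 0.8, p_distance = 0.3), "<= 1")
  expect_error(rewiring_config(p_in = 1.2), "probabilities")
})

test_that("deterministic functional rewiring cuts the weakest and adds the strongest flow", {
  # chain 3 -> 2 -> 1 plus direct 3 -> 1: in-profile of 1 is known; node 4
  # is unreachable so its kernel value toward 1 is zero
  A <- matrix(0, 4, 4)
  A[1, 2] <- 1; A[2, 3] <- 1; A[1, 3] <- 0.2
  g <- spatial_digraph(A, matrix(0, 4, 2))
  p <- inflow_profile(g, 1, 1)
  expect_true(p[["4"]] == 0)
  set.seed(20)
  sw <- functional_rewire(g, 1, "in", mode = "deterministic")
  # members of 1's in-neighborhood: {2, 3}; cut the lower kernel value
  keep <- names(which.max(p[c("2", "3")]))
  cut <- setdiff(c("2", "3"), keep)
  expect_equal(sw$removed, as.integer(cut))
  expect_equal(sw$added, 4L) # only complement node
  expect_equal(sw$weight, A[1, as.integer(cut)])
  expect_equal(sw$principle, "functional")
})

test_that("stochastic functional rewiring follows the kernel-derived probabilities", {
  set.seed(21)
  g <- random_small_graph(8, 25)
  v <- select_pivot(g, p_in = 1)$node
  p <- inflow_profile(g, v, 1)
  nb <- neighborhood(g, v, "in")
  vals_m <- p[as.character(nb$members)]
  vals_c <- p[as.character(nb$complement)]
  # skip degenerate draws for this graph
  expect_true(all(vals_m > 0))
  p_cut <- (1 / vals_m) / sum(1 / vals_m)
  p_add <- if (sum(vals_c) > 0) vals_c / sum(vals_c) else rep(1 / length(vals_c), length(vals_c))
  ntrials <- 4000
  cuts <- integer(ntrials); adds <- integer(ntrials)
  set.seed(22)
  for (i in seq_len(ntrials)) {
    sw <- functional_rewire(g, v, "in", mode = "stochastic")
    cuts[i] <- sw$removed
    adds[i] <- sw$added
  }
  emp_cut <- tabulate(cuts, g$n)[nb$members] / ntrials
  emp_add <- tabulate(adds, g$n)[nb$complement] / ntrials
  expect_equal(emp_cut, unname(p_cut), tolerance = 0.12)
  expect_equal(emp_add, unname(p_add), tolerance = 0.12)
})

test_that("all-zero complement flow falls back to a uniform addition", {
  # node 1 receives only from 2; nodes 3 and 4 cannot reach 1
  A <- matrix(0, 4, 4)
  A[1, 2] <- 1
  A[3, 4] <- 1; A[4, 3] <- 1
  g <- spatial_digraph(A, matrix(0, 4, 2))
  expect_equal(unname(inflow_profile(g, 1)[c("3", "4")]), c(0, 0))
  set.seed(23)
  adds <- replicate(2000, functional_rewire(g, 1, "in", mode = "stochastic")$added)
  tab <- table(factor(adds, levels = 3:4))
  expect_true(all(tab > 800)) # roughly uniform over {3, 4}
})

test_that("distance rewiring removes the farthest member and adds the closest candidate", {
  xy <- rbind(c(0, 0), c(0.2, 0), c(0.9, 0), c(0.1, 0), c(0.5, 0))
  A <- matrix(0, 5, 5)
  A[1, 2] <- 1; A[1, 3] <- 1 # members at distances 0.2 and 0.9
  g <- spatial_digraph(A, xy)
  set.seed(24)
  sw <- distance_rewire(g, 1, "in")
  expect_equal(sw$removed, 3L) # unique farthest
  expect_equal(sw$added, 4L)   # unique closest complement (0.1 < 0.5)

  # equidistant members: removal is uniform among ties
  xy2 <- rbind(c(0, 0), c(0.5, 0), c(0, 0.5), c(-0.5, 0))
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- 1; A2[1, 3] <- 1; A2[1, 4] <- 1
  g2 <- spatial_digraph(A2, xy2)
  # need a complement: add node 5 near the pivot
  A3 <- matrix(0, 5, 5); A3[1:4, 1:4] <- A2
  g3 <- spatial_digraph(A3, rbind(xy2, c(0.1, 0)))
  set.seed(25)
  rem <- replicate(3000, distance_rewire(g3, 1, "in")$removed)
  tab <- table(factor(rem, levels = 2:4))
  expect_true(all(tab > 800) && all(tab < 1200)) # ~1000 each
})

test_that("edge-field cosine matches plane geometry", {
  expect_equal(edge_field_cosine(c(1, 0), c(0, 0), c(1, 0)), 1)
  expect_equal(edge_field_cosine(c(0, 0), c(1, 0), c(1, 0)), -1)
  expect_equal(edge_field_cosine(c(0, 1), c(0, 0), c(1, 0)), 0)
  expect_equal(edge_field_cosine(c(1, 1), c(0, 0), c(1, 0)), cos(pi / 4))
  expect_error(edge_field_cosine(c(0, 0), c(0, 0), c(1, 0)), "zero-length")
  expect_error(edge_field_cosine(c(1, 0), c(0, 0), c(0, 0)), "zero field")
})

test_that("wave rewiring aligns edges with the field", {
  # pivot at origin; in-link tails east (cos -1), north (cos 0); complement west
  xy <- rbind(c(0, 0), c(0.5, 0), c(0, 0.5), c(-0.5, 0))
  A <- matrix(0, 4, 4)
  A[1, 2] <- 1; A[1, 3] <- 1
  g <- spatial_digraph(A, xy)
  set.seed(26)
  sw <- wave_rewire(g, 1, "in", field = "lateral")
  expect_equal(sw$removed, 2L) # tail east of pivot: edge points against (1, 0)
  expect_equal(sw$added, 4L)   # tail west: perfectly aligned
  expect_equal(sw$principle, "wave")

  # at pivot (0.5, 0) the radial field equals the lateral field (1, 0)
  xy2 <- rbind(c(0.5, 0), c(0.9, 0), c(0.5, 0.4), c(0.1, 0))
  g2 <- spatial_digraph(A, xy2)
  set.seed(27)
  s_lat <- wave_rewire(g2, 1, "in", field = "lateral")
  set.seed(27)
  s_rad <- wave_rewire(g2, 1, "in", field = "radial")
  expect_equal(s_lat[c("removed", "added")], s_rad[c("removed", "added")])

  # radial field undefined at the origin: falls back to random, tagged
  set.seed(28)
  s_fb <- wave_rewire(g, 1, "in", field = "radial")
  expect_equal(s_fb$principle, "wave_random_fallback")
  expect_true(s_fb$removed %in% c(2L, 3L) && s_fb$added == 4L)
})

test_that("random rewiring is uniform and never reattaches to the pivot", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 0.7
  g <- spatial_digraph(A, matrix(0, 3, 2))
  set.seed(29)
  sw <- random_rewire(g, 1, "in")
  expect_equal(sw$removed, 2L) # unique member
  expect_equal(sw$added, 3L)   # unique complement
  expect_equal(sw$weight, 0.7)

  set.seed(30)
  g2 <- random_small_graph(7, 15)
  v <- select_pivot(g2, 1)$node
  members <- neighborhood(g2, v, "in")$members
  rem <- replicate(3000, random_rewire(g2, v, "in")$removed)
  adds <- replicate(3000, random_rewire(g2, v, "in")$added)
  expect_false(v %in% adds)
  emp <- tabulate(rem, g2$n)[members] / 3000
  expect_equal(emp, rep(1 / length(members), length(members)), tolerance = 0.15)
})

test_that("applying a swap transfers the weight and preserves pivot strength", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- 0.7; A[1, 3] <- 0.3
  g <- spatial_digraph(A, matrix(0, 4, 2))
  sw <- structure(list(pivot = 1L, side = "in", removed = 2L, added = 4L,
                       weight = 0.7, principle = "random"), class = "edge_swap")
  g2 <- apply_swap(g, sw)
  expect_equal(g2$adjacency[1, 4], 0.7)
  expect_equal(g2$adjacency[1, 2], 0)
  expect_equal(strength(g2, 1, "in"), strength(g, 1, "in"))
  # k loses an out-link, l gains one
  expect_equal(sum(g2$adjacency[, 2] > 0), sum(g$adjacency[, 2] > 0) - 1)
  expect_equal(sum(g2$adjacency[, 4] > 0), sum(g$adjacency[, 4] > 0) + 1)
  expect_identical(graph_fingerprint(g2)[c("n", "m", "weights")],
                   graph_fingerprint(g)[c("n", "m", "weights")])

  g5 <- spatial_digraph(rbind(cbind(A, 0), 0), matrix(0, 5, 2))
  bad <- sw; bad$removed <- 5L # not an in-neighbor of the pivot
  expect_error(apply_swap(g5, bad), "absent")
  bad2 <- sw; bad2$added <- 3L # edge (3, 1) already exists
  expect_error(apply_swap(g5, bad2), "already present")
  bad3 <- sw; bad3$added <- 1L # would create a self-loop
  expect_error(apply_swap(g5, bad3), "degenerate")
})

test_that("deterministic and stochastic functional rules coincide with a single candidate", {
  # one member, one complement node: both rules have only one legal swap
  A <- matrix(0, 3, 3)
  A[1, 2] <- 1
  g <- spatial_digraph(A, matrix(0, 3, 2))
  set.seed(31)
  d <- functional_rewire(g, 1, "in", mode = "deterministic")
  s <- functional_rewire(g, 1, "in", mode = "stochastic")
  expect_equal(d[c("removed", "added", "weight")], s[c("removed", "added", "weight")])
})

test_that("trajectories conserve the graph and are reproducible", {
  set.seed(40)
  g0 <- generate_random_digraph(30, 150)
  cfg <- rewiring_config(p_in = 0.4, p_function = 0.4, p_distance = 0.2,
                         p_wave = 0.2, field = "lateral", steps = 200, seed = 5)

  traj0 <- run_rewiring(g0, rewiring_config(steps = 0, seed = 5),
                        checkpoint_every = 0)
  expect_equal(traj0$metrics$step, 0)
  expect_identical(traj0$final$adjacency, g0$adjacency)

  traj <- run_rewiring(g0, cfg, checkpoint_every = 100)
  expect_identical(graph_fingerprint(traj$final)[c("n", "m", "weights")],
                   graph_fingerprint(g0)[c("n", "m", "weights")])
  expect_equal(nrow(traj$swap_log), 200)
  expect_true(all(traj$swap_log$principle %in%
                  c("functional", "distance", "wave", "random", "wave_random_fallback")))
  # no self-loops or duplicate edges ever created
  expect_equal(sum(diag(traj$final$adjacency)), 0)
  expect_equal(traj$final$m, g0$m)

  traj2 <- run_rewiring(g0, cfg, checkpoint_every = 100)
  expect_identical(traj$metrics, traj2$metrics)
  expect_identical(traj$swap_log, traj2$swap_log)
  expect_identical(traj$final$adjacency, traj2$final$adjacency)
})

test_that("per-step conservation holds under an auditing callback", {
  set.seed(41)
  g0 <- generate_random_digraph(25, 120)
  cfg <- rewiring_config(p_in = 0.5, p_function = 0.3, p_distance = 0.3,
                         p_wave = 0.2, field = "radial", steps = 150, seed = 6)
  violations <- 0L
  audit <- function(step, g_before, swap, g_after) {
    s_before <- strength(g_before, swap$pivot, swap$side)
    s_after <- strength(g_after, swap$pivot, swap$side)
    if (abs(s_before - s_after) > 1e-12) violations <<- violations + 1L
    if (g_after$m != g_before$m) violations <<- violations + 1L
  }
  run_rewiring(g0, cfg, checkpoint_every = 0, metrics = FALSE, on_step = audit)
  expect_equal(violations, 0L)
})

test_that("pure principles drive their signature trends", {
  seeds <- 1:10
  hub_growth <- logical(length(seeds))
  dist_drop <- logical(length(seeds))
  cos_rise <- logical(length(seeds))
  for (k in seq_along(seeds)) {
    g0 <- local({
      set.seed(1000 + seeds[k])
      generate_random_digraph(100, 912)
    })
    # pure functional, out-link rewiring only: in-degrees concentrate
    trajf <- run_rewiring(g0, rewiring_config(p_in = 0, p_function = 1,
                                              steps = 500, seed = seeds[k]),
                          checkpoint_every = 0, metrics = FALSE)
    hub_growth[k] <- max(rowSums(trajf$final$adjacency > 0)) >
      max(rowSums(g0$adjacency > 0))
    # pure distance: mean edge length decreases
    trajd <- run_rewiring(g0, rewiring_config(p_in = 0.5, p_function = 0,
                                              p_distance = 1, steps = 500,
                                              seed = seeds[k]),
                          checkpoint_every = 0, metrics = FALSE)
    mel <- function(g) {
      e <- which(g$adjacency > 0, arr.ind = TRUE)
      xy <- g$coordinates
      mean(sqrt((xy[e[, 1], 1] - xy[e[, 2], 1])^2 + (xy[e[, 1], 2] - xy[e[, 2], 2])^2))
    }
    dist_drop[k] <- mel(trajd$final) < mel(g0)
    # pure lateral wave: mean edge cosine to (1, 0) increases
    trajw <- run_rewiring(g0, rewiring_config(p_in = 0.5, p_function = 0,
                                              p_wave = 1, field = "lateral",
                                              steps = 500, seed = seeds[k]),
                          checkpoint_every = 0, metrics = FALSE)
    mec <- function(g) compute_metrics(g, field = "lateral", include = "spatial")$mean_edge_cosine
    cos_rise[k] <- mec(trajw$final) > mec(g0)
  }
  expect_gte(sum(hub_growth), 9)
  expect_gte(sum(dist_drop), 8)
  expect_gte(sum(cos_rise), 8)
})
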