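# RDF with 2D periodic boundaries, cutoff selection, same-type neighbour
# graphs, degree and connectivity metrics.

test_that("RDF of Poisson configurations is flat at unity", {
  frames <- lapply(1:20, function(s) poisson_frame(500, 60, 100 + s))
  traj <- structure(list(frames = frames, dt_ps = NA_real_),
                    class = "monolayer_trajectory")
  rdf <- compute_rdf(traj, r_max = 20, bin_width = 0.5)
  sel <- rdf$r > 2 * 0.5
  expect_true(all(abs(rdf$g[sel] - 1) <= 0.05))
})

test_that("lattice RDF resolves the first two shells with an empty gap", {
  fr <- build_hexagonal_monolayer(100, 20)
  a <- sqrt(2 * 20 / sqrt(3))
  rdf <- compute_rdf(fr, r_max = 15, bin_width = 0.1)
  first_peak_bin <- rdf[abs(rdf$r - a) <= 0.05, ]
  expect_gt(first_peak_bin$g[1], 10)             # sharp shell
  gap <- rdf$g[rdf$r > a + 0.3 & rdf$r < sqrt(3) * a - 0.3]
  expect_true(all(gap == 0))                     # nothing between shells
  # single molecule: all-zero profile
  f1 <- build_hexagonal_monolayer(1, 20)
  expect_true(all(compute_rdf(f1, r_max = 2)$g == 0))
  expect_error(compute_rdf(fr, r_max = 100), class = "monomix_invalid_argument")
})

test_that("cutoff selection lands between the first and second shells", {
  fr <- build_hexagonal_monolayer(100, 20)
  a <- sqrt(2 * 20 / sqrt(3))
  # exact lattice and a thermally jittered one
  expect_gt(select_cutoff(compute_rdf(fr, r_max = 15)), a)
  traj <- make_trajectory(fr, 10, xy_jitter_sd = 0.4, seed = 3)
  rc <- select_cutoff(compute_rdf(traj, r_max = 15))
  expect_gt(rc, a)
  expect_lt(rc, sqrt(3) * a)
  # structureless g(r) has no two peaks to bracket a minimum
  flat <- compute_rdf(poisson_frame(400, 60, 1), r_max = 20, bin_width = 0.5)
  expect_error(select_cutoff(flat), class = "monomix_no_cutoff")
  # packaged defaults from condensed-film studies
  expect_identical(reference_cutoffs(),
                   c(high_pressure = 7.2, low_pressure = 7.4))
})

test_that("pure hexagonal film gives a 6-regular graph; cell list equals brute force", {
  fr <- build_hexagonal_monolayer(100, 20)
  g <- build_same_type_graph(fr, "LA", 7.2)
  degs <- table(factor(c(g$edges), levels = g$nodes))
  expect_true(all(degs == 6))
  expect_identical(mean_node_degree(g), 6)
  # brute-force oracle equality on assorted fixtures up to 500 nodes
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  for (s in 1:5) {
    base <- build_hexagonal_monolayer(c(100, 144, 256, 400, 484)[s], 20, mix,
                                      seed = s)
    jit <- make_trajectory(base, 2, xy_jitter_sd = 0.6, seed = s)$frames[[2]]
    jit <- desorb(jit, 0.2, seed = s)
    for (sp in c("LA", "PA", "all")) {
      gc <- build_same_type_graph(jit, sp, 7.2, method = "cell")
      gb <- build_same_type_graph(jit, sp, 7.2, method = "brute")
      expect_identical(edge_key(gc), edge_key(gb))
      expect_identical(gc$nodes, gb$nodes)
    }
  }
})

test_that("the graph is invariant under rigid translation with periodic wrap", {
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  fr <- build_hexagonal_monolayer(144, 20, mix, seed = 11)
  box <- frame_box(fr)
  shifted <- fr
  shifted$x <- (fr$x + 13.7) %% box[1]
  shifted$y <- (fr$y + 31.2) %% box[2]
  shifted <- monolayer_frame(as.data.frame(shifted), box)
  for (sp in c("LA", "PA"))
    expect_identical(edge_key(build_same_type_graph(shifted, sp, 7.2)),
                     edge_key(build_same_type_graph(fr, sp, 7.2)))
})

test_that("random equimolar labelling gives mean same-type degree near 3", {
  # expectation 6*(n/2-1)/(n-1) -> 3; checked at n=1024 over 50 seeds
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  vals <- vapply(1:50, function(s) {
    fr <- build_hexagonal_monolayer(1024, 20, mix, seed = s,
                                    assignment = "exact")
    (mean_node_degree(build_same_type_graph(fr, "LA", 7.2)) +
       mean_node_degree(build_same_type_graph(fr, "PA", 7.2))) / 2
  }, 0)
  expect_equal(mean(vals), 6 * (512 - 1) / 1023, tolerance = 0.05 / 3)
})

test_that("mean degree and connectivity agree with hand-computed small graphs", {
  # path of three molecules: degrees 1, 2, 1
  p3 <- point_frame(c(5, 10, 15), c(5, 5, 5), 40)
  gp <- build_same_type_graph(p3, "LA", 6)
  expect_equal(mean_node_degree(gp), 4 / 3)
  expect_equal(mean_connectivity(gp), 1)          # every pair joined by 1 path
  # complete graph on 4 molecules: connectivity n-1
  k4 <- point_frame(c(10, 13, 10, 13), c(10, 10, 13, 13), 40)
  gk <- build_same_type_graph(k4, "LA", 5)
  expect_identical(nrow(gk$edges), 6L)
  expect_equal(mean_connectivity(gk), 3)
  # two disjoint edges: 2 connected pairs of 6 total
  de <- point_frame(c(5, 8, 25, 28), c(5, 5, 25, 25), 40)
  gd <- build_same_type_graph(de, "LA", 5)
  expect_equal(mean_connectivity(gd), 1 / 3)
  # fully disconnected nodes
  iso <- point_frame(c(5, 20, 35), c(5, 20, 35), 60)
  expect_identical(mean_connectivity(build_same_type_graph(iso, "LA", 5)), 0)
  # empty graph convention
  ge <- build_same_type_graph(iso, "PA", 5)
  expect_identical(mean_node_degree(ge), 0)
})

test_that("pairwise connectivity matches a brute-force vertex-cut oracle", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(4:7, 1)
    fr <- point_frame(runif(n, 0, 20), runif(n, 0, 20), 20)
    g <- build_same_type_graph(fr, "LA", 8)
    adj <- graph_adjacency(g)
    expect_equal(mean_connectivity(g), oracle_mean_connectivity(adj),
                 tolerance = 1e-12)
    # universal bound: pair-averaged connectivity never exceeds mean degree
    expect_lte(mean_connectivity(g), mean_node_degree(g) + 1e-12)
  }
})

test_that("trajectory metrics: static runs have zero spread; demixing raises both species", {
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  fr <- build_hexagonal_monolayer(144, 20, mix, seed = 21, assignment = "exact")
  static <- make_trajectory(fr, 3)
  m <- metrics_over_trajectory(static, c("LA", "PA"), cutoff = 7.2)
  s <- attr(m, "summary")
  expect_true(all(s$sd_degree == 0))
  expect_true(all(s$sd_connectivity == 0))
  # demixed frames dominate mixed frames for both species
  dem <- demix_labels(fr, J = 5, n_sweeps = 2000, seed = 22)
  md <- metrics_over_trajectory(dem, c("LA", "PA"), cutoff = 7.2)
  sd_ <- attr(md, "summary")
  for (sp in c("LA", "PA")) {
    expect_gt(sd_$mean_degree[sd_$species == sp],
              s$mean_degree[s$species == sp])
    expect_gt(sd_$mean_connectivity[sd_$species == sp],
              s$mean_connectivity[s$species == sp])
  }
})
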