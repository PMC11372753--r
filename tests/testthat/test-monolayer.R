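# Synthetic monolayer generator: lattice geometry, label demixing,
# staggering, desorption, trajectories.

test_that("hexagonal lattice has the right constant, density and coordination", {
  fr <- build_hexagonal_monolayer(100, 20)
  a <- sqrt(2 * 20 / sqrt(3))
  expect_equal(a, 4.81, tolerance = 1e-3)
  box <- frame_box(fr)
  # site density equals 1/MMA (exact by construction, spec allows 1%)
  expect_equal(nrow(fr) / (box[1] * box[2]), 1 / 20, tolerance = 1e-6)
  # nearest-neighbour distance is the lattice constant
  d <- monomix:::pairwise_xy_dist(cbind(fr$x, fr$y), cbind(fr$x, fr$y),
                                  box[1], box[2])
  diag(d) <- Inf
  expect_equal(min(d), a, tolerance = 1e-9)
  # exactly 6 neighbours within the first-shell cutoff for every molecule
  expect_true(all(rowSums(d <= 7.2) == 6))
})

test_that("lattice construction handles edge cases and rejects untileable n", {
  f1 <- build_hexagonal_monolayer(1, 20)
  expect_identical(nrow(f1), 1L)
  expect_identical(nrow(build_same_type_graph(f1, "LA", 7.2)$edges), 0L)
  err <- tryCatch(build_hexagonal_monolayer(101, 20), error = identity)
  expect_s3_class(err, "monomix_invalid_argument")
  expect_match(conditionMessage(err), "nearby valid n")
  # both leaflets: n per leaflet, disjoint ids, z above/below midplane
  fb <- build_hexagonal_monolayer(36, 20, leaflet = "both")
  expect_identical(nrow(fb), 72L)
  expect_false(anyDuplicated(fb$molecule_id) > 0)
  expect_true(all((fb$z > frame_box(fb)[3] / 2) == (fb$leaflet == "upper")))
})

test_that("exact assignment gives exact stoichiometry; multinomial is close", {
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  fr <- build_hexagonal_monolayer(1024, 20, mix, seed = 5, assignment = "exact")
  expect_identical(as.integer(table(fr$species)), c(512L, 512L))
  fr4 <- build_hexagonal_monolayer(100, 20, quaternary_proxy(), seed = 5,
                                   assignment = "exact")
  expect_identical(as.integer(table(fr4$species)[c("LA", "MA", "PA", "SA")]),
                   c(10L, 20L, 40L, 30L))
})

test_that("demixing conserves counts, is identity at zero sweeps, and orders by J", {
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  fr <- build_hexagonal_monolayer(144, 20, mix, seed = 2, assignment = "exact")
  expect_identical(demix_labels(fr, 2, 0), fr)
  out <- demix_labels(fr, 5, 200, seed = 3)
  expect_identical(table(out$species), table(fr$species))
  expect_identical(out[, c("x", "y", "z")], fr[, c("x", "y", "z")])
  # same seed, same result
  expect_identical(demix_labels(fr, 5, 200, seed = 3), out)
  expect_error(demix_labels(fr, -1, 10), class = "monomix_invalid_argument")
  expect_error(demix_labels(fr, 1, -1), class = "monomix_invalid_argument")
})

test_that("strong same-type affinity produces connected domains (mean degree > 4.5)", {
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  fr <- build_hexagonal_monolayer(1024, 20, mix, seed = 7, assignment = "exact")
  dem <- demix_labels(fr, J = 5, n_sweeps = 1e4, seed = 8)
  deg <- mean(c(mean_node_degree(build_same_type_graph(dem, "LA", 7.2)),
                mean_node_degree(build_same_type_graph(dem, "PA", 7.2))))
  expect_gt(deg, 4.5)
})

test_that("zero-affinity swaps leave the label field exchangeable", {
  # chi-square on per-site occupancy over 200 independently seeded runs
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  fr <- build_hexagonal_monolayer(36, 20, mix, seed = 1, assignment = "exact")
  n_rep <- 200
  counts <- numeric(36)
  for (s in seq_len(n_rep)) {
    out <- demix_labels(fr, J = 0, n_sweeps = 20, seed = 1000 + s)
    counts <- counts + (out$species == "LA")
  }
  expected <- n_rep / 2
  stat <- sum((counts - expected)^2 / (expected * 0.5))  # var = n p(1-p)
  p <- stats::pchisq(stat, df = 35, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("staggering shifts z by group offsets and respects the sign convention", {
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  fr <- build_hexagonal_monolayer(64, 20, mix, seed = 4, pH = 8.2,
                                  leaflet = "both")
  flat <- data.frame(species = rep(c("LA", "PA"), each = 2),
                     protonated = c(TRUE, FALSE, TRUE, FALSE),
                     offset = 0)
  f0 <- apply_staggering(fr, flat, jitter_sd = 0)
  expect_true(all(monomix:::frame_deviations(f0) == 0))
  # deprotonated headgroups pushed toward the water sit lower in the profile
  off <- within(flat, offset <- ifelse(protonated, 0, -1))
  f1 <- apply_staggering(fr, off, jitter_sd = 0)
  dev <- monomix:::frame_deviations(f1)
  expect_lt(mean(dev[!f1$protonated]), mean(dev[f1$protonated]))
  # missing group key is an error
  expect_error(apply_staggering(fr, flat[1:2, ]), "no offset")
})

test_that("desorption removes the requested count and only the requested species", {
  mix <- mixture_composition(c("LA", "PA"), c(1, 1))
  fr <- build_hexagonal_monolayer(200, 20, mix, seed = 9, assignment = "exact")
  expect_identical(desorb(fr, 0), fr)
  d <- desorb(fr, 0.3, species = "LA", seed = 2)
  expect_identical(sum(!d$present), 30L)
  expect_true(all(d$species[!d$present] == "LA"))
  all_gone <- desorb(fr, 1, species = "LA", seed = 2)
  g <- build_same_type_graph(all_gone, "LA", 7.2)
  expect_identical(length(g$nodes), 0L)
  expect_identical(mean_connectivity(g), 0)
  expect_error(desorb(fr, 0.5, species = "XX"),
               class = "monomix_invalid_argument")
})

test_that("trajectories are deterministic, keep identity and box, start at the input frame", {
  fr <- build_hexagonal_monolayer(36, 20)
  t1 <- make_trajectory(fr, 5, xy_jitter_sd = 0.4, seed = 6)
  t2 <- make_trajectory(fr, 5, xy_jitter_sd = 0.4, seed = 6)
  expect_identical(t1, t2)
  expect_identical(t1$frames[[1]], fr)
  expect_identical(length(t1$frames), 5L)
  for (f in t1$frames) {
    expect_identical(frame_box(f), frame_box(fr))
    expect_identical(f$molecule_id, fr$molecule_id)
  }
  expect_error(make_trajectory(fr, 0), class = "monomix_invalid_argument")
})
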