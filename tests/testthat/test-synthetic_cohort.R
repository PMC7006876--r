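test_that("parcellation partitions regions over systems with 3D centroids", {
  cfg <- sim_config(n_regions = 7, n_systems = 7, n_subjects = 2, seed = 1)
  p <- make_parcellation(cfg)
  expect_equal(sort(p$system), sort(c("VIS", "SM", "DA", "VA", "LIM",
                                      "FP", "DM")))

  cfg <- sim_config(n_regions = 100, n_systems = 7, n_subjects = 2, seed = 1)
  p <- make_parcellation(cfg)
  tab <- table(p$system)
  expect_equal(sum(tab), 100)
  expect_length(tab, 7)
  expect_true(all(tab > 0))
  expect_true(all(is.finite(c(p$x, p$y, p$z))))

  p2 <- make_parcellation(cfg)
  expect_identical(p, p2)

  expect_error(sim_config(n_regions = 5, n_systems = 7, n_subjects = 2),
               "n_systems")
})

test_that("structural template is symmetric, connected, and spans the length thresholds", {
  cfg <- sim_config(n_regions = 12, n_subjects = 2, density = 1, seed = 5)
  p <- make_parcellation(cfg)
  tp <- make_structural_template(p, cfg)
  expect_true(all(tp$adjacency[upper.tri(tp$adjacency)] == 1))
  expect_true(all(tp$length_mm[tp$adjacency == 1] > 0))

  cfg <- sim_config(n_regions = 60, n_subjects = 2, density = 0.12, seed = 11)
  p <- make_parcellation(cfg)
  tp <- make_structural_template(p, cfg)
  expect_identical(tp$adjacency, t(tp$adjacency))
  expect_true(all(diag(tp$adjacency) == 0))
  # brute-force BFS connectivity check
  part <- bfs_cc_oracle(matrix(1L, nrow(tp$adjacency), 1), tp$adjacency,
                        temporal_self = FALSE, min_nodes = 1)
  expect_length(part, 1)
  # reproducible edge count
  tp2 <- make_structural_template(p, cfg)
  expect_identical(tp$adjacency, tp2$adjacency)
  lens <- tp$length_mm[tp$adjacency == 1]
  expect_true(any(lens < 20) && any(lens > 20))
  expect_true(any(lens < 42) && any(lens > 42))
})

test_that("pure-noise subjects match the Gaussian tail oracle and carry no spikes", {
  cfg <- sim_config(n_regions = 30, n_frames = 3000, n_subjects = 2,
                    density = 0.15, event_rate = 0, motion_spike_rate = 0,
                    seed = 7)
  p <- make_parcellation(cfg)
  tp <- make_structural_template(p, cfg)
  sub <- simulate_subject(p, tp, age = 20, cfg, seed = 42)
  expect_length(sub$ground_truth, 0)
  pp <- to_point_process(sub$bold)
  n_cells <- length(pp$active)
  tail_p <- pnorm(-2)
  expect_lt(abs(mean(pp$active) - tail_p),
            3 * sqrt(tail_p * (1 - tail_p) / n_cells) + 1e-4)
  expect_true(all(sub$motion$fd < 0.4))
  expect_true(all(sub$motion$dvars < 25))
})

test_that("a hand-planted path event is recovered as a single component", {
  cfg <- sim_config(n_regions = 20, n_frames = 60, n_subjects = 2,
                    density = 0.25, event_rate = 0, motion_spike_rate = 0,
                    amp_z = 8, seed = 9)
  p <- make_parcellation(cfg)
  tp <- make_structural_template(p, cfg)
  # find a path r1 - r2 - r3 in the template
  r1 <- which(rowSums(tp$adjacency) >= 2)[1]
  r2 <- which(tp$adjacency[r1, ] == 1)[1]
  r3 <- setdiff(which(tp$adjacency[r2, ] == 1), r1)[1]
  expect_false(is.na(r3))
  ev <- cbind(c(r1, r2, r3), c(30, 30, 30))
  sub <- simulate_subject(p, tp, age = 20, cfg, seed = 43,
                          events = list(ev))
  pp <- to_point_process(drop_initial_frames(sub$bold, 4))
  ccs <- extract_components(build_multilayer(pp, tp))
  hits <- which(vapply(ccs, function(cc)
    any(cc$nodes$region %in% c(r1, r2, r3) & cc$nodes$frame == 26),
    logical(1)))
  expect_length(hits, 1)
  nd <- ccs[[hits]]$nodes
  for (r in c(r1, r2, r3))
    expect_true(any(nd$region == r & nd$frame == 26))
})

test_that("cohorts are reproducible and carry the planted age gradients", {
  cfg <- sim_config(n_subjects = 10, n_regions = 40, n_frames = 60,
                    density = 0.15, seed = 2)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$subjects[[1]]$bold, co2$subjects[[1]]$bold)
  expect_identical(co1$participants, co2$participants)
  expect_true(all(co1$participants$age >= 6 & co1$participants$age <= 33))
  expect_identical(co1$participants$group,
                   ifelse(co1$participants$age < 18, "children", "adults"))
  # distinct per-subject noise
  expect_false(identical(co1$subjects[[1]]$bold, co1$subjects[[2]]$bold))
})

test_that("planted cross-system event fraction is higher in adults", {
  cfg <- sim_config(n_subjects = 16, n_regions = 60, n_frames = 150,
                    density = 0.12, seed = 3)
  co <- simulate_cohort(cfg)
  frac_cross <- vapply(co$subjects, function(sub) {
    nc <- vapply(sub$ground_truth, function(e) e$n_cross, integer(1))
    ns <- vapply(sub$ground_truth, function(e) e$n_steps, integer(1))
    sum(nc) / max(sum(ns), 1)
  }, numeric(1))
  grp <- co$participants$group
  expect_gt(mean(frac_cross[grp == "adults"]),
            mean(frac_cross[grp == "children"]))
})

test_that("generator rejects degenerate configurations", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(mixing = c(-0.1, 0.5)), "probabilities")
  expect_error(sim_config(amp_z = 2), "amp_z")
  cfg <- sim_config(n_frames = 4, n_subjects = 2, n_regions = 10,
                    density = 0.4)
  p <- make_parcellation(cfg)
  tp <- make_structural_template(p, cfg)
  expect_error(simulate_subject(p, tp, 10, cfg), "n_frames")
  expect_error(simulate_cohort(sim_config(n_subjects = 1)), "n_subjects")
})

test_that("effects-off mode removes every age dependence", {
  cfg <- sim_config(effects = FALSE)
  expect_equal(cfg$mixing[1], cfg$mixing[2])
  expect_equal(cfg$long_range_pref[1], cfg$long_range_pref[2])
  expect_equal(cfg$repertoire_size, c(0, 0))
  co <- simulate_cohort(sim_config(n_subjects = 4, n_regions = 30, density = 0.15,
                                   n_frames = 40, effects = FALSE, seed = 8))
  reused <- unlist(lapply(co$subjects, function(sub)
    vapply(sub$ground_truth, function(e) e$reused, logical(1))))
  expect_false(any(reused))
})
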