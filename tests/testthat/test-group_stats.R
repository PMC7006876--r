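make_grouped <- function(ccs, group, parc) {
  grouped_ccs(ccs, group, parc)
}

test_that("group statistics are means of SD and within-group pairwise STD", {
  parc <- make_parc(c("VIS", "SM", "DA", "VA"))
  # group A: SD values 0 and log 2; group B: copies of the same components
  cc1 <- make_cc(c(1, 1), c(1, 2))       # one system -> SD 0
  cc2 <- make_cc(c(1, 2), c(1, 1))       # two systems -> SD log 2
  g <- make_grouped(list(cc1, cc2, cc1, cc2), c("A", "A", "B", "B"), parc)

  sd_stat <- group_statistic(g, "SD")
  expect_equal(unname(sd_stat), rep(log(2) / 2, 2))  # identical multisets

  std_stat <- group_statistic(g, "STD", std_convention = "sim")
  expect_equal(unname(std_stat[1]), unname(std_stat[2]))

  # 3-component group: STD equals the hand-average of the three pairwise sims
  cc3 <- make_cc(c(3, 4), c(2, 2))
  g3 <- make_grouped(list(cc1, cc2, cc3, cc1, cc2), c(rep("A", 3), "B", "B"),
                     parc)
  vecs <- t(vapply(list(cc1, cc2, cc3),
                   function(cc) activation_vector(cc, 4)$x_norm, numeric(4)))
  expect_equal(unname(group_statistic(g3, "STD",
                                      std_convention = "sim")["A"]),
               naive_mean_pair_sim(vecs, 1:3))

  expect_error(group_statistic(g, "SD", selector = c(1L, 2L)), "group B")
})

test_that("permutation p-values match exhaustive enumeration for 3+3 groups", {
  parc <- make_parc(c("VIS", "SM", "DA", "VA", "LIM"))
  set.seed(21)
  ccs <- lapply(1:6, function(i)
    make_cc(sample(1:5, sample(2:4, 1)), rep(i, sample(2:4, 1))[1], i))
  ccs <- lapply(1:6, function(i)
    make_cc(sample(1:5, 3), sample(1:6, 3, replace = TRUE), i))
  group <- c("A", "A", "A", "B", "B", "B")
  g <- make_grouped(ccs, group, parc)

  for (tails in c("two", "one_greater", "one_less")) {
    res <- permutation_test(g, "SD", tails = tails, exact = TRUE)
    want <- exhaustive_perm_p(g$sd_values, group == "A", tails)
    expect_equal(res$p_value, want)
    expect_equal(res$n_perm, choose(6, 3))
  }

  # sampled estimator: +1-corrected bounds and agreement with exact p
  res_mc <- permutation_test(g, "SD", n_perm = 2000, seed = 5)
  res_ex <- permutation_test(g, "SD", exact = TRUE)
  expect_gte(res_mc$p_value, 1 / 2001)
  expect_lte(res_mc$p_value, 1)
  expect_lt(abs(res_mc$p_value - res_ex$p_value), 0.05)
})

test_that("a symmetric null with zero observed difference gives p near 1", {
  parc <- make_parc(c("VIS", "SM"))
  cc1 <- make_cc(c(1, 1), c(1, 2))
  cc2 <- make_cc(c(1, 2), c(3, 3))
  g <- make_grouped(list(cc1, cc2, cc1, cc2), c("A", "A", "B", "B"), parc)
  res <- permutation_test(g, "SD", n_perm = 500, seed = 2)
  expect_equal(res$observed_diff, 0)
  expect_gt(res$p_value, 0.99)
})

test_that("STD permutations agree between submatrix averaging and direct recomputation", {
  parc <- make_parc(c("VIS", "SM", "DA", "VA", "LIM", "FP"))
  set.seed(31)
  ccs <- lapply(1:10, function(i)
    make_cc(sample(1:6, 3), sample(1:8, 3, replace = TRUE), i))
  group <- rep(c("A", "B"), each = 5)
  g <- make_grouped(ccs, group, parc)
  res <- permutation_test(g, "STD", exact = TRUE, std_convention = "sim")

  vecs <- t(vapply(ccs, function(cc) activation_vector(cc, 6)$x_norm,
                   numeric(6)))
  combs <- utils::combn(10, 5)
  diffs <- apply(combs, 2, function(ix)
    naive_mean_pair_sim(vecs, ix) -
      naive_mean_pair_sim(vecs, setdiff(1:10, ix)))
  obs <- naive_mean_pair_sim(vecs, 1:5) - naive_mean_pair_sim(vecs, 6:10)
  expect_equal(res$observed_diff, obs)
  expect_equal(res$p_value, mean(abs(diffs) >= abs(obs) - 1e-12))

  # monotone relabeling: identical two-sided p for sim and div conventions
  res_div <- permutation_test(g, "STD", exact = TRUE,
                              std_convention = "div")
  expect_equal(res_div$p_value, res$p_value)
  expect_equal(res_div$observed_diff, -res$observed_diff)
})

test_that("BH correction matches a hand-written step-up oracle", {
  expect_equal(fdr_correct(rep(0.001, 7)), rep(0.001, 7))
  expect_equal(fdr_correct(0.03), 0.03)

  p <- seq(0.01, 0.07, by = 0.01)
  expect_equal(fdr_correct(p), hand_bh(p))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(7)
    expect_equal(fdr_correct(p), hand_bh(p))
  }
  expect_error(fdr_correct(c(0.5, 0)), "p-values")
})

test_that("nodal maps aggregate per-region components and flag undefined regions", {
  parc <- make_parc(c("VIS", "SM", "DA"))
  cc1 <- make_cc(c(1, 2), c(1, 1), 1)  # SD log 2
  cc2 <- make_cc(c(1, 3), c(2, 2), 2)  # SD log 2
  cc3 <- make_cc(c(1, 1), c(4, 5), 3)  # SD 0
  g <- make_grouped(list(cc1, cc2, cc3, cc1, cc2),
                    c("A", "A", "A", "B", "B"), parc)
  maps <- nodal_maps(g, std_convention = "sim")

  a1 <- maps[maps$group == "A" & maps$region == 1, ]
  expect_equal(a1$n_cc, 3)
  expect_equal(a1$sd, mean(c(log(2), log(2), 0)))
  vecs <- t(vapply(list(cc1, cc2, cc3),
                   function(cc) activation_vector(cc, 3)$x_norm, numeric(3)))
  expect_equal(a1$std, naive_mean_pair_sim(vecs, 1:3))

  # region 2 appears in one component of group B -> undefined
  b2 <- maps[maps$group == "B" & maps$region == 2, ]
  expect_false(b2$defined)
  expect_true(is.na(b2$std))

  # single-system components give nodal SD of zero wherever defined
  g0 <- make_grouped(list(cc3, cc3, cc3, cc3), c("A", "A", "B", "B"), parc)
  m0 <- nodal_maps(g0)
  expect_true(all(m0$sd[m0$defined] == 0))
})

test_that("map agreement is the Pearson correlation over jointly defined regions", {
  base <- data.frame(region = 1:100, group = "A", n_cc = 5,
                     sd = runif(100), std = runif(100), defined = TRUE)
  other <- base
  other$group <- "B"
  maps <- rbind(base, other)
  class(maps) <- c("nodal_maps", "data.frame")
  expect_equal(map_agreement(maps, "std")$r, 1)

  other2 <- other
  other2$std <- -other$std + 3
  maps2 <- rbind(base, other2)
  class(maps2) <- c("nodal_maps", "data.frame")
  expect_equal(map_agreement(maps2, "std")$r, -1)

  set.seed(13)
  other3 <- other
  other3$std <- runif(100)
  maps3 <- rbind(base, other3)
  class(maps3) <- c("nodal_maps", "data.frame")
  got <- map_agreement(maps3, "std")$r
  x <- base$std; y <- other3$std
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(abs(got - want), 1e-12)

  few <- maps3[maps3$region <= 2, ]
  expect_error(map_agreement(few, "std"), "fewer than 3")
})
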