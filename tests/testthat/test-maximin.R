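test_that("maximin pairs land where the cascades predict", {
  costs <- subject_count_costs()
  rect <- icc_rect(0.10, 0.70, 0.30, 0.90)
  # crossover treatment: worst case at the lower-left corner
  mm <- maximin_params("crossover", "treatment", costs, rect)
  expect_equal(unname(mm$rho_at), c(0.10, 0.30))
  # crossover interaction: worst case at the upper-right corner
  mi <- maximin_params("crossover", "treatment_by_period", costs, rect)
  expect_equal(unname(mi$rho_at), c(0.70, 0.90))
  # extended parallel treatment with equal costs: both upper bounds
  me <- maximin_params("extended_parallel", "treatment", costs, rect)
  expect_equal(unname(me$rho_at), c(0.70, 0.90))
  expect_match(me$branch, "rhoA_high, rhoB_high")
  # parallel with equal arm costs on a symmetric rectangle: the
  # variance-ratio locus phi* = 1 crosses the rectangle, variance
  # (c_A + c_B + 2(c_t + c_sp)) sigma_y^2 / C = 2
  mp <- maximin_params("parallel", "treatment", costs,
                       icc_rect(0.70, 1, 0.70, 1), sigma_y_sq = 1, C = 1)
  expect_equal(mp$variance, 2)
  expect_match(mp$branch, "locus")
})

test_that("a point rectangle degenerates to the optimal design there", {
  costs <- subject_count_costs()
  rect <- icc_rect(0.4, 0.4, 0.6, 0.6)
  mm <- maximin_params("crossover", "treatment", costs, rect)
  expect_match(mm$branch, "degenerate")
  expect_equal(mm$variance,
               optimal_variance("crossover", "treatment", costs, 0.4, 0.6))
  og <- maximin_grid_oracle("extended_parallel", "treatment", costs, rect)
  expect_equal(unname(og$rho_at), c(0.4, 0.6))
})

test_that("the grid oracle finds the monotone corners for the crossover", {
  costs <- subject_count_costs()
  o1 <- maximin_grid_oracle("crossover", "treatment", costs,
                            icc_rect(0.2, 0.4, 0.2, 0.4))
  expect_equal(unname(o1$rho_at), c(0.2, 0.2))
  o2 <- maximin_grid_oracle("crossover", "treatment_by_period", costs,
                            icc_rect(0.2, 0.4, 0.2, 0.4))
  expect_equal(unname(o2$rho_at), c(0.4, 0.4))
})

test_that("closed-form maximin agrees with the grid oracle on random draws", {
  set.seed(505)
  for (i in 1:60) {
    de <- random_design_effect()
    costs <- random_costs()
    rect <- rrect()
    mm <- suppressWarnings(maximin_params(de$design, de$effect, costs, rect))
    og <- maximin_grid_oracle(de$design, de$effect, costs, rect,
                              grid_resolution = 201)
    # closed form dominates the grid (the grid is a subset of the
    # rectangle) and exceeds it by at most the grid discretization error
    expect_gte(mm$variance, og$variance * (1 - 1e-9))
    expect_lte(mm$variance, og$variance * (1 + 1e-3))
  }
})

test_that("the maximin variance dominates the whole rectangle", {
  set.seed(606)
  for (i in 1:10) {
    de <- random_design_effect()
    costs <- random_costs()
    rect <- rrect()
    mm <- suppressWarnings(maximin_params(de$design, de$effect, costs, rect))
    gA <- seq(rect$rhoA_low, rect$rhoA_high, length.out = 200)
    gB <- seq(rect$rhoB_low, rect$rhoB_high, length.out = 200)
    v <- outer(gA, gB, function(a, b) {
      optimal_variance(de$design, de$effect, costs, a, b)
    })
    expect_gte(mm$variance, max(v) * (1 - 1e-9))
  }
})

test_that("enlarging the rectangle never decreases the maximin variance", {
  set.seed(707)
  for (i in 1:20) {
    de <- random_design_effect()
    costs <- random_costs()
    inner <- rrect()
    outer_rect <- icc_rect(max(0.01, inner$rhoA_low - runif(1, 0, 0.05)),
                           min(1, inner$rhoA_high + runif(1, 0, 0.05)),
                           max(0.01, inner$rhoB_low - runif(1, 0, 0.05)),
                           min(1, inner$rhoB_high + runif(1, 0, 0.05)))
    v_in <- suppressWarnings(
      maximin_params(de$design, de$effect, costs, inner)$variance)
    v_out <- suppressWarnings(
      maximin_params(de$design, de$effect, costs, outer_rect)$variance)
    expect_gte(v_out, v_in * (1 - 1e-12))
  }
})

test_that("maximin extended parallel dominates maximin crossover for the interaction", {
  set.seed(808)
  for (i in 1:50) {
    costs <- random_costs()
    rect <- rrect()
    v_ep <- suppressWarnings(maximin_params("extended_parallel",
                                            "treatment_by_period", costs,
                                            rect)$variance)
    v_c <- maximin_params("crossover", "treatment_by_period", costs,
                          rect)$variance
    # the dominance bound: ep maximin variance never exceeds the
    # crossover's worst case 4(c_A+c_B+2c_t+c_s2p)(1 + 2 rho rho/(rho+rho))
    expect_lte(v_ep, v_c * (1 + 1e-12))
  }
})

test_that("under a subject-count budget the maximin crossover needs no more subjects than the maximin parallel", {
  set.seed(909)
  costs <- subject_count_costs()
  spec <- power_spec(ES = 0.5)
  for (i in 1:30) {
    rect <- rrect()
    n_c <- maximin_sample_size("crossover", "treatment", spec, costs,
                               rect)$n_raw
    n_p <- maximin_sample_size("parallel", "treatment", spec, costs,
                               rect)$n_raw
    expect_lte(n_c, n_p * (1 + 1e-12))
  }
})

test_that("relative efficiencies reproduce the printed design comparisons", {
  costs <- subject_count_costs()
  effs <- function(rect) {
    sols <- lapply(c("crossover", "parallel", "extended_parallel"),
                   maximin_params, effect = "treatment", costs = costs,
                   rect = rect)
    relative_efficiency(sols)
  }
  e1 <- effs(icc_rect(0.01, 0.10, 0.90, 1.00))
  expect_equal(unname(e1["crossover"]), 1)
  expect_equal(round2(unname(e1["parallel"])), 0.61)
  expect_equal(round2(unname(e1["extended_parallel"])), 0.96)
  e2 <- effs(icc_rect(0.70, 1.00, 0.70, 1.00))
  expect_equal(round2(unname(e2[c("parallel", "extended_parallel")])),
               c(0.15, 0.15))
  # duplicated identical designs are co-best
  sols <- rep(list(maximin_params("crossover", "treatment", costs,
                                  icc_rect(0.3, 0.6, 0.3, 0.6))), 2)
  expect_equal(unname(relative_efficiency(sols)), c(1, 1))
  # mixed effects are rejected
  bad <- list(maximin_params("crossover", "treatment", costs,
                             icc_rect(0.3, 0.6, 0.3, 0.6)),
              maximin_params("crossover", "treatment_by_period", costs,
                             icc_rect(0.3, 0.6, 0.3, 0.6)))
  expect_error(relative_efficiency(bad), "same effect")
})

test_that("the scenario grid recovers the qualitative design rankings", {
  # equal treatment costs at CR_p = 1 and CR = 1: crossover always best
  g <- evaluation_grid("treatment", cr_A = 1, cr_B = 1, cr_p = 1,
                       widths = c(0.10, 0.30))
  keep <- g$rhoA_low >= 0.15 & g$rhoB_low >= 0.15
  expect_true(all(g$best[keep] == "crossover"))
  # interaction effect: extended parallel best in every scenario
  gi <- evaluation_grid("treatment_by_period", cr_A = c(10, 1, 0.1),
                        cr_B = c(10, 1, 0.1), cr_p = c(1, 2),
                        widths = 0.30)
  expect_true(all(grepl("extended_parallel", gi$best)))
  # a single cell is consistent with relative_efficiency on that cell
  g1 <- evaluation_grid("treatment", cr_A = 0.1, cr_B = 10, cr_p = 2,
                        widths = 0.30, max_lower = 0.2)
  row <- g1[g1$rhoA_low == 0.2 & g1$rhoB_low == 0.2, ][1, ]
  costs <- cost_structure(c_A = 0.1, c_B = 10, c_t = 0, c_sp = 1, c_s2p = 2)
  rect <- icc_rect(row$rhoA_low, row$rhoA_high, row$rhoB_low, row$rhoB_high)
  sols <- lapply(c("parallel", "extended_parallel", "crossover"),
                 maximin_params, effect = "treatment", costs = costs,
                 rect = rect)
  eff <- relative_efficiency(sols)
  expect_equal(row$best, names(eff)[which.max(eff)])
  expect_equal(row$crossover,
               sols[[3]]$variance / 2)  # grid reports per sigma_y^2/C = 1
})
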