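test_that("raw sample sizes match the closed-form effect-size expressions", {
  costs <- subject_count_costs()
  # medium effect, ICCs (0.10, 0.30): the planning example's 53.4 subjects
  expect_equal(raw_sample_size("crossover", "treatment",
                               power_spec(ES = 0.5), costs, 0.10, 0.30),
               2 * (z2() / 0.5)^2 * (1 - 2 * 0.03 / 0.4), tolerance = 1e-12)
  expect_equal(round(raw_sample_size("crossover", "treatment",
                                     power_spec(ES = 0.5), costs,
                                     0.10, 0.30), 1), 53.4)
  # large effect at high equal ICCs
  expect_equal(raw_sample_size("crossover", "treatment",
                               power_spec(ES = 0.8), costs, 0.7, 0.7),
               2 * (z2() / 0.8)^2 * 0.3, tolerance = 1e-12)
  # interaction: 8 (z/ES)^2 (1 + 2 rhoA rhoB / (rhoA + rhoB))
  expect_equal(raw_sample_size("crossover", "treatment_by_period",
                               power_spec(ES = 0.8), costs, 0.1, 0.1),
               8 * (z2() / 0.8)^2 * 1.1, tolerance = 1e-12)
})

test_that("the budget-identity route equals the closed-form sample-size formulas", {
  # independent oracle: direct transcription of the effect-size formulas
  # with general cost weighting
  closed_form <- function(design, effect, spec, costs, rA, rB) {
    z <- z2(spec$alpha, spec$power)
    a <- costs$c_A + costs$c_t + costs$c_sp
    b <- costs$c_B + costs$c_t + costs$c_sp
    wA <- 2 * costs$c_A + 2 * costs$c_t + costs$c_s2p
    wB <- 2 * costs$c_B + 2 * costs$c_t + costs$c_s2p
    s <- rA + rB
    if (design == "crossover" && effect == "treatment") {
      2 * (z / spec$ES)^2 * (1 - 2 * rA * rB / s)
    } else if (design == "crossover") {
      8 * (z / spec$ES)^2 * (1 + 2 * rA * rB / s)
    } else if (design == "parallel") {
      2 * (z / spec$ES)^2 * (1 + (a + b) / sqrt(a * b) * sqrt(rA * rB) / s)
    } else if (effect == "treatment") {
      (z / spec$ES)^2 * (1 + 2 * rA * rB / s + (wA + wB) / sqrt(wA * wB) *
                           sqrt(rA * rB * (1 + rA) * (1 + rB)) / s)
    } else {
      4 * (z / spec$ES)^2 * (1 - 2 * rA * rB / s + (wA + wB) /
                               sqrt(wA * wB) *
                               sqrt(rA * rB * (1 - rA) * (1 - rB)) / s)
    }
  }
  set.seed(111)
  for (i in 1:40) {
    de <- random_design_effect()
    costs <- random_costs()
    spec <- power_spec(ES = runif(1, 0.2, 1),
                       alpha = sample(c(0.01, 0.05), 1),
                       power = runif(1, 0.5, 0.95))
    rA <- runif(1, 0.05, 0.95); rB <- runif(1, 0.05, 0.95)
    expect_equal(raw_sample_size(de$design, de$effect, spec, costs, rA, rB),
                 closed_form(de$design, de$effect, spec, costs, rA, rB),
                 tolerance = 1e-9)
  }
})

test_that("sample size, variance, and power close the loop", {
  set.seed(222)
  for (i in 1:25) {
    de <- random_design_effect()
    costs <- random_costs()
    spec <- power_spec(ES = runif(1, 0.2, 1), alpha = runif(1, 0.01, 0.2),
                       power = runif(1, 0.5, 0.95))
    rA <- runif(1, 0.05, 0.95); rB <- runif(1, 0.05, 0.95)
    n <- raw_sample_size(de$design, de$effect, spec, costs, rA, rB)
    ratio <- optimal_allocation(de$design, de$effect, costs, rA, rB)
    C <- budget_required(de$design, n, ratio / (1 + ratio), costs) -
      2 * costs$c_ts
    v <- optimal_variance(de$design, de$effect, costs, rA, rB,
                          sigma_y_sq = 2, C = C)
    beta <- beta_from_effect_size(spec$ES, 2)
    expect_equal(power_from_variance(v, beta, spec$alpha), spec$power,
                 tolerance = 1e-9)
  }
})

test_that("maximin plans reproduce the published sample-size columns", {
  costs <- subject_count_costs()
  for (sc in bold_scenarios()) {
    plan <- maximin_sample_size(sc$design, sc$effect,
                                power_spec(ES = 0.8, alpha = sc$alpha),
                                costs, sc$rect)
    expect_equal(plan$N, sc$N,
                 label = sprintf("%s/%s alpha=%g N", sc$design, sc$effect,
                                 sc$alpha))
  }
  # the planning example: 27 + 1 per sequence, 56 in total
  plan <- maximin_sample_size("crossover", "treatment",
                              power_spec(ES = 0.5), costs,
                              icc_rect(0.10, 0.70, 0.30, 0.90))
  expect_equal(plan$n1_uncorrected, 27L)
  expect_equal(plan$correction_per_arm, 1L)
  expect_equal(c(plan$n1, plan$n2, plan$N), c(28L, 28L, 56L))
  # parallel plan splits 30/10 before the +2 unpooled correction
  p44 <- maximin_sample_size("parallel", "treatment",
                             power_spec(ES = 0.8), costs,
                             icc_rect(0.01, 0.10, 0.90, 1.00))
  expect_equal(c(p44$n1_uncorrected, p44$n2_uncorrected), c(30L, 10L))
  expect_equal(p44$correction_per_arm, 2L)
  expect_equal(p44$allocation_ratio, 3)
})

test_that("sample size is monotone in effect size, power, and alpha", {
  costs <- subject_count_costs()
  rect <- icc_rect(0.2, 0.5, 0.3, 0.7)
  N_at <- function(ES, power = 0.8, alpha = 0.05) {
    maximin_sample_size("crossover", "treatment",
                        power_spec(ES = ES, alpha = alpha, power = power),
                        costs, rect)$N
  }
  expect_true(all(diff(sapply(c(0.2, 0.4, 0.6, 0.8), N_at)) <= 0))
  expect_true(all(diff(sapply(c(0.6, 0.8, 0.9), function(p)
    N_at(0.5, power = p))) >= 0))
  expect_gte(N_at(0.5, alpha = 0.01), N_at(0.5, alpha = 0.05))
})

test_that("power inversion and its limits behave", {
  beta <- 0.7; alpha <- 0.05
  v <- (beta / z2(alpha, 0.8))^2
  expect_equal(power_from_variance(v, beta, alpha), 0.8, tolerance = 1e-12)
  expect_equal(power_from_variance(1, 0, alpha), alpha / 2)
  expect_equal(power_from_variance(1e14, 2, alpha), alpha / 2,
               tolerance = 1e-6)
})

test_that("predictive intervals quantify Monte Carlo error", {
  expect_equal(round(predictive_interval(0.80, 25000), 3),
               c(lower = 0.795, upper = 0.805))
  expect_equal(unname(predictive_interval(0.80, 100)),
               0.80 + c(-1, 1) * qnorm(0.975) * sqrt(0.16 / 100))
  wide <- predictive_interval(0.5, 1e12)
  expect_equal(unname(wide), c(0.5, 0.5), tolerance = 1e-5)
})
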