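# Shared fixtures: normal quantile sums and random scenario generators.

z2 <- function(alpha = 0.05, power = 0.80) {
  qnorm(1 - alpha / 2) + qnorm(power)
}

# random cost structure with well-separated components; suppresses the
# c_sp <= c_s2p <= 2 c_sp advisory warning for unconstrained draws
random_costs <- function() {
  suppressWarnings(cost_structure(
    c_A = runif(1, 0, 5), c_B = runif(1, 0, 5), c_t = runif(1, 0, 2),
    c_sp = runif(1, 0.1, 3), c_s2p = runif(1, 0.1, 5),
    c_ts = runif(1, 0, 2)))
}

# random valid ICC rectangle
rrect <- function() {
  a <- runif(1, 0.02, 0.9); b <- runif(1, 0.02, 0.9)
  icc_rect(a, min(1, a + runif(1, 0, 0.5)), b, min(1, b + runif(1, 0, 0.5)))
}

random_design_effect <- function() {
  design <- sample(c("parallel", "extended_parallel", "crossover"), 1)
  effect <- if (design == "parallel") "treatment" else
    sample(c("treatment", "treatment_by_period"), 1)
  list(design = design, effect = effect)
}

# the Table 4 / interaction-table scenarios whose sample-size column the
# planning rules reproduce; `bold` marks the design whose plan targets 80%
bold_scenarios <- function() {
  list(
    list(design = "extended_parallel", effect = "treatment", alpha = 0.05,
         rect = icc_rect(0.01, 0.10, 0.90, 1.00), N = 30),
    list(design = "parallel", effect = "treatment", alpha = 0.05,
         rect = icc_rect(0.01, 0.10, 0.90, 1.00), N = 44),
    list(design = "crossover", effect = "treatment", alpha = 0.05,
         rect = icc_rect(0.70, 1.00, 0.70, 1.00), N = 10),
    list(design = "crossover", effect = "treatment", alpha = 0.05,
         rect = icc_rect(0.90, 1.00, 0.90, 1.00), N = 6),
    list(design = "crossover", effect = "treatment", alpha = 0.01,
         rect = icc_rect(0.90, 1.00, 0.90, 1.00), N = 8),
    list(design = "crossover", effect = "treatment", alpha = 0.01,
         rect = icc_rect(0.70, 1.00, 0.70, 1.00), N = 16),
    list(design = "crossover", effect = "treatment_by_period", alpha = 0.05,
         rect = icc_rect(0.01, 0.10, 0.01, 0.10), N = 110),
    list(design = "crossover", effect = "treatment_by_period", alpha = 0.05,
         rect = icc_rect(0.01, 0.30, 0.01, 0.30), N = 130),
    list(design = "crossover", effect = "treatment_by_period", alpha = 0.01,
         rect = icc_rect(0.01, 0.10, 0.01, 0.10), N = 166),
    list(design = "extended_parallel", effect = "treatment_by_period",
         alpha = 0.05, rect = icc_rect(0.70, 1.00, 0.70, 1.00), N = 34),
    list(design = "extended_parallel", effect = "treatment_by_period",
         alpha = 0.01, rect = icc_rect(0.90, 1.00, 0.90, 1.00), N = 23)
  )
}

# half-up rounding to two decimals, as the printed tables round; the
# epsilon keeps exact halves from dropping through binary representation
round2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100
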