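z_sum <- function(spec) {
  stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
}

#' Unrounded required sample size at stated intraclass correlations
#'
#' Number of subjects for which the optimal-allocation variance of the
#' effect estimator meets the normal-approximation power equation
#' `Var = (beta / (z_{1-alpha/2} + z_{1-power}))^2`. Computed through the
#' budget identity (required budget divided by the per-subject cost at the
#' optimal allocation), which coincides with the closed-form effect-size
#' expressions for each design; e.g. for the crossover and the treatment
#' effect, `n_c = 2 ((z_{1-alpha/2}+z_{1-power}) / ES)^2
#' (1 - 2 rho_A rho_B / (rho_A + rho_B))`.
#'
#' @inheritParams optimal_allocation
#' @param spec A [power_spec].
#' @return The unrounded total number of subjects.
#' @examples
#' raw_sample_size("crossover", "treatment", power_spec(ES = 0.5),
#'                 subject_count_costs(), rhoA = 0.10, rhoB = 0.30)  # 53.4
#' @export
raw_sample_size <- function(design, effect, spec, costs, rhoA, rhoB) {
  de <- check_design_effect(design, effect)
  stopifnot(inherits(spec, "power_spec"))
  rho_in_unit(rhoA, "rhoA")
  rho_in_unit(rhoB, "rhoB")
  # budget needed so that the optimal variance (per sigma_y^2 = 2, making
  # beta == ES) equals the Eq-(8) variance; scale-free in sigma_y^2
  C_req <- 2 * (z_sum(spec) / spec$ES)^2 *
    optimal_variance_kernel(de$design, de$effect, costs, rhoA, rhoB)
  ratio <- optimal_allocation(de$design, de$effect, costs, rhoA, rhoB)
  p1 <- ratio / (1 + ratio)
  C_req / cost_per_subject(de$design, p1, costs)
}

# Small-sample corrections for planning with normal quantiles when the
# analysis is an exact t-test. Pooled-variance analyses (crossover): +1 per
# arm at alpha = 0.05, +2 at alpha = 0.01. Unpooled-variance analyses
# (parallel and extended parallel): +4 per arm at alpha = 0.01; at
# alpha = 0.05, +2 per arm when both arms have >= 8 subjects, else +3.
correction_per_arm <- function(pooled, alpha, min_arm) {
  if (pooled) {
    if (alpha <= 0.01) 2L else 1L
  } else {
    if (alpha <= 0.01) 4L else if (min_arm >= 8) 2L else 3L
  }
}

#' Maximin sample-size plan
#'
#' Plans a trial over an ICC rectangle: takes the maximin ICC pair from
#' [maximin_params], the unrounded total from [raw_sample_size] at that
#' pair, splits it over the two sequences at the optimal allocation, rounds
#' to integers, and adds the small-sample t-test corrections per arm.
#'
#' Rounding: the crossover design (analyzed by a pooled-variance t-test on
#' 1:1-allocated arms) takes the ceiling of half the raw total per arm; the
#' parallel and extended parallel designs (unpooled-variance t-tests) take
#' the ceiling of the raw total and split it by the optimal proportion to
#' the nearest integer. Corrections: +1 per arm (pooled, alpha = 0.05),
#' +2 (pooled, alpha = 0.01); +2 per arm (unpooled, alpha = 0.05, both arms
#' >= 8 before correction), +3 (unpooled, alpha = 0.05, an arm < 8),
#' +4 (unpooled, alpha = 0.01).
#'
#' @inheritParams maximin_params
#' @param spec A [power_spec].
#' @return An object of class `sample_size_plan` with fields `design`,
#'   `effect`, `rho_star`, `n_raw`, `allocation_ratio`, `p1`,
#'   `n1_uncorrected`, `n2_uncorrected`, `correction_per_arm`, `n1`, `n2`,
#'   `N`, `pooled`, `spec`, `maximin`.
#' @examples
#' maximin_sample_size("crossover", "treatment", power_spec(ES = 0.5),
#'                     subject_count_costs(),
#'                     icc_rect(0.10, 0.70, 0.30, 0.90))  # N = 56
#' @export
maximin_sample_size <- function(design, effect, spec, costs, rect) {
  de <- check_design_effect(design, effect)
  stopifnot(inherits(spec, "power_spec"))
  mm <- maximin_params(de$design, de$effect, costs, rect)
  rhoA <- unname(mm$rho_at["rhoA"]); rhoB <- unname(mm$rho_at["rhoB"])
  n_raw <- raw_sample_size(de$design, de$effect, spec, costs, rhoA, rhoB)
  pooled <- de$design == "crossover"
  if (pooled) {
    n1 <- n2 <- as.integer(ceiling(n_raw / 2 - 1e-9))
  } else {
    N0 <- as.integer(ceiling(n_raw - 1e-9))
    n1 <- as.integer(floor(N0 * mm$p1 + 0.5))
    n2 <- N0 - n1
  }
  n1 <- max(n1, 1L); n2 <- max(n2, 1L)
  corr <- correction_per_arm(pooled, spec$alpha, min(n1, n2))
  structure(list(design = de$design, effect = de$effect,
                 rho_star = c(rhoA = rhoA, rhoB = rhoB),
                 n_raw = n_raw, allocation_ratio = mm$allocation_ratio,
                 p1 = mm$p1, n1_uncorrected = n1, n2_uncorrected = n2,
                 correction_per_arm = corr,
                 n1 = n1 + corr, n2 = n2 + corr,
                 N = n1 + n2 + 2L * corr,
                 pooled = pooled, spec = spec, maximin = mm),
            class = "sample_size_plan")
}

#' @export
print.sample_size_plan <- function(x, ...) {
  seqs <- switch(x$design, parallel = c("A", "B"),
                 extended_parallel = c("AA", "BB"), crossover = c("AB", "BA"))
  cat(sprintf("Maximin sample-size plan: %s design, %s effect\n",
              x$design, x$effect))
  cat(sprintf("  ES = %g, alpha = %g (two-tailed), power = %g\n",
              x$spec$ES, x$spec$alpha, x$spec$power))
  cat(sprintf("  maximin ICCs: rho_A* = %.4f, rho_B* = %.4f\n",
              x$rho_star["rhoA"], x$rho_star["rhoB"]))
  cat(sprintf("  unrounded total: %.2f; allocation n1/n2 = %.4f\n",
              x$n_raw, x$allocation_ratio))
  cat(sprintf("  %s-variance t correction: +%d per arm\n",
              if (x$pooled) "pooled" else "unpooled", x$correction_per_arm))
  cat(sprintf("  final: %d (%s) + %d (%s) = %d subjects\n",
              x$n1, seqs[1], x$n2, seqs[2], x$N))
  invisible(x)
}

#' Power implied by an estimator variance
#'
#' Normal-approximation power of a two-tailed test of an effect `beta`
#' whose estimator has the given variance:
#' `power = Phi(|beta| / sqrt(Var) - z_{1-alpha/2})`. At `beta = 0` this is
#' one tail, `alpha / 2`.
#'
#' @param variance Variance of the effect estimator (> 0).
#' @param beta Effect magnitude.
#' @param alpha Two-tailed type-I error rate.
#' @return The approximate power.
#' @export
power_from_variance <- function(variance, beta, alpha = 0.05) {
  stopifnot(all(variance > 0), alpha > 0, alpha < 1)
  stats::pnorm(abs(beta) / sqrt(variance) - stats::qnorm(1 - alpha / 2))
}

#' Predictive interval for a simulated power estimate
#'
#' Normal-approximation interval around a nominal power reflecting pure
#' Monte Carlo error at a given replication count:
#' `pi +/- z * sqrt(pi (1 - pi) / n_sim)`.
#'
#' @param pi Nominal power in (0, 1).
#' @param n_sim Number of simulation replications (>= 1).
#' @param level Confidence level of the interval.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' predictive_interval(0.80, 25000)  # [0.795, 0.805]
#' @export
predictive_interval <- function(pi, n_sim, level = 0.95) {
  stopifnot(pi > 0, pi < 1, n_sim >= 1, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(pi * (1 - pi) / n_sim)
  c(lower = pi - half, upper = pi + half)
}
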