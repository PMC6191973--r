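# Per-subject cost weights. For the one-period parallel design the arm
# weights are a = c_A+c_t+c_sp and b = c_B+c_t+c_sp; for the two-period
# designs each subject is measured twice, giving w_A = 2c_A+2c_t+c_s2p and
# w_B = 2c_B+2c_t+c_s2p for the extended parallel arms and
# w = c_A+c_B+2c_t+c_s2p for a crossover subject (who receives both
# treatments).
cost_weights <- function(costs) {
  list(a = costs$c_A + costs$c_t + costs$c_sp,
       b = costs$c_B + costs$c_t + costs$c_sp,
       wA = 2 * costs$c_A + 2 * costs$c_t + costs$c_s2p,
       wB = 2 * costs$c_B + 2 * costs$c_t + costs$c_s2p,
       w = costs$c_A + costs$c_B + 2 * costs$c_t + costs$c_s2p)
}

#' Budget required by a design
#'
#' Total budget `C*` (including the sequence administration cost, which is
#' identical across the three designs) needed to run `n` subjects with a
#' proportion `p1` allocated to the first-listed sequence (A, AA, or AB).
#'
#' @param design `"parallel"`, `"extended_parallel"`, or `"crossover"`.
#' @param n Total number of subjects (> 0; need not be integer).
#' @param p1 Proportion of subjects in the first sequence, in (0, 1).
#' @param costs A [cost_structure].
#' @return The required budget `C*` in currency units.
#' @examples
#' budget_required("parallel", n = 100, p1 = 0.5, subject_count_costs())
#' @export
budget_required <- function(design, n, p1, costs) {
  design <- match_design(design)
  stopifnot(is.finite(n), n > 0)
  if (any(!is.finite(p1)) || any(p1 <= 0) || any(p1 >= 1)) {
    stop("p1 must lie strictly inside (0, 1)", call. = FALSE)
  }
  cw <- cost_weights(costs)
  2 * costs$c_ts + switch(design,
    parallel = n * (p1 * cw$a + (1 - p1) * cw$b),
    crossover = n * cw$w,
    extended_parallel = n * (p1 * cw$wA + (1 - p1) * cw$wB)
  )
}

# Per-subject cost of a design at allocation proportion p1 (net of the
# sequence administration cost): budget_required == 2*c_ts + n * cost.
cost_per_subject <- function(design, p1, costs) {
  cw <- cost_weights(costs)
  switch(design,
    parallel = p1 * cw$a + (1 - p1) * cw$b,
    crossover = cw$w,
    extended_parallel = p1 * cw$wA + (1 - p1) * cw$wB
  )
}

#' Asymptotic estimator variance at an arbitrary allocation
#'
#' Asymptotic variance of the ML estimator of the treatment effect or the
#' treatment-by-period interaction for a design with `N` subjects of which a
#' proportion `p` is allocated to the first sequence. Vectorized over `p`,
#' `rhoA`, and `rhoB`.
#'
#' @inheritParams budget_required
#' @param effect `"treatment"` or `"treatment_by_period"`.
#' @param p Proportion in the first-listed sequence (A, AA, or AB), in (0, 1).
#' @param rhoA,rhoB Intraclass correlations in (0, 1].
#' @param sigma_y_sq Total outcome variance `sigma_A^2 + sigma_B^2`.
#' @param N Total number of subjects.
#' @return The asymptotic variance of the effect estimator.
#' @examples
#' # equal ICCs, balanced crossover: (1 - rho) * sigma_y^2 / (2 N)
#' variance_at_allocation("crossover", "treatment", p = 0.5,
#'                        rhoA = 0.5, rhoB = 0.5, sigma_y_sq = 1, N = 100)
#' @export
variance_at_allocation <- function(design, effect, p, rhoA, rhoB,
                                   sigma_y_sq = 2, N = 1) {
  de <- check_design_effect(design, effect)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  }
  rho_in_unit(rhoA, "rhoA")
  rho_in_unit(rhoB, "rhoB")
  stopifnot(N > 0, sigma_y_sq > 0)
  s <- rhoA + rhoB
  q <- 1 - p
  if (de$design == "crossover" && de$effect == "treatment") {
    ((rhoA - rhoB)^2 * p * q + rhoA * rhoB * (1 - rhoA * rhoB)) /
      (s * (s + 2 * rhoA * rhoB)) * sigma_y_sq / (q * p * N)
  } else if (de$design == "crossover") {
    (1 + 2 * rhoA * rhoB / s) * sigma_y_sq / (q * p * N)
  } else if (de$design == "parallel") {
    (rhoB / (s * p) + rhoA / (s * q)) * sigma_y_sq / N
  } else if (de$effect == "treatment") {
    (rhoB / (s * p) + rhoA / (s * q) + rhoA * rhoB / (s * p * q)) *
      sigma_y_sq / (2 * N)
  } else {
    (rhoB * (1 - rhoA) / (s * p) + rhoA * (1 - rhoB) / (s * q)) *
      2 * sigma_y_sq / N
  }
}

#' Optimal allocation ratio
#'
#' Ratio `n1 / n2` of subjects in the first-listed sequence (A, AB, or AA)
#' over the second that minimizes the effect estimator's variance under the
#' budget constraint. The crossover ratio is always 1; the parallel and
#' extended parallel ratios shift subjects toward the cheaper and
#' higher-variance (lower-ICC) treatment.
#'
#' @inheritParams variance_at_allocation
#' @param costs A [cost_structure].
#' @return The allocation ratio `n1 / n2` (> 0).
#' @examples
#' optimal_allocation("parallel", "treatment", subject_count_costs(),
#'                    rhoA = 0.1, rhoB = 0.9)  # 3: thrice as many on A
#' @export
optimal_allocation <- function(design, effect, costs, rhoA, rhoB) {
  de <- check_design_effect(design, effect)
  rho_in_unit(rhoA, "rhoA")
  rho_in_unit(rhoB, "rhoB")
  cw <- cost_weights(costs)
  if (de$design == "crossover") {
    return(rep_len(1, max(length(rhoA), length(rhoB))))
  }
  if (de$design == "parallel") {
    return(sqrt(rhoB / rhoA) * sqrt(cw$b / cw$a))
  }
  if (de$effect == "treatment") {
    sqrt(rhoB * (1 + rhoA) / (rhoA * (1 + rhoB))) * sqrt(cw$wB / cw$wA)
  } else {
    if (any(rhoA >= 1) || any(rhoB >= 1)) {
      # the closed ratio divides by (1 - rho); minimize the variance
      # objective directly on the allocation scale
      return(mapply(function(ra, rb) {
        obj <- function(p) {
          variance_at_allocation("extended_parallel", "treatment_by_period",
                                 p, ra, rb, sigma_y_sq = 1,
                                 N = 1 / cost_per_subject("extended_parallel",
                                                          p, costs))
        }
        p <- stats::optimize(obj, c(1e-6, 1 - 1e-6))$minimum
        p / (1 - p)
      }, rhoA, rhoB))
    }
    sqrt(rhoB * (1 - rhoA) / (rhoA * (1 - rhoB))) * sqrt(cw$wB / cw$wA)
  }
}

# Variance of the effect estimator at the optimal allocation, per unit
# sigma_y^2 / C (Table-1 kernels). Vectorized over rhoA, rhoB.
optimal_variance_kernel <- function(design, effect, costs, rhoA, rhoB) {
  cw <- cost_weights(costs)
  s <- rhoA + rhoB
  if (design == "crossover" && effect == "treatment") {
    cw$w * (1 - 2 * rhoA * rhoB / s)
  } else if (design == "crossover") {
    4 * cw$w * (1 + 2 * rhoA * rhoB / s)
  } else if (design == "parallel") {
    (sqrt(cw$a * rhoB / s) + sqrt(cw$b * rhoA / s))^2
  } else if (effect == "treatment") {
    (sqrt(cw$wA * rhoB * (1 + rhoA) / s) +
       sqrt(cw$wB * rhoA * (1 + rhoB) / s))^2 / 2
  } else {
    2 * (sqrt(cw$wA * rhoB * (1 - rhoA) / s) +
           sqrt(cw$wB * rhoA * (1 - rhoB) / s))^2
  }
}

#' Minimal (optimal-allocation) variance under a budget
#'
#' Asymptotic variance of the effect estimator when the net budget `C` is
#' spent at the optimal allocation ratio. Equals [variance_at_allocation]
#' evaluated at the optimal proportion with the sample size implied by the
#' budget. Vectorized over `rhoA` and `rhoB`.
#'
#' @inheritParams optimal_allocation
#' @param sigma_y_sq Total outcome variance `sigma_A^2 + sigma_B^2`.
#' @param C Net budget `C = C* - 2 c_ts` (> 0).
#' @return The optimal variance of the effect estimator.
#' @examples
#' optimal_variance("crossover", "treatment", subject_count_costs(),
#'                  rhoA = 0.7, rhoB = 0.7, sigma_y_sq = 1, C = 1)  # 0.3
#' @export
optimal_variance <- function(design, effect, costs, rhoA, rhoB,
                             sigma_y_sq = 2, C = 1) {
  de <- check_design_effect(design, effect)
  rho_in_unit(rhoA, "rhoA")
  rho_in_unit(rhoB, "rhoB")
  if (!is.finite(C) || C <= 0) stop("net budget C must be > 0", call. = FALSE)
  stopifnot(sigma_y_sq > 0)
  optimal_variance_kernel(de$design, de$effect, costs, rhoA, rhoB) *
    sigma_y_sq / C
}

#' Design solution at stated intraclass correlations
#'
#' Bundles the optimal allocation and variance for one design, effect, and
#' ICC pair into a `design_solution` record.
#'
#' @inheritParams optimal_variance
#' @param branch Label recording how the ICC pair was chosen (for maximin
#'   solutions, the case of the decision cascade).
#' @return An object of class `design_solution` with fields `design`,
#'   `effect`, `allocation_ratio`, `p1`, `variance`, `rho_at`, `branch`.
#' @export
design_solution <- function(design, effect, costs, rhoA, rhoB,
                            sigma_y_sq = 2, C = 1, branch = "optimal") {
  de <- check_design_effect(design, effect)
  ratio <- optimal_allocation(de$design, de$effect, costs, rhoA, rhoB)
  structure(list(design = de$design, effect = de$effect,
                 allocation_ratio = ratio, p1 = ratio / (1 + ratio),
                 variance = optimal_variance(de$design, de$effect, costs,
                                             rhoA, rhoB, sigma_y_sq, C),
                 rho_at = c(rhoA = rhoA, rhoB = rhoB),
                 sigma_y_sq = sigma_y_sq, C = C, branch = branch),
            class = "design_solution")
}

#' @export
print.design_solution <- function(x, ...) {
  cat(sprintf("%s design, %s effect [%s]\n", x$design, x$effect, x$branch))
  cat(sprintf("  evaluated at rho_A=%.4f, rho_B=%.4f\n",
              x$rho_at["rhoA"], x$rho_at["rhoB"]))
  cat(sprintf("  allocation n1/n2 = %.4f (p1 = %.4f)\n",
              x$allocation_ratio, x$p1))
  cat(sprintf("  Var(effect estimator) = %.6g  (sigma_y^2=%g, C=%g)\n",
              x$variance, x$sigma_y_sq, x$C))
  invisible(x)
}
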