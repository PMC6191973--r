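# Decision cascades selecting the variance-maximizing ICC pair over a
# rectangle of plausible intraclass correlations, one per design/effect.
# Each returns list(rhoA, rhoB, branch). The cascade answer is cross-checked
# in maximin_params() against a direct arg-max over the candidate set
# (rectangle corners plus feasible edge stationary points), which is the
# authoritative value.

maximin_cascade_parallel <- function(costs, rect) {
  cw <- cost_weights(costs)
  phi_star <- cw$a / cw$b
  lo <- rect$rhoB_low / rect$rhoA_high
  hi <- rect$rhoB_high / rect$rhoA_low
  if (phi_star >= lo && phi_star <= hi) {
    rhoB <- min(rect$rhoB_high, phi_star * rect$rhoA_high)
    list(rhoA = rhoB / phi_star, rhoB = rhoB,
         branch = "interior variance-ratio locus")
  } else if (phi_star > hi) {
    list(rhoA = rect$rhoA_low, rhoB = rect$rhoB_high,
         branch = "corner (rhoA_low, rhoB_high)")
  } else {
    list(rhoA = rect$rhoA_high, rhoB = rect$rhoB_low,
         branch = "corner (rhoA_high, rhoB_low)")
  }
}

maximin_cascade_ep_treatment <- function(costs, rect) {
  cw <- cost_weights(costs)
  lambda <- cw$wA / cw$wB
  rAU <- rect$rhoA_high; rAL <- rect$rhoA_low
  rBU <- rect$rhoB_high; rBL <- rect$rhoB_low
  g1 <- lambda * (1 - rBU)^2 / ((1 + rBU) * rBU)
  g2 <- (1 - rAU)^2 / (lambda * (1 + rAU) * rAU)
  if (1 / rAU + 1 <= g1 && g1 <= 1 / rAL + 1) {
    rhoA <- rBU * (1 + rBU) / (lambda * (1 - rBU)^2 - rBU * (1 + rBU))
    list(rhoA = rhoA, rhoB = rBU, branch = "edge stationary at rhoB_high")
  } else if (1 / rBU + 1 <= g2 && g2 <= 1 / rBL + 1) {
    rhoB <- lambda * rAU * (1 + rAU) / ((1 - rAU)^2 - lambda * rAU * (1 + rAU))
    list(rhoA = rAU, rhoB = rhoB, branch = "edge stationary at rhoA_high")
  } else if (g1 < 1 / rAU + 1 && g2 < 1 / rBU + 1) {
    list(rhoA = rAU, rhoB = rBU, branch = "corner (rhoA_high, rhoB_high)")
  } else if (g1 < 1 / rAU + 1) {
    list(rhoA = rAU, rhoB = rBL, branch = "corner (rhoA_high, rhoB_low)")
  } else {
    list(rhoA = rAL, rhoB = rBU, branch = "corner (rhoA_low, rhoB_high)")
  }
}

maximin_cascade_ep_interaction <- function(costs, rect) {
  cw <- cost_weights(costs)
  lambda <- cw$wA / cw$wB
  rAU <- rect$rhoA_high; rAL <- rect$rhoA_low
  rBU <- rect$rhoB_high; rBL <- rect$rhoB_low
  h1 <- lambda * (1 + rBL)^2 / ((1 - rBL) * rBL)
  h2 <- (1 + rAL)^2 / (lambda * (1 - rAL) * rAL)
  if (is.finite(h1) && 1 / rAU - 1 <= h1 && h1 <= 1 / rAL - 1) {
    rhoA <- rBL * (1 - rBL) / (lambda * (1 + rBL)^2 + rBL * (1 - rBL))
    list(rhoA = rhoA, rhoB = rBL, branch = "edge stationary at rhoB_low")
  } else if (is.finite(h2) && 1 / rBU - 1 <= h2 && h2 <= 1 / rBL - 1) {
    rhoB <- lambda * rAL * (1 - rAL) / ((1 + rAL)^2 + lambda * rAL * (1 - rAL))
    list(rhoA = rAL, rhoB = rhoB, branch = "edge stationary at rhoA_low")
  } else if (h1 > 1 / rAL - 1 && h2 > 1 / rBL - 1) {
    list(rhoA = rAL, rhoB = rBL, branch = "corner (rhoA_low, rhoB_low)")
  } else if (h1 < 1 / rAU - 1) {
    list(rhoA = rAU, rhoB = rBL, branch = "corner (rhoA_high, rhoB_low)")
  } else {
    list(rhoA = rAL, rhoB = rBU, branch = "corner (rhoA_low, rhoB_high)")
  }
}

maximin_cascade <- function(design, effect, costs, rect) {
  if (design == "crossover") {
    if (effect == "treatment") {
      list(rhoA = rect$rhoA_low, rhoB = rect$rhoB_low,
           branch = "corner (rhoA_low, rhoB_low)")
    } else {
      list(rhoA = rect$rhoA_high, rhoB = rect$rhoB_high,
           branch = "corner (rhoA_high, rhoB_high)")
    }
  } else if (design == "parallel") {
    maximin_cascade_parallel(costs, rect)
  } else if (effect == "treatment") {
    maximin_cascade_ep_treatment(costs, rect)
  } else {
    maximin_cascade_ep_interaction(costs, rect)
  }
}

# Candidate ICC pairs at which the variance over the rectangle can attain
# its maximum: the four corners, plus (extended parallel) the stationary
# points of the optimal-variance profile along each rectangle edge, plus
# (parallel) a representative of the variance-ratio locus when it crosses
# the rectangle.
maximin_candidates <- function(design, effect, costs, rect) {
  cw <- cost_weights(costs)
  cand <- rbind(c(rect$rhoA_low, rect$rhoB_low),
                c(rect$rhoA_low, rect$rhoB_high),
                c(rect$rhoA_high, rect$rhoB_low),
                c(rect$rhoA_high, rect$rhoB_high))
  clamp_add <- function(rhoA, rhoB) {
    ok <- is.finite(rhoA) & is.finite(rhoB) &
      rhoA >= rect$rhoA_low & rhoA <= rect$rhoA_high &
      rhoB >= rect$rhoB_low & rhoB <= rect$rhoB_high
    if (any(ok)) cand <<- rbind(cand, cbind(rhoA[ok], rhoB[ok]))
  }
  if (design == "parallel") {
    phi_star <- cw$a / cw$b
    rhoB <- min(rect$rhoB_high, phi_star * rect$rhoA_high)
    clamp_add(rhoB / phi_star, rhoB)
  } else if (design == "extended_parallel") {
    lambda <- cw$wA / cw$wB
    edgeB <- c(rect$rhoB_low, rect$rhoB_high)
    edgeA <- c(rect$rhoA_low, rect$rhoA_high)
    if (effect == "treatment") {
      clamp_add(edgeB * (1 + edgeB) /
                  (lambda * (1 - edgeB)^2 - edgeB * (1 + edgeB)), edgeB)
      clamp_add(edgeA, lambda * edgeA * (1 + edgeA) /
                  ((1 - edgeA)^2 - lambda * edgeA * (1 + edgeA)))
    } else {
      clamp_add(edgeB * (1 - edgeB) /
                  (lambda * (1 + edgeB)^2 + edgeB * (1 - edgeB)), edgeB)
      clamp_add(edgeA, lambda * edgeA * (1 - edgeA) /
                  ((1 + edgeA)^2 + lambda * edgeA * (1 - edgeA)))
    }
  }
  cand
}

#' Maximin design over a rectangle of intraclass correlations
#'
#' Finds the intraclass-correlation pair inside the plausible rectangle at
#' which the optimal-allocation variance of the effect estimator is largest,
#' together with that worst-case (maximin) variance and the corresponding
#' allocation. Planning a trial at the maximin pair guarantees the target
#' power for every ICC pair in the rectangle at the lowest budget.
#'
#' The closed-form decision cascade is evaluated alongside a direct arg-max
#' over the candidate set (rectangle corners and feasible edge stationary
#' points); the candidate arg-max is authoritative and a disagreement beyond
#' numerical tolerance raises a warning.
#'
#' @inheritParams optimal_variance
#' @param rect An [icc_rect] of plausible ICC ranges.
#' @return An object of class `maximin_design`: a [design_solution] whose
#'   `rho_at` is the maximin pair and whose `branch` names the cascade case.
#' @examples
#' maximin_params("crossover", "treatment", subject_count_costs(),
#'                icc_rect(0.10, 0.70, 0.30, 0.90))
#' @export
maximin_params <- function(design, effect, costs, rect, sigma_y_sq = 2,
                           C = 1) {
  de <- check_design_effect(design, effect)
  stopifnot(inherits(rect, "icc_rect"))
  if (is_point_rect(rect)) {
    sol <- design_solution(de$design, de$effect, costs, rect$rhoA_low,
                           rect$rhoB_low, sigma_y_sq, C,
                           branch = "degenerate (point rectangle)")
    class(sol) <- c("maximin_design", class(sol))
    sol$rect <- rect
    return(sol)
  }
  casc <- maximin_cascade(de$design, de$effect, costs, rect)
  cand <- maximin_candidates(de$design, de$effect, costs, rect)
  v_cand <- optimal_variance_kernel(de$design, de$effect, costs,
                                    cand[, 1], cand[, 2])
  best <- which.max(v_cand)
  v_casc <- optimal_variance_kernel(de$design, de$effect, costs,
                                    casc$rhoA, casc$rhoB)
  branch <- casc$branch
  rhoA <- casc$rhoA; rhoB <- casc$rhoB
  if (!is.finite(v_casc) || v_cand[best] > v_casc * (1 + 1e-9)) {
    warning("maximin cascade disagrees with candidate-set arg-max; ",
            "using the candidate-set solution", call. = FALSE)
    rhoA <- cand[best, 1]; rhoB <- cand[best, 2]
    branch <- "candidate-set arg-max"
  }
  sol <- design_solution(de$design, de$effect, costs, rhoA, rhoB,
                         sigma_y_sq, C, branch = branch)
  class(sol) <- c("maximin_design", class(sol))
  sol$rect <- rect
  sol
}

#' Grid-search oracle for the maximin design
#'
#' Brute-force arg-max of the optimal-allocation variance over a regular
#' grid on the ICC rectangle. Serves as an independent check of the
#' closed-form [maximin_params]; the two agree to within one grid cell in
#' the maximin pair and to fine tolerance in the maximin variance.
#'
#' @inheritParams maximin_params
#' @param grid_resolution Number of grid points per axis (>= 2; default 201
#'   resolves the maximin pair to better than 0.005 on a unit range).
#' @return A `maximin_design` object with branch `"grid"`.
#' @export
maximin_grid_oracle <- function(design, effect, costs, rect,
                                sigma_y_sq = 2, C = 1,
                                grid_resolution = 201) {
  de <- check_design_effect(design, effect)
  stopifnot(inherits(rect, "icc_rect"), grid_resolution >= 2)
  gA <- seq(rect$rhoA_low, rect$rhoA_high, length.out = grid_resolution)
  gB <- seq(rect$rhoB_low, rect$rhoB_high, length.out = grid_resolution)
  if (rect$rhoA_low == rect$rhoA_high) gA <- rect$rhoA_low
  if (rect$rhoB_low == rect$rhoB_high) gB <- rect$rhoB_low
  rhoA <- rep(gA, times = length(gB))
  rhoB <- rep(gB, each = length(gA))
  v <- optimal_variance_kernel(de$design, de$effect, costs, rhoA, rhoB)
  best <- which.max(v)
  sol <- design_solution(de$design, de$effect, costs, rhoA[best], rhoB[best],
                         sigma_y_sq, C, branch = "grid")
  class(sol) <- c("maximin_design", class(sol))
  sol$rect <- rect
  sol
}

#' @export
print.maximin_design <- function(x, ...) {
  cat(sprintf("Maximin %s design, %s effect\n", x$design, x$effect))
  cat(sprintf("  ICC rectangle: rho_A in [%g, %g], rho_B in [%g, %g]\n",
              x$rect$rhoA_low, x$rect$rhoA_high,
              x$rect$rhoB_low, x$rect$rhoB_high))
  cat(sprintf("  maximin pair: rho_A* = %.4f, rho_B* = %.4f  [%s]\n",
              x$rho_at["rhoA"], x$rho_at["rhoB"], x$branch))
  cat(sprintf("  allocation n1/n2 = %.4f (p1 = %.4f)\n",
              x$allocation_ratio, x$p1))
  cat(sprintf("  maximin variance = %.6g  (sigma_y^2=%g, C=%g)\n",
              x$variance, x$sigma_y_sq, x$C))
  invisible(x)
}

#' Relative efficiency of competing design solutions
#'
#' For a set of solutions sharing the effect of interest, the budget, and
#' the outcome-variance scale, each design's asymptotic efficiency relative
#' to the most efficient design: the smallest variance among the solutions
#' divided by the design's own variance. The most efficient design scores 1
#' (ties are co-best); the score is also the fraction of the design's budget
#' (e.g. subjects) that the best design would need.
#'
#' @param solutions A list of [design_solution] / `maximin_design` objects.
#' @return A named numeric vector of efficiencies in (0, 1].
#' @export
relative_efficiency <- function(solutions) {
  stopifnot(length(solutions) >= 1,
            all(vapply(solutions, inherits, TRUE, "design_solution")))
  effects <- vapply(solutions, `[[`, "", "effect")
  if (length(unique(effects)) != 1) {
    stop("all solutions must target the same effect", call. = FALSE)
  }
  scales <- vapply(solutions, function(s) s$sigma_y_sq / s$C, 0)
  if (length(unique(scales)) != 1) {
    stop("all solutions must share sigma_y_sq and the budget C",
         call. = FALSE)
  }
  v <- vapply(solutions, `[[`, 0, "variance")
  out <- min(v) / v
  names(out) <- vapply(solutions, `[[`, "", "design")
  out
}

#' Numerical evaluation grid of maximin designs
#'
#' Sweeps cost-ratio scenarios and ICC-range pairs, computing each design's
#' maximin variance and flagging the most efficient design per scenario.
#' Cost ratios are `CR_A = (c_A + c_t) / c_sp`, `CR_B = (c_B + c_t) / c_sp`,
#' and `CR_p = c_s2p / c_sp` (relative maximin efficiencies depend on the
#' costs only through these ratios). ICC ranges are generated as
#' `[lower, lower + width]` for each width, with lower bounds
#' 0.01, 0.05, 0.10, 0.15, ... capped so the range stays within (0, 1].
#'
#' @param effect `"treatment"` or `"treatment_by_period"` (for the latter
#'   only the crossover and extended parallel designs apply).
#' @param cr_A,cr_B Cost-ratio values for the two treatments.
#' @param cr_p Ratio of two-period to one-period subject-specific costs.
#' @param widths Widths of the ICC ranges.
#' @param max_lower Largest lower bound considered before capping.
#' @return A data frame with one row per scenario: the cost ratios, the two
#'   ICC ranges, each design's maximin variance (per `sigma_y^2 / C`), and
#'   `best`, the most efficient design(s) (ties joined with `"+"`).
#' @examples
#' g <- evaluation_grid("treatment", cr_A = 1, cr_B = 1, cr_p = 1,
#'                      widths = 0.3)
#' table(g$best)
#' @export
evaluation_grid <- function(effect = "treatment",
                            cr_A = c(100, 20, 10, 1, 0.1, 0.05, 0.01),
                            cr_B = c(100, 20, 10, 1, 0.1, 0.05, 0.01),
                            cr_p = c(1, 2),
                            widths = c(0.10, 0.30, 0.60),
                            max_lower = 0.95) {
  effect <- match_effect(effect)
  designs <- if (effect == "treatment") DESIGNS else
    c("extended_parallel", "crossover")
  ranges <- do.call(rbind, lapply(widths, function(w) {
    lo <- c(0.01, 0.05, seq(0.10, max_lower, by = 0.05))
    lo <- lo[lo + w <= 1 + 1e-12]
    data.frame(low = lo, high = pmin(lo + w, 1), width = w)
  }))
  grid <- expand.grid(CR_A = cr_A, CR_B = cr_B, CR_p = cr_p,
                      iA = seq_len(nrow(ranges)), iB = seq_len(nrow(ranges)),
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    costs <- cost_structure(c_A = g$CR_A, c_B = g$CR_B, c_t = 0, c_sp = 1,
                            c_s2p = g$CR_p)
    rect <- icc_rect(ranges$low[g$iA], ranges$high[g$iA],
                     ranges$low[g$iB], ranges$high[g$iB])
    v <- vapply(designs, function(d) {
      maximin_params(d, effect, costs, rect, sigma_y_sq = 1, C = 1)$variance
    }, 0)
    best <- designs[v <= min(v) * (1 + 1e-9)]
    data.frame(CR_A = g$CR_A, CR_B = g$CR_B, CR_p = g$CR_p,
               rhoA_low = ranges$low[g$iA], rhoA_high = ranges$high[g$iA],
               rhoB_low = ranges$low[g$iB], rhoB_high = ranges$high[g$iB],
               t(v), best = paste(best, collapse = "+"))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
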