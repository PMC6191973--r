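#' @keywords internal
"_PACKAGE"

DESIGNS <- c("parallel", "extended_parallel", "crossover")
EFFECTS <- c("treatment", "treatment_by_period")

match_design <- function(design) {
  match.arg(design, DESIGNS)
}

match_effect <- function(effect) {
  match.arg(effect, EFFECTS)
}

#' Validate a design/effect combination
#'
#' The treatment-by-period interaction requires two measurement periods and
#' is therefore unavailable for the single-period parallel design.
#'
#' @param design One of `"parallel"`, `"extended_parallel"`, `"crossover"`.
#' @param effect One of `"treatment"`, `"treatment_by_period"`.
#' @return Invisibly, a list with the matched `design` and `effect`.
#' @export
check_design_effect <- function(design, effect) {
  design <- match_design(design)
  effect <- match_effect(effect)
  if (design == "parallel" && effect == "treatment_by_period") {
    stop("the treatment-by-period interaction is not estimable in a ",
         "single-period parallel design", call. = FALSE)
  }
  invisible(list(design = design, effect = effect))
}

#' Cost structure of a two-treatment trial
#'
#' Bundles the monetary components of the budget constraint: per-subject
#' treatment costs, a per-measurement cost, subject-specific costs (e.g.
#' recruitment or participation fees) which may differ between one-period
#' and two-period designs, and an administration cost per treatment sequence.
#'
#' @param c_A Cost of administering treatment A to one subject (>= 0).
#' @param c_B Cost of administering treatment B to one subject (>= 0).
#' @param c_t Cost of one measurement (>= 0).
#' @param c_sp Subject-specific cost in the parallel design (>= 0).
#' @param c_s2p Subject-specific cost in the two-period designs (AA/BB and
#'   AB/BA); typically `c_sp <= c_s2p <= 2 * c_sp` (a warning is issued
#'   outside that band, but values are accepted).
#' @param c_ts Administration cost per treatment sequence (>= 0).
#' @return An object of class `cost_structure`.
#' @examples
#' subject_count_costs()            # budget counts subjects
#' cost_structure(c_A = 2, c_B = 1, c_t = 1, c_sp = 1, c_s2p = 2)
#' @export
cost_structure <- function(c_A = 0, c_B = 0, c_t = 0, c_sp = 1,
                           c_s2p = c_sp, c_ts = 0) {
  comp <- c(c_A = c_A, c_B = c_B, c_t = c_t, c_sp = c_sp,
            c_s2p = c_s2p, c_ts = c_ts)
  if (any(!is.finite(comp)) || any(comp < 0)) {
    stop("all cost components must be finite and >= 0", call. = FALSE)
  }
  # every design arm must carry positive per-subject cost, else a budget
  # constraint places no limit on the sample size
  if (c_A + c_t + c_sp <= 0 || c_B + c_t + c_sp <= 0) {
    stop("per-subject cost of a parallel-design arm is zero", call. = FALSE)
  }
  if (c_A + c_B + 2 * c_t + c_s2p <= 0) {
    stop("per-subject cost of the crossover design is zero", call. = FALSE)
  }
  if (2 * c_A + 2 * c_t + c_s2p <= 0 || 2 * c_B + 2 * c_t + c_s2p <= 0) {
    stop("per-subject cost of an extended-parallel arm is zero", call. = FALSE)
  }
  if (c_s2p < c_sp || c_s2p > 2 * c_sp) {
    warning("subject-specific costs usually satisfy c_sp <= c_s2p <= 2*c_sp",
            call. = FALSE)
  }
  structure(as.list(comp), class = "cost_structure")
}

#' Subject-count and measurement-count budgets
#'
#' Convenience cost structures under which the budget is simply the total
#' number of subjects (`subject_count_costs()`: unit subject-specific costs,
#' all else zero) or the total number of measurements
#' (`measurement_count_costs()`: unit measurement cost, all else zero).
#'
#' @return A `cost_structure`.
#' @rdname subject_count_costs
#' @export
subject_count_costs <- function() {
  cost_structure(c_A = 0, c_B = 0, c_t = 0, c_sp = 1, c_s2p = 1, c_ts = 0)
}

#' @rdname subject_count_costs
#' @export
measurement_count_costs <- function() {
  cost_structure(c_A = 0, c_B = 0, c_t = 1, c_sp = 0, c_s2p = 0, c_ts = 0)
}

#' @export
print.cost_structure <- function(x, ...) {
  cat("Trial cost structure (currency units)\n")
  cat(sprintf("  treatment A / subject : %g\n", x$c_A))
  cat(sprintf("  treatment B / subject : %g\n", x$c_B))
  cat(sprintf("  measurement           : %g\n", x$c_t))
  cat(sprintf("  subject (1-period)    : %g\n", x$c_sp))
  cat(sprintf("  subject (2-period)    : %g\n", x$c_s2p))
  cat(sprintf("  sequence admin        : %g\n", x$c_ts))
  invisible(x)
}

#' Plausible ranges for the two intraclass correlations
#'
#' The rectangle `[rhoA_low, rhoA_high] x [rhoB_low, rhoB_high]` over which a
#' maximin design guards the power guarantee. Degenerate (point) rectangles
#' are allowed, in which case the maximin design reduces to the locally
#' optimal design at that point. A zero intraclass correlation is excluded
#' (the design formulas divide by the correlations); 1 is allowed and
#' corresponds to zero within-subject error.
#'
#' @param rhoA_low,rhoA_high Range for the intraclass correlation under
#'   treatment A, `0 < low <= high <= 1`.
#' @param rhoB_low,rhoB_high Range for treatment B.
#' @return An object of class `icc_rect`.
#' @examples
#' icc_rect(0.10, 0.70, 0.30, 0.90)
#' icc_rect(0.5, 0.5, 0.5, 0.5)  # point rectangle
#' @export
icc_rect <- function(rhoA_low, rhoA_high = rhoA_low,
                     rhoB_low = rhoA_low, rhoB_high = rhoB_low) {
  b <- c(rhoA_low = rhoA_low, rhoA_high = rhoA_high,
         rhoB_low = rhoB_low, rhoB_high = rhoB_high)
  if (any(!is.finite(b))) stop("ICC bounds must be finite", call. = FALSE)
  if (rhoA_low <= 0 || rhoB_low <= 0) {
    stop("intraclass correlations must be > 0", call. = FALSE)
  }
  if (rhoA_high > 1 || rhoB_high > 1) {
    stop("intraclass correlations cannot exceed 1", call. = FALSE)
  }
  if (rhoA_low > rhoA_high || rhoB_low > rhoB_high) {
    stop("lower ICC bound exceeds upper bound", call. = FALSE)
  }
  structure(as.list(b), class = "icc_rect")
}

is_point_rect <- function(rect) {
  rect$rhoA_low == rect$rhoA_high && rect$rhoB_low == rect$rhoB_high
}

#' @export
print.icc_rect <- function(x, ...) {
  cat(sprintf("ICC ranges: rho_A in [%g, %g], rho_B in [%g, %g]\n",
              x$rhoA_low, x$rhoA_high, x$rhoB_low, x$rhoB_high))
  invisible(x)
}

#' Parameters of the heteroscedastic mixed model
#'
#' Fixed effects and variance components of the linear mixed model that
#' generates two-treatment trial data: a shared between-subject random
#' intercept with variance `sigma0_sq` and treatment-specific within-subject
#' error variances `sigmaEpsA_sq`, `sigmaEpsB_sq`. The total outcome
#' variances are `sigma_A^2 = sigma0^2 + sigmaEpsA^2` (and analogously for
#' B), giving intraclass correlations `rho_A = sigma0^2 / sigma_A^2`,
#' `rho_B = sigma0^2 / sigma_B^2`.
#'
#' @param beta0 Intercept.
#' @param beta_treat Treatment effect (difference B - A at period 0).
#' @param beta_time Period effect.
#' @param beta_interaction Treatment-by-period interaction effect.
#' @param sigma0_sq Between-subject variance (>= 0).
#' @param sigmaEpsA_sq Within-subject error variance under treatment A (>= 0).
#' @param sigmaEpsB_sq Within-subject error variance under treatment B (>= 0).
#' @return An object of class `model_params` with derived fields
#'   `sigmaA_sq`, `sigmaB_sq`, `rhoA`, `rhoB`.
#' @export
model_params <- function(beta0 = 0, beta_treat = 0, beta_time = 0,
                         beta_interaction = 0, sigma0_sq, sigmaEpsA_sq,
                         sigmaEpsB_sq) {
  v <- c(sigma0_sq, sigmaEpsA_sq, sigmaEpsB_sq)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("variance components must be finite and >= 0", call. = FALSE)
  }
  sigmaA_sq <- sigma0_sq + sigmaEpsA_sq
  sigmaB_sq <- sigma0_sq + sigmaEpsB_sq
  if (sigmaA_sq <= 0 || sigmaB_sq <= 0) {
    stop("total outcome variance under each treatment must be > 0",
         call. = FALSE)
  }
  structure(list(beta0 = beta0, beta_treat = beta_treat,
                 beta_time = beta_time, beta_interaction = beta_interaction,
                 sigma0_sq = sigma0_sq, sigmaEpsA_sq = sigmaEpsA_sq,
                 sigmaEpsB_sq = sigmaEpsB_sq, sigmaA_sq = sigmaA_sq,
                 sigmaB_sq = sigmaB_sq, rhoA = sigma0_sq / sigmaA_sq,
                 rhoB = sigma0_sq / sigmaB_sq),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Heteroscedastic mixed-model parameters\n")
  cat(sprintf("  fixed effects: beta0=%g, treat=%g, time=%g, treat:time=%g\n",
              x$beta0, x$beta_treat, x$beta_time, x$beta_interaction))
  cat(sprintf("  variances: sigma0^2=%g, sigma_epsA^2=%g, sigma_epsB^2=%g\n",
              x$sigma0_sq, x$sigmaEpsA_sq, x$sigmaEpsB_sq))
  cat(sprintf("  ICCs: rho_A=%.4f, rho_B=%.4f (phi=%.4f)\n",
              x$rhoA, x$rhoB, x$sigmaA_sq / x$sigmaB_sq))
  invisible(x)
}

#' Power specification for sample-size planning
#'
#' @param ES Standardized effect size, the effect of interest divided by
#'   `sqrt(0.5 * (sigma_A^2 + sigma_B^2))`; must be nonzero (sign is
#'   ignored, planning is two-tailed).
#' @param alpha Two-tailed type-I error rate, in (0, 1).
#' @param power Target power, in (0, 1).
#' @return An object of class `power_spec`.
#' @examples
#' power_spec(ES = 0.5, alpha = 0.05, power = 0.80)
#' @export
power_spec <- function(ES, alpha = 0.05, power = 0.80) {
  if (!is.finite(ES) || ES == 0) stop("ES must be nonzero", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(power) || power <= 0 || power >= 1) {
    stop("power must lie in (0, 1)", call. = FALSE)
  }
  structure(list(ES = abs(ES), alpha = alpha, power = power),
            class = "power_spec")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf("Power specification: ES=%g, alpha=%g (two-tailed), power=%g\n",
              x$ES, x$alpha, x$power))
  invisible(x)
}

# Round half away from zero (commercial rounding), the convention used for
# reported whole-percent efficiencies; base round() is half-to-even.
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  # the small epsilon keeps exact halves (e.g. 42.5%) from rounding down
  # through binary representation error
  sign(x) * floor(abs(x) * pow + 0.5 + 1e-9) / pow
}

rho_in_unit <- function(rho, name) {
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho > 1)) {
    stop(name, " must lie in (0, 1]", call. = FALSE)
  }
  invisible(rho)
}
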