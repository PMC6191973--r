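#' Variance components implied by a pair of intraclass correlations
#'
#' Given the intraclass correlations under the two treatments and the total
#' outcome variance `sigma_y_sq = sigma_A^2 + sigma_B^2`, recovers the
#' variance components of the mixed model under the common-intercept
#' assumption: `sigma_A^2 = sigma_y^2 rho_B / (rho_A + rho_B)`,
#' `sigma_B^2 = sigma_y^2 rho_A / (rho_A + rho_B)`, and
#' `sigma_0^2 = sigma_y^2 rho_A rho_B / (rho_A + rho_B)`. The mapping is
#' the inverse of `rho = sigma_0^2 / (sigma_0^2 + sigma_eps^2)`.
#'
#' @param rhoA,rhoB Intraclass correlations in (0, 1].
#' @param sigma_y_sq Total outcome variance `sigma_A^2 + sigma_B^2` (> 0);
#'   defaults to 2, under which the standardized effect size equals the raw
#'   effect.
#' @return A list with `sigma0_sq`, `sigmaEpsA_sq`, `sigmaEpsB_sq`,
#'   `sigmaA_sq`, `sigmaB_sq`.
#' @examples
#' icc_to_variance_components(0.1, 0.9, sigma_y_sq = 1)
#' @export
icc_to_variance_components <- function(rhoA, rhoB, sigma_y_sq = 2) {
  rho_in_unit(rhoA, "rhoA")
  rho_in_unit(rhoB, "rhoB")
  if (!is.finite(sigma_y_sq) || sigma_y_sq <= 0) {
    stop("sigma_y_sq must be > 0", call. = FALSE)
  }
  s <- rhoA + rhoB
  sigmaA_sq <- sigma_y_sq * rhoB / s
  sigmaB_sq <- sigma_y_sq * rhoA / s
  sigma0_sq <- sigma_y_sq * rhoA * rhoB / s
  list(sigma0_sq = sigma0_sq,
       sigmaEpsA_sq = sigmaA_sq - sigma0_sq,
       sigmaEpsB_sq = sigmaB_sq - sigma0_sq,
       sigmaA_sq = sigmaA_sq,
       sigmaB_sq = sigmaB_sq)
}

#' Ratio of total outcome variances
#'
#' The variance ratio `phi = sigma_A^2 / sigma_B^2` equals `rho_B / rho_A`
#' under the shared between-subject variance assumption.
#'
#' @inheritParams icc_to_variance_components
#' @return `phi = rhoB / rhoA`.
#' @export
variance_ratio <- function(rhoA, rhoB) {
  rho_in_unit(rhoA, "rhoA")
  rho_in_unit(rhoB, "rhoB")
  rhoB / rhoA
}

#' Raw effect implied by a standardized effect size
#'
#' Inverts `ES = beta / sqrt(0.5 * sigma_y_sq)`.
#'
#' @param ES Standardized effect size.
#' @param sigma_y_sq Total outcome variance `sigma_A^2 + sigma_B^2` (> 0).
#' @return The raw regression effect `beta = ES * sqrt(sigma_y_sq / 2)`.
#' @export
beta_from_effect_size <- function(ES, sigma_y_sq = 2) {
  if (!is.finite(sigma_y_sq) || sigma_y_sq <= 0) {
    stop("sigma_y_sq must be > 0", call. = FALSE)
  }
  ES * sqrt(sigma_y_sq / 2)
}

#' Model parameters for a design scenario
#'
#' Builds generating `model_params` at given intraclass correlations, with
#' the effect of interest set from a standardized effect size and all other
#' fixed effects zero.
#'
#' @inheritParams icc_to_variance_components
#' @param ES Standardized effect size of the effect of interest.
#' @param effect Which fixed effect carries `ES`: `"treatment"` or
#'   `"treatment_by_period"`.
#' @return A `model_params` object.
#' @export
params_from_icc <- function(rhoA, rhoB, ES = 0, effect = "treatment",
                            sigma_y_sq = 2) {
  effect <- match_effect(effect)
  vc <- icc_to_variance_components(rhoA, rhoB, sigma_y_sq)
  beta <- beta_from_effect_size(ES, sigma_y_sq)
  model_params(
    beta_treat = if (effect == "treatment") beta else 0,
    beta_interaction = if (effect == "treatment_by_period") beta else 0,
    sigma0_sq = vc$sigma0_sq,
    sigmaEpsA_sq = vc$sigmaEpsA_sq,
    sigmaEpsB_sq = vc$sigmaEpsB_sq
  )
}
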