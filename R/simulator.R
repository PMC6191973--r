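design_sequences <- function(design) {
  switch(design,
    parallel = list(c("A"), c("B")),
    extended_parallel = list(c("A", "A"), c("B", "B")),
    crossover = list(c("A", "B"), c("B", "A"))
  )
}

#' Simulate one trial under the heteroscedastic mixed model
#'
#' Generates outcomes `y = beta0 + beta_treat * treat + beta_time * time +
#' beta_interaction * treat * time + u0_j + eps_ij`, with a subject-shared
#' random intercept `u0_j ~ N(0, sigma0^2)` and within-subject errors drawn
#' with variance `sigmaEpsA^2` under treatment A and `sigmaEpsB^2` under B.
#' The parallel design has one measurement per subject (the intercept and
#' error then merge into the treatment-specific total variance); the
#' two-period designs have measurements at periods 0 and 1 following the
#' design's treatment sequences.
#'
#' @inheritParams budget_required
#' @param n1 Subjects in the first sequence (A, AA, or AB); >= 2.
#' @param n2 Subjects in the second sequence (B, BB, or BA); >= 2.
#' @param params A [model_params].
#' @param seed Optional integer seed for reproducibility.
#' @return A `trial_data` data frame with columns `subject_id`, `period`
#'   (0/1), `treatment` (0 = A, 1 = B), `y`, plus attributes `design`,
#'   `n1`, `n2`.
#' @examples
#' simulate_trial("crossover", 5, 5,
#'                params_from_icc(0.7, 0.7, ES = 0.8), seed = 1)
#' @export
simulate_trial <- function(design, n1, n2, params, seed = NULL) {
  design <- match_design(design)
  stopifnot(inherits(params, "model_params"), n1 >= 2, n2 >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  seqs <- design_sequences(design)
  n_per <- length(seqs[[1]])
  arm <- rep(c(1L, 2L), c(n1, n2))
  subject_id <- rep(seq_len(n), each = n_per)
  period <- rep(seq_len(n_per) - 1L, times = n)
  treat_chr <- unlist(lapply(arm, function(a) seqs[[a]]))
  treatment <- as.integer(treat_chr == "B")
  u0 <- rep(stats::rnorm(n, 0, sqrt(params$sigma0_sq)), each = n_per)
  eps_sd <- ifelse(treatment == 1L, sqrt(params$sigmaEpsB_sq),
                   sqrt(params$sigmaEpsA_sq))
  y <- params$beta0 + params$beta_treat * treatment +
    params$beta_time * period +
    params$beta_interaction * treatment * period +
    u0 + stats::rnorm(n * n_per, 0, eps_sd)
  out <- data.frame(subject_id = subject_id, period = period,
                    treatment = treatment, y = y)
  attr(out, "design") <- design
  attr(out, "n1") <- as.integer(n1)
  attr(out, "n2") <- as.integer(n2)
  class(out) <- c("trial_data", "data.frame")
  out
}

# Per-subject summary scores and arm labels for the analysis t-tests.
# Returns list(score1, score2): numeric vectors for the first- and
# second-listed sequence.
summary_scores <- function(data, effect) {
  design <- attr(data, "design")
  if (design == "parallel") {
    return(list(score1 = data$y[data$treatment == 0L],
                score2 = data$y[data$treatment == 1L]))
  }
  p0 <- data[data$period == 0L, ]
  p1 <- data[data$period == 1L, ]
  p1 <- p1[match(p0$subject_id, p1$subject_id), ]
  if (design == "crossover") {
    arm1 <- p0$treatment == 0L  # AB sequence: A first
    score <- if (effect == "treatment") p1$y - p0$y else (p0$y + p1$y) / 2
  } else {
    arm1 <- p0$treatment == 0L  # AA sequence
    score <- if (effect == "treatment") (p0$y + p1$y) / 2 else p1$y - p0$y
  }
  list(score1 = score[arm1], score2 = score[!arm1])
}

two_sample_t <- function(x1, x2, alpha, pooled) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("each arm needs >= 2 subjects", call. = FALSE)
  m <- mean(x1) - mean(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    # exact separation with zero residual variance: treat a nonzero mean
    # difference as certain rejection
    statistic <- if (m == 0) 0 else sign(m) * Inf
    p_value <- if (m == 0) 1 else 0
    df <- if (pooled) n1 + n2 - 2 else NaN
  } else {
    statistic <- m / se
    p_value <- 2 * stats::pt(-abs(statistic), df)
  }
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 reject = p_value < alpha, alpha = alpha, pooled = pooled),
            class = "trial_test")
}

#' Analyze a simulated trial with the exact t-test
#'
#' Analyses follow from the mixed model and are exact (no asymptotics):
#' crossover data are reduced to per-subject difference scores (treatment
#' effect) or per-subject means (interaction) and compared between the
#' AB and BA arms with a pooled-variance two-sample t-test (the model
#' implies equal variances of these scores across sequences); parallel data
#' are compared on the raw scores, and extended parallel data on
#' per-subject means (treatment) or differences (interaction), with an
#' unpooled-variance (Welch-Satterthwaite) t-test, since those scores may
#' have treatment-dependent variances.
#'
#' @param data A `trial_data` object from [simulate_trial].
#' @param effect `"treatment"` or `"treatment_by_period"`.
#' @param alpha Two-tailed type-I error rate.
#' @return An object of class `trial_test`: `statistic`, `df` (fractional
#'   for Welch), two-tailed `p_value`, and `reject`.
#' @export
analyze_trial <- function(data, effect, alpha = 0.05) {
  stopifnot(inherits(data, "trial_data"))
  effect <- match_effect(effect)
  check_design_effect(attr(data, "design"), effect)
  sc <- summary_scores(data, effect)
  two_sample_t(sc$score1, sc$score2, alpha,
               pooled = attr(data, "design") == "crossover")
}

#' @export
print.trial_test <- function(x, ...) {
  cat(sprintf("Two-sample %s-variance t-test: t = %.4f, df = %.2f, p = %.4g\n",
              if (x$pooled) "pooled" else "unpooled",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  %s H0 at two-tailed alpha = %g\n",
              if (x$reject) "reject" else "do not reject", x$alpha))
  invisible(x)
}

#' Monte Carlo power of a maximin-planned trial
#'
#' Plans the trial with [maximin_sample_size], generates `n_sim` seeded
#' replications under the mixed model at the stated (default: maximin)
#' intraclass correlations with the effect of interest set from the
#' standardized effect size, analyzes each with [analyze_trial], and
#' reports the rejection proportion together with the predictive interval
#' around the target power.
#'
#' @inheritParams maximin_sample_size
#' @param rho_eval Generating ICC pair `c(rhoA, rhoB)`, or `"maximin"`
#'   (default) to generate at the worst-case pair the plan guards against.
#' @param sigma_y_sq Total outcome variance of the generating model.
#' @param n_sim Number of replications.
#' @param seed Master seed; each replication is seeded from a substream so
#'   results are reproducible and independent of evaluation order.
#' @param null_effect If `TRUE`, generate under a zero effect (type-I error
#'   calibration) while keeping the planned sample sizes.
#' @return An object of class `mc_power`: `power` (rejection proportion),
#'   `n_sim`, the `plan`, the generating `rho`, the `predictive_interval`
#'   around the target power, and `meets_target` (rejection proportion at
#'   or above the interval's lower bound).
#' @examples
#' monte_carlo_power("crossover", "treatment", power_spec(ES = 0.8),
#'                   subject_count_costs(), icc_rect(0.70, 1, 0.70, 1),
#'                   n_sim = 200, seed = 1)
#' @export
monte_carlo_power <- function(design, effect, spec, costs, rect,
                              rho_eval = "maximin", sigma_y_sq = 2,
                              n_sim = 1000, seed = 1, null_effect = FALSE) {
  de <- check_design_effect(design, effect)
  stopifnot(n_sim >= 1)
  plan <- maximin_sample_size(de$design, de$effect, spec, costs, rect)
  if (identical(rho_eval, "maximin")) {
    rho_eval <- plan$rho_star
  }
  stopifnot(length(rho_eval) == 2)
  params <- params_from_icc(rho_eval[1], rho_eval[2],
                            ES = if (null_effect) 0 else spec$ES,
                            effect = de$effect, sigma_y_sq = sigma_y_sq)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_sim)
  rejections <- vapply(rep_seeds, function(s) {
    dat <- simulate_trial(de$design, plan$n1, plan$n2, params, seed = s)
    analyze_trial(dat, de$effect, spec$alpha)$reject
  }, NA)
  pow <- mean(rejections)
  pi_band <- predictive_interval(spec$power, n_sim)
  structure(list(power = pow, n_sim = n_sim, plan = plan,
                 rho = c(rhoA = unname(rho_eval[1]),
                         rhoB = unname(rho_eval[2])),
                 null_effect = null_effect, seed = seed,
                 predictive_interval = pi_band,
                 meets_target = !null_effect && pow >= pi_band["lower"]),
            class = "mc_power")
}

#' @export
print.mc_power <- function(x, ...) {
  cat(sprintf("Monte Carlo %s: %s design, %s effect\n",
              if (x$null_effect) "type-I error" else "power",
              x$plan$design, x$plan$effect))
  cat(sprintf("  N = %d (%d + %d), generated at rho_A=%.3f, rho_B=%.3f\n",
              x$plan$N, x$plan$n1, x$plan$n2, x$rho["rhoA"], x$rho["rhoB"]))
  cat(sprintf("  rejection proportion = %.4f over %d replications (seed %d)\n",
              x$power, x$n_sim, x$seed))
  if (!x$null_effect) {
    cat(sprintf("  95%% predictive interval around target: [%.4f, %.4f] -> %s\n",
                x$predictive_interval["lower"], x$predictive_interval["upper"],
                if (x$meets_target) "target met" else "below target"))
  }
  invisible(x)
}
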