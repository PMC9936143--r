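# Inferential stage: linear mixed-effects models for the precision metrics
# (one LPE/PPE value per subject x condition x rotation cell), mixed-effects
# logistic regression for trial-level front-back confusions, Tukey-adjusted
# marginal-mean contrasts, and a Monte-Carlo harness for type-I error and
# power of the whole simulate -> analyze -> stats chain.

as_model_frame <- function(mt, metric) {
  d <- data.frame(value = mt[[metric]],
                  condition = factor(mt$condition),
                  rotation = factor(mt$rotation),
                  subject = factor(mt$subject))
  d <- d[!is.na(d$value), , drop = FALSE]
  d
}

# fixed-effect formula from the factors that actually vary: condition and
# rotation enter (with interaction) only when they have >= 2 levels
fixed_terms <- function(d) {
  terms <- c("condition", "rotation")[c(nlevels(d$condition) >= 2,
                                        nlevels(d$rotation) >= 2)]
  if (length(terms) == 0) "1"
  else paste(terms, collapse = " * ")
}

# Empty condition x rotation cells (a session that never pairs a condition
# with a rotation) make the interaction rank-deficient in a benign,
# structured way: lme4 drops the aliased columns and emmeans flags the
# affected marginal means non-estimable. Any deficiency beyond that is a
# genuine aliasing error.
check_rank <- function(d) {
  mm <- stats::model.matrix(stats::as.formula(paste("~", fixed_terms(d))), d)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    n_empty <- sum(table(d$condition, d$rotation) == 0)
    aliased <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    if (ncol(mm) - q$rank > n_empty)
      stop("rank-deficient design; aliased terms: ",
           paste(aliased, collapse = ", "))
    message("empty design cell(s); dropping aliased term(s): ",
            paste(aliased, collapse = ", "))
  }
}

#' Linear mixed model for a precision metric
#'
#' Fits `metric ~ condition * rotation + (1 | subject)` by REML on the
#' cell-level metrics table (condition and rotation as fixed effects with
#' interaction, subject as a random intercept). A singular REML fit is
#' refit by ML with a warning.
#'
#' @param mt a `metrics_table` (at least 2 subjects and 2 levels per
#'   factor).
#' @param metric `"lpe_deg"` or `"ppe_deg"`.
#' @return a fitted `lmerMod` model.
#' @export
fit_precision_model <- function(mt, metric = c("lpe_deg", "ppe_deg")) {
  metric <- match.arg(metric)
  d <- as_model_frame(mt, metric)
  if (nlevels(d$subject) < 2 || nlevels(d$condition) < 2 ||
      nlevels(d$rotation) < 2)
    stop("need >= 2 subjects and >= 2 levels of condition and rotation")
  check_rank(d)
  fit <- lme4::lmer(value ~ condition * rotation + (1 | subject), data = d,
                    REML = TRUE)
  if (lme4::isSingular(fit)) {
    warning("singular REML fit; refitting by maximum likelihood")
    fit <- lme4::lmer(value ~ condition * rotation + (1 | subject), data = d,
                      REML = FALSE)
  }
  fit
}

#' Mixed-effects logistic regression for front-back confusions
#'
#' Fits `fbc ~ condition * rotation + (1 | subject)` on trial-level 0/1
#' labels (Laplace approximation). Cells in which the labels are constant
#' (complete separation risk) are reported in a warning.
#'
#' @param trials a data.frame from [fbc_trials()] with columns `fbc`,
#'   `cue_condition`, `rotation`, `subject_id`.
#' @return a fitted `glmerMod` model.
#' @export
fit_fbc_model <- function(trials) {
  if (!all(trials$fbc %in% c(0, 1))) stop("fbc labels must be 0/1")
  d <- data.frame(fbc = trials$fbc,
                  condition = factor(trials$cue_condition),
                  rotation = factor(trials$rotation),
                  subject = factor(trials$subject_id))
  check_rank(d)
  cellmeans <- tapply(d$fbc, interaction(d$condition, d$rotation, drop = TRUE),
                      mean)
  if (any(cellmeans %in% c(0, 1)))
    warning("constant FBC labels in cell(s) ",
            paste(names(cellmeans)[cellmeans %in% c(0, 1)], collapse = ", "),
            "; contrasts involving them are unstable")
  form <- stats::as.formula(paste("fbc ~", fixed_terms(d), "+ (1 | subject)"))
  lme4::glmer(form, data = d, family = stats::binomial())
}

#' Tukey-adjusted marginal-mean contrasts
#'
#' Pairwise comparisons of estimated (least-squares) marginal means, with
#' Tukey multiplicity adjustment per family. `scheme = "by_cue"` compares
#' rotation types within each cue condition; `scheme = "by_rotation"`
#' compares cue conditions within each rotation type (the two groupings of
#' the experiment's results tables). Each grouping level forms one Tukey
#' family.
#'
#' @param model a model from [fit_precision_model()] or [fit_fbc_model()].
#' @param scheme `"by_cue"` or `"by_rotation"`.
#' @param alpha,alpha_high significance thresholds for the flag columns.
#' @return a data.frame of class `contrast_table` with columns `grouping`,
#'   `contrast`, `estimate`, `se`, `p_adj`, `significant`,
#'   `highly_significant`.
#' @export
marginal_contrasts <- function(model, scheme = c("by_cue", "by_rotation"),
                               alpha = 0.05, alpha_high = 0.001) {
  scheme <- match.arg(scheme)
  spec <- if (scheme == "by_cue") ~ rotation | condition
          else ~ condition | rotation
  em <- emmeans::emmeans(model, spec)
  pr <- as.data.frame(summary(emmeans::contrast(em, "pairwise",
                                                adjust = "tukey")))
  grouping <- if (scheme == "by_cue") pr$condition else pr$rotation
  estimable <- !is.na(pr$estimate)   # drop contrasts touching empty cells
  pr <- pr[estimable, , drop = FALSE]
  grouping <- grouping[estimable]
  out <- data.frame(grouping = as.character(grouping),
                    contrast = as.character(pr$contrast),
                    estimate = pr$estimate,
                    se = pr$SE,
                    p_adj = pr$p.value,
                    significant = pr$p.value < alpha,
                    highly_significant = pr$p.value < alpha_high)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Monte-Carlo operating characteristics of the analysis chain
#'
#' Repeatedly simulates responses, screens them, computes metrics and fits
#' the mixed models, recording whether a pre-specified contrast rejects at
#' `alpha`. With `effect = "null"` all cells share the same parameters, so
#' the rejection rate estimates the type-I error of the precision
#' (LPE) contrast static-vs-yaw. With `effect = "fbc_yaw"` the flat
#' condition's reversal probability drops from `p_static` to `p_yaw` under
#' yaw rotation and the rejection rate of the corresponding logistic
#' contrast estimates power.
#'
#' @param effect `"null"` or `"fbc_yaw"`.
#' @param n_subjects simulated subjects per replicate.
#' @param n_reps Monte-Carlo replicates.
#' @param trials_per_cell test-list trials per cell per subject.
#' @param p_static,p_yaw reversal probabilities for the power setting.
#' @param subject_sd_fbc between-subject log-odds SD.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return a list with `rejection_rate`, a binomial 95% confidence
#'   interval `ci`, and the per-replicate p-values.
#' @export
simulation_harness <- function(effect = c("null", "fbc_yaw"),
                               n_subjects = 7, n_reps = 200,
                               trials_per_cell = 40,
                               p_static = 0.40, p_yaw = 0.15,
                               subject_sd_fbc = 0.4, alpha = 0.05,
                               seed = 1) {
  effect <- match.arg(effect)
  # compact grid: enough targets for stable cell SDs, away from the
  # front/back boundary so reversal labels are clean
  grid <- make_source_grid(list(
    list(lateral_deg = 0, polar_deg = c(-30, 0, 30, 150, 180, 210)),
    list(lateral_deg = 30, polar_deg = c(0, 30, 180)),
    list(lateral_deg = -30, polar_deg = c(0, 30, 180))))
  reps <- max(1L, round(trials_per_cell / (nrow(grid) + sum(grid$on_median))))
  pvals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- split_seed(seed, r)
    if (effect == "null") {
      cells <- expand.grid(condition = c("full", "flat"),
                           rotation = c("static", "yaw"),
                           stringsAsFactors = FALSE)
      cells$sigma_lat <- 12; cells$sigma_pol <- 25; cells$p_fbc <- 0.15
      params <- listener_params(cells = cells, subject_sd_fbc = subject_sd_fbc)
      plan <- rbind(
        make_static_session(grid, conditions = c("full", "flat"), reps = reps,
                            seed = s, subjects = paste0("S", 1:n_subjects)),
        make_dynamic_session(grid, conditions = c("full", "flat"), reps = reps,
                             seed = s + 1,
                             subjects = paste0("S", 1:n_subjects)))
      plan <- plan[plan$rotation %in% c("static", "yaw"), , drop = FALSE]
      rt <- simulate_responses(plan, params, seed = s + 2)
      rt <- qc_filter(rt)$responses
      mt <- compute_metrics(rt)
      fit <- fit_precision_model(mt, "lpe_deg")
      em <- emmeans::emmeans(fit, ~ rotation | condition)
      pr <- as.data.frame(summary(emmeans::contrast(em, "pairwise",
                                                    adjust = "none")))
      pvals[r] <- pr$p.value[pr$condition == "full"][1]
    } else {
      cells <- data.frame(condition = "flat",
                          rotation = c("static", "yaw"),
                          sigma_lat = 13, sigma_pol = 38,
                          p_fbc = c(p_static, p_yaw))
      params <- listener_params(cells = cells, subject_sd_fbc = subject_sd_fbc)
      plan <- rbind(
        make_static_session(grid, conditions = "flat", reps = reps,
                            seed = s, subjects = paste0("S", 1:n_subjects)),
        make_dynamic_session(grid, conditions = "flat", reps = reps,
                             seed = s + 1,
                             subjects = paste0("S", 1:n_subjects)))
      plan <- plan[plan$rotation %in% c("static", "yaw"), , drop = FALSE]
      rt <- simulate_responses(plan, params, seed = s + 2)
      rt <- qc_filter(rt)$responses
      tr <- fbc_trials(rt)
      fit <- fit_fbc_model(tr)
      pvals[r] <- summary(fit)$coefficients["rotationyaw", "Pr(>|z|)"]
    }
  }
  k <- sum(pvals < alpha)
  ci <- stats::binom.test(k, n_reps)$conf.int
  list(effect = effect, rejection_rate = k / n_reps,
       ci = as.numeric(ci), p_values = pvals)
}
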