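#' Validate automated counts against a manual tester
#'
#' Each subject contributes two measurements (one per leg), so agreement
#' between the tester's count and the automated count is assessed with a
#' random-intercept mixed model, `manual ~ script + (1 | subject)`:
#' perfect agreement corresponds to slope 1 and intercept 0. The
#' strength of the relation is the conditional pseudo R-squared in the
#' Nakagawa form — variance explained by fixed plus random effects over
#' the total. Agreement is summarised as the median manual-minus-script
#' difference with empirical 2.5/97.5 percentile limits, and the bias
#' trend as the slope of the difference on the manual count.
#'
#' When the mixed fit is singular (e.g. a single row per subject, or a
#' perfect fit leaving no subject variance) the function falls back to
#' ordinary least squares with a warning; the pseudo R-squared is then
#' the OLS R-squared.
#'
#' @param table Data frame with columns `subject`, `manual_count`,
#'   `script_count` (one row per subject-leg).
#' @return An object of class `count_validation`: `slope`, `intercept`
#'   (each with 95% CI), `conditional_pseudo_r2`, `median_difference`,
#'   `limits_of_agreement`, `difference_slope` (+ `difference_slope_p`),
#'   `method` (`"lmm"` or `"ols"`).
#' @export
validate_counts <- function(table) {
  need <- c("subject", "manual_count", "script_count")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (length(unique(table$subject)) < 3)
    stop("count validation needs at least 3 subjects")
  fit_ols <- function() {
    m <- stats::lm(manual_count ~ script_count, data = table)
    ci <- suppressWarnings(stats::confint(m))
    list(slope = unname(stats::coef(m)[2]),
         intercept = unname(stats::coef(m)[1]),
         slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
         r2 = summary(m)$r.squared, method = "ols")
  }
  fit <- tryCatch({
    m <- lme4::lmer(manual_count ~ script_count + (1 | subject),
                    data = table,
                    control = lme4::lmerControl(
                      check.conv.singular = lme4::.makeCC(
                        action = "message", tol = 1e-4)))
    if (lme4::isSingular(m, tol = 1e-4)) stop("singular fit")
    vc <- as.data.frame(lme4::VarCorr(m))
    var_u <- vc$vcov[vc$grp == "subject"]
    var_e <- vc$vcov[vc$grp == "Residual"]
    var_f <- stats::var(as.vector(
      stats::model.matrix(m) %*% lme4::fixef(m)))
    ci <- suppressWarnings(
      stats::confint(m, parm = "beta_", method = "Wald"))
    list(slope = unname(lme4::fixef(m)[2]),
         intercept = unname(lme4::fixef(m)[1]),
         slope_ci = unname(ci["script_count", ]),
         intercept_ci = unname(ci["(Intercept)", ]),
         r2 = (var_f + var_u) / (var_f + var_u + var_e),
         method = "lmm")
  }, error = function(e) {
    warning("mixed count-validation model unavailable (", conditionMessage(e),
            "); falling back to ordinary least squares", call. = FALSE)
    fit_ols()
  })
  diffs <- table$manual_count - table$script_count
  dtrend <- stats::lm(diffs ~ table$manual_count)
  dcoef <- summary(dtrend)$coefficients
  dslope <- unname(dcoef[2, 1])
  dslope_p <- if (nrow(dcoef) > 1 && !is.nan(dcoef[2, 4]))
    unname(dcoef[2, 4]) else NA_real_
  structure(list(
    slope = fit$slope, slope_ci = fit$slope_ci,
    intercept = fit$intercept, intercept_ci = fit$intercept_ci,
    conditional_pseudo_r2 = fit$r2,
    median_difference = stats::median(diffs),
    limits_of_agreement = unname(stats::quantile(diffs, c(0.025, 0.975))),
    difference_slope = dslope, difference_slope_p = dslope_p,
    method = fit$method, n = nrow(table)), class = "count_validation")
}

#' @export
print.count_validation <- function(x, ...) {
  cat(sprintf("<count_validation> n = %d (%s)\n", x$n,
              if (x$method == "lmm") "mixed model" else "OLS fallback"))
  cat(sprintf("  slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f]\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  conditional pseudo-R2 %.3f; median diff %.2f, LoA [%.2f, %.2f]\n",
              x$conditional_pseudo_r2, x$median_difference,
              x$limits_of_agreement[1], x$limits_of_agreement[2]))
  invisible(x)
}

#' Natural-log transform with strict positivity check
#'
#' Error parameters are log-transformed before modelling to restore
#' residual normality. Non-positive values are a data error, never
#' silently offset; the offending rows are named.
#'
#' @param values Numeric vector.
#' @return `log(values)`.
#' @export
log_transform <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad))
    stop("log transform requires positive values; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  log(values)
}

#' Speed-accuracy residualization against a control-group model
#'
#' Error parameters rise with movement speed (the speed-accuracy
#' trade-off), so slower patients would look spuriously accurate. The
#' control rows define the expected relation — a least-squares line of
#' `Ln(parameter)` on the in-target count — and every row's residual
#' (observed minus predicted log parameter) becomes the speed-controlled
#' value for downstream models. Control residuals are mean-zero by
#' construction.
#'
#' @param table Data frame with `group`, `in_count` and the parameter
#'   column; rows of all groups receive residuals.
#' @param parameter Name of the (positive) parameter column.
#' @param control_group Level of `group` defining the reference relation.
#' @return A list: `residuals` (aligned with `table` rows), `intercept`,
#'   `slope`, `slope_se`, `intercept_se`, `n_control`.
#' @export
speed_accuracy_residuals <- function(table, parameter,
                                     control_group = "control") {
  stopifnot(parameter %in% names(table), "in_count" %in% names(table))
  ctrl <- table$group == control_group & !is.na(table[[parameter]])
  if (sum(ctrl) < 3)
    stop("need at least 3 control rows to fit the prediction model")
  ln_y <- log_transform(table[[parameter]])
  fit <- stats::lm(ln_y[ctrl] ~ table$in_count[ctrl])
  co <- summary(fit)$coefficients
  pred <- co[1, 1] + co[2, 1] * table$in_count
  list(residuals = ln_y - pred,
       intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       intercept_se = unname(co[1, 2]), slope_se = unname(co[2, 2]),
       n_control = sum(ctrl))
}

#' Group-by-leg mixed model with Holm-adjusted post hocs
#'
#' Fits the full factorial mixed model `dv ~ group * leg + (1 | subject)`
#' on subject-leg observations. `leg` is recoded to the two-level
#' within-subject factor pairing the paretic with the dominant leg
#' (tested first) and the non-paretic with the non-dominant leg: levels
#' `"first"` and `"second"`. Type-III F tests use Satterthwaite
#' denominator degrees of freedom (reported in the output); estimated
#' marginal means per cell and all pairwise cell comparisons are
#' adjusted by the Holm step-down (sequential Bonferroni) procedure.
#'
#' @param table Data frame with `subject`, `group`, `leg` and the dv
#'   column; `leg` in paretic/non-paretic/dominant/non-dominant (or
#'   already first/second).
#' @param dv Name of the dependent-variable column (used as is; apply
#'   [log_transform()] beforehand when modelling error parameters).
#' @return An object of class `group_leg_model`: `anova` (data frame
#'   with effect, F, df1, df2, p), `emmeans`, `posthoc` (Holm-adjusted),
#'   `df_method`, `formula`, `degenerate` flag.
#' @export
fit_group_leg_model <- function(table, dv) {
  stopifnot(dv %in% names(table))
  d <- table[!is.na(table[[dv]]), , drop = FALSE]
  d$leg_pair <- recode_leg_pair(d$leg)
  d$group <- factor(d$group)
  if (nlevels(d$group) != 2)
    stop("exactly two groups are required")
  if (any(tapply(d$subject, d$group, function(s) length(unique(s))) < 2))
    stop("each group needs at least 2 subjects")
  d$.dv <- d[[dv]]
  eff_names <- c("group", "leg_pair", "group:leg_pair")
  degenerate_result <- function() {
    structure(list(
      anova = data.frame(effect = eff_names, F = c(0, 0, 0),
                         df1 = c(1, 1, 1), df2 = rep(NA_real_, 3),
                         p = c(1, 1, 1)),
      emmeans = NULL, posthoc = NULL,
      df_method = "none (degenerate: constant dv)",
      formula = "dv ~ group * leg_pair + (1 | subject)",
      degenerate = TRUE), class = "group_leg_model")
  }
  if (stats::var(d$.dv) < 1e-12) return(degenerate_result())
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  m <- tryCatch(
    lmerTest::lmer(.dv ~ group * leg_pair + (1 | subject), data = d),
    error = function(e) NULL)
  if (is.null(m)) return(degenerate_result())
  an <- suppressMessages(stats::anova(m, type = 3))
  an_df <- data.frame(effect = rownames(an), F = an$`F value`,
                      df1 = an$NumDF, df2 = an$DenDF, p = an$`Pr(>F)`)
  emm <- emmeans::emmeans(m, ~ group * leg_pair,
                          lmer.df = "satterthwaite")
  ph <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "holm"))
  structure(list(anova = an_df,
                 emmeans = as.data.frame(emm),
                 posthoc = ph,
                 df_method = "Satterthwaite",
                 formula = "dv ~ group * leg_pair + (1 | subject)",
                 degenerate = FALSE,
                 n_obs = nrow(d),
                 n_subjects = length(unique(d$subject))),
            class = "group_leg_model")
}

recode_leg_pair <- function(leg) {
  leg <- as.character(leg)
  map <- c(paretic = "first", dominant = "first",
           "non-paretic" = "second", "non-dominant" = "second",
           first = "first", second = "second")
  if (!all(leg %in% names(map)))
    stop("unrecognised leg label(s): ",
         paste(unique(leg[!leg %in% names(map)]), collapse = ", "))
  factor(unname(map[leg]), levels = c("first", "second"))
}

#' @export
print.group_leg_model <- function(x, ...) {
  cat("<group_leg_model>", x$formula, "| df:", x$df_method, "\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Spearman association with effect-size label
#'
#' Rank correlation between two measures with the conventional effect
#' bands: |rho| >= 0.50 large, >= 0.30 medium, >= 0.10 small, below that
#' negligible. Constant input has no defined rank correlation and is
#' flagged rather than silently returned as zero.
#'
#' @param x,y Numeric vectors of equal length (>= 5).
#' @return A list: `rho`, `p`, `effect`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, effect = "undefined (constant input)",
                n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  effect <- if (abs(rho) >= 0.5) "large"
            else if (abs(rho) >= 0.3) "medium"
            else if (abs(rho) >= 0.1) "small"
            else "negligible"
  list(rho = rho, p = ct$p.value, effect = effect, n = length(x))
}
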