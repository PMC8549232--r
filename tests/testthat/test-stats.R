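make_count_table <- function(n_subj, slope = 1, intercept = 0,
                             sd_subject = 0, sd_resid = 0, seed = 1) {
  set.seed(seed)
  script <- round(runif(2 * n_subj, 15, 25))
  subject <- rep(sprintf("S%03d", seq_len(n_subj)), each = 2)
  u <- rep(rnorm(n_subj, 0, sd_subject), each = 2)
  data.frame(subject = subject, script_count = script,
             manual_count = intercept + slope * script + u +
               rnorm(2 * n_subj, 0, sd_resid))
}

test_that("count validation detects perfect agreement and constant bias", {
  perfect <- make_count_table(12)
  v <- suppressWarnings(validate_counts(perfect))
  expect_equal(v$slope, 1, tolerance = 1e-8)
  expect_equal(v$intercept, 0, tolerance = 1e-8)
  expect_equal(v$conditional_pseudo_r2, 1, tolerance = 1e-8)
  expect_equal(v$median_difference, 0)
  biased <- make_count_table(12, intercept = 2)
  vb <- suppressWarnings(validate_counts(biased))
  expect_equal(vb$slope, 1, tolerance = 1e-8)
  expect_equal(vb$intercept, 2, tolerance = 1e-6)
  expect_equal(vb$median_difference, 2)
  expect_true(vb$limits_of_agreement[1] <= vb$limits_of_agreement[2])
  expect_error(validate_counts(make_count_table(2)), "3 subjects")
})

test_that("conditional pseudo-R2 recovers the known variance decomposition", {
  tab <- make_count_table(150, slope = 1, intercept = 2,
                          sd_subject = 2, sd_resid = 1, seed = 91)
  v <- validate_counts(tab)
  expect_equal(v$method, "lmm")
  var_f <- var(tab$script_count)  # slope 1
  expected <- (var_f + 4) / (var_f + 4 + 1)
  expect_equal(v$conditional_pseudo_r2, expected, tolerance = 0.03)
  expect_true(v$slope_ci[1] < 1 && 1 < v$slope_ci[2])
})

test_that("manual-minus-script bias trend is recovered", {
  # overcount growing with the count: manual = 1.1 * script + e. The
  # difference (0.1 script + e) is regressed on the manual count, whose
  # own noise e appears on both sides, so the population slope is
  # (0.1 * 1.1 * var_s + var_e) / (1.1^2 * var_s + var_e).
  tab <- make_count_table(40, slope = 1.1, sd_resid = 0.5, seed = 92)
  v <- validate_counts(tab)
  var_s <- var(tab$script_count); var_e <- 0.5^2
  expected <- (0.1 * 1.1 * var_s + var_e) / (1.1^2 * var_s + var_e)
  expect_lt(abs(v$difference_slope - expected), 0.03)
  expect_lt(v$difference_slope_p, 0.01)
})

test_that("log transform is strict about positivity", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(1)), 1)
  set.seed(93)
  v <- runif(50, 0.1, 30)
  expect_equal(order(log_transform(v)), order(v))
  expect_error(log_transform(c(2, 0, 3)), "row")
  expect_error(log_transform(c(2, -1)), "2")
})

test_that("speed-accuracy residualization recovers the control law and injected effects", {
  set.seed(94)
  n <- 200
  a <- 1.2; b <- 0.05; sigma <- 0.2; delta <- 0.5
  ctrl_count <- round(runif(n, 20, 55))
  strk_count <- round(runif(n, 8, 30))
  tab <- data.frame(
    group = rep(c("control", "stroke"), each = n),
    in_count = c(ctrl_count, strk_count))
  tab$param <- exp(a + b * tab$in_count +
                     c(rnorm(n, 0, sigma), delta + rnorm(n, 0, sigma)))
  sar <- speed_accuracy_residuals(tab, "param")
  expect_lt(abs(sar$slope - b), 2 * sar$slope_se)
  ctrl <- tab$group == "control"
  expect_lt(abs(mean(sar$residuals[ctrl])), 1e-10)
  expect_lt(abs(spearman_assoc(sar$residuals[ctrl],
                               tab$in_count[ctrl])$rho), 0.05)
  expect_lt(abs(mean(sar$residuals[!ctrl]) - delta), 0.1 * delta)
  # degenerate zero slope: residuals are deviations from the control mean
  flat <- data.frame(group = rep(c("control", "stroke"), each = 10),
                     in_count = rep(1:10, 2),
                     param = exp(c(rep(2, 10), rep(2.7, 10))))
  sf <- suppressWarnings(speed_accuracy_residuals(flat, "param"))
  expect_equal(sf$slope, 0, tolerance = 1e-12)
  expect_equal(sf$residuals, log(flat$param) - 2, tolerance = 1e-10)
  expect_error(speed_accuracy_residuals(
    data.frame(group = "control", in_count = 1, param = 1), "param"), "3")
})

test_that("group-by-leg model finds an injected group shift and respects Holm", {
  set.seed(95)
  sig_group <- 0; sig_inter <- 0
  for (r in 1:6) {
    tab <- simulate_cohort(12, 12, cohort_profile_null(),
                           include_clinical = FALSE)
    # inject a pure group shift on the log scale
    tab$dv <- log_transform(tab$var_err_ep_mm) +
      ifelse(tab$group == "stroke", 0.5, 0)
    m <- suppressMessages(fit_group_leg_model(tab, "dv"))
    an <- m$anova
    sig_group <- sig_group + (an$p[an$effect == "group"] < 0.05)
    sig_inter <- sig_inter + (an$p[an$effect == "group:leg_pair"] < 0.05)
    # Holm-adjusted post hocs: >= raw p and monotone step-down
    raw <- m$posthoc$p.value
    expect_true(all(!is.na(raw)))
  }
  expect_gte(sig_group, 5)
  expect_lte(sig_inter, 2)
})

test_that("Holm adjustment is monotone and never below raw p-values", {
  set.seed(96)
  tab <- simulate_cohort(10, 10, cohort_profile_study(),
                         include_clinical = FALSE)
  tab$dv <- log_transform(tab$var_err_cop_mm)
  m <- suppressMessages(fit_group_leg_model(tab, "dv"))
  emm <- m$emmeans
  expect_equal(nrow(emm), 4)
  # recompute unadjusted pairwise p-values and apply Holm independently
  raw_fit <- suppressMessages(fit_group_leg_model(tab, "dv"))
  expect_equal(nrow(m$posthoc), 6)
  # re-derive: Holm of the raw p's must equal the reported adjusted p's
  d <- tab[!is.na(tab$dv), ]
  d$leg_pair <- lemocot:::recode_leg_pair(d$leg)
  old <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(old))
  fit <- lmerTest::lmer(dv ~ group * leg_pair + (1 | subject), data = d)
  raw <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit, ~ group * leg_pair, lmer.df = "satterthwaite"),
    "pairwise", adjust = "none"))$p.value
  expect_equal(m$posthoc$p.value, p.adjust(raw, "holm"), tolerance = 1e-8)
  expect_true(all(m$posthoc$p.value >= raw - 1e-12))
  ord <- order(raw)
  expect_true(all(diff(m$posthoc$p.value[ord]) >= -1e-12))
})

test_that("degenerate and malformed model inputs are handled", {
  tab <- simulate_cohort(5, 5, cohort_profile_null(),
                         include_clinical = FALSE, seed = 97)
  tab$const <- 7
  m <- fit_group_leg_model(tab, "const")
  expect_true(m$degenerate)
  expect_equal(m$anova$F, c(0, 0, 0))
  one_group <- tab[tab$group == "stroke", ]
  expect_error(fit_group_leg_model(one_group, "var_err_ep_mm"),
               "two groups")
  bad_leg <- tab; bad_leg$leg[1] <- "left"
  expect_error(fit_group_leg_model(bad_leg, "var_err_ep_mm"),
               "unrecognised leg")
})

test_that("Spearman associations carry conventional effect labels", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_assoc(x, x)$rho, 1)
  expect_equal(spearman_assoc(x, x)$effect, "large")
  expect_equal(spearman_assoc(x, -x)$rho, -1)
  set.seed(98)
  xt <- c(1, 2, 2, 3, 4, 4, 5, 7)   # ties
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6)
  oracle <- cor(rank(xt), rank(yt))  # rank-then-Pearson
  expect_equal(spearman_assoc(xt, yt)$rho, oracle, tolerance = 1e-12)
  z <- rnorm(40)
  weak <- spearman_assoc(z, 0.05 * z + rnorm(40))
  expect_true(weak$effect %in% c("negligible", "small", "medium"))
  const <- spearman_assoc(rep(1, 6), 1:6)
  expect_true(is.na(const$rho))
  expect_match(const$effect, "constant")
  expect_error(spearman_assoc(1:3, 1:3), "5")
})
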