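# Mixed-model machinery

sim_lmm_table <- function(n_groups, per_group, beta_phase = c(0, 0, 0),
                          sd_group = 0.7, sd_resid = 1, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = per_group)
  phase <- factor(rep_len(c("pre", "closure", "post"), n_groups * per_group),
                  levels = c("pre", "closure", "post"))
  b <- rnorm(n_groups, 0, sd_group)
  data.frame(
    y = beta_phase[as.integer(phase)] + b[g] + rnorm(length(g), 0, sd_resid),
    phase = phase,
    h_fs = runif(length(g)),
    sex = factor(rep_len(c("F", "M"), length(g)), levels = c("F", "M")),
    ind = sprintf("g%03d", g),
    animal_id = sprintf("g%03d", g))
}

test_that("with zero between-group variance the fit collapses to least squares", {
  set.seed(1)
  d <- data.frame(x = rnorm(160), ind = sprintf("g%02d", rep(1:20, each = 8)))
  d$y <- 1 + 2 * d$x + rnorm(160, 0, 0.5)   # no group effect at all
  fit <- fit_lmm(d, "y", "x")
  expect_true(fit$singular)
  ols <- lm(y ~ x, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("an exact linear response gives vanishing residual variance and R2 near 1", {
  d <- data.frame(x = rnorm(100), ind = rep(sprintf("g%d", 1:10), 10))
  d$y <- 3 - 1.5 * d$x
  fit <- fit_lmm(d, "y", "x")
  expect_lt(fit$varcomp["residual"], 1e-6)
  expect_gt(fit$r2["conditional"], 0.999)
})

test_that("variance-partition R2 matches the generative variance components", {
  set.seed(77)
  n_g <- 200; per <- 10
  g <- rep(1:n_g, each = per)
  x <- rnorm(n_g * per)             # slope 1, var(x) = 1
  b <- rnorm(n_g, 0, 1)             # random-intercept variance 1
  d <- data.frame(y = x + b[g] + rnorm(n_g * per, 0, 1), x = x,
                  ind = sprintf("g%03d", g))
  fit <- fit_lmm(d, "y", "x")
  r2 <- r_squared(fit)
  expect_equal(unname(r2["marginal"]), 1 / 3, tolerance = 0.07)
  expect_equal(unname(r2["conditional"]), 2 / 3, tolerance = 0.07)
  expect_lte(r2["marginal"], r2["conditional"])
  expect_true(all(r2 >= 0 & r2 <= 1))

  # no grouping variance: marginal equals conditional
  d$y2 <- x + rnorm(n_g * per, 0, 1)
  r2b <- r_squared(fit_lmm(d, "y2", "x"))
  expect_equal(unname(r2b["marginal"]), unname(r2b["conditional"]),
               tolerance = 1e-6)

  # pure noise: both near zero
  d$y3 <- rnorm(n_g * per)
  r2c <- r_squared(fit_lmm(d, "y3", "x"))
  expect_lt(r2c["conditional"], 0.05)
})

test_that("true null terms are dropped; marginality protects main effects", {
  d <- sim_lmm_table(40, 6, beta_phase = c(0, 1, 1.2), seed = 42)
  fit <- fit_lmm(d, "y", c("phase", "sex", "phase:sex"))
  red <- drop_nonsignificant(fit, d)
  expect_true("phase" %in% red$terms)
  expect_false("sex" %in% red$terms)
  expect_false("phase:sex" %in% red$terms)
  expect_true(all(red$drop_log$p > 0.05))

  # interaction-only truth: both mains are retained while it stands
  set.seed(9)
  d2 <- data.frame(x1 = rnorm(300), x2 = rnorm(300),
                   ind = rep(sprintf("g%02d", 1:30), 10))
  d2$y <- 2 * d2$x1 * d2$x2 + rnorm(300, 0, 0.5)
  fit2 <- fit_lmm(d2, "y", c("x1", "x2", "x1:x2"))
  red2 <- drop_nonsignificant(fit2, d2)
  expect_true(all(c("x1", "x2", "x1:x2") %in% red2$terms))

  # an all-significant model is left unchanged
  d3 <- sim_lmm_table(40, 6, beta_phase = c(0, 2, 3), seed = 3)
  fit3 <- fit_lmm(d3, "y", "phase")
  red3 <- drop_nonsignificant(fit3, d3)
  expect_identical(red3$terms, fit3$terms)
  expect_equal(nrow(red3$drop_log), 0)
})

test_that("the nested sequence is likelihood-monotone with stable signs under known truth", {
  d <- sim_lmm_table(40, 6, beta_phase = c(0, 1, 0.8), seed = 15)
  seq_fit <- build_model_sequence(d, "y",
                                  base_terms = c("phase", "h_fs", "phase:h_fs"))
  expect_true(all(diff(seq_fit$logLik) >= -1e-6))
  # phase coefficients keep their sign at every stage
  expect_false("phaseclosure" %in% seq_fit$sign_flips)
  # the preference covariate, unrelated to the response, stays non-significant
  for (f in seq_fit$fits) {
    tt <- f$term_tests
    if (!is.null(tt) && "h_fs" %in% tt$term[tt$droppable])
      expect_gt(tt$p[tt$term == "h_fs"], 0.005)
  }
  # empty term list: a single intercept-only fit
  seq0 <- build_model_sequence(d, "y", base_terms = character(0))
  expect_equal(length(seq0$fits), 1)
  expect_equal(seq0$fits[[1]]$coefficients$coefficient, "(Intercept)")
})

test_that("binomial mixed models recover known coefficients within two standard errors", {
  set.seed(31)
  n_g <- 20; per <- 400
  g <- rep(1:n_g, each = per)
  x <- rnorm(n_g * per)
  b <- rnorm(n_g, 0, 0.8)
  eta <- -1 + 1.5 * x + b[g]
  d <- data.frame(u_M = rbinom(n_g * per, 1, plogis(eta)), h_fs = x,
                  phase = factor(rep_len(c("pre", "closure", "post"), n_g * per),
                                 levels = c("pre", "closure", "post")),
                  sex = factor("F", levels = c("F", "M")),
                  ind = sprintf("g%02d", g))
  fit <- fsmanip:::fit_mixed_core(d, "u_M", "h_fs", "ind", family = binomial())
  co <- fit$coefficients
  est <- co$estimate[co$coefficient == "h_fs"]
  se <- co$se[co$coefficient == "h_fs"]
  expect_lt(abs(est - 1.5), 2 * se)
  i0 <- co$coefficient == "(Intercept)"
  expect_lt(abs(co$estimate[i0] - (-1)), 2 * co$se[i0])
})

test_that("degenerate binary responses are refused", {
  d <- data.frame(u_M = 0L, u_A = 1L, phase = factor("pre",
                  levels = c("pre", "closure", "post")),
                  h_fs = 0.5, sex = factor("F", levels = c("F", "M")),
                  ind = "g1")[rep(1, 50), ]
  expect_error(fit_resource_glmm(d, "M"), class = "fs_degenerate")
})

test_that("resource models keep their direction with and without response lags", {
  an <- default_analysis()
  for (nm in c("u_M", "u_A")) {
    w <- an$fits[[nm]]$with_lags$coefficients
    wo <- an$fits[[nm]]$without_lags$coefficients
    cw <- w$estimate[w$coefficient == "phaseclosure"]
    cwo <- wo$estimate[wo$coefficient == "phaseclosure"]
    expect_equal(sign(cw), sign(cwo))
  }
  # the vegetation model has no pre-closure level (circularity guard)
  v <- an$fits$u_V$with_lags$coefficients$coefficient
  expect_false(any(grepl("phasepre", v)))
  expect_true(any(grepl("phasepost", v)))
})

test_that("grouping by animal instead of animal-year is a no-op without repeats", {
  d <- sim_lmm_table(30, 6, beta_phase = c(0, 1, 1), seed = 8)  # one year each
  fit <- fit_lmm(d, "y", "phase")
  sens <- random_effect_sensitivity(fit, d)
  expect_equal(sens$alternative$logLik, fit$logLik, tolerance = 1e-6)
  expect_true(all(sens$agreement$agrees))

  d$animal_id <- NULL
  expect_error(random_effect_sensitivity(fit, d), "animal",
               class = "fs_bad_input")
})

test_that("repeat individuals give a per-term concordance report", {
  an <- default_analysis()
  tab <- an$tables$area95
  expect_gt(length(unique(tab$ind)), length(unique(tab$animal_id)))
  sens <- random_effect_sensitivity(an$fits$area95, tab)
  expect_true(is.data.frame(sens$agreement))
  expect_gt(nrow(sens$agreement), 0)
})
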