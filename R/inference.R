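# Mixed-model machinery: ML fits via lme4, drop-one likelihood-ratio tests
# respecting marginality, staged model building, and Nakagawa-style
# variance-partition coefficients of determination.

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# TRUE when `big` is a higher-order term containing every variable of `small`
contains_term <- function(big, small) {
  bv <- term_vars(big); sv <- term_vars(small)
  length(bv) > length(sv) && all(sv %in% bv)
}

# terms not participating in any retained higher-order interaction
droppable_terms <- function(terms) {
  if (!length(terms)) return(character(0))
  keep <- vapply(terms, function(tm)
    !any(vapply(terms, contains_term, logical(1), small = tm)), logical(1))
  terms[keep]
}

build_mixed_formula <- function(response, terms, random) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  as.formula(sprintf("%s ~ %s + (1 | %s)", response, rhs, random))
}

is_binomial_fit <- function(model) {
  inherits(model, "glmerMod") && family(model)$family == "binomial"
}

# Core fitting routine. Returns an `fs_fit` object; never errors on
# convergence trouble (messages are collected, fit retained).
fit_mixed_core <- function(table, response, terms, random, family = NULL,
                           nagq = 1L, compute_p = TRUE) {
  f <- build_mixed_formula(response, terms, random)
  msgs <- character(0)
  collect <- function(cond) {
    msgs <<- c(msgs, conditionMessage(cond))
    if (inherits(cond, "warning")) invokeRestart("muffleWarning")
    else invokeRestart("muffleMessage")
  }
  model <- withCallingHandlers(
    if (is.null(family))
      lme4::lmer(f, data = table, REML = FALSE)
    else
      lme4::glmer(f, data = table, family = family, nAGQ = nagq),
    warning = collect, message = collect)
  singular <- suppressWarnings(lme4::isSingular(model))
  if (singular)
    msgs <- c(msgs, "random-effect variance estimated at (or near) zero")

  co <- summary(model)$coefficients
  coefs <- data.frame(coefficient = rownames(co),
                      estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL

  fit <- structure(list(
    model = model, response = response, terms = terms, random = random,
    family = family, nagq = nagq, formula = f,
    coefficients = coefs, term_tests = NULL,
    logLik = as.numeric(logLik(model)),
    singular = singular, messages = msgs,
    varcomp = varcomp_of(model)
  ), class = "fs_fit")
  fit$r2 <- r_squared(fit)

  if (compute_p && length(terms)) {
    dr <- droppable_terms(terms)
    tt <- data.frame(term = terms, droppable = terms %in% dr,
                     chisq = NA_real_, df = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
    for (tm in dr) {
      sub <- fit_mixed_core(table, response, setdiff(terms, tm), random,
                            family, nagq, compute_p = FALSE)
      a <- anova(sub$model, model)
      i <- match(tm, tt$term)
      tt$chisq[i] <- a$Chisq[2]
      tt$df[i] <- a$Df[2]
      tt$p[i] <- a[["Pr(>Chisq)"]][2]
    }
    fit$term_tests <- tt
  }
  fit
}

varcomp_of <- function(model) {
  vc <- lme4::VarCorr(model)
  re <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  resid <- if (is_binomial_fit(model)) pi^2 / 3 else stats::sigma(model)^2
  c(random = re, residual = resid)
}

#' Fit a linear mixed model with drop-one likelihood-ratio tests
#'
#' Fits `response ~ fixed_terms + (1 | random)` by maximum likelihood.
#' Term-level p-values come from likelihood-ratio tests of each term against
#' the model without it, respecting marginality: a main effect participating
#' in a retained interaction is not tested (its p is `NA`). A singular
#' random-effect variance is retained at zero with a recorded message.
#' Responses are expected already transformed (log areas, logit overlaps,
#' log step length, logit-scaled absolute turning angle).
#'
#' @param table model table (one row per observation unit, no missing values
#'   in modelled columns).
#' @param response name of the response column.
#' @param fixed_terms character vector of fixed-effect terms, interactions as
#'   `"a:b"`; empty for an intercept-only model.
#' @param random name of the grouping column for the random intercept
#'   (default `"ind"`, the animal-year).
#' @return An object of class `fs_fit`: the `lme4` model plus coefficient
#'   table, term tests, variance components, marginal/conditional R-squared,
#'   and convergence notes.
#' @export
fit_lmm <- function(table, response, fixed_terms, random = "ind") {
  fit_mixed_core(table, response, fixed_terms, random, family = NULL)
}

#' @export
print.fs_fit <- function(x, ...) {
  kind <- if (is.null(x$family)) "Linear" else "Binomial (logit)"
  cat(sprintf("%s mixed model: %s\n", kind, deparse(x$formula)))
  cat(sprintf("logLik %.2f | random var %.4g | residual var %.4g | R2m %.3f | R2c %.3f%s\n",
              x$logLik, x$varcomp["random"], x$varcomp["residual"],
              x$r2["marginal"], x$r2["conditional"],
              if (x$singular) " | singular" else ""))
  print(x$coefficients, digits = 4)
  if (!is.null(x$term_tests)) {
    cat("Term likelihood-ratio tests:\n")
    print(x$term_tests, digits = 4)
  }
  invisible(x)
}

#' @export
summary.fs_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Marginal and conditional coefficients of determination
#'
#' Variance-partition R-squared for a mixed model: the marginal statistic is
#' the fixed-effect variance over the total
#' (fixed + random + residual); the conditional statistic adds the
#' random-intercept variance to the numerator. The fixed-effect variance is
#' the variance of the linear predictor from the fixed effects alone; for
#' binomial-logit models the residual variance is the logistic distribution
#' variance `pi^2 / 3`.
#'
#' @param fit an `fs_fit` or `merMod` object.
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
r_squared <- function(fit) {
  model <- if (inherits(fit, "fs_fit")) fit$model else fit
  X <- lme4::getME(model, "X")
  beta <- lme4::fixef(model)
  s2f <- as.numeric(var(as.numeric(X %*% beta)))
  vc <- varcomp_of(model)
  den <- s2f + vc["random"] + vc["residual"]
  out <- c(marginal = s2f / den,
           conditional = (s2f + vc["random"]) / den)
  names(out) <- c("marginal", "conditional")
  out
}

#' Backward elimination of non-significant fixed effects
#'
#' Iteratively removes the least-significant droppable term (p above `alpha`)
#' and refits, until every remaining droppable term is significant. A main
#' effect participating in a retained interaction is never dropped
#' (marginality). The sequence of removals is recorded in the `drop_log`
#' field of the returned fit.
#'
#' @param fit an `fs_fit` from [fit_lmm()] or [fit_resource_glmm()].
#' @param table the model table the fit was built from.
#' @param alpha significance threshold (default 0.05).
#' @param never_drop terms exempt from elimination.
#' @return The reduced `fs_fit`, with `drop_log` (data.frame of removed terms
#'   and their p-values at removal).
#' @export
drop_nonsignificant <- function(fit, table, alpha = 0.05,
                                never_drop = character(0)) {
  log <- data.frame(term = character(0), p = numeric(0),
                    stringsAsFactors = FALSE)
  repeat {
    tt <- fit$term_tests
    if (is.null(tt)) break
    cand <- tt[tt$droppable & !is.na(tt$p) & tt$p > alpha &
                 !(tt$term %in% never_drop), , drop = FALSE]
    if (!nrow(cand)) break
    worst <- cand$term[which.max(cand$p)]
    log <- rbind(log, data.frame(term = worst, p = max(cand$p)))
    fit <- fit_mixed_core(table, fit$response, setdiff(fit$terms, worst),
                          fit$random, fit$family, fit$nagq)
  }
  fit$drop_log <- log
  fit
}

#' Progressive construction of the fixed-effect structure
#'
#' Fits a nested sequence of mixed models, starting from the simplest
#' formulation and adding terms in the conventional order (phase; + preference;
#' + phase-by-preference; + sex; + phase-by-sex), to check that the data
#' support the full structure: shared coefficients should keep their sign and
#' magnitude across stages, and the maximized log-likelihood must never
#' decrease. Covariates in `always` (e.g. lagged responses) enter every stage.
#'
#' @param table model table.
#' @param response response column name.
#' @param base_terms ordered terms defining the nested stages; an empty vector
#'   yields a single intercept-only fit.
#' @param always terms present at every stage.
#' @param random random-intercept grouping column.
#' @param family `NULL` for linear, or a GLM family for generalized fits.
#' @param nagq integration points for generalized fits.
#' @return An object of class `fs_model_sequence`: list of `fs_fit`s, the
#'   log-likelihood path, a coefficient-stability table and the sign flips
#'   found (if any).
#' @export
build_model_sequence <- function(table, response,
                                 base_terms = c("phase", "h_fs", "phase:h_fs",
                                                "sex", "phase:sex"),
                                 always = character(0),
                                 random = "ind", family = NULL, nagq = 1L) {
  stages <- if (length(base_terms))
    lapply(seq_along(base_terms), function(k) base_terms[seq_len(k)])
  else list(character(0))
  fits <- lapply(stages, function(tm)
    fit_mixed_core(table, response, c(tm, always), random, family, nagq))
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  stab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    co <- fits[[i]]$coefficients
    data.frame(stage = i, coefficient = co$coefficient,
               estimate = co$estimate, stringsAsFactors = FALSE)
  }))
  flips <- character(0)
  for (cf in unique(stab$coefficient)) {
    est <- stab$estimate[stab$coefficient == cf]
    if (length(est) > 1 && any(sign(est[-1]) * sign(est[-length(est)]) < 0))
      flips <- c(flips, cf)
  }
  structure(list(fits = fits, logLik = ll, stability = stab,
                 sign_flips = flips),
            class = "fs_model_sequence")
}

#' @export
print.fs_model_sequence <- function(x, ...) {
  cat(sprintf("Nested model sequence: %d stages, logLik %s\n",
              length(x$fits), paste(sprintf("%.1f", x$logLik), collapse = " -> ")))
  if (length(x$sign_flips))
    cat("Sign flips in:", paste(x$sign_flips, collapse = ", "), "\n")
  else cat("No sign flips across stages\n")
  invisible(x)
}

#' Binomial mixed models for resource-state use
#'
#' Fits a mixed-effect logistic regression to one of the three single-state
#' presence/absence series (`u_M`, `u_A`, `u_V`), with phase, preference, sex
#' and their interactions as fixed effects and an animal-year random
#' intercept. The model is fitted both with and without the lagged response
#' covariates (`u_*_lag1`, `u_*_lag2`, `u_*_lag24`); both fits are returned so
#' their consistency can be checked. For the vegetation state V the
#' pre-closure phase is excluded (closure becomes the reference level): the
#' preference score is defined as one minus the mean pre-closure `u_V`, so
#' including that phase would be circular. Animal-years flagged unusable by
#' [usable_for_resource_models()] should be excluded from `table` beforehand.
#'
#' @param table resource model table (one row per fix, lag columns present).
#' @param state `"M"`, `"A"` or `"V"`.
#' @param random random-intercept grouping column.
#' @param nagq integration points passed to `glmer` (0 is fastest and
#'   adequate for direction checks; 1 is the default Laplace approximation).
#' @param lags lag horizons (hours) of the response covariates.
#' @return list with elements `with_lags` and `without_lags`, both `fs_fit`.
#' @export
fit_resource_glmm <- function(table, state = c("M", "A", "V"),
                              random = "ind", nagq = 1L, lags = c(1, 2, 24)) {
  state <- match.arg(state)
  resp <- paste0("u_", state)
  if (state == "V") {
    table <- table[table$phase != "pre", , drop = FALSE]
    table$phase <- droplevels(table$phase)
    table$phase <- stats::relevel(table$phase, ref = "closure")
  }
  y <- table[[resp]]
  if (!length(y) || all(y == 0) || all(y == 1))
    fs_stop(sprintf("response %s is degenerate (all %d)", resp,
                    if (length(y) && all(y == 1)) 1 else 0), "fs_degenerate")
  base <- c("phase", "h_fs", "phase:h_fs", "sex", "phase:sex")
  lag_terms <- paste0(resp, "_lag", lags)
  lag_terms <- lag_terms[lag_terms %in% names(table)]
  with_lags <- fit_mixed_core(table, resp, c(base, lag_terms), random,
                              family = stats::binomial(), nagq = nagq)
  without_lags <- fit_mixed_core(table, resp, base, random,
                                 family = stats::binomial(), nagq = nagq)
  sep <- any(abs(with_lags$coefficients$estimate) > 15)
  if (sep) with_lags$messages <- c(with_lags$messages,
                                   "very large coefficients: possible separation")
  list(with_lags = with_lags, without_lags = without_lags)
}

#' Sensitivity of a fit to the random-effect grouping
#'
#' Refits the model with the animal (individual) as grouping factor instead of
#' the animal-year, and reports per-term agreement in coefficient sign and
#' significance. When every animal contributes a single year the two
#' groupings coincide and the fits are identical.
#'
#' @param fit an `fs_fit`.
#' @param table the model table; must contain an `animal_id` column.
#' @param group alternative grouping column (default `"animal_id"`).
#' @return list with `alternative` (the refit), and `agreement` (data.frame of
#'   per-coefficient signs under both groupings).
#' @export
random_effect_sensitivity <- function(fit, table, group = "animal_id") {
  if (!group %in% names(table))
    fs_stop(sprintf("column '%s' not present in the model table; cannot refit by animal",
                    group), "fs_bad_input")
  alt <- fit_mixed_core(table, fit$response, fit$terms, group, fit$family,
                        fit$nagq)
  a <- fit$coefficients; b <- alt$coefficients
  common <- intersect(a$coefficient, b$coefficient)
  agreement <- data.frame(
    coefficient = common,
    sign_original = sign(a$estimate[match(common, a$coefficient)]),
    sign_alternative = sign(b$estimate[match(common, b$coefficient)]),
    stringsAsFactors = FALSE)
  agreement$agrees <- agreement$sign_original == agreement$sign_alternative
  list(alternative = alt, agreement = agreement)
}
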