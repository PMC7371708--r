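# End-to-end analysis of a feeding-site closure experiment, plus the model
# table builders that bridge the spatial modules and the mixed models.

animal_meta <- function(fixes) {
  m <- unique(fixes[, intersect(c("animal_year_id", "animal_id", "sex", "year"),
                                names(fixes))])
  rownames(m) <- NULL
  m
}

#' Model table for isopleth areas
#'
#' One row per animal-year and phase at a fixed isopleth level; response is
#' the log-transformed area in hectares.
#'
#' @param areas data.frame `animal_year_id,phase,level,area_ha`.
#' @param h_fs preference scores from [compute_h_fs()].
#' @param meta data.frame `animal_year_id,animal_id,sex` (one row per
#'   animal-year).
#' @param level isopleth level to keep (0.95 or 0.50).
#' @return model table with `log_area`, `phase`, `h_fs`, `sex`, `ind`,
#'   `animal_id`.
#' @export
build_area_table <- function(areas, h_fs, meta, level = 0.95) {
  d <- areas[areas$level == level, , drop = FALSE]
  d$log_area <- log(d$area_ha)
  d$h_fs <- h_fs$h_fs[match(d$animal_year_id, h_fs$animal_year_id)]
  d$sex <- factor(meta$sex[match(d$animal_year_id, meta$animal_year_id)],
                  levels = c("F", "M"))
  d$ind <- d$animal_year_id
  d$animal_id <- meta$animal_id[match(d$animal_year_id, meta$animal_year_id)]
  d$phase <- factor(as.character(d$phase), levels = c("pre", "closure", "post"))
  d[!is.na(d$log_area) & !is.na(d$h_fs), , drop = FALSE]
}

#' Model table for space-use overlap
#'
#' One row per animal-year and phase contrast; response is the logit-
#' transformed volume of intersection (clamped as in [transform_movement()]).
#' The contrast factor references the pre-closure/closure pair.
#'
#' @param overlaps data.frame `animal_year_id,contrast,vi`.
#' @param h_fs,meta as in [build_area_table()].
#' @param eps logit clamp width.
#' @return model table with `logit_vi`, `contrast`, `h_fs`, `sex`, `ind`.
#' @export
build_overlap_table <- function(overlaps, h_fs, meta, eps = 1e-6) {
  d <- overlaps
  d$logit_vi <- logit_clamped(d$vi, eps)
  d$contrast <- factor(as.character(d$contrast),
                       levels = c("pre.closure", "closure.post", "pre.post"))
  d$h_fs <- h_fs$h_fs[match(d$animal_year_id, h_fs$animal_year_id)]
  d$sex <- factor(meta$sex[match(d$animal_year_id, meta$animal_year_id)],
                  levels = c("F", "M"))
  d$ind <- d$animal_year_id
  d$animal_id <- meta$animal_id[match(d$animal_year_id, meta$animal_year_id)]
  d[!is.na(d$logit_vi) & !is.na(d$h_fs), , drop = FALSE]
}

#' Model table for movement metrics
#'
#' One row per modelled step: complete steps only (no gap, defined turning
#' angle, all lagged step lengths available — the excluded row count is
#' attached as attribute `"n_excluded"`). Lag covariates enter on the log
#' scale with the same 1 m floor as the response.
#'
#' @param steps transformed, lag-augmented step series
#'   ([transform_movement()] then [lag_features()]).
#' @param h_fs,meta as in [build_area_table()].
#' @param lags lag horizons present in `steps`.
#' @param s_min floor (m) for log-scale lag covariates.
#' @return model table with `log_s`, `phi`, `phase`, `h_fs`, `sex`, lag
#'   columns `log_s_lag<k>`, `ind`.
#' @export
build_movement_table <- function(steps, h_fs, meta, lags = c(1, 2, 24),
                                 s_min = 1) {
  lag_cols <- paste0("s_lag", lags)
  ok <- !steps$gap & !is.na(steps$theta) & !is.na(steps$phase)
  for (col in lag_cols) ok <- ok & !is.na(steps[[col]])
  d <- steps[ok, , drop = FALSE]
  n_excl <- sum(!ok)
  for (k in lags)
    d[[paste0("log_s_lag", k)]] <- log(pmax(d[[paste0("s_lag", k)]], s_min))
  d$h_fs <- h_fs$h_fs[match(d$animal_year_id, h_fs$animal_year_id)]
  d$sex <- factor(as.character(d$sex), levels = c("F", "M"))
  d$ind <- d$animal_year_id
  if (!"animal_id" %in% names(d))
    d$animal_id <- meta$animal_id[match(d$animal_year_id, meta$animal_year_id)]
  d <- d[!is.na(d$h_fs), , drop = FALSE]
  attr(d, "n_excluded") <- n_excl
  d
}

#' Model table for resource-state use
#'
#' One row per retained fix of the usable animal-years, with the three binary
#' state indicators, their lags, phase, preference and sex.
#'
#' @param states lag-augmented state series ([classify_states()] then
#'   [lag_states()]).
#' @param h_fs,meta as in [build_area_table()].
#' @param usable output of [usable_for_resource_models()]; unusable
#'   animal-years are excluded (pass `NULL` to keep everything for a
#'   sensitivity rerun).
#' @param lags lag horizons present in `states`.
#' @return model table for [fit_resource_glmm()].
#' @export
build_resource_table <- function(states, h_fs, meta, usable = NULL,
                                 lags = c(1, 2, 24)) {
  d <- states
  if (!is.null(usable)) {
    keep_ids <- usable$animal_year_id[usable$usable]
    d <- d[d$animal_year_id %in% keep_ids, , drop = FALSE]
  }
  lag_cols <- as.vector(outer(c("u_M", "u_A", "u_V"), lags,
                              function(v, k) paste0(v, "_lag", k)))
  ok <- !is.na(d$phase)
  for (col in lag_cols) ok <- ok & !is.na(d[[col]])
  d <- d[ok, , drop = FALSE]
  d$h_fs <- h_fs$h_fs[match(d$animal_year_id, h_fs$animal_year_id)]
  d$sex <- factor(as.character(d$sex), levels = c("F", "M"))
  d$ind <- d$animal_year_id
  d$phase <- factor(as.character(d$phase), levels = c("pre", "closure", "post"))
  d[!is.na(d$h_fs), , drop = FALSE]
}

#' Analyse a feeding-site manipulation experiment
#'
#' Runs the full pipeline on a set of hourly GPS trajectories, feeding-site
#' coordinates and a phase schedule: phase truncation to a common duration;
#' step/turn computation and the population mean hourly displacement `l`;
#' identification of each animal-year's manipulated site; resource-state
#' classification at buffer `buffer_scale * l` with preference scores and the
#' buffer-scale sensitivity table; per-phase kernel utilization distributions
#' (bandwidth `l/2`), isopleth areas and volume-of-intersection overlaps; and
#' the staged mixed models for areas, overlap, movement and resource use,
#' with backward elimination of non-significant fixed effects.
#'
#' @param fixes fixes data.frame ([read_fixes()] schema).
#' @param sites sites data.frame ([read_sites()] schema).
#' @param schedule schedule data.frame ([read_schedule()] schema).
#' @param target_days common phase duration, days.
#' @param buffer_scale working buffer scale (multiple of `l`).
#' @param resolution UD grid resolution, metres.
#' @param alpha significance threshold for term dropping.
#' @param nagq integration points for the binomial models (0 = fast PIRLS
#'   fit, 1 = Laplace).
#' @param sensitivity_scales buffer scales for the sensitivity analysis
#'   (`NULL` to skip).
#' @param fit_models set `FALSE` to stop after the descriptive stages.
#' @param drop_terms set `FALSE` to keep full fixed-effect structures.
#' @return An object of class `fs_analysis`; see [print.fs_analysis()].
#' @export
analyze_experiment <- function(fixes, sites, schedule,
                               target_days = 14, buffer_scale = 1,
                               resolution = 10, alpha = 0.05, nagq = 1L,
                               sensitivity_scales = c(0.5, 1, 1.5, 2, 3, 4),
                               fit_models = TRUE, drop_terms = TRUE) {
  trunc <- truncate_phases(fixes, schedule, target_days)
  steps <- compute_steps(trunc)
  l <- mean_hourly_displacement(steps)
  meta <- animal_meta(fixes)

  ids <- unique(trunc$animal_year_id)
  roles <- data.frame(animal_year_id = ids, m_site_id = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    pre <- trunc[trunc$animal_year_id == ids[i] & trunc$phase == "pre", ]
    roles$m_site_id[i] <- tryCatch(
      assign_manipulated_site(pre, sites, radius = l),
      fs_no_fs_user = function(e) NA_character_)
  }

  states <- classify_states(trunc, sites, roles, buffer = buffer_scale * l)
  h_fs <- compute_h_fs(states)
  sens <- if (!is.null(sensitivity_scales))
    buffer_sensitivity(trunc, sites, roles, l, sensitivity_scales) else NULL
  usable <- usable_for_resource_models(states)

  bw <- l / 2
  su <- lapply(ids, function(id)
    phase_space_use(trunc[trunc$animal_year_id == id, ], resolution, bw))
  names(su) <- ids
  areas <- do.call(rbind, lapply(ids, function(id)
    cbind(animal_year_id = id, su[[id]]$areas)))
  overlaps <- do.call(rbind, lapply(ids, function(id)
    cbind(animal_year_id = id, su[[id]]$overlaps)))

  steps <- transform_movement(steps)
  steps <- lag_features(steps)
  states <- lag_states(states)

  out <- list(
    l = l, bandwidth = bw, buffer = buffer_scale * l,
    target_days = target_days, meta = meta, roles = roles,
    fixes = trunc, steps = steps, states = states,
    h_fs = h_fs, sensitivity = sens, usable = usable,
    areas = areas, overlaps = overlaps
  )

  if (fit_models) {
    tab_a95 <- build_area_table(areas, h_fs, meta, 0.95)
    tab_a50 <- build_area_table(areas, h_fs, meta, 0.50)
    tab_vi <- build_overlap_table(overlaps, h_fs, meta)
    tab_mv <- build_movement_table(steps, h_fs, meta)
    tab_rs <- build_resource_table(states, h_fs, meta, usable)
    base <- c("phase", "h_fs", "phase:h_fs", "sex", "phase:sex")
    vi_base <- c("contrast", "h_fs", "contrast:h_fs", "sex", "contrast:sex")
    lag_cov <- paste0("log_s_lag", c(1, 2, 24))

    fits <- list(
      area95 = fit_lmm(tab_a95, "log_area", base),
      area50 = fit_lmm(tab_a50, "log_area", base),
      overlap = fit_lmm(tab_vi, "logit_vi", vi_base),
      step = fit_lmm(tab_mv, "log_s", c(base, lag_cov)),
      turn = fit_lmm(tab_mv, "phi", c(base, lag_cov)),
      u_M = fit_resource_glmm(tab_rs, "M", nagq = nagq),
      u_A = fit_resource_glmm(tab_rs, "A", nagq = nagq),
      u_V = fit_resource_glmm(tab_rs, "V", nagq = nagq)
    )
    final <- fits
    if (drop_terms) {
      final$area95 <- drop_nonsignificant(fits$area95, tab_a95, alpha)
      final$area50 <- drop_nonsignificant(fits$area50, tab_a50, alpha)
      final$overlap <- drop_nonsignificant(fits$overlap, tab_vi, alpha)
      final$step <- drop_nonsignificant(fits$step, tab_mv, alpha,
                                        never_drop = lag_cov)
      final$turn <- drop_nonsignificant(fits$turn, tab_mv, alpha,
                                        never_drop = lag_cov)
    }
    out$tables <- list(area95 = tab_a95, area50 = tab_a50, overlap = tab_vi,
                       movement = tab_mv, resource = tab_rs)
    out$fits <- fits
    out$final <- final
  }
  class(out) <- "fs_analysis"
  out
}

# Headline descriptive summaries used by print() and the acceptance script.
analysis_headline <- function(x) {
  mean_by <- function(v, g) tapply(v, g, mean)
  area95 <- x$areas[x$areas$level == 0.95, ]
  area50 <- x$areas[x$areas$level == 0.50, ]
  steps <- x$steps[!x$steps$gap & !is.na(x$steps$phase), ]
  st <- x$states[!is.na(x$states$phase), ]
  use <- function(u) {
    per <- aggregate(st[[u]], list(phase = st$phase, id = st$animal_year_id), mean)
    tapply(per$x, per$phase, mean)
  }
  list(
    l = x$l,
    h_fs_mean = mean(x$h_fs$h_fs),
    h_fs_iqr = IQR(x$h_fs$h_fs),
    area95_by_phase = mean_by(area95$area_ha, area95$phase),
    area50_by_phase = mean_by(area50$area_ha, area50$phase),
    vi_by_contrast = mean_by(x$overlaps$vi, x$overlaps$contrast),
    step_by_phase = mean_by(steps$s, steps$phase),
    use_M = use("u_M"), use_A = use("u_A"), use_V = use("u_V")
  )
}

#' @export
print.fs_analysis <- function(x, ...) {
  h <- analysis_headline(x)
  cat("Feeding-site manipulation analysis\n")
  cat(sprintf("  %d animal-years | %d retained fixes | phases truncated to %g days\n",
              nrow(x$meta), nrow(x$fixes), x$target_days))
  cat(sprintf("  mean hourly displacement l = %.1f m | buffer %.1f m | bandwidth %.1f m\n",
              x$l, x$buffer, x$bandwidth))
  cat(sprintf("  preference h_FS: mean %.3f, IQR %.3f\n", h$h_fs_mean, h$h_fs_iqr))
  cat(sprintf("  home range (95%%), ha: pre %.2f | closure %.2f | post %.2f\n",
              h$area95_by_phase["pre"], h$area95_by_phase["closure"],
              h$area95_by_phase["post"]))
  cat(sprintf("  core area (50%%), ha:  pre %.2f | closure %.2f | post %.2f\n",
              h$area50_by_phase["pre"], h$area50_by_phase["closure"],
              h$area50_by_phase["post"]))
  cat(sprintf("  overlap VI: pre/closure %.3f | closure/post %.3f | pre/post %.3f\n",
              h$vi_by_contrast["pre.closure"], h$vi_by_contrast["closure.post"],
              h$vi_by_contrast["pre.post"]))
  cat(sprintf("  step length, m: pre %.1f | closure %.1f | post %.1f\n",
              h$step_by_phase["pre"], h$step_by_phase["closure"],
              h$step_by_phase["post"]))
  cat(sprintf("  use of M: pre %.2f | closure %.2f | post %.2f\n",
              h$use_M["pre"], h$use_M["closure"], h$use_M["post"]))
  cat(sprintf("  use of A: pre %.2f | closure %.2f | post %.2f\n",
              h$use_A["pre"], h$use_A["closure"], h$use_A["post"]))
  cat(sprintf("  use of V: pre %.2f | closure %.2f | post %.2f\n",
              h$use_V["pre"], h$use_V["closure"], h$use_V["post"]))
  if (!is.null(x$final))
    cat(sprintf("  fitted models: %s\n", paste(names(x$final), collapse = ", ")))
  invisible(x)
}

#' @export
summary.fs_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$final)) {
    for (nm in c("area95", "area50", "overlap", "step", "turn")) {
      cat("\n==", nm, "==\n")
      print(object$final[[nm]])
    }
    for (nm in c("u_M", "u_A", "u_V")) {
      cat("\n==", nm, "(with lags) ==\n")
      print(object$final[[nm]]$with_lags)
    }
  }
  invisible(object)
}
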