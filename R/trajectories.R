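#' Read GPS fixes from CSV
#'
#' Reads an hourly GPS fix table (schema:
#' `animal_year_id,animal_id,sex,timestamp,x,y`, optional `year`; timestamps
#' ISO-8601 UTC; coordinates in projected metres) and validates it: required
#' columns present, coordinates finite, sex codes in `{F, M}`, timestamps
#' parseable, strictly increasing and free of duplicates within each
#' animal-year. Rows are returned sorted by animal-year and time. A gap report
#' (number of missing hourly slots per animal-year) is attached as attribute
#' `"gap_report"`.
#'
#' @param path path to the fixes CSV.
#' @param nominal_interval_hours nominal fix interval, hours.
#' @return data.frame of fixes with POSIXct `timestamp`.
#' @export
read_fixes <- function(path, nominal_interval_hours = 1) {
  if (!file.exists(path)) fs_stop(sprintf("file '%s' not found", path), "fs_io_error")
  # "F" in the sex column must not be read as a logical
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in intersect(c("x", "y", "year"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  req <- c("animal_year_id", "animal_id", "sex", "timestamp", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss))
    fs_stop(sprintf("fixes file missing columns: %s", paste(miss, collapse = ", ")),
            "fs_parse_error")
  bad_sex <- which(!df$sex %in% c("F", "M"))
  if (length(bad_sex))
    fs_stop(sprintf("unknown sex code '%s' at row %d", df$sex[bad_sex[1]], bad_sex[1]),
            "fs_parse_error")
  ts <- parse_utc(df$timestamp)
  if (anyNA(ts))
    fs_stop(sprintf("unparseable timestamp '%s' at row %d",
                    df$timestamp[which(is.na(ts))[1]], which(is.na(ts))[1]),
            "fs_parse_error")
  df$timestamp <- ts
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    fs_stop(sprintf("non-finite coordinate at row %d",
                    which(!is.finite(df$x) | !is.finite(df$y))[1]), "fs_parse_error")
  df <- df[order(df$animal_year_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  gaps <- integer(0)
  for (id in unique(df$animal_year_id)) {
    t <- df$timestamp[df$animal_year_id == id]
    d <- diff(as.numeric(t)) / 3600
    if (any(d == 0))
      fs_stop(sprintf("duplicated timestamp in animal-year '%s'", id), "fs_parse_error")
    if (any(d < 0))
      fs_stop(sprintf("non-monotone timestamps in animal-year '%s'", id), "fs_parse_error")
    if (any(d %% nominal_interval_hours != 0))
      fs_stop(sprintf("inter-fix gap not a multiple of the nominal interval in '%s'", id),
              "fs_parse_error")
    gaps[id] <- sum(d / nominal_interval_hours - 1)
  }
  attr(df, "gap_report") <- gaps
  attr(df, "nominal_interval_hours") <- nominal_interval_hours
  df
}

#' Write GPS fixes to CSV (inverse of [read_fixes()])
#' @param fixes data.frame of fixes with POSIXct `timestamp`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format_utc(out$timestamp)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the experimental phase schedule
#'
#' Schema: `animal_year_id,pre_start,closure_start,post_start,post_end`
#' with optional `capture_x,capture_y,manipulated_site_id`. Instants are
#' ISO-8601 UTC and must be strictly ordered within each animal-year; phases
#' are contiguous and half-open `[start, end)`.
#'
#' @param path path to the schedule CSV.
#' @return data.frame with POSIXct boundary columns.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) fs_stop(sprintf("file '%s' not found", path), "fs_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_year_id", "pre_start", "closure_start", "post_start", "post_end")
  miss <- setdiff(req, names(df))
  if (length(miss))
    fs_stop(sprintf("schedule file missing columns: %s", paste(miss, collapse = ", ")),
            "fs_parse_error")
  for (col in c("pre_start", "closure_start", "post_start", "post_end")) {
    df[[col]] <- parse_utc(df[[col]])
    if (anyNA(df[[col]]))
      fs_stop(sprintf("unparseable instant in column '%s'", col), "fs_parse_error")
  }
  bad <- with(df, !(pre_start < closure_start & closure_start < post_start &
                      post_start < post_end))
  if (any(bad))
    fs_stop(sprintf("schedule not strictly ordered for animal-year '%s'",
                    df$animal_year_id[which(bad)[1]]), "fs_parse_error")
  df
}

#' Detect resettlement after capture
#'
#' After capture, ranging behaviour is disturbed; the first re-visitation of
#' the capture location is taken as the sign of resettlement in the original
#' range, and its timestamp is used as the onset of the pre-closure phase.
#' A fix is "at" the capture location when within `radius` metres of it
#' (closed disc). If the animal never leaves the radius, the first fix time is
#' returned; if it leaves and never returns, that animal-year is unusable and
#' an error of class `fs_no_resettlement` is signalled.
#'
#' @param fixes data.frame of fixes for one animal-year (ordered in time).
#' @param capture_location numeric `c(x, y)` in metres.
#' @param radius re-visitation radius in metres (conventionally the population
#'   mean hourly displacement `l`).
#' @return POSIXct timestamp of resettlement.
#' @export
detect_resettlement <- function(fixes, capture_location, radius) {
  stopifnot(radius > 0, length(capture_location) == 2)
  d <- dist_to_point(fixes$x, fixes$y, capture_location[1], capture_location[2])
  inside <- d <= radius
  if (!any(!inside)) return(fixes$timestamp[1])
  first_out <- which(!inside)[1]
  back <- which(inside & seq_along(inside) > first_out)
  if (!length(back))
    fs_stop("no re-visitation of the capture location found", "fs_no_resettlement")
  fixes$timestamp[back[1]]
}

#' Truncate experimental phases to a common duration
#'
#' Homogenises phase durations across animal-years to `target_days` by
#' removing initial excess positions of the pre-closure and closure phases and
#' terminal excess positions of the post-closure phase. Concretely, the
#' retained windows are: pre-closure `[closure_start - target, closure_start)`,
#' closure `[post_start - target, post_start)`, and post-closure
#' `[post_start, post_start + target)` (half-open, UTC). Any raw phase shorter
#' than the target is an error of class `fs_short_phase`. Retained fixes carry
#' a `phase` factor (`pre`, `closure`, `post`).
#'
#' @param fixes fixes data.frame (one or many animal-years).
#' @param schedule schedule data.frame as from [read_schedule()].
#' @param target_days common phase duration, days (default 14).
#' @return fixes restricted to the retained windows, with a `phase` column.
#' @export
truncate_phases <- function(fixes, schedule, target_days = 14) {
  target <- target_days * 86400
  out <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    sc <- schedule[i, ]
    id <- sc$animal_year_id
    raw <- c(difftime(sc$closure_start, sc$pre_start, units = "secs"),
             difftime(sc$post_start, sc$closure_start, units = "secs"),
             difftime(sc$post_end, sc$post_start, units = "secs"))
    if (any(as.numeric(raw) < target))
      fs_stop(sprintf("raw phase shorter than %g days for animal-year '%s'",
                      target_days, id), "fs_short_phase")
    fx <- fixes[fixes$animal_year_id == id, , drop = FALSE]
    t <- fx$timestamp
    phase <- rep(NA_character_, nrow(fx))
    phase[t >= sc$closure_start - target & t < sc$closure_start] <- "pre"
    phase[t >= sc$post_start - target & t < sc$post_start] <- "closure"
    phase[t >= sc$post_start & t < sc$post_start + target] <- "post"
    fx$phase <- phase
    out[[i]] <- fx[!is.na(phase), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$phase <- factor(res$phase, levels = c("pre", "closure", "post"))
  res
}

#' Compute step lengths and turning angles
#'
#' For each animal-year, hourly step lengths `s_t` (Euclidean distance between
#' successive relocations) and turning angles `theta_t` (signed angular
#' difference between successive headings, wrapped to `(-pi, pi]`,
#' counterclockwise positive). Steps spanning a temporal gap larger than the
#' nominal interval are flagged (`gap = TRUE`) and never enter turning-angle or
#' lag chains; their `s` is the displacement over the whole gap and is not an
#' hourly step. Zero-length steps have no defined heading: their `theta` is
#' missing and the previous non-zero heading is carried forward for the next
#' step's turn.
#'
#' @param fixes fixes data.frame, optionally phase-labelled by
#'   [truncate_phases()].
#' @param nominal_interval_hours nominal fix interval, hours.
#' @return data.frame with one row per step: `animal_year_id`, `t_end`
#'   (timestamp of the step's end fix), `slot` (hours since the animal's first
#'   fix), `s`, `theta`, `dt` (hours), `gap`, plus `phase`/`sex`/`animal_id`
#'   carried from the end fix when present.
#' @export
compute_steps <- function(fixes, nominal_interval_hours = 1) {
  parts <- split(fixes, fixes$animal_year_id)
  res <- lapply(parts, function(fx) {
    fx <- fx[order(fx$timestamp), , drop = FALSE]
    n <- nrow(fx)
    if (n < 2) return(NULL)
    dx <- diff(fx$x); dy <- diff(fx$y)
    dt <- diff(as.numeric(fx$timestamp)) / 3600
    s <- sqrt(dx^2 + dy^2)
    gap <- dt > nominal_interval_hours
    heading_raw <- atan2(dy, dx)          # undefined where s == 0
    heading <- heading_raw
    zero <- s == 0
    for (i in which(zero)) heading[i] <- if (i > 1) heading[i - 1] else NA_real_
    theta <- rep(NA_real_, n - 1)
    if (n >= 3) {
      for (i in 2:(n - 1)) {
        # a turn needs a defined heading for this step, a previous (possibly
        # carried) heading, and an unbroken hourly chain across both steps
        if (!zero[i] && !is.na(heading[i - 1]) && !gap[i] && !gap[i - 1])
          theta[i] <- wrap_angle(heading_raw[i] - heading[i - 1])
      }
    }
    out <- data.frame(
      animal_year_id = fx$animal_year_id[1],
      t_end = fx$timestamp[-1],
      slot = round((as.numeric(fx$timestamp[-1]) - as.numeric(fx$timestamp[1])) / 3600),
      s = s, theta = theta, dt = dt, gap = gap,
      stringsAsFactors = FALSE
    )
    for (col in c("phase", "sex", "animal_id", "year"))
      if (col %in% names(fx)) out[[col]] <- fx[[col]][-1]
    out
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

#' Transform movement metrics for linear modelling
#'
#' Adds `log_s = log(max(s, s_min))` and the logit-transformed absolute
#' turning angle `phi = logit(clamp(|theta| / pi, eps, 1 - eps))`. Turning
#' angles live on `(-pi, pi]`; dividing the absolute angle by `pi` maps it
#' onto `(0, 1)`, the domain the logit requires. Clamping by `eps` keeps the
#' transform total at the boundary values 0 and `pi`.
#'
#' @param steps step series from [compute_steps()].
#' @param eps clamp width in `(0, 0.5)` (default `1e-6`).
#' @param s_min floor (m) for the log step length (default 1 m).
#' @return `steps` with `log_s` and `phi` columns appended.
#' @export
transform_movement <- function(steps, eps = 1e-6, s_min = 1) {
  stopifnot(eps > 0, eps < 0.5)
  steps$log_s <- log(pmax(steps$s, s_min))
  steps$phi <- ifelse(is.na(steps$theta), NA_real_,
                      logit_clamped(abs(steps$theta) / pi, eps))
  steps
}

#' Attach lagged step-length covariates
#'
#' For each step at hour slot `t`, attaches the step length observed at
#' `t - k` for each lag `k` (default 1, 2 and 24 h). A lag is available only
#' when the source slot holds a complete modelled step: present, not spanning
#' a gap, and with a defined turning angle (so lag chains never reach across
#' missing fixes or the undefined first heading). Rows with any missing lag
#' are retained here but excluded (and counted) when the movement model table
#' is assembled.
#'
#' @param steps step series from [compute_steps()] / [transform_movement()].
#' @param lags integer lags in hours.
#' @return `steps` with `s_lag<k>` columns appended.
#' @export
lag_features <- function(steps, lags = c(1, 2, 24)) {
  parts <- split(seq_len(nrow(steps)), steps$animal_year_id)
  for (k in lags) steps[[paste0("s_lag", k)]] <- NA_real_
  for (rows in parts) {
    slot <- steps$slot[rows]
    complete <- !steps$gap[rows] & !is.na(steps$theta[rows])
    for (k in lags) {
      src <- match(slot - k, slot)
      ok <- !is.na(src) & complete[ifelse(is.na(src), 1L, src)]
      col <- paste0("s_lag", k)
      steps[[col]][rows[ok]] <- steps$s[rows[src[ok]]]
    }
  }
  if (max(steps$slot) < max(lags) + 1)
    warning("series shorter than the longest lag; model table will be empty")
  steps
}

#' Population mean hourly displacement
#'
#' The mean hourly step length `l` over all non-gap steps of all animal-years.
#' `l` sets the feeding-site buffer radius and, halved, the kernel bandwidth
#' of the utilization distributions.
#'
#' @param steps step series from [compute_steps()].
#' @return numeric scalar, metres.
#' @export
mean_hourly_displacement <- function(steps) {
  mean(steps$s[!steps$gap])
}
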