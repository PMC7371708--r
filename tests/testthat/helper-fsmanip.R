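# Shared fixtures, all generated in code. The default synthetic experiment
# (25 animal-years, three 14-day phases, hourly fixes) is simulated and
# analysed once per test run and cached for every file that needs it.

.fs_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fs_cache$bundle))
    .fs_cache$bundle <- simulate_experiment(sim_config(rng_seed = 101))
  .fs_cache$bundle
}

default_analysis <- function() {
  if (is.null(.fs_cache$analysis)) {
    b <- default_bundle()
    .fs_cache$analysis <- analyze_experiment(b$fixes, b$sites, b$schedule,
                                             nagq = 0L)
  }
  .fs_cache$analysis
}

true_preferences <- function(bundle) {
  vapply(bundle$truth, function(tr) tr$p_i, numeric(1))
}

# A minimal hourly trajectory from a coordinate matrix.
make_fixes <- function(xy, id = "T1", start = "2018-01-01 00:00:00",
                       sex = "F", phase = NULL) {
  xy <- as.matrix(xy)
  df <- data.frame(
    animal_year_id = id, animal_id = id, sex = sex, year = 2018L,
    timestamp = as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(nrow(xy)) - 1),
    x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
  if (!is.null(phase)) df$phase <- phase
  df
}

# A contiguous raw schedule with given phase lengths in days.
make_schedule <- function(id = "T1", start = "2018-01-01 00:00:00",
                          days = c(14, 14, 14)) {
  t0 <- as.POSIXct(start, tz = "UTC")
  b <- t0 + cumsum(c(0, days)) * 86400
  data.frame(animal_year_id = id, pre_start = b[1], closure_start = b[2],
             post_start = b[3], post_end = b[4], stringsAsFactors = FALSE)
}

# One small neighbourhood (an M site at the centre plus alternates) for
# driving simulate_animal_year directly.
make_neighbourhood <- function(n_alt = 3, spacing = 700) {
  ang <- seq(0, 2 * pi, length.out = n_alt + 1)[-(n_alt + 1)]
  data.frame(
    site_id = sprintf("S%02d", 0:n_alt),
    x = c(0, spacing * cos(ang)), y = c(0, spacing * sin(ang)),
    managed = TRUE, stringsAsFactors = FALSE)
}

# Brute-force all-pairs state classification oracle (M > A > V precedence,
# closed discs), deliberately written as an explicit loop.
brute_force_states <- function(fixes, sites, m_site_id, buffer) {
  managed <- sites[sites$managed, , drop = FALSE]
  out <- character(nrow(fixes))
  for (i in seq_len(nrow(fixes))) {
    in_m <- FALSE; in_a <- FALSE
    for (j in seq_len(nrow(managed))) {
      d <- sqrt((fixes$x[i] - managed$x[j])^2 + (fixes$y[i] - managed$y[j])^2)
      if (d <= buffer) {
        if (!is.na(m_site_id) && managed$site_id[j] == m_site_id) in_m <- TRUE
        else in_a <- TRUE
      }
    }
    out[i] <- if (in_m) "M" else if (in_a) "A" else "V"
  }
  out
}
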