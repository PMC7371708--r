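#' Configuration for a synthetic feeding-site manipulation experiment
#'
#' Builds the configuration object consumed by [generate_landscape()],
#' [simulate_animal_year()] and [simulate_experiment()]. Defaults reproduce the
#' design of a winter closure experiment on a home-ranging herbivore: hourly GPS
#' fixes, three experimental phases of about two weeks each (raw phase lengths
#' exceed the 14-day analysis window so that phase truncation has work to do),
#' one manipulated feeding site (M) per animal-year whose food access is
#' withdrawn during the closure phase, on average four alternate sites (A)
#' about 700 m from M, and inter-individual variation in feeding-site
#' preference drawn from a Beta distribution with mean 0.34.
#'
#' Movement is a three-mode biased correlated random walk (see
#' [simulate_animal_year()]). The per-mode step-length means (10 / 55 / 150 m
#' for attendance, foraging and relocation) and the remaining behavioural rates
#' are shipped as calibrated constants chosen so that the synthetic population
#' lands near the observed regime (~60 m mean hourly displacement, mean
#' feeding-site preference near 0.34, home ranges of tens of hectares); see
#' `scripts/calibrate.R` for the coarse search used.
#'
#' @param n_animal_years number of animal-year trajectories (default 25).
#' @param phase_days target analysis length of each phase, days.
#' @param raw_phase_extra_days maximum uniform surplus added to each raw phase
#'   beyond `phase_days`; raw phase lengths are `phase_days + U(0, extra)`.
#' @param fix_interval_hours nominal GPS fix interval, hours.
#' @param n_alt_sites_mean mean number of alternate feeding sites per
#'   animal-year (truncated-Poisson, at least 1).
#' @param site_spacing_mean,site_spacing_sd mean and sd (m) of the M-to-A
#'   distance distribution (Gaussian, truncated below at `min_spacing`).
#' @param min_spacing minimum pairwise distance (m) allowed between sites.
#' @param pref_mean,pref_kappa mean and concentration (shape1 + shape2) of the
#'   Beta distribution of true feeding-site preference `p_i`.
#' @param attend_mean,forage_mean,relocate_mean gamma step-length means (m) of
#'   the three movement modes (gamma shape 2).
#' @param forage_rho turn-angle concentration of the foraging correlated
#'   random walk (mean cosine of the wrapped-normal turn distribution).
#' @param relocate_w weight given to the bearing-to-target when relocating
#'   (the rest goes to the previous heading).
#' @param home_bias_w maximum weight of the pull toward the home-range centre
#'   while foraging; the realised weight ramps up linearly with distance from
#'   the centre, saturating at `home_bias_range` metres.
#' @param home_bias_range distance (m) at which the homeward pull saturates.
#' @param attend_gain probability, per foraging hour and unit preference, of
#'   initiating a feeding-site visit (the realised probability is
#'   `attend_gain * p_i`).
#' @param attend_leave probability per hour of ending a feeding-site visit.
#' @param arrival_radius distance (m) to the target below which a relocating
#'   animal switches to attendance.
#' @param target_delta distance-decay scale (m) in the target-site choice
#'   weight `familiarity * exp(-d / target_delta) * availability`.
#' @param target_gate half-saturation constant of the overall attraction: an
#'   initiated visit proceeds with probability `S / (S + target_gate)` where
#'   `S` is the summed choice weight, so closing the familiar site depresses
#'   visit rates instead of merely redirecting them.
#' @param alt_familiarity familiarity weight of alternate sites relative to
#'   the manipulated site (which has familiarity 1).
#' @param closure_effect availability of M during the closure phase (0 =
#'   fully closed; 1 disables the manipulation).
#' @param dropout probability that any given fix after the first is lost
#'   (uniform thinning; lost fixes are never interpolated).
#' @param sex_ratio_f probability that an animal is female.
#' @param rng_seed integer seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return An object of class `fs_sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_animal_years = 2, rng_seed = 7)
#' cfg$phase_days
sim_config <- function(n_animal_years = 25,
                       phase_days = 14,
                       raw_phase_extra_days = 3,
                       fix_interval_hours = 1,
                       n_alt_sites_mean = 4,
                       site_spacing_mean = 700,
                       site_spacing_sd = 300,
                       min_spacing = 150,
                       pref_mean = 0.34,
                       pref_kappa = 2.5,
                       attend_mean = 10,
                       forage_mean = 55,
                       relocate_mean = 150,
                       forage_rho = 0.3,
                       relocate_w = 0.7,
                       home_bias_w = 0.5,
                       home_bias_range = 600,
                       attend_gain = 0.5,
                       attend_leave = 0.3,
                       arrival_radius = 25,
                       target_delta = 1000,
                       target_gate = 0.1,
                       alt_familiarity = 0.05,
                       closure_effect = 0,
                       dropout = 0,
                       sex_ratio_f = 0.68,
                       rng_seed = 1L) {
  cfg <- list(
    n_animal_years = as.integer(n_animal_years),
    phase_days = phase_days,
    raw_phase_extra_days = raw_phase_extra_days,
    fix_interval_hours = fix_interval_hours,
    n_alt_sites_mean = n_alt_sites_mean,
    site_spacing_mean = site_spacing_mean,
    site_spacing_sd = site_spacing_sd,
    min_spacing = min_spacing,
    pref_mean = pref_mean,
    pref_kappa = pref_kappa,
    attend_mean = attend_mean,
    forage_mean = forage_mean,
    relocate_mean = relocate_mean,
    forage_rho = forage_rho,
    relocate_w = relocate_w,
    home_bias_w = home_bias_w,
    home_bias_range = home_bias_range,
    attend_gain = attend_gain,
    attend_leave = attend_leave,
    arrival_radius = arrival_radius,
    target_delta = target_delta,
    target_gate = target_gate,
    alt_familiarity = alt_familiarity,
    closure_effect = closure_effect,
    dropout = dropout,
    sex_ratio_f = sex_ratio_f,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "fs_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$phase_days < 1) fs_stop("phase_days must be at least 1 day", "fs_bad_config")
  dists <- c(cfg$site_spacing_mean, cfg$min_spacing, cfg$attend_mean,
             cfg$forage_mean, cfg$relocate_mean, cfg$arrival_radius,
             cfg$target_delta)
  if (any(!is.finite(dists)) || any(dists <= 0))
    fs_stop("all distances must be finite and positive", "fs_bad_config")
  if (cfg$pref_mean < 0 || cfg$pref_mean > 1)
    fs_stop("pref_mean must lie in [0, 1]", "fs_bad_config")
  if (cfg$n_alt_sites_mean < 1)
    fs_stop("n_alt_sites_mean must be at least 1", "fs_bad_config")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    fs_stop("dropout must lie in [0, 1)", "fs_bad_config")
  invisible(cfg)
}

#' Generate the synthetic feeding-site landscape
#'
#' Lays out one neighbourhood per animal-year on a featureless plane:
#' a home-range centre, one candidate manipulated site (M) close to the centre,
#' and a truncated-Poisson number of alternate sites (A) placed at
#' Gaussian-distributed distances (default mean 700 m, sd 300 m) from M in
#' uniform directions. Pairwise distances within a neighbourhood respect
#' `config$min_spacing`; neighbourhoods are spaced kilometres apart so that
#' animals never interact. All sites are managed (provisioned); the M/A role
#' split is an animal-level attribute recovered downstream from the data.
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed; defaults to `config$rng_seed`.
#' @return A list with `sites` (data.frame: `site_id`, `x`, `y`, `managed`,
#'   `animal_year_id`), `centres` (data.frame of home-range centres with the
#'   true M site id per animal-year).
#' @export
generate_landscape <- function(config, seed = config$rng_seed) {
  set.seed(seed)
  n <- config$n_animal_years
  grid_n <- ceiling(sqrt(n))
  spacing_km <- 10000  # neighbourhood spacing, m; animals never meet
  ids <- sprintf("AY%02d", seq_len(n))
  sites_list <- vector("list", n)
  centres <- data.frame(animal_year_id = ids, cx = NA_real_, cy = NA_real_,
                        m_site_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cx <- ((i - 1) %% grid_n) * spacing_km
    cy <- ((i - 1) %/% grid_n) * spacing_km
    nbhd <- place_neighbourhood_sites(config, cx, cy, prefix = ids[i])
    nbhd$animal_year_id <- ids[i]
    sites_list[[i]] <- nbhd
    centres$cx[i] <- cx
    centres$cy[i] <- cy
    centres$m_site_id[i] <- nbhd$site_id[1]
  }
  sites <- do.call(rbind, sites_list)
  rownames(sites) <- NULL
  list(sites = sites, centres = centres)
}

# Place the M candidate plus alternates for one neighbourhood. Rejection
# sampling enforces the minimum pairwise spacing; persistent failure is an
# explicit error (infeasible spacing for the requested geometry).
place_neighbourhood_sites <- function(config, cx, cy, prefix) {
  # M sits near the home-range centre
  ang <- runif(1, -pi, pi)
  d_m <- abs(rnorm(1, 150, 50))
  mx <- cx + d_m * cos(ang)
  my <- cy + d_m * sin(ang)
  n_alt <- max(1L, rpois(1, config$n_alt_sites_mean))
  xs <- mx; ys <- my
  for (k in seq_len(n_alt)) {
    ok <- FALSE
    for (tries in 1:200) {
      a <- runif(1, -pi, pi)
      d <- rnorm(1, config$site_spacing_mean, config$site_spacing_sd)
      if (d < config$min_spacing) next
      nx <- mx + d * cos(a)
      ny <- my + d * sin(a)
      if (all(sqrt((xs - nx)^2 + (ys - ny)^2) >= config$min_spacing)) {
        xs <- c(xs, nx); ys <- c(ys, ny); ok <- TRUE; break
      }
    }
    if (!ok) fs_stop(
      sprintf("could not place %d sites with min spacing %.0f m", n_alt + 1,
              config$min_spacing), "fs_infeasible_spacing")
  }
  data.frame(
    site_id = sprintf("%s_S%02d", prefix, seq_along(xs)),
    x = xs, y = ys, managed = TRUE, stringsAsFactors = FALSE
  )
}

# Availability of a site at a given phase under the closure manipulation.
site_availability <- function(site_ids, m_site_id, phase, closure_effect) {
  av <- rep(1, length(site_ids))
  if (phase == "closure") av[site_ids == m_site_id] <- closure_effect
  av
}

#' Simulate one animal-year trajectory
#'
#' Hourly positions from a three-mode movement process:
#' \describe{
#'   \item{ATTEND}{small steps (gamma, mean `attend_mean`) that hover around
#'     the current target feeding site.}
#'   \item{FORAGE}{a correlated random walk (gamma mean `forage_mean`, turn
#'     concentration `forage_rho`) with a linear bias toward the home-range
#'     centre that strengthens with distance.}
#'   \item{RELOCATE}{directed travel (gamma mean `relocate_mean`) whose heading
#'     is the circular weighted mean of the previous heading and the bearing to
#'     the target site.}
#' }
#' A foraging animal initiates a feeding-site visit with probability
#' `attend_gain * p_i` per hour; the target is drawn with weight
#' `familiarity * exp(-distance / target_delta) * availability`, familiarity
#' being maximal for the manipulated site M. During the closure phase the
#' availability of M is `config$closure_effect` (0 by default), diverting
#' high-preference animals to alternate sites or the vegetation matrix;
#' post-closure, restored availability and familiarity drive the return to M.
#'
#' @param sites data.frame of this animal's feeding sites
#'   (`site_id`, `x`, `y`, `managed`).
#' @param p_i true feeding-site preference in `[0, 1]`.
#' @param schedule one-row data.frame with POSIXct `pre_start`,
#'   `closure_start`, `post_start`, `post_end` (contiguous raw phases).
#' @param config an [sim_config()] object.
#' @param seed integer seed for this trajectory.
#' @param m_site_id site id of the true manipulated site; defaults to the
#'   first site.
#' @param centre home-range centre `c(x, y)`; defaults to the M location.
#' @return list with `fixes` (data.frame `timestamp`, `x`, `y`) and `truth`
#'   (list: `p_i`, `centre`, `m_site_id`, `mode` per fix).
#' @export
simulate_animal_year <- function(sites, p_i, schedule, config, seed,
                                 m_site_id = sites$site_id[1],
                                 centre = NULL) {
  if (!is.finite(p_i) || p_i < 0 || p_i > 1)
    fs_stop("p_i must lie in [0, 1]", "fs_bad_config")
  b <- as.numeric(c(schedule$pre_start, schedule$closure_start,
                    schedule$post_start, schedule$post_end))
  if (any(diff(b) <= 0))
    fs_stop("phase schedule must be strictly ordered and contiguous", "fs_bad_schedule")
  set.seed(seed)
  if (is.null(centre)) {
    centre <- c(sites$x[match(m_site_id, sites$site_id)],
                sites$y[match(m_site_id, sites$site_id)])
  }
  step_h <- config$fix_interval_hours
  times <- seq(schedule$pre_start, schedule$post_end - 1, by = step_h * 3600)
  n <- length(times)
  phase <- ifelse(times < schedule$closure_start, "pre",
                  ifelse(times < schedule$post_start, "closure", "post"))

  x <- numeric(n); y <- numeric(n); mode <- character(n)
  # start near the centre, foraging
  x[1] <- centre[1] + rnorm(1, 0, 100)
  y[1] <- centre[2] + rnorm(1, 0, 100)
  mode[1] <- "FORAGE"
  heading <- runif(1, -pi, pi)
  target <- NA_integer_  # row index into sites
  cur <- mode[1]
  turn_sd <- sqrt(-2 * log(config$forage_rho))
  gshape <- 2

  for (t in 2:n) {
    ph <- phase[t]
    avail <- site_availability(sites$site_id, m_site_id, ph, config$closure_effect)
    # mode transitions
    if (cur == "ATTEND") {
      if (is.na(target) || avail[target] <= 0 || runif(1) < config$attend_leave) {
        cur <- "FORAGE"; target <- NA_integer_
      }
    } else if (cur == "FORAGE") {
      if (runif(1) < min(1, config$attend_gain * p_i)) {
        fam <- ifelse(sites$site_id == m_site_id, 1, config$alt_familiarity)
        d <- sqrt((sites$x - x[t - 1])^2 + (sites$y - y[t - 1])^2)
        w <- fam * exp(-d / config$target_delta) * avail
        S <- sum(w)
        # the visit goes ahead with probability S / (S + gate): when the most
        # familiar site is unavailable the total attraction drops and many
        # would-be visits dissolve into matrix foraging
        if (S > 0 && runif(1) < S / (S + config$target_gate)) {
          target <- sample.int(nrow(sites), 1, prob = w)
          cur <- "RELOCATE"
        }
      }
    } else if (cur == "RELOCATE") {
      if (is.na(target) || avail[target] <= 0) { cur <- "FORAGE"; target <- NA_integer_ }
    }

    # take one hourly step
    if (cur == "ATTEND") {
      len <- rgamma(1, gshape, scale = config$attend_mean / gshape)
      d_site <- sqrt((sites$x[target] - x[t - 1])^2 + (sites$y[target] - y[t - 1])^2)
      bear <- atan2(sites$y[target] - y[t - 1], sites$x[target] - x[t - 1])
      w <- min(1, d_site / (3 * config$attend_mean))
      heading <- circ_wmean(bear, runif(1, -pi, pi), w)
      len <- min(len, d_site + config$attend_mean)  # never overshoot far
    } else if (cur == "RELOCATE") {
      d_site <- sqrt((sites$x[target] - x[t - 1])^2 + (sites$y[target] - y[t - 1])^2)
      bear <- atan2(sites$y[target] - y[t - 1], sites$x[target] - x[t - 1])
      heading <- circ_wmean(bear, heading, config$relocate_w)
      len <- rgamma(1, gshape, scale = config$relocate_mean / gshape)
      if (len >= d_site) {  # arrive
        len <- d_site
        heading <- bear
        cur_next <- "ATTEND"
      } else cur_next <- "RELOCATE"
    } else {  # FORAGE
      turn <- rnorm(1, 0, turn_sd)
      crw_heading <- wrap_angle(heading + turn)
      d_home <- sqrt((centre[1] - x[t - 1])^2 + (centre[2] - y[t - 1])^2)
      bear_home <- atan2(centre[2] - y[t - 1], centre[1] - x[t - 1])
      w_home <- config$home_bias_w * min(1, d_home / config$home_bias_range)
      heading <- circ_wmean(bear_home, crw_heading, w_home)
      len <- rgamma(1, gshape, scale = config$forage_mean / gshape)
    }
    x[t] <- x[t - 1] + len * cos(heading)
    y[t] <- y[t - 1] + len * sin(heading)
    if (cur == "RELOCATE") {
      if (cur_next == "ATTEND") { x[t] <- sites$x[target]; y[t] <- sites$y[target] }
      cur <- cur_next
    }
    mode[t] <- cur
  }

  fixes <- data.frame(timestamp = times, x = x, y = y, stringsAsFactors = FALSE)
  keep <- rep(TRUE, n)
  if (config$dropout > 0) keep[-1] <- runif(n - 1) >= config$dropout
  truth <- list(p_i = p_i, centre = centre, m_site_id = m_site_id,
                mode = mode[keep], n_slots = n,
                availability = list(pre = 1, closure = config$closure_effect,
                                    post = 1))
  list(fixes = fixes[keep, , drop = FALSE], truth = truth)
}

#' Simulate a complete synthetic experiment
#'
#' Generates the landscape, per-animal preferences, phase schedules and hourly
#' trajectories for `config$n_animal_years` animal-years, and (optionally)
#' writes the pipeline's three CSV inputs plus a ground-truth JSON and a run
#' manifest. Some individuals are reused across years (as in a multi-winter
#' field campaign) so that animal-level and animal-year-level grouping differ.
#'
#' @param config an [sim_config()] object.
#' @param out_dir optional directory; when given, writes `fixes.csv`,
#'   `sites.csv`, `schedule.csv`, `ground_truth.json` and `manifest.json`.
#' @return Invisibly, a list with `fixes`, `sites`, `schedule` (data.frames),
#'   `truth` (per-animal-year list), and `config`.
#' @export
#' @examples
#' bundle <- simulate_experiment(sim_config(n_animal_years = 2, rng_seed = 42))
#' nrow(bundle$schedule)
simulate_experiment <- function(config, out_dir = NULL) {
  set.seed(config$rng_seed)
  n <- config$n_animal_years
  land <- generate_landscape(config, seed = config$rng_seed)
  set.seed(config$rng_seed + 1L)

  # animals: roughly 30% of individuals are manipulated in two winters
  n_repeat <- floor(n * 0.28)
  n_animals <- n - n_repeat
  animal_idx <- c(seq_len(n_animals), seq_len(max(1, n_repeat)))[seq_len(n)]
  animal_ids <- sprintf("A%02d", animal_idx)
  sex_by_animal <- ifelse(runif(n_animals) < config$sex_ratio_f, "F", "M")
  years <- ifelse(duplicated(animal_ids), 2019L, 2018L)

  p_i <- rbeta(n, config$pref_mean * config$pref_kappa,
               (1 - config$pref_mean) * config$pref_kappa)
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  sched_list <- vector("list", n)
  fixes_list <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- land$centres$animal_year_id[i]
    yr <- years[i]
    t0 <- as.POSIXct(sprintf("%d-01-10 00:00:00", yr), tz = "UTC") +
      3600 * 24 * sample.int(20, 1)
    len <- config$phase_days + runif(3, 0, config$raw_phase_extra_days)
    b <- t0 + c(0, cumsum(round(len * 24))) * 3600
    sched <- data.frame(
      animal_year_id = id,
      pre_start = b[1], closure_start = b[2], post_start = b[3], post_end = b[4],
      stringsAsFactors = FALSE
    )
    own <- land$sites[land$sites$animal_year_id == id, , drop = FALSE]
    sim <- simulate_animal_year(
      own, p_i[i], sched, config, seed = seeds[i],
      m_site_id = land$centres$m_site_id[i],
      centre = c(land$centres$cx[i], land$centres$cy[i])
    )
    sched$capture_x <- sim$fixes$x[1]
    sched$capture_y <- sim$fixes$y[1]
    sched$manipulated_site_id <- land$centres$m_site_id[i]
    sched_list[[i]] <- sched
    fx <- sim$fixes
    fx <- data.frame(animal_year_id = id, animal_id = animal_ids[i],
                     sex = sex_by_animal[animal_idx[i]], year = yr,
                     timestamp = fx$timestamp, x = fx$x, y = fx$y,
                     stringsAsFactors = FALSE)
    fixes_list[[i]] <- fx
    truth[[i]] <- c(list(animal_year_id = id), sim$truth)
  }
  fixes <- do.call(rbind, fixes_list)
  schedule <- do.call(rbind, sched_list)
  rownames(fixes) <- rownames(schedule) <- NULL
  names(truth) <- schedule$animal_year_id
  bundle <- list(fixes = fixes, sites = land$sites[, c("site_id", "x", "y", "managed")],
                 site_owner = land$sites$animal_year_id,
                 schedule = schedule, truth = truth, config = config)
  if (!is.null(out_dir)) write_experiment(bundle, out_dir)
  invisible(bundle)
}

#' Write a simulated experiment bundle to disk
#'
#' Emits `fixes.csv`, `sites.csv` and `schedule.csv` in the pipeline's input
#' schemas, plus `ground_truth.json` (true preference, M identity and mode
#' counts per animal-year) and `manifest.json` (configuration and seed).
#'
#' @param bundle result of [simulate_experiment()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the vector of written paths.
#' @export
write_experiment <- function(bundle, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    fs_stop(sprintf("cannot create output directory '%s'", out_dir), "fs_io_error")
  fx <- bundle$fixes
  fx$timestamp <- format_utc(fx$timestamp)
  p1 <- file.path(out_dir, "fixes.csv")
  write.csv(fx, p1, row.names = FALSE, quote = FALSE)
  p2 <- file.path(out_dir, "sites.csv")
  write.csv(bundle$sites, p2, row.names = FALSE, quote = FALSE)
  sc <- bundle$schedule
  for (col in c("pre_start", "closure_start", "post_start", "post_end"))
    sc[[col]] <- format_utc(sc[[col]])
  p3 <- file.path(out_dir, "schedule.csv")
  write.csv(sc, p3, row.names = FALSE, quote = FALSE)
  gt <- lapply(bundle$truth, function(tr) list(
    p_i = tr$p_i, m_site_id = tr$m_site_id,
    centre = as.numeric(tr$centre),
    mode_counts = as.list(table(tr$mode))
  ))
  p4 <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(gt, p4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- unclass(bundle$config)
  p5 <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(config = cfg, seed = bundle$config$rng_seed),
                       p5, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3, p4, p5))
}
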