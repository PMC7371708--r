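#' Read feeding-site coordinates
#'
#' Schema: `site_id,x,y,managed` (projected metres; `managed` logical — a site
#' provisioned during the study). Only managed sites can take the M or A role.
#'
#' @param path path to the sites CSV.
#' @return data.frame of sites.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) fs_stop(sprintf("file '%s' not found", path), "fs_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "x", "y", "managed")
  miss <- setdiff(req, names(df))
  if (length(miss))
    fs_stop(sprintf("sites file missing columns: %s", paste(miss, collapse = ", ")),
            "fs_parse_error")
  df$managed <- as.logical(df$managed)
  df$site_id <- as.character(df$site_id)
  df
}

#' Identify the manipulated feeding site of an animal-year
#'
#' The manipulated site (M) is the managed site with the largest number of
#' pre-closure fixes within `radius` metres — the site the animal is most
#' familiar with. Ties are broken by the smaller mean distance to the
#' pre-closure fixes, then lexicographically by `site_id`, so the choice is
#' deterministic. If no managed site holds a single fix within the radius the
#' animal is not a feeding-site user and an error of class `fs_no_fs_user` is
#' signalled.
#'
#' @param pre_fixes data.frame of this animal-year's pre-closure fixes.
#' @param sites data.frame of sites; only `managed` rows are considered.
#' @param radius attendance radius in metres (conventionally `l`).
#' @return the selected `site_id`.
#' @export
assign_manipulated_site <- function(pre_fixes, sites, radius) {
  stopifnot(radius > 0)
  sites <- sites[sites$managed, , drop = FALSE]
  if (!nrow(sites)) fs_stop("no managed sites supplied", "fs_bad_input")
  counts <- integer(nrow(sites)); meand <- numeric(nrow(sites))
  for (j in seq_len(nrow(sites))) {
    d <- dist_to_point(pre_fixes$x, pre_fixes$y, sites$x[j], sites$y[j])
    counts[j] <- sum(d <= radius)
    meand[j] <- mean(d)
  }
  if (all(counts == 0))
    fs_stop("no pre-closure fixes within radius of any managed site (no FS user)",
            "fs_no_fs_user")
  ord <- order(-counts, meand, sites$site_id)
  sites$site_id[ord[1]]
}

#' Classify fixes into resource states M / A / V
#'
#' Intersects relocations with three spatial domains: the manipulated feeding
#' site (M), alternate feeding sites (A — all other managed sites), and the
#' vegetation matrix (V — everything else). Sites become areas by buffering
#' their point coordinate by `buffer` metres (closed disc: distance equal to
#' the buffer counts as inside). Where buffers overlap, precedence is
#' M over A over V. Alongside the categorical state, the three binary
#' indicator series `u_M`, `u_A`, `u_V` are returned; they partition every
#' fix (`u_M + u_A + u_V = 1`).
#'
#' @param fixes fixes data.frame (any number of animal-years), typically
#'   phase-labelled.
#' @param sites sites data.frame.
#' @param roles data.frame `animal_year_id,m_site_id` giving each
#'   animal-year's manipulated site (`NA` allowed: no M domain, all managed
#'   sites count as A).
#' @param buffer buffer radius, metres.
#' @return `fixes` with `state` (factor M/A/V), `u_M`, `u_A`, `u_V` and
#'   `buffer` columns appended.
#' @export
classify_states <- function(fixes, sites, roles, buffer) {
  stopifnot(buffer > 0)
  managed <- sites[sites$managed, , drop = FALSE]
  out <- vector("list", length(unique(fixes$animal_year_id)))
  ids <- unique(fixes$animal_year_id)
  for (i in seq_along(ids)) {
    id <- ids[i]
    fx <- fixes[fixes$animal_year_id == id, , drop = FALSE]
    m_id <- roles$m_site_id[match(id, roles$animal_year_id)]
    in_m <- rep(FALSE, nrow(fx)); in_a <- rep(FALSE, nrow(fx))
    for (j in seq_len(nrow(managed))) {
      inside <- dist_to_point(fx$x, fx$y, managed$x[j], managed$y[j]) <= buffer
      if (!is.na(m_id) && managed$site_id[j] == m_id) in_m <- in_m | inside
      else in_a <- in_a | inside
    }
    state <- ifelse(in_m, "M", ifelse(in_a, "A", "V"))
    fx$state <- factor(state, levels = c("M", "A", "V"))
    fx$u_M <- as.integer(state == "M")
    fx$u_A <- as.integer(state == "A")
    fx$u_V <- as.integer(state == "V")
    fx$buffer <- buffer
    out[[i]] <- fx
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Feeding-site preference scores
#'
#' An animal-year's preference for feeding sites, `h_FS`, is the relative use
#' of feeding sites over natural vegetation during the (truncated) pre-closure
#' phase: the proportion of pre-closure fixes classified as either M or A.
#' Preference is evaluated per animal-year (repeat individuals get one score
#' per winter). Animal-years with no pre-closure fixes are an error of class
#' `fs_empty_phase`.
#'
#' @param states state series from [classify_states()] with a `phase` column.
#' @return data.frame `animal_year_id,h_fs,n_pre,buffer`.
#' @export
compute_h_fs <- function(states) {
  pre <- states[states$phase == "pre", , drop = FALSE]
  ids <- unique(states$animal_year_id)
  if (!nrow(pre)) fs_stop("no pre-closure fixes in state series", "fs_empty_phase")
  res <- lapply(ids, function(id) {
    p <- pre[pre$animal_year_id == id, , drop = FALSE]
    if (!nrow(p))
      fs_stop(sprintf("no pre-closure fixes for animal-year '%s'", id), "fs_empty_phase")
    data.frame(animal_year_id = id,
               h_fs = mean(p$state != "V"),
               n_pre = nrow(p),
               buffer = p$buffer[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Buffer-scale sensitivity of the preference score
#'
#' Recomputes `h_FS` for every animal-year at each buffer scale (multiples of
#' the population mean hourly displacement `l`) and summarises the across-
#' animal variability per scale. The scale maximising the interquartile range
#' of `h_FS` discriminates best between feeding-site users and non-users and
#' is flagged as the working definition (the conventional default remains
#' `1 * l`).
#'
#' @param fixes phase-labelled fixes.
#' @param sites sites data.frame.
#' @param roles role map data.frame (`animal_year_id,m_site_id`).
#' @param l population mean hourly displacement, metres.
#' @param scales buffer multipliers (default `c(0.5, 1, 1.5, 2, 3, 4)`).
#' @return list with `per_animal` (long data.frame
#'   `animal_year_id,scale,buffer,h_fs`), `summary`
#'   (`scale,buffer,iqr,mean`), and `best_scale` (IQR-maximising scale).
#' @export
buffer_sensitivity <- function(fixes, sites, roles, l,
                               scales = c(0.5, 1, 1.5, 2, 3, 4)) {
  per <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    st <- classify_states(fixes, sites, roles, buffer = scales[i] * l)
    h <- compute_h_fs(st)
    h$scale <- scales[i]
    per[[i]] <- h
  }
  per_animal <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(split(per_animal, per_animal$scale), function(d)
    data.frame(scale = d$scale[1], buffer = d$buffer[1],
               iqr = IQR(d$h_fs), mean = mean(d$h_fs))))
  rownames(summ) <- NULL
  list(per_animal = per_animal, summary = summ,
       best_scale = summ$scale[which.max(summ$iqr)])
}

#' Flag animal-years unusable for resource-use models
#'
#' The three-state resource-use models contrast M, A and V use; an animal-year
#' that never visited an alternate feeding site before the manipulation (zero
#' pre-closure A-state fixes) carries no information on the M-vs-A
#' compensation and is excluded (with its reason logged). A sensitivity rerun
#' with the exclusions retained is supported by ignoring the flag.
#'
#' @param states state series from [classify_states()] with `phase`.
#' @return data.frame `animal_year_id,usable,reason`.
#' @export
usable_for_resource_models <- function(states) {
  ids <- unique(states$animal_year_id)
  res <- lapply(ids, function(id) {
    p <- states[states$animal_year_id == id & states$phase == "pre", , drop = FALSE]
    ok <- sum(p$u_A) >= 1
    data.frame(animal_year_id = id, usable = ok,
               reason = if (ok) "" else "no alternate FS used",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Attach lagged resource-state indicators
#'
#' For each fix at hour slot `t`, attaches the binary indicator observed at
#' `t - k` (k in `lags`) for each of `u_M`, `u_A`, `u_V`. A lag is available
#' only when the source slot holds a retained fix; rows with missing lags are
#' dropped when the resource model table is assembled.
#'
#' @param states state series from [classify_states()].
#' @param lags integer lags in hours.
#' @return `states` with `u_M_lag<k>` (etc.) columns appended.
#' @export
lag_states <- function(states, lags = c(1, 2, 24)) {
  parts <- split(seq_len(nrow(states)), states$animal_year_id)
  for (v in c("u_M", "u_A", "u_V"))
    for (k in lags) states[[paste0(v, "_lag", k)]] <- NA_integer_
  for (rows in parts) {
    slot <- round(as.numeric(states$timestamp[rows]) / 3600)
    for (k in lags) {
      src <- match(slot - k, slot)
      ok <- !is.na(src)
      for (v in c("u_M", "u_A", "u_V")) {
        col <- paste0(v, "_lag", k)
        states[[col]][rows[ok]] <- states[[v]][rows[src[ok]]]
      }
    }
  }
  states
}
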