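# Internal numerical helpers shared across modules.

# Wrap an angle (radians) to (-pi, pi].
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

# Weighted circular mean of two angles; w is the weight on `a`.
circ_wmean <- function(a, b, w) {
  atan2(w * sin(a) + (1 - w) * sin(b), w * cos(a) + (1 - w) * cos(b))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# logit with total clamping; eps must be in (0, 0.5)
logit_clamped <- function(p, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.5)
  qlogis(clamp(p, eps, 1 - eps))
}

# Euclidean distance from points (x, y) to a single point (px, py)
dist_to_point <- function(x, y, px, py) sqrt((x - px)^2 + (y - py)^2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-8601 UTC timestamp formatting/parsing used by all CSV interfaces
format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_utc <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- is.na(t) & !is.na(s)
  if (any(bad)) {
    # tolerate a plain "YYYY-mm-dd HH:MM:SS" variant
    t2 <- as.POSIXct(s[bad], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
    t[bad] <- t2
  }
  t
}

# Condition constructor for explicit, classed failures
fs_stop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
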