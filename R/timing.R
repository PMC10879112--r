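#' Build a camera/SLM/LED synchronization scheme
#'
#' One camera exposure per pattern.  Within each exposure the SLM displays
#' the pattern (LED on), then, after a refresh gap, displays the inverted
#' pattern for an equal duration with the LED off: ferroelectric LCOS
#' pixels must be DC-balanced (every state followed by its inverse) to
#' avoid charge build-up, and the light source must be blanked during
#' refresh and inverted display so the camera only integrates the normal
#' pattern.  All times are integer microseconds.
#'
#' @param sequence_length Number of patterns (>= 1).
#' @param exposure Camera exposure per pattern, us.  Must be at least
#'   `2 * display + refresh`.
#' @param display Duration of the normal (and inverted) pattern display, us.
#' @param refresh SLM refresh gap between normal and inverted display, us.
#' @param led_guard Safety margin (us) by which each LED-on interval is
#'   kept strictly inside its normal-display interval.
#' @return An object of class `timing_scheme` with fields `events` (a
#'   data.frame: channel, state, pattern, t_start, duration),
#'   `sequence_length`, `period` (us per pattern).
#' @export
build_timing <- function(sequence_length, exposure, display, refresh,
                         led_guard = 1) {
  stopifnot(sequence_length >= 1)
  vals <- c(exposure, display, refresh, led_guard)
  if (any(vals <= 0) || any(vals != round(vals))) {
    stop("durations must be positive integer microseconds", call. = FALSE)
  }
  if (exposure < display) {
    stop("`exposure` must be at least `display`", call. = FALSE)
  }
  if (exposure < 2 * display + refresh) {
    stop(sprintf(paste0(
      "exposure (%d us) too short to contain pattern display, refresh and ",
      "DC-balancing inverted display (needs >= 2*display + refresh = %d us)"),
      exposure, 2 * display + refresh), call. = FALSE)
  }
  if (display <= 2 * led_guard) {
    stop("`display` must exceed twice the LED guard time", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(sequence_length) - 1L) {
    t0 <- i * exposure
    rows[[length(rows) + 1]] <- data.frame(
      channel = c("camera", "slm", "led", "slm", "slm"),
      state = c("expose", "display_normal", "on", "refresh",
                "display_inverted"),
      pattern = i,
      t_start = c(t0, t0, t0 + led_guard, t0 + display,
                  t0 + display + refresh),
      duration = c(exposure, display, display - 2 * led_guard, refresh,
                   display)
    )
  }
  events <- do.call(rbind, rows)
  events <- events[order(events$t_start, events$channel), ]
  rownames(events) <- NULL
  structure(list(events = events,
                 sequence_length = as.integer(sequence_length),
                 period = as.integer(exposure)),
            class = "timing_scheme")
}

#' @export
print.timing_scheme <- function(x, ...) {
  cat(sprintf("<timing_scheme> %d patterns, period %d us, %d events\n",
              x$sequence_length, x$period, nrow(x$events)))
  invisible(x)
}

intervals_overlap <- function(s1, d1, s2, d2) {
  s1 < s2 + d2 & s2 < s1 + d1
}

#' Validate a timing scheme
#'
#' Checks, and returns as data (not errors): per-channel non-overlap; DC
#' balance (equal normal and inverted display duration per pattern); every
#' LED-on interval contained in a normal-display interval; no LED-on
#' interval intersecting any refresh or inverted-display interval; every
#' pattern index present.
#'
#' @param scheme A `timing_scheme`.
#' @return A data.frame of violations (`type`, `detail`); zero rows iff the
#'   scheme is valid.
#' @export
validate_timing <- function(scheme) {
  stopifnot(inherits(scheme, "timing_scheme"))
  ev <- scheme$events
  out <- list()
  add <- function(type, detail) {
    out[[length(out) + 1]] <<- data.frame(type = type, detail = detail)
  }
  for (ch in unique(ev$channel)) {
    e <- ev[ev$channel == ch, ]
    e <- e[order(e$t_start), ]
    if (nrow(e) > 1) {
      bad <- which(e$t_start[-1] < (e$t_start + e$duration)[-nrow(e)])
      for (b in bad) {
        add("channel_overlap",
            sprintf("%s events at t=%d and t=%d overlap", ch,
                    e$t_start[b], e$t_start[b + 1]))
      }
    }
  }
  for (p in unique(ev$pattern)) {
    dn <- ev$duration[ev$pattern == p & ev$state == "display_normal"]
    di <- ev$duration[ev$pattern == p & ev$state == "display_inverted"]
    if (length(dn) != 1 || length(di) != 1 || dn != di) {
      add("dc_balance",
          sprintf("pattern %d: normal display %s us vs inverted %s us", p,
                  paste(dn, collapse = "/"), paste(di, collapse = "/")))
    }
  }
  led <- ev[ev$state == "on", ]
  normals <- ev[ev$state == "display_normal", ]
  blanked <- ev[ev$state %in% c("refresh", "display_inverted"), ]
  for (i in seq_len(nrow(led))) {
    contained <- any(led$t_start[i] >= normals$t_start &
                       led$t_start[i] + led$duration[i] <=
                       normals$t_start + normals$duration)
    if (!contained) {
      add("led_containment",
          sprintf("LED-on at t=%d not inside any normal display interval",
                  led$t_start[i]))
    }
    hit <- which(intervals_overlap(led$t_start[i], led$duration[i],
                                   blanked$t_start, blanked$duration))
    for (h in hit) {
      add("led_blanking",
          sprintf("LED-on at t=%d overlaps %s at t=%d", led$t_start[i],
                  blanked$state[h], blanked$t_start[h]))
    }
  }
  missing <- setdiff(seq_len(scheme$sequence_length) - 1L, unique(ev$pattern))
  for (m in missing) {
    add("missing_pattern", sprintf("pattern %d has no events", m))
  }
  if (length(out) == 0) {
    data.frame(type = character(0), detail = character(0))
  } else {
    do.call(rbind, out)
  }
}

#' Fraction of total sequence time with the LED on
#'
#' Photon-budget accounting: DC balancing costs at least half of the
#' exposure (the inverted display is dark), so the duty approaches 0.5 as
#' the refresh time becomes negligible and decreases as it grows.
#'
#' @param scheme A `timing_scheme`.
#' @return Fraction in `[0, 1]`.
#' @export
illumination_duty <- function(scheme) {
  stopifnot(inherits(scheme, "timing_scheme"))
  on_time <- sum(scheme$events$duration[scheme$events$state == "on"])
  on_time / (scheme$period * scheme$sequence_length)
}

#' Export a timing scheme as a delimited event table
#'
#' @param scheme A `timing_scheme`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_timing <- function(scheme, path) {
  utils::write.table(scheme$events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
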