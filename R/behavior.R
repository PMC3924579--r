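#' Shock-zone specification
#'
#' An angular sector fixed in room coordinates on the rotating arena.
#'
#' @param center_angle_deg sector center, degrees, room frame.
#' @param width_deg sector width, degrees (default 60).
#' @export
zone_spec <- function(center_angle_deg = 0, width_deg = 60) {
  if (width_deg <= 0 || width_deg > 360) stop_config("width_deg must be in (0, 360]")
  structure(list(center_angle_deg = center_angle_deg, width_deg = width_deg,
                 frame = "room"), class = "zone_spec")
}

# signed angular difference in degrees, wrapped to (-180, 180]
angle_diff_deg <- function(a, b) ((a - b + 180) %% 360) - 180

#' Count shock-zone entrances
#'
#' Counts transitions from outside to inside the room-frame angular sector.
#' An entrance is only re-armed after the animal has spent at least
#' `debounce_s` continuously outside the zone, so tracker jitter at the
#' sector edge does not inflate the count.  A trial that starts inside the
#' zone counts that initial presence as one entrance.
#'
#' @param pos position data.frame with `t_s`, `x_cm`, `y_cm` (room frame) and
#'   optionally `valid`.
#' @param zone a [zone_spec()].
#' @param debounce_s minimum continuous outside time before the next entrance
#'   can be scored (default 0.5 s).
#' @return integer entrance count.
#' @export
count_entrances <- function(pos, zone, debounce_s = 0.5) {
  stopifnot(inherits(zone, "zone_spec"))
  if (nrow(pos) == 0) stop_data("empty position series")
  if ("valid" %in% names(pos)) pos <- pos[pos$valid, , drop = FALSE]
  if (nrow(pos) == 0) stop_data("no valid position samples")
  ang <- atan2(pos$y_cm, pos$x_cm) * 180 / pi
  inside <- abs(angle_diff_deg(ang, zone$center_angle_deg)) <= zone$width_deg / 2
  t <- pos$t_s
  entrances <- 0L
  armed <- TRUE
  outside_since <- t[1]
  was_inside <- FALSE
  for (i in seq_along(inside)) {
    if (inside[i]) {
      if (armed) {
        entrances <- entrances + 1L
        armed <- FALSE
      }
      was_inside <- TRUE
    } else {
      if (was_inside) {
        outside_since <- t[i]
        was_inside <- FALSE
      }
      if (!armed && (t[i] - outside_since) >= debounce_s) armed <- TRUE
    }
  }
  entrances
}

#' Average locomotion speed
#'
#' Path length divided by elapsed time over valid samples; samples with
#' duplicated timestamps are skipped.
#'
#' @param pos position data.frame with `t_s`, `x_cm`, `y_cm` and optionally
#'   `valid`.
#' @return speed in cm/s.
#' @export
avg_speed <- function(pos) {
  if ("valid" %in% names(pos)) pos <- pos[pos$valid, , drop = FALSE]
  if (nrow(pos) < 2) stop_data("need at least 2 valid samples")
  keep <- c(TRUE, diff(pos$t_s) > 0)
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) < 2) stop_data("need at least 2 distinct timestamps")
  path <- sum(sqrt(diff(pos$x_cm)^2 + diff(pos$y_cm)^2))
  path / (pos$t_s[nrow(pos)] - pos$t_s[1])
}

#' Score a place-avoidance trial
#'
#' @param pos position data.frame.
#' @param zone a [zone_spec()].
#' @param debounce_s entrance debounce (see [count_entrances()]).
#' @return data.frame: `entrances`, `avg_speed_cm_s`, `trial_duration_s`.
#' @export
score_trial <- function(pos, zone, debounce_s = 0.5) {
  data.frame(entrances = count_entrances(pos, zone, debounce_s),
             avg_speed_cm_s = avg_speed(pos),
             trial_duration_s = diff(range(pos$t_s)))
}

#' Correlate synchrony with avoidance behavior
#'
#' Pearson correlation (with two-sided p-value) between per-animal band PLVs
#' and per-animal total entrance counts, the statistic used to relate
#' inter-hippocampal synchrony to place-avoidance performance.
#'
#' @param plvs numeric vector of per-animal band PLVs.
#' @param entrances numeric vector of per-animal entrance totals (same
#'   order/length, n >= 3).
#' @return list with `r`, `p`, `n`.
#' @export
correlate_sync_behavior <- function(plvs, entrances) {
  if (length(plvs) != length(entrances)) stop_data("paired vectors must have equal length")
  if (length(plvs) < 3) stop_data("need at least 3 animals")
  if (sd(plvs) == 0 || sd(entrances) == 0) stop_data("degenerate: zero variance")
  ct <- cor.test(plvs, entrances, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(plvs))
}
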