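#' Choice-arena geometry
#'
#' The two-choice shoal-association arena: an elongate tank with a stimulus
#' container near each end wall and a neutral corridor between the two
#' association zones. An association zone is every point within
#' `association_radius_bl` body lengths of the stimulus container's outer
#' wall (the shoal occupies the container, so distance is measured from the
#' wall, not the centre).
#'
#' @param body_length_cm Standard length of the focal fish, cm.
#' @param length_cm,width_cm Arena dimensions, cm (defaults 90 x 30).
#' @param container_offset_cm Distance of each container centre from its end
#'   wall, cm (default 6).
#' @param container_diameter_cm Stimulus container diameter, cm (default 10).
#' @param association_radius_bl Association distance in body lengths
#'   (default 2).
#' @return A list of class `arena_geometry` with the derived association
#'   radius `zone_radius_cm` (container radius + association distance).
#' @export
arena_geometry <- function(body_length_cm, length_cm = 90, width_cm = 30,
                           container_offset_cm = 6,
                           container_diameter_cm = 10,
                           association_radius_bl = 2) {
  stopifnot(body_length_cm > 0, length_cm > 0, width_cm > 0)
  zone_radius <- container_diameter_cm / 2 +
    association_radius_bl * body_length_cm
  structure(list(length_cm = length_cm, width_cm = width_cm,
                 container_offset_cm = container_offset_cm,
                 container_radius_cm = container_diameter_cm / 2,
                 association_radius_bl = association_radius_bl,
                 body_length_cm = body_length_cm,
                 zone_radius_cm = zone_radius),
            class = "arena_geometry")
}

#' Build the familiar/unfamiliar/neutral zone map
#'
#' Places the two circular association zones at the container centres and
#' labels them by which side holds the familiar shoal. Zones that would
#' reach the arena midline (leaving no neutral corridor) are a geometry
#' error.
#'
#' @param geom An [arena_geometry()].
#' @param familiar_side `"left"` or `"right"`.
#' @return A list of class `zone_map` with `familiar` and `unfamiliar`
#'   components (`centre_x_cm`, `centre_y_cm`, `radius_cm`) plus the geometry.
#' @export
build_zones <- function(geom, familiar_side = c("left", "right")) {
  stopifnot(inherits(geom, "arena_geometry"))
  familiar_side <- match.arg(familiar_side)
  if (geom$container_offset_cm + geom$zone_radius_cm >= geom$length_cm / 2) {
    stop("association zones would reach the arena midline (zone radius ",
         geom$zone_radius_cm, " cm); no neutral corridor remains",
         call. = FALSE)
  }
  cy <- geom$width_cm / 2
  left <- list(centre_x_cm = geom$container_offset_cm, centre_y_cm = cy,
               radius_cm = geom$zone_radius_cm)
  right <- list(centre_x_cm = geom$length_cm - geom$container_offset_cm,
                centre_y_cm = cy, radius_cm = geom$zone_radius_cm)
  structure(list(
    familiar = if (familiar_side == "left") left else right,
    unfamiliar = if (familiar_side == "left") right else left,
    familiar_side = familiar_side,
    geometry = geom), class = "zone_map")
}

.in_zone <- function(x, y, zone) {
  (x - zone$centre_x_cm)^2 + (y - zone$centre_y_cm)^2 <= zone$radius_cm^2
}

#' Score a choice-test trajectory
#'
#' Computes the three behavioural endpoints of a two-choice association
#' trial from the focal fish's position record: the proportion of scored
#' time spent in each association zone (and, as `pref_familiar`, time with
#' the familiar shoal as a share of total shoaling time — the quantity whose
#' no-preference null is 0.5), the zone of first entry, and the total number
#' of shoal visits (entry events into either zone). A trial is "informed"
#' only if both zones were visited.
#'
#' @param traj A `data.frame` with `time_s`, `x_cm`, `y_cm` (positions of
#'   the focal fish at the native video rate, starting at barrier lift).
#' @param zones A [build_zones()] map.
#' @param debounce_samples Minimum number of consecutive in-zone samples for
#'   an entry to count as a visit (default 1; 2 suppresses boundary jitter).
#' @return A one-row `data.frame`: `prop_familiar`, `prop_unfamiliar`,
#'   `prop_neutral`, `pref_familiar`, `initial_choice`
#'   (`"familiar"`/`"unfamiliar"`/`"none"`), `total_visits`, `informed`.
#' @export
score_trajectory <- function(traj, zones, debounce_samples = 1) {
  stopifnot(inherits(zones, "zone_map"),
            all(c("time_s", "x_cm", "y_cm") %in% names(traj)))
  g <- zones$geometry
  if (any(traj$x_cm < -1e-9 | traj$x_cm > g$length_cm + 1e-9 |
            traj$y_cm < -1e-9 | traj$y_cm > g$width_cm + 1e-9)) {
    stop("trajectory positions outside arena bounds", call. = FALSE)
  }
  n <- nrow(traj)
  in_f <- .in_zone(traj$x_cm, traj$y_cm, zones$familiar)
  in_u <- .in_zone(traj$x_cm, traj$y_cm, zones$unfamiliar) & !in_f

  state <- integer(n)                     # 0 neutral, 1 familiar, 2 unfamiliar
  state[in_f] <- 1L
  state[in_u] <- 2L
  if (debounce_samples > 1) {
    r <- rle(state)
    r$values[r$values != 0L & r$lengths < debounce_samples] <- 0L
    state <- inverse.rle(r)
  }
  runs <- rle(state)
  zone_runs <- runs$values[runs$values != 0L]
  total_visits <- length(zone_runs)
  initial_choice <- if (total_visits == 0) "none" else
    c("familiar", "unfamiliar")[zone_runs[1]]
  informed <- all(c(1L, 2L) %in% zone_runs)

  prop_familiar <- mean(state == 1L)
  prop_unfamiliar <- mean(state == 2L)
  shoaling <- prop_familiar + prop_unfamiliar
  data.frame(prop_familiar = prop_familiar,
             prop_unfamiliar = prop_unfamiliar,
             prop_neutral = 1 - shoaling,
             pref_familiar = if (shoaling > 0) prop_familiar / shoaling
                             else NA_real_,
             initial_choice = initial_choice,
             total_visits = total_visits,
             informed = informed)
}

#' Informed-choice filter
#'
#' Trials in which the focal fish did not visit both association zones are
#' not scoreable as an informed choice; those fish are flagged for retesting
#' rather than imputed.
#'
#' @param results A `data.frame` of [score_trajectory()] rows, ideally with
#'   identifier columns (e.g. `fish_id`).
#' @return A list with `retained` (informed rows) and `retest` (uninformed
#'   rows).
#' @export
apply_informed_filter <- function(results) {
  stopifnot("informed" %in% names(results))
  list(retained = results[results$informed, , drop = FALSE],
       retest = results[!results$informed, , drop = FALSE])
}
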