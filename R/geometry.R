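# Arrangement geometry: four per-egg metrics and nest-level before/after
# change scores. Angles are degrees; directional quantities have period 360,
# axial quantities (undirected long axes) period 180.

deg_mod <- function(x, period) {
  out <- x %% period
  # guard against -1e-16 %% 360 == 360 from floating point
  out[out >= period] <- 0
  out
}

# smallest absolute circular difference between two angles, in [0, period/2]
circ_diff <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Mardia circular standard deviation of a set of directional angles (deg):
# sqrt(-2 log Rbar), reported in degrees.
circ_sd_deg <- function(theta_deg) {
  th <- theta_deg * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  rbar <- min(rbar, 1)
  sqrt(-2 * log(rbar)) * 180 / pi
}

# Axial analogue: double the angles, take the circular SD, halve.
axial_sd_deg <- function(theta_deg) {
  circ_sd_deg(2 * theta_deg) / 2
}

# Two-point circular SD from the circular difference in closed form:
# Rbar of two unit vectors d apart is cos(d/2), so the SD is
# sqrt(-2 log cos(d/2)). Exact zero for identical angles; the axial case
# (period 180) runs on doubled angles. Antipodal pairs give Inf (Rbar = 0).
two_point_circ_sd <- function(a1, a2, period = 360) {
  f <- 360 / period
  d <- circ_diff(a1, a2, period) * f * pi / 180
  rbar <- cos(d / 2)
  if (rbar <= 0) return(Inf)
  sqrt(-2 * log(min(1, rbar))) * 180 / pi / f
}

check_point <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 2 || !all(is.finite(p)))
    stop(what, " must be a finite numeric length-2 vector")
  as.numeric(p)
}

#' Blunt pole distance
#'
#' Euclidean distance (pixels) between the nest center and the egg's blunt
#' pole.
#'
#' @param blunt_pole numeric length-2 blunt-pole pixel coordinates.
#' @param center numeric length-2 nest-center pixel coordinates.
#' @return non-negative distance in pixels.
#' @export
blunt_pole_distance <- function(blunt_pole, center) {
  b <- check_point(blunt_pole, "blunt_pole")
  ctr <- check_point(center, "center")
  sqrt(sum((b - ctr)^2))
}

#' Blunt pole angle
#'
#' Angle in degrees, in \[0, 360), between the positive x axis and the vector
#' from the nest center to the egg's blunt pole. Image coordinates (y down)
#' are flipped to mathematical y-up before the angle is taken, so the angle
#' increases counter-clockwise in the y-up frame (clockwise as displayed in
#' the photograph).
#'
#' @inheritParams blunt_pole_distance
#' @return angle in degrees in \[0, 360).
#' @export
blunt_pole_angle <- function(blunt_pole, center) {
  b <- check_point(blunt_pole, "blunt_pole")
  ctr <- check_point(center, "center")
  if (all(b == ctr)) stop("undefined angle: blunt pole coincides with nest center")
  dx <- b[1] - ctr[1]
  dy <- ctr[2] - b[2]  # flip image y-down to mathematical y-up
  deg_mod(atan2(dy, dx) * 180 / pi, 360)
}

#' Blunt pole orientation
#'
#' Axial angle in degrees, in \[0, 180), between the positive x axis and the
#' egg's long axis (the undirected line through blunt and sharp poles).
#' Swapping the two poles leaves the result unchanged.
#'
#' @param blunt_pole,sharp_pole numeric length-2 pole pixel coordinates.
#' @return axial angle in degrees in \[0, 180).
#' @export
blunt_pole_orientation <- function(blunt_pole, sharp_pole) {
  b <- check_point(blunt_pole, "blunt_pole")
  s <- check_point(sharp_pole, "sharp_pole")
  if (all(b == s)) stop("undefined orientation: zero-length egg axis")
  dx <- b[1] - s[1]
  dy <- s[2] - b[2]  # image y-down -> math y-up
  deg_mod(atan2(dy, dx) * 180 / pi, 180)
}

# Clockwise (as photographed) ordering of eggs around the nest center:
# decreasing polar angle in the y-up frame; ties broken by blunt pole
# distance, then egg_id.
clockwise_order <- function(obs, hosts_only = FALSE) {
  eggs <- if (hosts_only) host_eggs(obs) else obs$eggs
  ang <- vapply(seq_len(nrow(eggs)), function(i)
    blunt_pole_angle(c(eggs$blunt_x[i], eggs$blunt_y[i]), obs$center),
    numeric(1))
  dst <- vapply(seq_len(nrow(eggs)), function(i)
    blunt_pole_distance(c(eggs$blunt_x[i], eggs$blunt_y[i]), obs$center),
    numeric(1))
  eggs[order(-ang, dst, eggs$egg_id), , drop = FALSE]
}

#' Adjacent angles of a clutch
#'
#' Eggs are ordered clockwise (as displayed in the photograph) by the polar
#' angle of their blunt poles around the nest center; for each cyclic pair
#' (egg N, egg N+1) the adjacent angle is the axial difference between the
#' two long-axis orientations, `(orientation_N - orientation_{N+1}) mod 180`,
#' in \[0, 180). The ring is closed (last egg pairs with the first), so a
#' clutch of N eggs yields N adjacent angles, and the signed cyclic
#' differences telescope to 0 mod 180.
#'
#' @param obs a [clutch_observation()].
#' @param hosts_only if `TRUE`, exclude the model egg before ordering.
#' @return numeric vector of adjacent angles in degrees, length = number of
#'   eggs used, named by the first egg of each pair.
#' @export
adjacent_angles <- function(obs, hosts_only = FALSE) {
  eggs <- clockwise_order(obs, hosts_only = hosts_only)
  n <- nrow(eggs)
  if (n < 2) stop("adjacent angles need at least 2 eggs")
  ori <- vapply(seq_len(n), function(i)
    blunt_pole_orientation(c(eggs$blunt_x[i], eggs$blunt_y[i]),
                           c(eggs$sharp_x[i], eggs$sharp_y[i])),
    numeric(1))
  nxt <- c(seq_len(n)[-1], 1L)
  out <- deg_mod(ori - ori[nxt], 180)
  names(out) <- as.character(eggs$egg_id)
  out
}

#' All four arrangement metrics for one observation
#'
#' @param obs a [clutch_observation()].
#' @return a list with a per-egg data.frame (`egg_id`, `blunt_pole_distance`,
#'   `blunt_pole_angle`, `blunt_pole_orientation`) and the vector of
#'   `adjacent_angle`s (all eggs, cyclic).
#' @export
arrangement_metrics <- function(obs) {
  e <- obs$eggs
  per_egg <- data.frame(
    egg_id = e$egg_id,
    is_model_egg = e$is_model_egg,
    blunt_pole_distance = vapply(seq_len(nrow(e)), function(i)
      blunt_pole_distance(c(e$blunt_x[i], e$blunt_y[i]), obs$center), numeric(1)),
    blunt_pole_angle = vapply(seq_len(nrow(e)), function(i)
      blunt_pole_angle(c(e$blunt_x[i], e$blunt_y[i]), obs$center), numeric(1)),
    blunt_pole_orientation = vapply(seq_len(nrow(e)), function(i)
      blunt_pole_orientation(c(e$blunt_x[i], e$blunt_y[i]),
                             c(e$sharp_x[i], e$sharp_y[i])), numeric(1)))
  list(per_egg = per_egg,
       adjacent_angle = if (nrow(e) >= 2) adjacent_angles(obs) else numeric(0))
}

# Pair host eggs between phases. By egg_id when the id sets coincide,
# otherwise by exhaustive nearest-centroid assignment (clutches have at most
# five host eggs, so all permutations are enumerable).
pair_host_eggs <- function(before, after) {
  hb <- host_eggs(before); ha <- host_eggs(after)
  if (nrow(hb) != nrow(ha))
    stop("cannot pair eggs: host egg counts differ between phases (",
         nrow(hb), " vs ", nrow(ha), ")")
  if (setequal(hb$egg_id, ha$egg_id)) {
    ha <- ha[match(hb$egg_id, ha$egg_id), , drop = FALSE]
    return(list(before = hb, after = ha))
  }
  ctr <- function(e) cbind((e$blunt_x + e$sharp_x) / 2, (e$blunt_y + e$sharp_y) / 2)
  cb <- ctr(hb); ca <- ctr(ha)
  n <- nrow(hb)
  perms <- permutations_of(n)
  costs <- vapply(perms, function(p)
    sum(sqrt(rowSums((cb - ca[p, , drop = FALSE])^2))), numeric(1))
  best <- perms[[which.min(costs)]]
  list(before = hb, after = ha[best, , drop = FALSE])
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos)
  }
  out
}

two_point_sd <- function(x1, x2) abs(x1 - x2) / sqrt(2)

#' Before/after arrangement change scores
#'
#' For each of the four arrangement metrics, computes the per-egg (or
#' per-adjacent-pair) standard deviation over its before/after pair of
#' values and averages over the host eggs, giving one nest-level change
#' score per metric. Linear metrics use the two-point SD `|delta|/sqrt(2)`;
#' the directional blunt pole angle uses the circular SD (Mardia, degrees);
#' axial metrics (orientation, adjacent angle) use the doubled-angle axial
#' SD. The model egg has no "before" state and is excluded from pairing.
#'
#' Adjacent pairs are fixed by the before observation's clockwise ordering;
#' the same egg pairs are re-measured in the after observation, so the pair
#' identity is stable even when the manipulation reorders the eggs.
#'
#' @param before,after [clutch_observation()] objects for the same nest.
#' @return a one-row data.frame of class `arrangement_change` with columns
#'   `nest_id`, `sd_blunt_pole_distance`, `sd_blunt_pole_angle`,
#'   `sd_blunt_pole_orientation`, `sd_adjacent_angle`.
#' @export
arrangement_change <- function(before, after) {
  if (!identical(as.character(before$nest_id), as.character(after$nest_id)))
    stop("before and after observations belong to different nests")
  pr <- pair_host_eggs(before, after)
  hb <- pr$before; ha <- pr$after
  n <- nrow(hb)

  db <- vapply(seq_len(n), function(i)
    blunt_pole_distance(c(hb$blunt_x[i], hb$blunt_y[i]), before$center), numeric(1))
  da <- vapply(seq_len(n), function(i)
    blunt_pole_distance(c(ha$blunt_x[i], ha$blunt_y[i]), after$center), numeric(1))

  ab <- vapply(seq_len(n), function(i)
    blunt_pole_angle(c(hb$blunt_x[i], hb$blunt_y[i]), before$center), numeric(1))
  aa <- vapply(seq_len(n), function(i)
    blunt_pole_angle(c(ha$blunt_x[i], ha$blunt_y[i]), after$center), numeric(1))

  ob <- vapply(seq_len(n), function(i)
    blunt_pole_orientation(c(hb$blunt_x[i], hb$blunt_y[i]),
                           c(hb$sharp_x[i], hb$sharp_y[i])), numeric(1))
  oa <- vapply(seq_len(n), function(i)
    blunt_pole_orientation(c(ha$blunt_x[i], ha$blunt_y[i]),
                           c(ha$sharp_x[i], ha$sharp_y[i])), numeric(1))

  sd_adj <- NA_real_
  if (n >= 2) {
    ord <- clockwise_order(strip_to_hosts(before), hosts_only = FALSE)
    idx_b <- match(ord$egg_id, hb$egg_id)
    nxt <- c(seq_len(n)[-1], 1L)
    adj_b <- deg_mod(ob[idx_b] - ob[idx_b][nxt], 180)
    adj_a <- deg_mod(oa[idx_b] - oa[idx_b][nxt], 180)
    sd_adj <- mean(vapply(seq_len(n), function(i)
      two_point_circ_sd(adj_b[i], adj_a[i], period = 180), numeric(1)))
  }

  out <- data.frame(
    nest_id = before$nest_id,
    sd_blunt_pole_distance = mean(two_point_sd(db, da)),
    sd_blunt_pole_angle = mean(vapply(seq_len(n), function(i)
      two_point_circ_sd(ab[i], aa[i], period = 360), numeric(1))),
    sd_blunt_pole_orientation = mean(vapply(seq_len(n), function(i)
      two_point_circ_sd(ob[i], oa[i], period = 180), numeric(1))),
    sd_adjacent_angle = sd_adj)
  class(out) <- c("arrangement_change", "data.frame")
  out
}

# An observation restricted to its host eggs (pairing and adjacency never
# see the model egg).
strip_to_hosts <- function(obs) {
  obs$eggs <- host_eggs(obs)
  obs
}
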