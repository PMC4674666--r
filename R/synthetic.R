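# Synthetic clutches, treatments, rendered masks, and behavioral outcomes.
#
# The generator emulates the experimental design: blackbird-sized clutches
# of 4-5 eggs in a circular nest cup, photographed before and after one of
# three manipulations (control = handling jitter only; constant = handling
# jitter + one model egg added at the cup perimeter; rearranged = positions
# and orientations redrawn + model egg), and per-nest behavioral outcomes
# (desertion, ejection, latency in days) drawn from a stated
# logistic / negative-binomial model.

#' Generator configuration for synthetic clutches
#'
#' Defaults reproduce the study conditions: group sizes 19/30/30
#' (control/constant/rearranged), clutch sizes 4 or 5, a 22.40 x 16.89 mm
#' model egg, and host eggs of 29 x 21 mm (typical for the European
#' blackbird) in a 50 mm radius cup rendered at 2 px/mm.
#'
#' @param n_nests named integer vector of nests per treatment group.
#' @param clutch_size_probs probabilities of clutch sizes 4 and 5 (named).
#' @param cup_radius_mm nest cup radius.
#' @param host_egg_mm host egg length and breadth (named `length`, `breadth`).
#' @param model_egg_mm model egg length and breadth.
#' @param jitter_sd_mm SD of photographic/handling displacement noise applied
#'   to host egg centers at control nests.
#' @param orientation_jitter_sd_deg SD of the matching angular noise.
#' @param constant_disturbance_multiplier factor by which inserting the model
#'   egg at "constant" nests inflates the handling jitter on host eggs
#'   (the inserted egg contacts and nudges its neighbours).
#' @param shuffle_intensity in \[0, 1\]: 1 = positions/orientations fully
#'   redrawn at rearranged nests, 0 = left in place.
#' @param px_per_mm rendering scale.
#' @param frame_margin_mm blank margin around the cup in rendered masks.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_nests = c(control = 19, constant = 30, rearranged = 30),
                             clutch_size_probs = c(`4` = 0.5, `5` = 0.5),
                             cup_radius_mm = 50,
                             host_egg_mm = c(length = 29, breadth = 21),
                             model_egg_mm = c(length = 22.40, breadth = 16.89),
                             jitter_sd_mm = 1.0,
                             orientation_jitter_sd_deg = 5,
                             constant_disturbance_multiplier = 2,
                             shuffle_intensity = 1,
                             px_per_mm = 2,
                             frame_margin_mm = 6) {
  stopifnot(all(c("control", "constant", "rearranged") %in% names(n_nests)),
            all(n_nests >= 0),
            abs(sum(clutch_size_probs) - 1) < 1e-8, all(clutch_size_probs >= 0),
            cup_radius_mm > 0, all(host_egg_mm > 0), all(model_egg_mm > 0),
            jitter_sd_mm >= 0, orientation_jitter_sd_deg >= 0,
            constant_disturbance_multiplier >= 1,
            shuffle_intensity >= 0, shuffle_intensity <= 1,
            px_per_mm > 0, frame_margin_mm >= 0)
  if (cup_radius_mm <= host_egg_mm[["length"]] / 2)
    stop("cup too small to hold a host egg")
  structure(as.list(environment()), class = "generator_config")
}

# ---- internal mm-space egg representation -------------------------------
# An egg in cup coordinates: center (x, y) mm with the cup center at the
# origin and y up; axis angle deg (direction from center to the blunt
# pole); semi-axes a (half length), b (half breadth).

egg_fits_cup <- function(egg, cup_radius) {
  # farthest point of an ellipse from the origin is bounded by |center| + a
  sqrt(sum(egg$center^2)) + egg$a <= cup_radius
}

ellipse_boundary <- function(egg, n = 72, margin = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- egg$axis_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts <- rot %*% rbind((egg$a + margin) * cos(t), (egg$b + margin) * sin(t))
  sweep(t(pts), 2, egg$center, FUN = "+")
}

point_in_ellipse <- function(pts, egg, margin = 0) {
  th <- egg$axis_deg * pi / 180
  d <- sweep(pts, 2, egg$center)
  u <- d[, 1] * cos(th) + d[, 2] * sin(th)
  v <- -d[, 1] * sin(th) + d[, 2] * cos(th)
  (u / (egg$a + margin))^2 + (v / (egg$b + margin))^2 <= 1
}

eggs_overlap <- function(e1, e2, margin = 0.5) {
  # quick reject on bounding circles
  if (sqrt(sum((e1$center - e2$center)^2)) > e1$a + e2$a + 2 * margin)
    return(FALSE)
  any(point_in_ellipse(ellipse_boundary(e1, margin = margin / 2), e2, margin = margin / 2)) ||
    any(point_in_ellipse(matrix(e2$center, 1), e1, margin = margin / 2)) ||
    any(point_in_ellipse(matrix(e1$center, 1), e2, margin = margin / 2))
}

any_overlap <- function(eggs, margin = 0.5) {
  n <- length(eggs)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (eggs_overlap(eggs[[i]], eggs[[j]], margin = margin)) return(TRUE)
  FALSE
}

# draw one host egg pose: center around the cup at base polar angle,
# long axis roughly radial, blunt pole outward
draw_host_pose <- function(config, base_angle_deg) {
  a <- config$host_egg_mm[["length"]] / 2
  r_max <- config$cup_radius_mm - a - 1
  pos_angle <- base_angle_deg + stats::rnorm(1, 0, 12)
  r <- stats::runif(1, 0.45, 0.95) * r_max
  th <- pos_angle * pi / 180
  center <- c(r * cos(th), r * sin(th))
  axis_deg <- pos_angle + stats::rnorm(1, 0, 15)
  list(center = center, axis_deg = axis_deg,
       a = a, b = config$host_egg_mm[["breadth"]] / 2, is_model = FALSE)
}

place_host_eggs <- function(config, clutch_size, max_restarts = 30,
                            max_tries = 300) {
  for (restart in seq_len(max_restarts)) {
    base <- stats::runif(1, 0, 360) + 360 * (seq_len(clutch_size) - 1) / clutch_size
    eggs <- list()
    ok <- TRUE
    for (k in seq_len(clutch_size)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- draw_host_pose(config, base[k])
        if (egg_fits_cup(cand, config$cup_radius_mm) &&
            !any(vapply(eggs, eggs_overlap, logical(1), e2 = cand))) {
          eggs[[k]] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(eggs)
  }
  stop("could not place ", clutch_size, " eggs without overlap after ",
       max_restarts, " restarts")
}

place_model_egg <- function(config, host_eggs_mm, max_tries = 500) {
  a <- config$model_egg_mm[["length"]] / 2
  r <- config$cup_radius_mm - a - 0.5  # at the cup perimeter
  for (try in seq_len(max_tries)) {
    pos_angle <- stats::runif(1, 0, 360)
    th <- pos_angle * pi / 180
    cand <- list(center = c(r * cos(th), r * sin(th)),
                 axis_deg = pos_angle + stats::rnorm(1, 0, 10),
                 a = a, b = config$model_egg_mm[["breadth"]] / 2,
                 is_model = TRUE)
    if (egg_fits_cup(cand, config$cup_radius_mm) &&
        !any(vapply(host_eggs_mm, eggs_overlap, logical(1), e2 = cand)))
      return(cand)
  }
  stop("could not place the model egg at the cup perimeter without overlap")
}

# convert mm-space eggs to an annotated clutch_observation in image pixels
eggs_to_observation <- function(eggs_mm, config, nest_id, phase,
                                egg_ids = NULL) {
  half <- config$cup_radius_mm + config$frame_margin_mm
  ppm <- config$px_per_mm
  to_px <- function(p_mm) c((p_mm[1] + half) * ppm, (half - p_mm[2]) * ppm)
  if (is.null(egg_ids))
    egg_ids <- ifelse(vapply(eggs_mm, `[[`, logical(1), "is_model"),
                      "model", paste0("egg", seq_along(eggs_mm)))
  rows <- lapply(seq_along(eggs_mm), function(i) {
    e <- eggs_mm[[i]]
    th <- e$axis_deg * pi / 180
    u <- c(cos(th), sin(th))
    blunt <- to_px(e$center + e$a * u)   # blunt pole points outward
    sharp <- to_px(e$center - e$a * u)
    data.frame(egg_id = egg_ids[i], blunt_x = blunt[1], blunt_y = blunt[2],
               sharp_x = sharp[1], sharp_y = sharp[2],
               is_model_egg = e$is_model)
  })
  obs <- clutch_observation(nest_id = nest_id, phase = phase,
                            center = c(half * ppm, half * ppm),
                            eggs = do.call(rbind, rows),
                            px_per_mm = ppm)
  attr(obs, "eggs_mm") <- eggs_mm
  obs
}

#' Generate one synthetic "before" clutch
#'
#' Host eggs are placed without overlap inside the circular cup, long axes
#' roughly radial with blunt poles biased outward, matching how thrush
#' clutches sit in the cup. Deterministic given `seed`.
#'
#' @param config a [generator_config()].
#' @param clutch_size number of host eggs (4 or 5 under the default design;
#'   any size >= 1 that physically fits is accepted).
#' @param nest_id nest identifier.
#' @param seed optional integer seed.
#' @return a [clutch_observation()] with `phase = "before"`.
#' @export
generate_clutch <- function(config = generator_config(), clutch_size = 4,
                            nest_id = "nest1", seed = NULL) {
  stopifnot(inherits(config, "generator_config"), clutch_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  eggs <- place_host_eggs(config, clutch_size)
  eggs_to_observation(eggs, config, nest_id, "before")
}

# jitter host poses; retried until the jittered clutch is overlap-free
jitter_eggs <- function(eggs_mm, config, sd_mm, sd_deg, max_tries = 300) {
  if (sd_mm == 0 && sd_deg == 0) return(eggs_mm)
  for (try in seq_len(max_tries)) {
    cand <- lapply(eggs_mm, function(e) {
      e$center <- e$center + stats::rnorm(2, 0, sd_mm)
      e$axis_deg <- e$axis_deg + stats::rnorm(1, 0, sd_deg)
      e
    })
    if (all(vapply(cand, egg_fits_cup, logical(1),
                   cup_radius = config$cup_radius_mm)) &&
        !any_overlap(cand))
      return(cand)
  }
  stop("could not jitter the clutch without creating overlaps")
}

#' Apply an experimental treatment to a clutch
#'
#' * `control`: host eggs receive photographic/handling jitter only; no
#'   model egg ("hand held over the cup without touching the eggs").
#' * `constant`: the same handling plus one model egg added at the cup
#'   perimeter; the insertion contacts neighbouring eggs, modeled as jitter
#'   inflated by `constant_disturbance_multiplier`.
#' * `rearranged`: host positions and orientations redrawn (scaled by
#'   `shuffle_intensity`, emulating a 10 s figure-eight shuffle by hand)
#'   plus the model egg.
#'
#' @param before a `phase = "before"` [clutch_observation()] without a
#'   model egg (typically from [generate_clutch()]).
#' @param treatment `"control"`, `"constant"` or `"rearranged"`.
#' @param config the [generator_config()] used to build `before`.
#' @param seed optional integer seed.
#' @return a [clutch_observation()] with `phase = "after"`; under the two
#'   parasitized treatments it contains exactly one model egg.
#' @export
apply_treatment <- function(before, treatment, config = generator_config(),
                            seed = NULL) {
  if (!treatment %in% c("control", "constant", "rearranged"))
    stop("unknown treatment: ", treatment)
  if (any(before$eggs$is_model_egg))
    stop("'before' observation already contains a model egg")
  if (!is.null(seed)) set.seed(seed)
  eggs_mm <- attr(before, "eggs_mm")
  if (is.null(eggs_mm))
    stop("'before' observation lacks generator metadata; use generate_clutch()")
  ids <- before$eggs$egg_id

  if (treatment == "control") {
    out <- jitter_eggs(eggs_mm, config, config$jitter_sd_mm,
                       config$orientation_jitter_sd_deg)
  } else if (treatment == "constant") {
    mult <- config$constant_disturbance_multiplier
    out <- jitter_eggs(eggs_mm, config, config$jitter_sd_mm * mult,
                       config$orientation_jitter_sd_deg * mult)
    out <- c(out, list(place_model_egg(config, out)))
    ids <- c(ids, "model")
  } else {
    s <- config$shuffle_intensity
    n <- length(eggs_mm)
    for (try in seq_len(50)) {
      redrawn <- place_host_eggs(config, n)
      cand <- lapply(seq_len(n), function(i) {
        e <- eggs_mm[[i]]
        e$center <- (1 - s) * e$center + s * redrawn[[i]]$center
        e$axis_deg <- e$axis_deg + s * deg_signed(redrawn[[i]]$axis_deg - e$axis_deg)
        e
      })
      if (all(vapply(cand, egg_fits_cup, logical(1),
                     cup_radius = config$cup_radius_mm)) && !any_overlap(cand)) {
        out <- cand; break
      }
      if (try == 50) stop("could not rearrange the clutch without overlaps")
    }
    out <- c(out, list(place_model_egg(config, out)))
    ids <- c(ids, "model")
  }
  eggs_to_observation(out, config, before$nest_id, "after", egg_ids = ids)
}

# signed angular difference mapped to (-180, 180]
deg_signed <- function(d) {
  out <- d %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Rasterize a clutch observation to a binary silhouette mask
#'
#' Eggs are filled ellipses (semi-major axis from the annotated pole-to-pole
#' distance; semi-minor axis from the configured breadth for host or model
#' eggs) rendered at `config$px_per_mm` on a square frame covering the cup
#' plus margin. Deterministic.
#'
#' @param obs a [clutch_observation()].
#' @param config a [generator_config()].
#' @return a logical mask matrix (rows = image rows, i.e. y; columns = x).
#' @export
render_mask <- function(obs, config = generator_config()) {
  e <- obs$eggs
  if (nrow(e) == 0) stop("cannot render an empty clutch")
  ppm <- obs$px_per_mm %||% config$px_per_mm
  side <- ceiling(2 * (config$cup_radius_mm + config$frame_margin_mm) * ppm)
  mask <- matrix(FALSE, side, side)
  xs <- seq_len(side); ys <- seq_len(side)
  for (i in seq_len(nrow(e))) {
    blunt <- c(e$blunt_x[i], e$blunt_y[i]); sharp <- c(e$sharp_x[i], e$sharp_y[i])
    ctr <- (blunt + sharp) / 2
    a <- sqrt(sum((blunt - sharp)^2)) / 2
    b_mm <- if (e$is_model_egg[i]) config$model_egg_mm[["breadth"]]
            else config$host_egg_mm[["breadth"]]
    b <- b_mm / 2 * ppm
    th <- atan2(blunt[2] - sharp[2], blunt[1] - sharp[1])  # image coords
    if (ctr[1] - a < 1 || ctr[1] + a > side || ctr[2] - a < 1 || ctr[2] + a > side)
      stop("egg ", e$egg_id[i], " falls outside the rendering frame")
    ci <- max(1, floor(ctr[1] - a)):min(side, ceiling(ctr[1] + a))
    ri <- max(1, floor(ctr[2] - a)):min(side, ceiling(ctr[2] + a))
    dyy <- outer(ys[ri] - ctr[2], rep(1, length(ci)))  # rows = y offsets
    dxx <- outer(rep(1, length(ri)), xs[ci] - ctr[1])  # cols = x offsets
    u <- dxx * cos(th) + dyy * sin(th)
    v <- -dxx * sin(th) + dyy * cos(th)
    mask[ri, ci] <- mask[ri, ci] | ((u / a)^2 + (v / b)^2 <= 1)
  }
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Behavioral model configuration
#'
#' Defaults reproduce the study's printed outcome structure: a
#' treatment-independent desertion probability of 0.127 (10 of 79 nests),
#' ejection at non-deserted parasitized nests with baseline log-odds 1.34
#' (constant) plus 0.74 for the rearranged treatment, and ejection latency
#' (days, 0 = same day) drawn negative-binomially with log-mean 0.37 minus
#' 1.21 for five-egg clutches, truncated to the 6-day monitoring window.
#'
#' @param desertion_prob treatment-independent desertion probability.
#' @param beta0 baseline (constant treatment) ejection log-odds.
#' @param beta_treat added log-odds of ejection at rearranged nests.
#' @param beta_age,beta_date log-odds effects of nest age and laying date
#'   (0 by default: the covariates are null, as in the reduced model).
#' @param gamma0 latency log-mean intercept (clutch of 4).
#' @param gamma_clutch added log-mean for five-egg clutches.
#' @param gamma_treat added latency log-mean at rearranged nests.
#' @param nb_theta negative-binomial dispersion (size) parameter.
#' @param max_latency_days monitoring window; draws beyond it are resampled.
#' @return an object of class `behavior_config`.
#' @export
behavior_config <- function(desertion_prob = 10 / 79,
                            beta0 = 1.34, beta_treat = 0.74,
                            beta_age = 0, beta_date = 0,
                            gamma0 = 0.37, gamma_clutch = -1.21,
                            gamma_treat = 0,
                            nb_theta = 2, max_latency_days = 6) {
  stopifnot(desertion_prob >= 0, desertion_prob <= 1,
            nb_theta > 0, max_latency_days >= 0)
  structure(as.list(environment()), class = "behavior_config")
}

#' Simulate behavioral outcomes for a set of nests
#'
#' Desertion is Bernoulli(`desertion_prob`) in every group. Non-deserted
#' parasitized nests eject with probability
#' `plogis(beta0 + beta_treat * rearranged + beta_age * nest_age +
#' beta_date * laying_date)`; control nests (no foreign egg) can only
#' accept or desert. Ejection latency is negative-binomial on the log
#' scale with clutch-size and treatment terms, resampled into the 0-6 day
#' monitoring window. Nest age (days since clutch completion at
#' manipulation) and laying date (day of season) covariates are drawn to
#' match the field distribution (age 4.65 +/- 3.7 days; date uniform over
#' a 90-day season).
#'
#' @param assignments data.frame with columns `nest_id`, `treatment`
#'   (`control`/`constant`/`rearranged`) and `clutch_size` (4 or 5).
#' @param behavior a [behavior_config()].
#' @param seed optional integer seed.
#' @return data.frame of class `nest_outcomes`: `nest_id`, `treatment`,
#'   `clutch_size`, `nest_age`, `laying_date`, `response`
#'   (`eject`/`accept`/`desert`), `latency_days` (NA unless ejected).
#' @export
simulate_outcomes <- function(assignments, behavior = behavior_config(),
                              seed = NULL) {
  stopifnot(inherits(behavior, "behavior_config"),
            all(c("nest_id", "treatment", "clutch_size") %in% names(assignments)))
  if (!all(assignments$treatment %in% c("control", "constant", "rearranged")))
    stop("unknown treatment label in assignments")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(assignments)
  nest_age <- pmax(0, stats::rnorm(n, 4.65, 3.7))
  laying_date <- stats::runif(n, 1, 90)
  deserted <- stats::runif(n) < behavior$desertion_prob
  rearranged <- assignments$treatment == "rearranged"
  parasitized <- assignments$treatment != "control"
  eta <- behavior$beta0 + behavior$beta_treat * rearranged +
    behavior$beta_age * nest_age + behavior$beta_date * laying_date
  eject <- !deserted & parasitized & (stats::runif(n) < stats::plogis(eta))
  response <- ifelse(deserted, "desert", ifelse(eject, "eject", "accept"))

  latency <- rep(NA_real_, n)
  mu <- exp(behavior$gamma0 + behavior$gamma_clutch * (assignments$clutch_size == 5) +
              behavior$gamma_treat * rearranged)
  idx <- which(eject)
  if (length(idx)) {
    lat <- stats::rnbinom(length(idx), size = behavior$nb_theta, mu = mu[idx])
    for (round in seq_len(1000)) {
      bad <- lat > behavior$max_latency_days
      if (!any(bad)) break
      lat[bad] <- stats::rnbinom(sum(bad), size = behavior$nb_theta,
                                 mu = mu[idx][bad])
    }
    if (any(lat > behavior$max_latency_days))
      stop("latency resampling failed to land in the monitoring window")
    latency[idx] <- lat
  }
  out <- data.frame(nest_id = assignments$nest_id,
                    treatment = assignments$treatment,
                    clutch_size = assignments$clutch_size,
                    nest_age = nest_age, laying_date = laying_date,
                    response = response, latency_days = latency)
  class(out) <- c("nest_outcomes", "data.frame")
  out
}

#' Draw clutch sizes for a set of nests
#'
#' @param n number of nests.
#' @param config a [generator_config()].
#' @return integer vector of clutch sizes.
#' @export
draw_clutch_sizes <- function(n, config = generator_config()) {
  sizes <- as.integer(names(config$clutch_size_probs))
  sample(sizes, n, replace = TRUE, prob = config$clutch_size_probs)
}
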