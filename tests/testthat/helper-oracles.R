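# Independent brute-force re-implementations of the arrangement metrics
# (complex-number arithmetic instead of the package's atan2/vector code)
# plus small builders for random test fixtures.

o_dist <- function(blunt, center) {
  Mod(complex(real = blunt[1] - center[1], imaginary = blunt[2] - center[2]))
}

# image y-down flipped to math y-up, angle counter-clockwise from +x
o_angle <- function(blunt, center) {
  z <- complex(real = blunt[1] - center[1], imaginary = center[2] - blunt[2])
  (Arg(z) * 180 / pi) %% 360
}

# axial orientation via the angle-doubling trick
o_orient <- function(blunt, sharp) {
  z <- complex(real = blunt[1] - sharp[1], imaginary = sharp[2] - blunt[2])
  ((Arg(z * z) * 180 / pi) / 2) %% 180
}

# clockwise-in-photo ordering = decreasing y-up polar angle
o_clockwise_ids <- function(obs) {
  e <- obs$eggs
  ang <- mapply(function(bx, by) o_angle(c(bx, by), obs$center),
                e$blunt_x, e$blunt_y)
  dst <- mapply(function(bx, by) o_dist(c(bx, by), obs$center),
                e$blunt_x, e$blunt_y)
  e$egg_id[order(-ang, dst, e$egg_id)]
}

o_adjacent <- function(obs) {
  e <- obs$eggs
  ids <- o_clockwise_ids(obs)
  ori <- sapply(ids, function(id) {
    r <- e[e$egg_id == id, ]
    o_orient(c(r$blunt_x, r$blunt_y), c(r$sharp_x, r$sharp_y))
  })
  n <- length(ori)
  out <- numeric(n)
  for (k in seq_len(n)) {
    nxt <- if (k == n) 1 else k + 1
    out[k] <- (ori[k] - ori[nxt]) %% 180
  }
  names(out) <- as.character(ids)
  out
}

# two-point circular SD by explicit unit-vector summation
o_circ_sd2 <- function(a1, a2, period = 360) {
  f <- 360 / period
  th <- c(a1, a2) * f * pi / 180
  rbar <- min(1, Mod(mean(exp(1i * th))))
  sqrt(-2 * log(rbar)) * 180 / pi / f
}

# a random, geometrically valid clutch observation (points need not look
# like real eggs; only the metric contracts matter here)
random_clutch <- function(n_eggs = 4, nest_id = "r1", phase = "before",
                          center = c(100, 100), spread = 60) {
  repeat {
    bl <- matrix(center + stats::runif(2 * n_eggs, -spread, spread),
                 ncol = 2, byrow = TRUE)
    sh <- bl + matrix(stats::runif(2 * n_eggs, -20, 20), ncol = 2)
    ok <- all(rowSums((bl - sh)^2) > 1) &&
      all(rowSums((t(t(bl) - center))^2) > 1) && all(bl > 0) && all(sh > 0)
    if (ok) break
  }
  clutch_observation(
    nest_id = nest_id, phase = phase, center = center,
    eggs = data.frame(egg_id = paste0("e", seq_len(n_eggs)),
                      blunt_x = bl[, 1], blunt_y = bl[, 2],
                      sharp_x = sh[, 1], sharp_y = sh[, 2],
                      is_model_egg = FALSE))
}

# translate / rescale / rotate an observation (center included)
transform_obs <- function(obs, shift = c(0, 0), scale = 1,
                          rotate_deg = 0) {
  rot <- function(p, ctr) {
    th <- -rotate_deg * pi / 180  # image y-down: positive = clockwise on screen
    d <- p - ctr
    ctr + c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
  }
  e <- obs$eggs
  for (i in seq_len(nrow(e))) {
    b <- rot(c(e$blunt_x[i], e$blunt_y[i]), obs$center)
    s <- rot(c(e$sharp_x[i], e$sharp_y[i]), obs$center)
    e[i, c("blunt_x", "blunt_y")] <- obs$center + scale * (b - obs$center)
    e[i, c("sharp_x", "sharp_y")] <- obs$center + scale * (s - obs$center)
  }
  e$blunt_x <- e$blunt_x + shift[1]; e$blunt_y <- e$blunt_y + shift[2]
  e$sharp_x <- e$sharp_x + shift[1]; e$sharp_y <- e$sharp_y + shift[2]
  clutch_observation(obs$nest_id, obs$phase, obs$center + shift, e,
                     px_per_mm = obs$px_per_mm)
}

# filled-disk and ring masks for dissimilarity fixtures
disk_mask <- function(side, center, radius) {
  r <- outer(seq_len(side) - center[1], rep(1, side))
  c <- outer(rep(1, side), seq_len(side) - center[2])
  r^2 + c^2 <= radius^2
}

ring_mask <- function(side, center, r_in, r_out) {
  disk_mask(side, center, r_out) & !disk_mask(side, center, r_in)
}

# hand-coded IRLS for a logistic GLM (oracle for stats::glm estimates)
irls_logit <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(t(X) %*% (X * w), t(X) %*% (w * z))
    if (max(abs(beta_new - beta)) < tol) return(as.numeric(beta_new))
    beta <- as.numeric(beta_new)
  }
  as.numeric(beta)
}

# parasitized-only assignments for model-recovery simulations
parasitized_assignments <- function(n) {
  data.frame(nest_id = seq_len(n),
             treatment = rep(c("constant", "rearranged"), length.out = n),
             clutch_size = rep(c(4L, 5L), each = ceiling(n / 2))[seq_len(n)])
}
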