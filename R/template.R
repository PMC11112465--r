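# Monotone piecewise-cubic stance templates.
#
# The synthetic generator needs a smooth M-shaped curve through a handful of
# anchor points that (a) has local extrema exactly at the anchors and nowhere
# else, and (b) leaves enough shape freedom to hit prescribed window means
# and 80%-crossing slopes. A shape-preserving cubic Hermite interpolant
# (Fritsch-Butland derivative choice) gives (a) for free: between anchors the
# curve is monotone, and at anchors where the data change direction the
# derivative is zero.

# Fritsch-Butland derivatives for a shape-preserving cubic Hermite interpolant
monotone_hermite_derivs <- function(u, v) {
  n <- length(u)
  h <- diff(u)
  delta <- diff(v) / h
  d <- numeric(n)
  d[1] <- delta[1]
  d[n] <- delta[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      if (delta[i - 1] * delta[i] <= 0) {
        d[i] <- 0
      } else {
        w1 <- 2 * h[i] + h[i - 1]
        w2 <- h[i] + 2 * h[i - 1]
        d[i] <- (w1 + w2) / (w1 / delta[i - 1] + w2 / delta[i])
      }
    }
  }
  d
}

# Vectorized evaluation of the cubic Hermite interpolant at points x
hermite_eval <- function(x, u, v, d) {
  i <- findInterval(x, u, rightmost.closed = TRUE)
  i[i < 1] <- 1
  i[i >= length(u)] <- length(u) - 1
  h <- u[i + 1] - u[i]
  t <- (x - u[i]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * v[i] + h10 * h * d[i] + h01 * v[i + 1] + h11 * h * d[i + 1]
}

# Builds a function(x) from anchors; x outside [u1, un] evaluates the
# boundary segments' extrapolation, so callers must stay inside the span.
hermite_fun <- function(u, v) {
  d <- monotone_hermite_derivs(u, v)
  function(x) hermite_eval(x, u, v, d)
}

#' Construct an M-shaped stance-curve template
#'
#' Builds a smooth force template over the unit stance interval through
#' structural anchors -- near-threshold boundaries, the first maximum (Fz2),
#' the midstance minimum (Fz3) and the second maximum (Fz4) -- as a
#' shape-preserving cubic Hermite interpolant.
#'
#' The loading (unloading) slope target fixes the time at which the rising
#' (falling) flank crosses 80% of the respective maximum, because the slope
#' parameters are defined by those crossings on the 100-point index axis. A
#' short steep "shoulder" is placed just before each crossing so that the
#' crossing location is insensitive to sensor noise. Around each flank one
#' shape handle (and a valley-width handle for midstance) is calibrated so
#' that the loading, midstance and unloading window means of the
#' discretised curve -- measured at the extremum indices a noise-free
#' pipeline run would detect after Gaussian smoothing -- hit the requested
#' targets.
#'
#' Forces are fractions of body weight throughout.
#'
#' @param fz2,fz3,fz4 Extremum values in body-weight fractions; must satisfy
#'   the strict M-shape `fz3 < fz2` and `fz3 < fz4`.
#' @param t_fz2,t_fz3,t_fz4 Extremum positions as fractions of stance
#'   duration, strictly increasing within (0, 1).
#' @param loading_slope,unloading_slope Target slopes in percent body weight
#'   per percent stance duration (`loading_slope > 0`, `unloading_slope < 0`).
#' @param fmean_load,fmean_mid,fmean_unload Target window means
#'   (body-weight fractions) for the inclusive index windows up to Fz2,
#'   Fz2--Fz4 and Fz4 to the end. `NULL` leaves a window uncalibrated.
#' @param boundary_level Force at the stance boundaries (fraction of body
#'   weight), slightly above the 30 N contact threshold for typical weights.
#' @param n_index Number of samples of the normalized curve (default 100).
#'
#' @return A list of class `stance_template` with elements `f` (the template
#'   function over \[0, 1\]), `anchors` (tibble of anchor positions/values),
#'   `clamped` (logical per window: calibration target outside the
#'   achievable range, nearest achievable shape used), `realized` (the nine
#'   discretised parameter values a noise-free pipeline extracts from this
#'   template, plus the detected indices) and the input `targets`.
#' @export
#' @examples
#' p <- default_grade_parameters()[5, ] # horizontal walking
#' tpl <- make_stance_template(
#'   fz2 = p$fz2_mean, fz3 = p$fz3_mean, fz4 = p$fz4_mean,
#'   loading_slope = p$loading_slope_mean,
#'   unloading_slope = p$unloading_slope_mean,
#'   fmean_load = p$fmean_load_mean, fmean_mid = p$fmean_mid_mean,
#'   fmean_unload = p$fmean_unload_mean
#' )
#' unlist(tpl$realized[c("fz2", "fz3", "fz4")])
make_stance_template <- function(fz2, fz3, fz4,
                                 t_fz2 = 0.25, t_fz3 = 0.50, t_fz4 = 0.75,
                                 loading_slope = NULL, unloading_slope = NULL,
                                 fmean_load = NULL, fmean_mid = NULL,
                                 fmean_unload = NULL,
                                 boundary_level = 0.08, n_index = 100) {
  if (!(fz3 < fz2 && fz3 < fz4)) {
    stop(sprintf(
      "anchor draw violates the strict M-shape (fz2=%.3f, fz3=%.3f, fz4=%.3f)",
      fz2, fz3, fz4), call. = FALSE)
  }
  if (!(0 < t_fz2 && t_fz2 < t_fz3 && t_fz3 < t_fz4 && t_fz4 < 1)) {
    stop("extremum times must satisfy 0 < t_fz2 < t_fz3 < t_fz4 < 1",
         call. = FALSE)
  }
  f0 <- boundary_level
  thr_l <- 0.8 * fz2
  thr_u <- 0.8 * fz4
  if (f0 >= thr_l - 0.1 || f0 >= thr_u - 0.1) {
    stop("boundary_level must lie well below 80% of both maxima", call. = FALSE)
  }
  m <- n_index - 1
  shoulder <- 0.04 # force margin of the steep pre-crossing shoulder
  sh_w <- 2 / m    # shoulder width in stance fraction (2 indices)

  # crossing times implied by the slope targets (index axis, percent BW)
  run_l <- if (is.null(loading_slope)) t_fz2 / 2 * m else {
    if (loading_slope <= 0) stop("loading_slope target must be positive", call. = FALSE)
    (thr_l - f0) * 100 / loading_slope
  }
  run_u <- if (is.null(unloading_slope)) (1 - t_fz4) / 2 * m else {
    if (unloading_slope >= 0) stop("unloading_slope target must be negative", call. = FALSE)
    (thr_u - f0) * 100 / abs(unloading_slope)
  }
  t80_l <- run_l / m
  t80_u <- 1 - run_u / m
  if (t80_l <= 3.5 / m || t80_l >= t_fz2 - 0.02) {
    stop(sprintf(
      "loading-slope target places the 80%% crossing at %.3f, outside (0, t_fz2)",
      t80_l), call. = FALSE)
  }
  if (t80_u <= t_fz4 + 0.02 || t80_u >= 1 - 3.5 / m) {
    stop(sprintf(
      "unloading-slope target places the 80%% crossing at %.3f, outside (t_fz4, 1)",
      t80_u), call. = FALSE)
  }

  # anchor skeleton: each flank has a low handle, a steep shoulder into the
  # 80% crossing, and an upper sag/bulge handle; the valley has the
  # alpha-controlled width anchors
  t_a <- 0.35 * (t80_l - sh_w)
  t_a2 <- 0.75 * (t80_l - sh_w)
  t_shl <- t80_l - sh_w
  t_ab <- (t80_l + t_fz2) / 2
  t_m1 <- (t_fz2 + t_fz3) / 2
  t_m2 <- (t_fz3 + t_fz4) / 2
  t_ps <- t_fz4 - 4 / m # sharpens the often-shallow second peak so its
                        # smoothed argmax stays put under sensor noise
  t_ba <- (t_fz4 + t80_u - sh_w) / 2
  t_shu <- t80_u - sh_w
  t_c <- t80_u + 2 / m  # the first samples past the crossing follow the
                        # intended slope line, so a noise-shifted crossing
                        # index reads a value still on that line
  t_b <- (t_c + 1) / 2
  u <- c(0, t_a, t_a2, t_shl, t80_l, t_ab, t_fz2, t_m1, t_fz3, t_m2, t_ps,
         t_fz4, t_ba, t_shu, t80_u, t_c, t_b, 1)
  mid1 <- (fz2 + fz3) / 2
  mid2 <- (fz4 + fz3) / 2
  sh_l <- max(thr_l - shoulder, f0 + 0.02)
  values <- function(theta_l, alpha, theta_u) {
    sh_u <- thr_u + shoulder * (0.4 + 0.6 * theta_u)
    # a mid-window mean above the chords is achieved by bulging only the
    # steep descending half; bulging the shallow ascending half would
    # flatten the approach to the second peak into a noise-prone plateau
    v_m2 <- fz3 + min(alpha, 1) * (mid2 - fz3)
    v_a <- f0 + theta_l * (sh_l - f0)                      # early ramp height
    v_c <- max(thr_u - 2 * (thr_u - f0) / run_u, f0 + 0.04)
    v_b <- f0 + theta_u * (v_c - 0.01 - f0)                # tail height
    c(f0,
      v_a,
      v_a + 0.75 * theta_l * (sh_l - v_a),                 # ramp fullness
      sh_l,
      thr_l,
      thr_l + (0.2 + 0.75 * theta_l) * (fz2 - thr_l),      # upper-ramp sag/bulge
      fz2,
      fz3 + alpha * (mid1 - fz3), fz3, v_m2,
      max(fz4 - 0.04, v_m2 + 0.25 * (fz4 - v_m2)),         # peak shoulder
      fz4,
      max(thr_u + (0.12 + 0.8 * theta_u) * (fz4 - thr_u), sh_u + 0.01),
      sh_u,
      thr_u,
      v_c,
      v_b,
      f0)
  }
  build <- function(theta_l, alpha, theta_u) {
    hermite_fun(u, values(theta_l, alpha, theta_u))
  }

  # each handle only influences its own window (derivatives vanish at the
  # extremum anchors), so three independent 1-d solves suffice; the window
  # mean is close to linear in each handle, so a bracketed secant converges
  # in a couple of corrections
  solve_handle <- function(lo, hi, target, grid, make) {
    if (is.null(target)) return(list(x = (lo + hi) / 2, clamped = FALSE))
    obj <- function(x) mean(make(x)(grid)) - target
    flo <- obj(lo); fhi <- obj(hi)
    if (flo >= 0) return(list(x = lo, clamped = TRUE))
    if (fhi <= 0) return(list(x = hi, clamped = TRUE))
    x0 <- lo; f0_ <- flo; x1 <- hi; f1_ <- fhi
    for (it in 1:6) {
      x2 <- x1 - f1_ * (x1 - x0) / (f1_ - f0_)
      x2 <- min(max(x2, lo), hi)
      f2_ <- obj(x2)
      if (abs(f2_) < 2e-4) return(list(x = x2, clamped = FALSE))
      if (sign(f2_) == sign(f0_)) { x0 <- x2; f0_ <- f2_ } else { x1 <- x2; f1_ <- f2_ }
    }
    list(x = x2, clamped = FALSE)
  }
  calibrate <- function(i2, i4) {
    grid_load <- (0:i2) / m
    grid_mid <- (i2:i4) / m
    grid_unload <- (i4:m) / m
    sl <- solve_handle(0.03, 0.97, fmean_load, grid_load,
                       function(x) build(x, 1, 0.5))
    sa <- solve_handle(0.05, 1.95, fmean_mid, grid_mid,
                       function(a) build(sl$x, a, 0.5))
    su <- solve_handle(0.03, 0.97, fmean_unload, grid_unload,
                       function(x) build(sl$x, sa$x, x))
    list(theta_l = sl$x, alpha = sa$x, theta_u = su$x,
         clamped = c(load = sl$clamped, mid = sa$clamped, unload = su$clamped))
  }

  # calibrate on the indices a clean pipeline run (Gaussian smoothing +
  # strict local extrema) detects; iterate until the detected indices of the
  # calibrated shape are the ones the calibration used
  i2a <- round(t_fz2 * m); i4a <- round(t_fz4 * m)
  idx <- detect_template_indices(build(0.5, 1, 0.5),
                                 m, i2a, round(t_fz3 * m), i4a)
  for (pass in 1:3) {
    h2 <- calibrate(idx[1], idx[3])
    f <- build(h2$theta_l, h2$alpha, h2$theta_u)
    idx2 <- detect_template_indices(f, m, idx[1], idx[2], idx[3])
    if (identical(idx2, idx)) break
    idx <- idx2
  }
  clamped <- h2$clamped
  v_grid <- f((0:m) / m)
  wm <- stance_window_means(v_grid, idx[1], idx[3])
  realized <- list(
    fz2 = v_grid[idx[1] + 1L], fz3 = v_grid[idx[2] + 1L],
    fz4 = v_grid[idx[3] + 1L],
    fz2_idx = idx[1], fz3_idx = idx[2], fz4_idx = idx[3],
    fmean_stance = wm$fmean_stance,
    fmean_load = wm$fmean_load, fmean_mid = wm$fmean_mid,
    fmean_unload = wm$fmean_unload,
    loading_slope = stance_loading_slope(v_grid, v_grid[idx[1] + 1L]),
    unloading_slope = stance_unloading_slope(v_grid, v_grid[idx[3] + 1L],
                                             idx[3])
  )
  structure(list(
    f = f,
    anchors = tibble::new_tibble(
      list(u = u, v = values(h2$theta_l, h2$alpha, h2$theta_u)),
      nrow = length(u)),
    clamped = clamped,
    realized = realized,
    targets = list(
      fz2 = fz2, fz3 = fz3, fz4 = fz4,
      t_fz2 = t_fz2, t_fz3 = t_fz3, t_fz4 = t_fz4,
      loading_slope = loading_slope, unloading_slope = unloading_slope,
      fmean_load = fmean_load, fmean_mid = fmean_mid,
      fmean_unload = fmean_unload, boundary_level = boundary_level
    )
  ), class = "stance_template")
}

# extremum indices (0-based fz2/fz3/fz4) that the pipeline's smoothed-curve
# detection finds on the discretised clean template; falls back to the
# supplied anchor indices if detection is not unambiguous
detect_template_indices <- function(f, m, i2, i3, i4) {
  fs <- gaussian_smooth(f((0:m) / m))
  cands <- candidates_core(fs)
  maxima <- cands$index[cands$polarity == "max"]
  minima <- cands$index[cands$polarity == "min"]
  if (length(maxima) == 2 && length(minima) == 1 &&
      maxima[1] < minima && minima < maxima[2]) {
    c(maxima[1], minima, maxima[2])
  } else {
    c(i2, i3, i4)
  }
}
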