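# small, fast scene for unit tests (full-size defaults are exercised in
# the acceptance suite)
test_scene_params <- function(...) {
  base <- list(n_cells = 2L, cell_width_px = 60L, cell_height_px = 48L,
               membrane_band_px = 4, junction_belt_px = 3,
               nucleus_radius_px = 10, n_spots_per_cell = 12L,
               n_z = 11L, margin_px = 8, seed = 42L)
  do.call(scene_params, utils::modifyList(base, list(...)))
}

# render isotropic 2D Gaussians onto a constant background
render_gaussians_2d <- function(ny, nx, y, x, amplitude, sigma, background = 0) {
  img <- matrix(background, ny, nx)
  for (i in seq_along(y)) {
    img <- img + amplitude[i] *
      (exp(-(seq_len(ny) - y[i])^2 / (2 * sigma^2)) %o%
         exp(-(seq_len(nx) - x[i])^2 / (2 * sigma^2)))
  }
  img
}

# minimal spot_set builder for calibration/counting tests
make_spot_set <- function(amplitude, retained = TRUE, isolated = TRUE,
                          mode = "amplitude") {
  n <- length(amplitude)
  df <- data.frame(spot_id = seq_len(n), y = seq_len(n) * 10, x = 5,
                   amplitude = amplitude, background = 0, sigma = 1.3,
                   intensity = 2 * pi * amplitude * 1.3^2,
                   response = amplitude, quality = 0.01,
                   retained = rep_len(retained, n),
                   isolated = rep_len(isolated, n),
                   flag = "ok", units = NA_integer_,
                   stringsAsFactors = FALSE)
  class(df) <- c("spot_set", "data.frame")
  attr(df, "det_params") <- det_params(mode = mode)
  df
}

# greedy one-to-one matching of detections to ground truth
match_spots <- function(det_y, det_x, gt_y, gt_x, tol = 1) {
  if (!length(det_y) || !length(gt_y))
    return(list(recall = 0, precision = 0, errors = numeric(0)))
  D <- sqrt(outer(det_y, gt_y, "-")^2 + outer(det_x, gt_x, "-")^2)
  m_gt <- rep(FALSE, length(gt_y)); m_det <- rep(FALSE, length(det_y))
  errs <- numeric(0)
  for (k in order(D)) {
    if (D[k] > tol) break
    i <- (k - 1L) %% nrow(D) + 1L
    j <- (k - 1L) %/% nrow(D) + 1L
    if (!m_det[i] && !m_gt[j]) {
      m_det[i] <- TRUE; m_gt[j] <- TRUE; errs <- c(errs, D[k])
    }
  }
  list(recall = mean(m_gt), precision = mean(m_det), errors = errs)
}

# random convex polygon: convex hull of points on a jittered circle
random_convex_polygon <- function(n = 8L, radius = 10, center = c(20, 20)) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- radius * stats::runif(n, 0.6, 1)
  pts <- cbind(x = center[1L] + r * cos(th), y = center[2L] + r * sin(th))
  hull <- grDevices::chull(pts)
  pts[hull, , drop = FALSE]
}
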