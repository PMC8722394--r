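#' Detection parameters for smFISH spots
#'
#' @param sigma Expected lateral spot sigma in pixels (diffraction-limited
#'   PSF width).
#' @param threshold Detection threshold on the amplitude-normalized
#'   band-pass (LoG) response; `NULL` picks `threshold_k` robust noise sds
#'   of the response (MAD-based), estimated per image.
#' @param threshold_k Multiplier for the automatic threshold.
#' @param min_separation Minimum center-to-center distance in pixels;
#'   closer candidates are merged keeping the brighter (default 1.2, just
#'   above the pixel grid, so near-diffraction-limit pairs stay separable).
#' @param fit_window_factor Half-width of the Gaussian fit window in units
#'   of `sigma` (default 2; small windows keep fits local so neighboring
#'   spots cannot capture them).
#' @param sigma_range Allowed fitted sigma range `c(min, max)` in pixels
#'   when `sigma_fit = "free"`.
#' @param sigma_fit `"fixed"` (default) pins the fitted width to `sigma`
#'   (the PSF width is known for a given objective), which substantially
#'   reduces amplitude noise and so the bias of the dimmest-5 unit
#'   calibration; `"free"` fits the width per spot.
#' @param center_bound_px Maximum distance the fitted center may move from
#'   the detected candidate (default 1.5 px).
#' @param residual_threshold_factor Multiplier on the detection threshold
#'   for the second (residual) candidate pass; residual peaks must clear
#'   this higher bar so that model-mismatch ripples around bright spots
#'   are not called as spots (default 3).
#' @param min_unit_fraction Retained spots must reach this fraction of the
#'   modal fitted amplitude (default 0.5). Since a retained dot represents
#'   at least one mRNA and the modal dot is a single mRNA, fits far below
#'   the mode are flux-splitting artifacts of crowded regions, not spots;
#'   0 disables the filter.
#' @param mode Spot intensity read-out used for unit calibration and
#'   counting: fitted peak `"amplitude"` (default) or `"integrated"`
#'   intensity (`2 * pi * A * s^2`).
#' @return A list of class `det_params`.
#' @export
det_params <- function(sigma = 1.3, threshold = NULL, threshold_k = 6,
                       min_separation = 1.2, fit_window_factor = 3,
                       sigma_range = c(0.4, 2.5) * sigma,
                       sigma_fit = c("fixed", "free"),
                       center_bound_px = 1.5,
                       residual_threshold_factor = 3,
                       min_unit_fraction = 0.5,
                       mode = c("amplitude", "integrated")) {
  mode <- match.arg(mode)
  sigma_fit <- match.arg(sigma_fit)
  stopifnot(sigma > 0, min_separation >= 0, fit_window_factor > 0,
            center_bound_px > 0, residual_threshold_factor >= 1,
            min_unit_fraction >= 0, min_unit_fraction < 1,
            length(sigma_range) == 2L, sigma_range[1L] > 0,
            sigma_range[1L] < sigma_range[2L])
  if (!is.null(threshold)) stopifnot(is.numeric(threshold), threshold > 0)
  structure(list(sigma = sigma, threshold = threshold,
                 threshold_k = threshold_k, min_separation = min_separation,
                 fit_window_factor = fit_window_factor,
                 sigma_range = sigma_range, sigma_fit = sigma_fit,
                 center_bound_px = center_bound_px,
                 residual_threshold_factor = residual_threshold_factor,
                 min_unit_fraction = min_unit_fraction, mode = mode),
            class = "det_params")
}

# Amplitude-normalized negated-LoG kernel: the filter response at the
# center of a Gaussian spot of matched sigma equals the spot's amplitude,
# and the kernel has zero DC so constant background does not respond.
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  g <- seq(-r, r)
  xx <- matrix(rep(g, each = length(g)), length(g))
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- -(1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))  # negated LoG shape
  k <- k - mean(k)
  spot <- exp(-r2 / (2 * sigma^2))
  k / sum(k * spot)
}

empty_spot_set <- function() {
  structure(data.frame(spot_id = integer(0), y = numeric(0), x = numeric(0),
                       amplitude = numeric(0), background = numeric(0),
                       sigma = numeric(0), intensity = numeric(0),
                       response = numeric(0), quality = numeric(0),
                       retained = logical(0), isolated = logical(0),
                       flag = character(0),
                       units = integer(0), stringsAsFactors = FALSE),
            class = c("spot_set", "data.frame"))
}

#' Detect smFISH spots in a 2D image
#'
#' Candidate spots are local maxima of an amplitude-normalized
#' Laplacian-of-Gaussian (band-pass) response above a threshold; candidates
#' closer than the minimum separation are merged keeping the brighter.
#' Each surviving candidate is refined to subpixel position by a local
#' least-squares Gaussian fit ([fit_amplitude()]). Because neighboring
#' spots bias single-spot fits, detection then (i) refits every spot with
#' the current model of all other spots subtracted from its window, and
#' (ii) runs a second candidate search on the residual image (raw image
#' minus the fitted spot model) so that close pairs hidden under a
#' brighter neighbor's flank are recovered, followed by a final
#' subtraction refit. Spots whose fit window is clipped by the image edge
#' are flagged and excluded from calibration; non-convergent fits are
#' dropped. Detection is deterministic.
#'
#' Seam-cell analyses run on maximum-intensity projections; pass the
#' output of [max_project()].
#'
#' @param img Numeric (y, x) matrix, single channel.
#' @param params A [det_params()] object.
#' @return A `spot_set` data frame with columns `spot_id`, subpixel
#'   `y`/`x`, `amplitude`, `background`, `sigma`, integrated `intensity`,
#'   LoG `response`, fit `quality` (RMS residual / amplitude), `retained`,
#'   `flag`, and `units` (`NA` until [count_mrna()]).
#' @export
detect_spots <- function(img, params = det_params()) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (any(!is.finite(img))) stop("image contains non-finite pixels")
  if (stats::sd(img) == 0) {
    warning("zero-variance image: no spots detected")
    out <- empty_spot_set()
    attr(out, "det_params") <- params
    return(out)
  }
  kern <- log_kernel(params$sigma)
  resp <- ebi_filter2(img, kern)
  thr <- params$threshold
  if (is.null(thr)) thr <- params$threshold_k * stats::mad(resp, center = 0)

  cand <- log_candidates(resp, thr, params$min_separation)
  if (nrow(cand) == 0L) {
    out <- empty_spot_set()
    attr(out, "det_params") <- params
    return(out)
  }
  fits <- fit_candidates(img, cand, params, subtract = NULL)
  fits <- refit_clusters(img, fits, params)

  # second pass on the residual: spots hiding under a neighbor's flank
  resid <- img - spot_model_image(fits, dim(img))
  resp2 <- ebi_filter2(resid, kern)
  cand2 <- log_candidates(resp2, params$residual_threshold_factor * thr,
                          params$min_separation)
  if (nrow(cand2) > 0L) {
    # components closer than ~1.5 sigma to an already-fitted spot are not
    # resolvable as separate emitters; rejecting them stops the residual
    # pass from splitting one spot's flux into two fits (the joint cluster
    # refit arbitrates the remainder)
    excl <- max(params$min_separation, 1.2 * params$sigma)
    ok <- fits$retained
    far <- vapply(seq_len(nrow(cand2)), function(i) {
      all(((fits$y[ok] - cand2$y[i])^2 + (fits$x[ok] - cand2$x[i])^2)
          >= excl^2)
    }, logical(1L))
    cand2 <- cand2[far, , drop = FALSE]
  }
  if (nrow(cand2) > 0L) {
    fits2 <- fit_candidates(img, cand2, params, subtract = fits)
    fits <- rbind(fits, fits2)
    fits <- refit_clusters(img, fits, params)
  }

  out <- fits[order(-fits$response), , drop = FALSE]
  # fits of distinct candidates can converge onto the same spot: drop
  # refined positions that collapse onto a brighter one
  out <- out[merge_by_separation(out$y, out$x, min(1, params$min_separation)), ,
             drop = FALSE]
  # a refitted amplitude can fall below the detection bar once its
  # neighbors' contribution is accounted for
  out$retained <- out$retained & out$amplitude >= thr
  out$flag[!out$retained & out$flag == "ok"] <- "below_threshold"
  if (params$min_unit_fraction > 0 && sum(out$retained) >= 10L) {
    amps <- out$amplitude[out$retained]
    dens <- stats::density(amps, n = 512)
    modal <- dens$x[which.max(dens$y)]
    sub <- out$retained & out$amplitude < params$min_unit_fraction * modal
    out$retained[sub] <- FALSE
    out$flag[sub] <- "sub_unit"
  }
  out$spot_id <- seq_len(nrow(out))
  out$units <- NA_integer_
  # isolation flag: no other retained spot within 4 sigma; isolated spots
  # carry crowding-free amplitudes and anchor the unit calibration
  ry <- out$y[out$retained]; rx <- out$x[out$retained]
  out$isolated <- vapply(seq_len(nrow(out)), function(i) {
    d2 <- (ry - out$y[i])^2 + (rx - out$x[i])^2
    sum(d2 < (4 * params$sigma)^2) <= sum(out$retained[i])
  }, logical(1L))
  out <- out[, c("spot_id", "y", "x", "amplitude", "background", "sigma",
                 "intensity", "response", "quality", "retained", "isolated",
                 "flag", "units")]
  rownames(out) <- NULL
  class(out) <- c("spot_set", "data.frame")
  attr(out, "det_params") <- params
  attr(out, "threshold") <- thr
  out
}

# threshold + plateau-tolerant local maxima + keep-brighter merge
log_candidates <- function(resp, thr, min_sep) {
  mx <- neighborhood_max(resp)
  cand <- which(resp >= mx & resp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(y = numeric(0), x = numeric(0), response = numeric(0)))
  v <- resp[cand]
  ord <- order(-v, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  v <- v[ord]
  keep <- merge_by_separation(cand[, 1L], cand[, 2L], min_sep)
  data.frame(y = as.numeric(cand[keep, 1L]), x = as.numeric(cand[keep, 2L]),
             response = v[keep])
}

fit_candidates <- function(img, cand, params, subtract = NULL) {
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    w <- neighbor_subtracted(img, cand$y[i], cand$x[i], params, subtract,
                             exclude = 0L)
    ft <- fit_amplitude(w, cand$y[i], cand$x[i],
                        sigma = params$sigma,
                        window_factor = params$fit_window_factor,
                        sigma_range = params$sigma_range,
                        sigma_fit = params$sigma_fit,
                        center_bound_px = params$center_bound_px)
    ft$response <- cand$response[i]
    rows[[i]] <- ft
  }
  do.call(rbind, rows)
}

# image with the fitted model of all spots except `exclude` removed
# (full-frame subtraction is wasteful; only the fit window matters, but the
# fitter re-extracts its window from a full matrix, so patch in place)
neighbor_subtracted <- function(img, y, x, params, fits, exclude) {
  if (is.null(fits)) return(img)
  r <- ceiling(params$fit_window_factor * params$sigma)
  reach <- r + 4 * max(params$sigma, max(fits$sigma, na.rm = TRUE))
  near <- which(fits$retained & abs(fits$y - y) <= reach &
                  abs(fits$x - x) <= reach)
  near <- setdiff(near, exclude)
  if (!length(near)) return(img)
  y0 <- round(y); x0 <- round(x)
  iy <- max(1L, y0 - r):min(nrow(img), y0 + r)
  ix <- max(1L, x0 - r):min(ncol(img), x0 + r)
  w <- img[iy, ix]
  for (j in near) {
    w <- w - fits$amplitude[j] *
      (exp(-(iy - fits$y[j])^2 / (2 * fits$sigma[j]^2)) %o%
         exp(-(ix - fits$x[j])^2 / (2 * fits$sigma[j]^2)))
  }
  img[iy, ix] <- w
  img
}

refit_with_subtraction <- function(img, fits, params, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(fits))
  ord <- idx[order(-fits$response[idx])]
  for (i in ord) {
    if (!fits$retained[i]) next
    w <- neighbor_subtracted(img, fits$y[i], fits$x[i], params, fits,
                             exclude = i)
    ft <- fit_amplitude(w, round(fits$y[i]), round(fits$x[i]),
                        sigma = params$sigma,
                        window_factor = params$fit_window_factor,
                        sigma_range = params$sigma_range,
                        sigma_fit = params$sigma_fit,
                        center_bound_px = params$center_bound_px)
    if (ft$retained) {
      fits[i, c("y", "x", "amplitude", "background", "sigma",
                "intensity", "quality")] <-
        ft[, c("y", "x", "amplitude", "background", "sigma",
               "intensity", "quality")]
    }
  }
  fits
}

# single-linkage clusters of retained spots (link if closer than 4 sigma)
spot_clusters <- function(fits, link_dist) {
  idx <- which(fits$retained)
  n <- length(idx)
  if (n == 0L) return(list())
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if ((fits$y[idx[i]] - fits$y[idx[j]])^2 +
          (fits$x[idx[i]] - fits$x[idx[j]])^2 <= link_dist^2) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
  }
  unname(split(idx, comp))
}

# Spots whose PSFs overlap cannot be fit one at a time without flux
# stealing; clusters up to `max_joint` members are refit jointly (common
# background, sum of fixed-width Gaussians), larger clusters fall back to
# iterated single-spot refits with the neighbor model subtracted.
refit_clusters <- function(img, fits, params, max_joint = 8L) {
  cl <- spot_clusters(fits, link_dist = 4 * params$sigma)
  for (idx in cl) {
    if (length(idx) == 1L) {
      # even isolated spots see the flank of neighbors one window away
      fits <- refit_with_subtraction(img, fits, params, idx = idx)
      next
    }
    if (length(idx) <= max_joint) {
      fits <- joint_fit_cluster(img, fits, idx, params)
    } else {
      fits <- refit_with_subtraction(img, fits, params, idx = idx)
      fits <- refit_with_subtraction(img, fits, params, idx = idx)
    }
  }
  fits
}

joint_fit_cluster <- function(img, fits, idx, params) {
  r <- ceiling(params$fit_window_factor * params$sigma)
  y0 <- round(fits$y[idx]); x0 <- round(fits$x[idx])
  iy <- max(1L, min(y0) - r):min(nrow(img), max(y0) + r)
  ix <- max(1L, min(x0) - r):min(ncol(img), max(x0) + r)
  # subtract retained spots outside the cluster that reach into the window
  w <- img
  reach <- r + 4 * params$sigma
  near <- setdiff(which(fits$retained &
                          fits$y >= min(iy) - reach & fits$y <= max(iy) + reach &
                          fits$x >= min(ix) - reach & fits$x <= max(ix) + reach),
                  idx)
  for (j in near) {
    w[iy, ix] <- w[iy, ix] - fits$amplitude[j] *
      (exp(-(iy - fits$y[j])^2 / (2 * fits$sigma[j]^2)) %o%
         exp(-(ix - fits$x[j])^2 / (2 * fits$sigma[j]^2)))
  }
  v <- as.vector(w[iy, ix])
  Y <- rep(iy, times = length(ix)); X <- rep(ix, each = length(iy))
  k <- length(idx)
  sig <- params$sigma
  cb <- params$center_bound_px
  par0 <- c(min(v), rbind(pmax(fits$amplitude[idx], 1e-6),
                          fits$y[idx], fits$x[idx]))
  lower <- c(-Inf, rbind(rep(1e-9, k), fits$y[idx] - cb, fits$x[idx] - cb))
  upper <- c(Inf, rbind(rep(Inf, k), fits$y[idx] + cb, fits$x[idx] + cb))
  model <- function(p) {
    m <- rep(p[1L], length(v))
    for (q in seq_len(k)) {
      a <- p[3L * q - 1L]; cy <- p[3L * q]; cx <- p[3L * q + 1L]
      m <- m + a * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sig^2))
    }
    m
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = function(p) model(p) - v,
                       control = minpack.lm::nls.lm.control(maxiter = 80)),
    error = function(e) NULL)
  if (is.null(res)) return(fits)
  p <- res$par
  rms <- sqrt(mean((model(p) - v)^2))
  for (q in seq_len(k)) {
    i <- idx[q]
    fits$amplitude[i] <- p[3L * q - 1L]
    fits$y[i] <- p[3L * q]
    fits$x[i] <- p[3L * q + 1L]
    fits$background[i] <- p[1L]
    fits$sigma[i] <- sig
    fits$intensity[i] <- 2 * pi * fits$amplitude[i] * sig^2
    fits$quality[i] <- rms / max(fits$amplitude[i], 1e-9)
  }
  fits
}

# sum of all retained fitted Gaussians (no background), windowed at 4 sigma
spot_model_image <- function(fits, d) {
  model <- matrix(0, d[1L], d[2L])
  for (i in which(fits$retained)) {
    s <- fits$sigma[i]
    iy <- max(1L, floor(fits$y[i] - 4 * s)):min(d[1L], ceiling(fits$y[i] + 4 * s))
    ix <- max(1L, floor(fits$x[i] - 4 * s)):min(d[2L], ceiling(fits$x[i] + 4 * s))
    model[iy, ix] <- model[iy, ix] + fits$amplitude[i] *
      (exp(-(iy - fits$y[i])^2 / (2 * s^2)) %o%
         exp(-(ix - fits$x[i])^2 / (2 * s^2)))
  }
  model
}

# 2D convolution with edge replication via EBImage's FFT filter
ebi_filter2 <- function(img, kern) {
  r <- (dim(kern)[1L] - 1L) / 2
  padded <- img[c(rep(1L, r), seq_len(nrow(img)), rep(nrow(img), r)),
                c(rep(1L, r), seq_len(ncol(img)), rep(ncol(img), r))]
  f <- EBImage::filter2(EBImage::Image(padded), kern)
  EBImage::imageData(f)[r + seq_len(nrow(img)), r + seq_len(ncol(img))]
}

neighborhood_max <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(-Inf, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    out <- pmax(out, pad[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx])
  }
  out
}

# greedy keep-brighter merge; input must be ordered by decreasing brightness
merge_by_separation <- function(y, x, min_sep) {
  n <- length(y)
  keep <- logical(n)
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_len(n)) {
    if (!length(ky) || all((ky - y[i])^2 + (kx - x[i])^2 >= min_sep^2)) {
      keep[i] <- TRUE
      ky <- c(ky, y[i]); kx <- c(kx, x[i])
    }
  }
  keep
}

#' Fit a 2D Gaussian to one spot
#'
#' Least-squares fit of `b + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 s^2))`
#' in a square window (half-width `window_factor * sigma`) around the
#' candidate position. The amplitude is the fitted peak height above the
#' fitted local background — the spot intensity used for unit calibration.
#' The fitted center is constrained to within `center_bound_px` of the
#' candidate so a brighter neighbor inside the window cannot capture the
#' fit, and the width is pinned to the PSF sigma by default (see
#' [det_params()]).
#'
#' @param img Numeric (y, x) matrix.
#' @param y,x Candidate center (pixels, may be integer candidate position).
#' @param sigma PSF sigma (fixed width, or starting value when free).
#' @param window_factor Window half-width in sigmas.
#' @param sigma_range Admissible fitted sigma range (free fits).
#' @param sigma_fit `"fixed"` or `"free"` width.
#' @param center_bound_px Center movement bound in pixels.
#' @return One-row data frame with `y`, `x` (subpixel), `amplitude`,
#'   `background`, `sigma`, `intensity`, `quality`, `retained`, `flag`
#'   (`"ok"`, `"edge"` or `"fit_failed"`).
#' @export
fit_amplitude <- function(img, y, x, sigma = 1.3, window_factor = 3,
                          sigma_range = c(0.4, 2.5) * sigma,
                          sigma_fit = c("fixed", "free"),
                          center_bound_px = 1.5) {
  sigma_fit <- match.arg(sigma_fit)
  r <- ceiling(window_factor * sigma)
  y <- unname(as.numeric(y)); x <- unname(as.numeric(x))
  y0 <- round(y); x0 <- round(x)
  row <- data.frame(y = as.numeric(y), x = as.numeric(x),
                    amplitude = NA_real_, background = NA_real_,
                    sigma = NA_real_, intensity = NA_real_,
                    quality = NA_real_, retained = FALSE, flag = "edge",
                    stringsAsFactors = FALSE)
  if (y0 - r < 1L || y0 + r > nrow(img) || x0 - r < 1L || x0 + r > ncol(img))
    return(row)
  iy <- (y0 - r):(y0 + r); ix <- (x0 - r):(x0 + r)
  w <- img[iy, ix]
  df <- data.frame(v = as.vector(w),
                   Y = rep(iy, times = length(ix)),
                   X = rep(ix, each = length(iy)))
  b0 <- min(w)
  a0 <- max(w) - b0
  if (a0 <= 0) { row$flag <- "fit_failed"; return(row) }
  cb <- center_bound_px
  fit <- tryCatch(
    if (sigma_fit == "fixed") {
      minpack.lm::nlsLM(
        v ~ b + A * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma^2)),
        data = df,
        start = list(b = b0, A = a0, cx = x0, cy = y0),
        lower = c(b = -Inf, A = 1e-9, cx = x0 - cb, cy = y0 - cb),
        upper = c(b = Inf, A = Inf, cx = x0 + cb, cy = y0 + cb),
        control = minpack.lm::nls.lm.control(maxiter = 60))
    } else {
      minpack.lm::nlsLM(
        v ~ b + A * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * s^2)),
        data = df,
        start = list(b = b0, A = a0, cx = x0, cy = y0, s = sigma),
        lower = c(b = -Inf, A = 1e-9, cx = x0 - cb, cy = y0 - cb,
                  s = sigma_range[1L]),
        upper = c(b = Inf, A = Inf, cx = x0 + cb, cy = y0 + cb,
                  s = sigma_range[2L]),
        control = minpack.lm::nls.lm.control(maxiter = 60))
    },
    error = function(e) NULL)
  if (is.null(fit)) { row$flag <- "fit_failed"; return(row) }
  cf <- stats::coef(fit)
  if (cf[["A"]] <= 0 || !all(is.finite(cf))) {
    row$flag <- "fit_failed"; return(row)
  }
  row$y <- cf[["cy"]]; row$x <- cf[["cx"]]
  row$amplitude <- cf[["A"]]; row$background <- cf[["b"]]
  row$sigma <- if (sigma_fit == "fixed") sigma else cf[["s"]]
  row$intensity <- 2 * pi * cf[["A"]] * row$sigma^2
  row$quality <- sqrt(mean(stats::resid(fit)^2)) / cf[["A"]]
  row$retained <- TRUE
  row$flag <- "ok"
  row
}

#' Calibrate the single-mRNA intensity unit
#'
#' The unit is the arithmetic mean of the intensities of the five dimmest
#' calibration-grade spots — operationally the "lightest" dots, taken to
#' be single mRNAs. Calibration-grade means retained and isolated (no
#' other spot within four PSF sigmas): this automates the manual practice
#' of outlining clean, well-separated dim dots, whose amplitudes are free
#' of crowding bias. If fewer isolated spots than requested exist, all
#' retained spots are eligible. Per-image calibration (pooling all cells
#' of one embryo image) is the default scope; call on a cell subset for
#' per-cell calibration.
#'
#' When the mRNA channel z-stack is supplied, each selected dot is
#' re-measured from its axial profile: per-slice amplitudes are obtained
#' in closed form (linear regression of the slice window on the Gaussian
#' template at the known center) and a 1D Gaussian is fit through them
#' over z. Amplitudes measured on maximum-intensity projections sit on a
#' noise-inflated floor (the projection raises the background by the
#' expected maximum of the noise but the spot peak by less); the z-profile
#' read-out removes that attenuation and, because it pools photons from
#' every slice, is precise enough that the selection (order-statistic)
#' bias of picking the dimmest few stays small.
#'
#' @param spots A `spot_set` from [detect_spots()].
#' @param n_dimmest Number of dimmest spots averaged (default 5).
#' @param allow_fewer If fewer than `n_dimmest` retained spots are
#'   available, fail (default) or use all available with a warning.
#' @param zstack Optional (z, y, x) array of the smFISH channel (e.g.
#'   `stack$voxels[1, , , ]`) for per-slice amplitude refits.
#' @return A `unit_calibration` list: `unit_amplitude`, `n_spots_used`,
#'   `mode`.
#' @export
calibrate_unit <- function(spots, n_dimmest = 5L, allow_fewer = FALSE,
                           zstack = NULL) {
  stopifnot(inherits(spots, "spot_set"))
  dp <- attr(spots, "det_params")
  mode <- dp$mode %||% "amplitude"
  elig <- which(spots$retained & is.finite(spots$amplitude))
  if (sum(spots$isolated[elig]) >= n_dimmest)
    elig <- elig[spots$isolated[elig]]
  if (length(elig) < n_dimmest) {
    if (!allow_fewer || length(elig) == 0L)
      stop("unit calibration needs >= ", n_dimmest, " retained spots (have ",
           length(elig), "); set allow_fewer = TRUE to use all available")
    warning("calibrating unit from only ", length(elig), " spots")
    n_dimmest <- length(elig)
  }
  v <- if (mode == "integrated") spots$intensity else spots$amplitude
  sel <- elig[order(v[elig])][seq_len(n_dimmest)]
  vals <- v[sel]
  if (!is.null(zstack)) {
    stopifnot(length(dim(zstack)) == 3L)
    for (k in seq_along(sel)) {
      i <- sel[k]
      a <- zprofile_amplitude(zstack, spots$y[i], spots$x[i],
                              sigma = spots$sigma[i], dp = dp)
      if (is.finite(a))
        vals[k] <- if (mode == "integrated")
          2 * pi * a * spots$sigma[i]^2 else a
    }
  }
  unit <- mean(vals)
  structure(list(unit_amplitude = unit, n_spots_used = as.integer(n_dimmest),
                 mode = mode),
            class = "unit_calibration")
}

# closed-form amplitude of a fixed-center, fixed-width Gaussian plus
# constant background: slope of the window regressed on the template
slice_amplitude <- function(slice, iy, ix, y, x, sigma) {
  w <- as.vector(slice[iy, ix])
  g <- as.vector(exp(-(iy - y)^2 / (2 * sigma^2)) %o%
                   exp(-(ix - x)^2 / (2 * sigma^2)))
  gc <- g - mean(g)
  sum(gc * w) / sum(gc * g)
}

# peak amplitude from the spot's axial profile: per-slice closed-form
# amplitudes, then a 1D Gaussian through them over z
zprofile_amplitude <- function(zstack, y, x, sigma, dp) {
  d <- dim(zstack)
  if (!is.finite(sigma)) sigma <- dp$sigma
  r <- ceiling((dp$fit_window_factor %||% 3) * sigma)
  y0 <- round(y); x0 <- round(x)
  if (y0 - r < 1L || y0 + r > d[2L] || x0 - r < 1L || x0 + r > d[3L])
    return(NA_real_)
  iy <- (y0 - r):(y0 + r); ix <- (x0 - r):(x0 + r)
  az <- vapply(seq_len(d[1L]), function(z)
    slice_amplitude(zstack[z, , ], iy, ix, y, x, sigma), numeric(1L))
  zz <- seq_len(d[1L])
  z0 <- zz[which.max(az)]
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ A * exp(-(z - cz)^2 / (2 * sz^2)),
                      data = data.frame(a = az, z = zz),
                      start = list(A = max(az), cz = z0, sz = 1.5),
                      lower = c(A = 1e-9, cz = 1, sz = 0.5),
                      upper = c(A = Inf, cz = d[1L], sz = d[1L]),
                      control = minpack.lm::nls.lm.control(maxiter = 60)),
    error = function(e) NULL)
  if (is.null(fit)) return(max(az))
  unname(stats::coef(fit)[["A"]])
}

#' @export
print.unit_calibration <- function(x, ...) {
  cat(sprintf("unit_calibration: 1 mRNA = %.2f (%s of %d dimmest spots)\n",
              x$unit_amplitude, x$mode, x$n_spots_used))
  invisible(x)
}

#' Convert spot intensities to mRNA counts
#'
#' Divides each retained spot's intensity by the calibrated single-mRNA
#' unit and rounds to the nearest integer with a floor of one: a detected,
#' retained dot represents at least one mRNA.
#'
#' @param spots A `spot_set`.
#' @param cal A `unit_calibration` from [calibrate_unit()].
#' @return The `spot_set` with the `units` column filled for retained
#'   spots.
#' @export
count_mrna <- function(spots, cal) {
  stopifnot(inherits(spots, "spot_set"), inherits(cal, "unit_calibration"))
  if (!is.finite(cal$unit_amplitude) || cal$unit_amplitude <= 0)
    stop("unit_amplitude must be positive")
  v <- if (cal$mode == "integrated") spots$intensity else spots$amplitude
  u <- rep(NA_integer_, nrow(spots))
  r <- spots$retained
  u[r] <- pmax(1L, as.integer(round(v[r] / cal$unit_amplitude)))
  spots$units <- u
  spots
}
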