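#' Parameters for a synthetic seam-cell scene
#'
#' Describes a ground-truthed synthetic embryo patch: a lateral row of
#' rectangular epithelial cells with a junction belt along the cell
#' borders, one nucleus per cell, and diffraction-limited smFISH spots
#' whose compartment (membrane band / cytoplasm / nucleus) and per-spot
#' mRNA multiplicity are drawn from controlled distributions. Scenes are
#' rendered as 4-channel 3D stacks (smFISH mRNA, junction protein GFP,
#' AJM-1 immunostain, DAPI) with a Gaussian PSF and Poisson + Gaussian
#' noise.
#'
#' Defaults emulate bean/comma-stage seam cells imaged on a widefield
#' system at 65 nm pixels: cells about 10 x 5 um (150 x 75 px), nuclei
#' about 2.6 um across, a 6 px (about 0.4 um) peri-membrane ground-truth
#' band, and a multiplicity distribution dominated by single mRNAs
#' (P(1)=0.8, P(2)=0.15, P(4)=0.05) so unit calibration from the dimmest
#' dots is well-posed.
#'
#' @param n_cells Number of cells in the row.
#' @param cell_width_px,cell_height_px Cell rectangle size in pixels.
#' @param membrane_band_px Width of the peri-membrane zone counted as
#'   "membrane" ground truth (inside the border).
#' @param junction_belt_px Rendered junction-marker belt width in pixels.
#' @param nucleus_radius_px Nucleus radius in pixels.
#' @param n_spots_per_cell Spots drawn per cell.
#' @param membrane_fraction,nuclear_fraction Placement probabilities for
#'   the membrane band and the nucleus; the remainder goes to interior
#'   cytoplasm. Must sum to at most 1.
#' @param multiplicity_dist Named numeric vector: probabilities of
#'   mRNAs-per-spot keyed by positive-integer multiplicity; must sum to 1.
#' @param unit_amplitude Peak intensity of a single mRNA (photon scale).
#' @param psf_sigma_px `c(lateral, axial)` Gaussian PSF sigma in pixels
#'   (axial in z-slice units).
#' @param background_level Mean background intensity.
#' @param noise Logical: apply Poisson noise on signal plus additive
#'   Gaussian read noise.
#' @param noise_gaussian_sd Read-noise standard deviation.
#' @param junction_amplitude,ajm_amplitude,dapi_amplitude Peak intensities
#'   of the junction-GFP belt, AJM-1 belt and DAPI nuclei.
#' @param n_z Number of z slices.
#' @param margin_px Margin between cells and the image boundary; must
#'   exceed 3 lateral PSF sigmas so no spot is clipped at the border.
#' @param apical_band_px Depth of the apical outline strip along the top
#'   cell edge.
#' @param profile_halfwidth_px Half-width of the apicobasal/apical profile
#'   bands.
#' @param voxel_size_um Physical voxel size `c(z, y, x)` in micrometers.
#' @param seed Integer RNG seed; a scene is fully determined by its
#'   parameters including the seed.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(n_cells = 5L,
                         cell_width_px = 150L,
                         cell_height_px = 75L,
                         membrane_band_px = 6,
                         junction_belt_px = 3,
                         nucleus_radius_px = 20,
                         n_spots_per_cell = 25L,
                         membrane_fraction = 0.6,
                         nuclear_fraction = 0.1,
                         multiplicity_dist = c("1" = 0.8, "2" = 0.15, "4" = 0.05),
                         unit_amplitude = 150,
                         psf_sigma_px = c(lateral = 1.3, axial = 1.5),
                         background_level = 20,
                         noise = TRUE,
                         noise_gaussian_sd = 2,
                         junction_amplitude = 120,
                         ajm_amplitude = 150,
                         dapi_amplitude = 80,
                         n_z = 15L,
                         margin_px = 12,
                         apical_band_px = 6,
                         profile_halfwidth_px = 4,
                         voxel_size_um = c(z = 0.2, y = 0.065, x = 0.065),
                         seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), cell_width_px = cell_width_px,
            cell_height_px = cell_height_px, membrane_band_px = membrane_band_px,
            junction_belt_px = junction_belt_px,
            nucleus_radius_px = nucleus_radius_px,
            n_spots_per_cell = as.integer(n_spots_per_cell),
            membrane_fraction = membrane_fraction,
            nuclear_fraction = nuclear_fraction,
            multiplicity_dist = multiplicity_dist,
            unit_amplitude = unit_amplitude, psf_sigma_px = psf_sigma_px,
            background_level = background_level, noise = isTRUE(noise),
            noise_gaussian_sd = noise_gaussian_sd,
            junction_amplitude = junction_amplitude,
            ajm_amplitude = ajm_amplitude, dapi_amplitude = dapi_amplitude,
            n_z = as.integer(n_z), margin_px = margin_px,
            apical_band_px = apical_band_px,
            profile_halfwidth_px = profile_halfwidth_px,
            voxel_size_um = voxel_size_um, seed = as.integer(seed))
  geom <- c("n_cells", "cell_width_px", "cell_height_px", "membrane_band_px",
            "junction_belt_px", "nucleus_radius_px", "unit_amplitude",
            "n_z", "margin_px", "apical_band_px", "profile_halfwidth_px")
  for (f in geom) if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
    stop("scene_params: '", f, "' must be a single positive number")
  if (p$n_spots_per_cell < 0L) stop("scene_params: n_spots_per_cell must be >= 0")
  if (p$membrane_fraction < 0 || p$nuclear_fraction < 0 ||
      p$membrane_fraction + p$nuclear_fraction > 1)
    stop("scene_params: membrane_fraction + nuclear_fraction must lie in [0, 1]")
  md <- p$multiplicity_dist
  if (is.null(names(md)) || any(is.na(suppressWarnings(as.integer(names(md))))) ||
      any(as.integer(names(md)) < 1L))
    stop("scene_params: multiplicity_dist must be named by positive integers")
  if (abs(sum(md) - 1) > 1e-8 || any(md < 0))
    stop("scene_params: multiplicity_dist probabilities must be >= 0 and sum to 1")
  if (length(p$psf_sigma_px) != 2L || any(p$psf_sigma_px <= 0))
    stop("scene_params: psf_sigma_px must be c(lateral, axial), both positive")
  names(p$psf_sigma_px) <- c("lateral", "axial")
  if (p$margin_px < 3 * p$psf_sigma_px[["lateral"]])
    stop("scene_params: margin_px must be at least 3 lateral PSF sigmas")
  if (p$background_level < 0 || p$noise_gaussian_sd < 0)
    stop("scene_params: background and noise sd must be non-negative")
  structure(p, class = "scene_params")
}

scene_channels <- c("mRNA", "DLG1_GFP", "AJM1", "DAPI")

cell_rect <- function(params, i) {
  x0 <- params$margin_px + (i - 1L) * params$cell_width_px
  c(x0 = x0, y0 = params$margin_px,
    x1 = x0 + params$cell_width_px, y1 = params$margin_px + params$cell_height_px)
}

scene_image_dim <- function(params) {
  c(n_z = params$n_z,
    n_y = as.integer(ceiling(2 * params$margin_px + params$cell_height_px)),
    n_x = as.integer(ceiling(2 * params$margin_px +
                               params$n_cells * params$cell_width_px)))
}

# rejection-sample n points uniformly over {accept(x, y)} within a bbox
sample_region <- function(n, bbox, accept) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  out <- matrix(numeric(0), 0L, 2L)
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("rejection sampling failed to fill a region")
    m <- max(2L * (n - nrow(out)), 32L)
    x <- stats::runif(m, bbox["x0"], bbox["x1"])
    y <- stats::runif(m, bbox["y0"], bbox["y1"])
    ok <- accept(x, y)
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Generate a ground-truthed synthetic scene
#'
#' Builds per-cell outlines (total border; interior outline inset by the
#' membrane-band width; nuclear disc; apical strip; profile bands) and
#' draws spot ground truth: each spot gets a compartment by the stated
#' placement probabilities, a uniform position within that compartment's
#' region, and an mRNA multiplicity from the multiplicity distribution.
#' Deterministic given the seed.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `rois` (a [roi_set]) and `truth` (class
#'   `ground_truth`: per-spot records, per-cell true counts and fractions,
#'   and the generating parameters).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  sz <- params$psf_sigma_px[["axial"]]
  zr <- c(1 + 3 * sz, params$n_z - 3 * sz)
  if (zr[1L] >= zr[2L])
    stop("n_z too small to keep spots 3 axial sigmas away from the z boundary")

  cells <- vector("list", params$n_cells)
  spot_rows <- vector("list", params$n_cells)
  for (i in seq_len(params$n_cells)) {
    r <- cell_rect(params, i)
    cid <- sprintf("cell%02d", i)
    total <- rect_polygon(r["x0"], r["y0"], r["x1"], r["y1"])
    interior <- tryCatch(
      offset_polygon_inward(total, params$membrane_band_px),
      error = function(e) stop("cell '", cid, "': membrane_band_px too large ",
                               "for the cell dimensions", call. = FALSE))
    cx <- (r["x0"] + r["x1"]) / 2; cy <- (r["y0"] + r["y1"]) / 2
    nuclear <- disc_polygon(cx, cy, params$nucleus_radius_px)
    if (!polygon_contains(interior, nuclear))
      stop("cell '", cid, "': nucleus (radius ", params$nucleus_radius_px,
           " px) does not fit inside the interior outline")
    apical <- rect_polygon(r["x0"], r["y0"], r["x1"],
                           min(r["y0"] + params$apical_band_px, r["y1"]))
    hw <- params$profile_halfwidth_px
    # bands extend past the cell edges so junction peaks at the borders are
    # interior maxima of the trace, not endpoints
    ext <- min(params$margin_px / 2, 2 * params$junction_belt_px)
    band_ab <- rect_polygon(r["x0"] - ext, cy - hw, r["x1"] + ext, cy + hw)
    band_ap <- rect_polygon(r["x0"] - ext, max(r["y0"] - hw, 1),
                            r["x1"] + ext, r["y0"] + hw)
    cells[[i]] <- roi_cell(cid, polygons = list(
      total = total, interior = interior, nuclear = nuclear, apical = apical,
      profile_band_apicobasal = band_ab, profile_band_apical = band_ap))

    n <- params$n_spots_per_cell
    if (n > 0L) {
      comp <- sample(c("membrane", "nucleus", "cytoplasm"), n, replace = TRUE,
                     prob = c(params$membrane_fraction, params$nuclear_fraction,
                              1 - params$membrane_fraction - params$nuclear_fraction))
      bbox <- c(x0 = unname(r["x0"]), x1 = unname(r["x1"]),
                y0 = unname(r["y0"]), y1 = unname(r["y1"]))
      pos <- matrix(NA_real_, n, 2L)
      for (cc in c("membrane", "cytoplasm", "nucleus")) {
        k <- which(comp == cc)
        if (!length(k)) next
        accept <- switch(cc,
          membrane = function(x, y) point_in_polygon(x, y, total) &
            !point_in_polygon(x, y, interior),
          cytoplasm = function(x, y) point_in_polygon(x, y, interior) &
            !point_in_polygon(x, y, nuclear),
          nucleus = function(x, y) point_in_polygon(x, y, nuclear))
        pos[k, ] <- sample_region(length(k), bbox, accept)
      }
      mult <- as.integer(sample(names(params$multiplicity_dist), n,
                                replace = TRUE, prob = params$multiplicity_dist))
      spot_rows[[i]] <- data.frame(
        cell_id = cid, z = stats::runif(n, zr[1L], zr[2L]),
        y = pos[, 2L], x = pos[, 1L], compartment = comp,
        multiplicity = mult, stringsAsFactors = FALSE)
    }
  }
  spots <- if (length(sr <- Filter(Negate(is.null), spot_rows))) {
    do.call(rbind, sr)
  } else {
    data.frame(cell_id = character(0), z = numeric(0), y = numeric(0),
               x = numeric(0), compartment = character(0),
               multiplicity = integer(0), stringsAsFactors = FALSE)
  }
  rownames(spots) <- NULL

  cell_ids <- vapply(cells, `[[`, character(1L), "cell_id")
  truth_cells <- do.call(rbind, lapply(cell_ids, function(cid) {
    s <- spots[spots$cell_id == cid, , drop = FALSE]
    tot <- sum(s$multiplicity)
    mem <- sum(s$multiplicity[s$compartment == "membrane"])
    nuc <- sum(s$multiplicity[s$compartment == "nucleus"])
    data.frame(cell_id = cid, n_spots = nrow(s), total_units = tot,
               membrane_units = mem, nuclear_units = nuc,
               true_fraction = if (tot > 0) mem / tot else NA_real_,
               stringsAsFactors = FALSE)
  }))
  truth <- structure(list(spots = spots, cells = truth_cells, params = params,
                          seed = params$seed),
                     class = "ground_truth")
  list(rois = roi_set(cells), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d spots across %d cells (seed %d)\n",
              nrow(x$spots), nrow(x$cells), x$seed))
  invisible(x)
}

# add an anisotropic 3D Gaussian of peak `amp` at (z0, y0, x0) into arr[z,y,x]
add_gaussian3d <- function(arr, z0, y0, x0, amp, sl, sa) {
  d <- dim(arr)
  iz <- max(1L, floor(z0 - 4 * sa)):min(d[1L], ceiling(z0 + 4 * sa))
  iy <- max(1L, floor(y0 - 4 * sl)):min(d[2L], ceiling(y0 + 4 * sl))
  ix <- max(1L, floor(x0 - 4 * sl)):min(d[3L], ceiling(x0 + 4 * sl))
  wz <- exp(-((iz - z0)^2) / (2 * sa^2))
  wy <- exp(-((iy - y0)^2) / (2 * sl^2))
  wx <- exp(-((ix - x0)^2) / (2 * sl^2))
  arr[iz, iy, ix] <- arr[iz, iy, ix] + amp * (wz %o% wy %o% wx)
  arr
}

# distance from grid points to the boundary of an axis-aligned rectangle
rect_border_distance <- function(px, py, r) {
  dx <- pmax(r["x0"] - px, px - r["x1"], 0)
  dy <- pmax(r["y0"] - py, py - r["y1"], 0)
  outside <- sqrt(dx^2 + dy^2)
  inside <- pmin(px - r["x0"], r["x1"] - px, py - r["y0"], r["y1"] - py)
  ifelse(outside > 0, outside, pmax(inside, 0))
}

#' Render a scene into a 4-channel image stack
#'
#' Channel order is documented and fixed: 1 = smFISH mRNA, 2 = junction
#' protein GFP (DLG-1::GFP), 3 = AJM-1 immunostain, 4 = DAPI. Each spot is
#' rendered as a 3D Gaussian whose peak is `multiplicity x unit_amplitude`;
#' the junction channels render a belt along the cell borders, DAPI renders
#' filled nuclei, and all structural channels are blurred with the lateral
#' PSF. Poisson noise on the signal plus additive Gaussian read noise is
#' applied last (negative values are clamped to zero). Deterministic given
#' the scene seed.
#'
#' @param scene Output of [generate_scene()].
#' @param params The same [scene_params()] used to generate the scene.
#' @return An [image_stack].
#' @export
render_stack <- function(scene, params) {
  stopifnot(inherits(params, "scene_params"), is.list(scene),
            inherits(scene$truth, "ground_truth"))
  d <- scene_image_dim(params)
  if (any(d <= 0)) stop("non-positive image dimensions")
  nz <- d[["n_z"]]; ny <- d[["n_y"]]; nx <- d[["n_x"]]
  sl <- params$psf_sigma_px[["lateral"]]; sa <- params$psf_sigma_px[["axial"]]

  fish <- array(params$background_level, c(nz, ny, nx))
  sp <- scene$truth$spots
  if (nrow(sp) > 0L) {
    for (i in seq_len(nrow(sp))) {
      fish <- add_gaussian3d(fish, sp$z[i], sp$y[i], sp$x[i],
                             sp$multiplicity[i] * params$unit_amplitude, sl, sa)
    }
  }

  px <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  py <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  belt <- matrix(0, ny, nx)
  dapi <- matrix(0, ny, nx)
  for (i in seq_len(params$n_cells)) {
    r <- cell_rect(params, i)
    bd <- rect_border_distance(px, py, r)
    belt <- belt + (bd <= params$junction_belt_px / 2)
    cx <- (r["x0"] + r["x1"]) / 2; cy <- (r["y0"] + r["y1"]) / 2
    dapi <- dapi + ((px - cx)^2 + (py - cy)^2 <= params$nucleus_radius_px^2)
  }
  blur <- function(m) {
    b <- EBImage::gblur(EBImage::Image(m), sigma = sl)
    EBImage::imageData(b)
  }
  belt <- blur(belt)
  dapi <- blur(pmin(dapi, 1))
  zc <- (nz + 1) / 2
  zprof <- exp(-((seq_len(nz) - zc)^2) / (2 * (nz / 5)^2))

  vox <- array(0, c(4L, nz, ny, nx))
  vox[1L, , , ] <- fish
  for (zi in seq_len(nz)) {
    vox[2L, zi, , ] <- params$background_level +
      params$junction_amplitude * zprof[zi] * belt
    vox[3L, zi, , ] <- params$background_level +
      params$ajm_amplitude * zprof[zi] * belt
    vox[4L, zi, , ] <- params$background_level +
      params$dapi_amplitude * zprof[zi] * dapi
  }

  if (params$noise) {
    set.seed(params$seed + 1L)
    n <- length(vox)
    vox[] <- stats::rpois(n, lambda = as.vector(vox)) +
      stats::rnorm(n, mean = 0, sd = params$noise_gaussian_sd)
    vox[vox < 0] <- 0
  }
  image_stack(vox, voxel_size = params$voxel_size_um,
              channel_names = scene_channels)
}

#' Generate and render a synthetic embryo in one call
#' @inheritParams render_stack
#' @param params A [scene_params()] object.
#' @return A list with `rois`, `truth`, and `stack`.
#' @export
simulate_embryo <- function(params = scene_params()) {
  scene <- generate_scene(params)
  scene$stack <- render_stack(scene, params)
  scene
}

#' Sample per-cell ground-truth localization fractions
#'
#' Draws spot compartments and multiplicities from the scene model without
#' rendering images, returning each cell's true membrane fraction
#' (multiplicity-weighted). This is the sampling distribution that per-cell
#' localization estimates inherit, and the input for power and type-I-error
#' simulations of the condition-level statistics.
#'
#' @param n_cells Number of cells.
#' @param n_spots Spots per cell.
#' @param membrane_fraction,nuclear_fraction Placement probabilities.
#' @param multiplicity_dist Named probability vector over multiplicities.
#' @return Numeric vector of per-cell membrane fractions in `[0, 1]`.
#' @export
simulate_fraction_table <- function(n_cells = 25L, n_spots = 200L,
                                    membrane_fraction = 0.6,
                                    nuclear_fraction = 0.1,
                                    multiplicity_dist =
                                      c("1" = 0.8, "2" = 0.15, "4" = 0.05)) {
  stopifnot(n_cells >= 1L, n_spots >= 1L,
            membrane_fraction >= 0, membrane_fraction <= 1)
  n <- n_cells * n_spots
  memb <- stats::runif(n) < membrane_fraction
  mult <- as.integer(sample(names(multiplicity_dist), n, replace = TRUE,
                            prob = multiplicity_dist))
  cell <- rep(seq_len(n_cells), each = n_spots)
  tot <- tapply(mult, cell, sum)
  mem <- tapply(mult * memb, cell, sum)
  as.numeric(mem / tot)
}
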