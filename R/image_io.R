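#' Multi-channel 3D image stacks
#'
#' An `image_stack` holds a 4D voxel array indexed `[channel, z, y, x]`
#' (1-based) together with the physical voxel size and ordered channel
#' names. All pipeline stages share this convention; pixel centers sit at
#' integer coordinates and polygon vertices live in the same (x, y) frame.
#'
#' @param voxels 4D numeric array of non-negative intensities with
#'   dimensions (channel, z, y, x). A 2D matrix or 3D (z, y, x) array is
#'   promoted by adding leading unit dimensions.
#' @param voxel_size Named numeric vector `c(z=, y=, x=)`, physical size of
#'   one voxel in micrometers.
#' @param channel_names Character vector, one label per channel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels,
                        voxel_size = c(z = 1, y = 1, x = 1),
                        channel_names = NULL) {
  if (is.matrix(voxels)) dim(voxels) <- c(1L, 1L, dim(voxels))
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(1L, dim(voxels))
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a (channel, z, y, x) array (2D/3D inputs are promoted)")
  if (any(dim(voxels) < 1L)) stop("all image dimensions must be positive")
  if (!is.numeric(voxels)) stop("voxels must be numeric")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (z, y, x) in micrometers")
  names(voxel_size) <- c("z", "y", "x")
  nc <- dim(voxels)[1L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length (", length(channel_names),
         ") must equal channel count (", nc, ")")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 channel_names = as.character(channel_names)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d channel(s) [%s], %d z-slice(s), %d x %d px\n",
              d[1L], paste(x$channel_names, collapse = ", "), d[2L], d[3L], d[4L]))
  cat(sprintf("voxel size (um): z=%g y=%g x=%g\n",
              x$voxel_size["z"], x$voxel_size["y"], x$voxel_size["x"]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to multi-page TIFF
#'
#' Pages are written channel-major (all z of channel 1, then channel 2,
#' ...) as 16-bit grayscale. Intensities are stored as camera-style
#' integer counts: values are divided by a quantization step (1 when the
#' maximum fits 16 bits, so integer data up to 65535 round-trips exactly)
#' and rounded. Stack metadata (dimensions, channel names, voxel size,
#' intensity step) goes to a JSON sidecar at `<path>.json` because
#' baseline TIFF carries no multi-channel metadata.
#'
#' @param stack An [image_stack].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (min(stack$voxels) < 0) stop("voxel intensities must be non-negative")
  step <- max(1, ceiling(max(stack$voxels) / 65535))
  pages <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (ci in seq_len(d[1L])) for (zi in seq_len(d[2L])) {
    k <- k + 1L
    pages[[k]] <- round(stack$voxels[ci, zi, , ] / step) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  meta <- list(n_channels = d[1L], n_z = d[2L], n_y = d[3L], n_x = d[4L],
               channel_names = stack$channel_names,
               voxel_size_um = as.list(stack$voxel_size),
               intensity_step = step,
               page_order = "channel-major")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Reads a multi-page TIFF written by [write_stack()] using its JSON
#' sidecar for dimensions and metadata. Without a sidecar the pages are
#' interpreted as a single-channel z-stack (a plain 2D TIFF therefore
#' becomes a (1, 1, y, x) stack) and the voxel size defaults to 1.0 um per
#' axis with a warning.
#'
#' @param path TIFF path.
#' @return An [image_stack].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("TIFF '", path, "' contains no pages")
  if (any(!vapply(pages, is.matrix, logical(1L))))
    stop("TIFF '", path, "' contains non-grayscale pages; one sample per pixel expected")
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    nc <- meta$n_channels; nz <- meta$n_z
    if (nc * nz != length(pages))
      stop("TIFF '", path, "' is truncated or inconsistent: sidecar declares ",
           nc * nz, " pages, file has ", length(pages))
    vs <- unlist(meta$voxel_size_um)[c("z", "y", "x")]
    cn <- meta$channel_names
    step <- meta$intensity_step %||% 1
  } else {
    nc <- 1L; nz <- length(pages)
    vs <- c(z = 1, y = 1, x = 1)
    cn <- NULL
    step <- NA_real_
    warning("no metadata sidecar for '", path,
            "': assuming single channel, voxel size 1.0 um")
  }
  d2 <- dim(pages[[1L]])
  if (any(!vapply(pages, function(p) identical(dim(p), d2), logical(1L))))
    stop("TIFF '", path, "' pages have inconsistent dimensions")
  vox <- array(0, dim = c(nc, nz, d2[1L], d2[2L]))
  k <- 0L
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    k <- k + 1L
    pg <- pages[[k]]
    # pages are read as native integer counts (as.is = TRUE); undo the
    # quantization step recorded by write_stack
    if (is.finite(step)) pg <- pg * step
    vox[ci, zi, , ] <- pg
  }
  image_stack(vox, voxel_size = vs, channel_names = cn)
}

#' Maximum intensity projection over a z-range
#'
#' Per-pixel maximum of one channel over an inclusive 1-based z-range —
#' the 2D substrate for seam-cell spot quantification (top views are
#' analyzed on maximum projections of a stated z-range).
#'
#' @param stack An [image_stack].
#' @param channel Channel index or name.
#' @param z_range `c(z0, z1)` inclusive 1-based slice range; `NULL` (default)
#'   projects the full depth.
#' @return A (y, x) matrix.
#' @export
max_project <- function(stack, channel = 1L, z_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  stopifnot(channel >= 1L, channel <= d[1L])
  if (is.null(z_range)) z_range <- c(1L, d[2L])
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || z_range[1L] > z_range[2L])
    stop("z_range must be c(z0, z1) with z0 <= z1")
  if (z_range[1L] < 1L || z_range[2L] > d[2L])
    stop("z_range [", z_range[1L], ", ", z_range[2L],
         "] outside stack depth 1..", d[2L])
  out <- stack$voxels[channel, z_range[1L], , ]
  if (z_range[2L] > z_range[1L]) {
    for (zi in seq(z_range[1L] + 1L, z_range[2L]))
      out <- pmax(out, stack$voxels[channel, zi, , ])
  }
  out
}

#' Extract one image plane across all channels
#' @param stack An [image_stack]. @param z 1-based slice index.
#' @return A (channel, y, x) array carrying channel names.
#' @export
stack_plane <- function(stack, z) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  stopifnot(z >= 1L, z <= d[2L])
  out <- stack$voxels[, z, , , drop = FALSE]
  dim(out) <- d[c(1L, 3L, 4L)]
  attr(out, "channel_names") <- stack$channel_names
  out
}

#' Maximum projection of every channel
#' @inheritParams max_project
#' @return A (channel, y, x) array carrying channel names.
#' @export
project_channels <- function(stack, z_range = NULL) {
  d <- dim(stack$voxels)
  out <- array(0, d[c(1L, 3L, 4L)])
  for (ci in seq_len(d[1L])) out[ci, , ] <- max_project(stack, ci, z_range)
  attr(out, "channel_names") <- stack$channel_names
  out
}

# ---------------------------------------------------------------------------
# ROI sets

roi_roles <- c("total", "interior", "nuclear", "apical",
               "profile_band_apicobasal", "profile_band_apical")

#' Per-cell polygon ROI sets
#'
#' A `roi_set` is a list of cell records; each record carries identifying
#' labels (`cell_id`, `embryo_id`, `condition`, `stage`) and a named list of
#' polygons keyed by role: `total` (cell border), `interior` (outline drawn
#' parallel to the border, inset inward), `nuclear`, `apical`, and optional
#' profile bands. Validation enforces that every polygon is simple and that
#' `interior` lies inside `total` and `nuclear` inside `interior` whenever
#' both are present.
#'
#' @param cells List of cell records as produced by [roi_cell()].
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(cells = list()) {
  stopifnot(is.list(cells))
  rs <- structure(list(cells = cells), class = "roi_set")
  validate_rois(rs)
  rs
}

#' @rdname roi_set
#' @param cell_id,embryo_id,condition,stage Character labels.
#' @param polygons Named list of n x 2 (x, y) polygon matrices.
#' @export
roi_cell <- function(cell_id, polygons, embryo_id = "embryo1",
                     condition = "wildtype", stage = "bean") {
  stopifnot(is.character(cell_id), length(cell_id) == 1L, is.list(polygons))
  if (is.null(names(polygons)) || any(!nzchar(names(polygons))))
    stop("polygons must be a named list (roles: ",
         paste(roi_roles, collapse = ", "), ")")
  polygons <- lapply(polygons, as_polygon)
  list(cell_id = cell_id, embryo_id = embryo_id, condition = condition,
       stage = stage, polygons = polygons)
}

validate_rois <- function(rois) {
  ids <- vapply(rois$cells, `[[`, character(1L), "cell_id")
  if (anyDuplicated(ids)) stop("duplicate cell_id in roi_set: ",
                               ids[duplicated(ids)][1L])
  for (cell in rois$cells) {
    for (role in names(cell$polygons)) {
      if (!is_simple_polygon(cell$polygons[[role]]))
        stop("cell '", cell$cell_id, "': polygon '", role,
             "' is self-intersecting")
    }
    p <- cell$polygons
    if (!is.null(p$total) && !is.null(p$interior) &&
        !polygon_contains(p$total, p$interior))
      stop("cell '", cell$cell_id, "': interior polygon not contained in total")
    if (!is.null(p$interior) && !is.null(p$nuclear) &&
        !polygon_contains(p$interior, p$nuclear))
      stop("cell '", cell$cell_id, "': nuclear polygon not contained in interior")
  }
  invisible(rois)
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set with", length(x$cells), "cell(s)\n")
  for (cell in x$cells)
    cat(sprintf("  %s [%s/%s/%s]: %s\n", cell$cell_id, cell$embryo_id,
                cell$condition, cell$stage,
                paste(names(cell$polygons), collapse = ", ")))
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$cells)

#' Read / write ROI sets as JSON
#'
#' The JSON schema is one object per cell with its labels and a `polygons`
#' object mapping role names to arrays of `[x, y]` vertex pairs. Round-trips
#' are lossless; containment and simplicity invariants are re-validated at
#' load and violations are rejected naming the offending cell. An empty
#' file yields an empty (valid) `roi_set`.
#'
#' @param path JSON file path.
#' @return [read_rois()] returns a [roi_set]; [write_rois()] returns `path`
#'   invisibly.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0L) return(roi_set())
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cells <- lapply(raw, function(rec) {
    polys <- lapply(rec$polygons, function(v) {
      m <- do.call(rbind, lapply(v, function(p) as.numeric(unlist(p))))
      as_polygon(m)
    })
    roi_cell(cell_id = rec$cell_id, polygons = polys,
             embryo_id = rec$embryo_id %||% "embryo1",
             condition = rec$condition %||% "wildtype",
             stage = rec$stage %||% "bean")
  })
  roi_set(cells)
}

#' @rdname read_rois
#' @param rois A [roi_set].
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  out <- lapply(rois$cells, function(cell) {
    list(cell_id = cell$cell_id, embryo_id = cell$embryo_id,
         condition = cell$condition, stage = cell$stage,
         polygons = lapply(cell$polygons, function(p)
           lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
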