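#' Intensity profiles along a band across cells
#'
#' A `profile_trace` holds per-channel mean intensities sampled along the
#' axis of a band polygon: for each 1 px axial bin, each channel is
#' averaged over the band pixels falling in that bin. This reproduces the
#' apicobasal / apical line-profile read-out used to relate mRNA signal to
#' the apical junction (CeAJ) marked by AJM-1 peaks.
#'
#' @param img A (channel, y, x) array (e.g. from [project_channels()] or
#'   [stack_plane()]) or a plain (y, x) matrix for a single channel.
#' @param band_polygon n x 2 (x, y) polygon delimiting the band; must
#'   overlap the image.
#' @param axis `"x"` (profile runs left-right, default) or `"y"`.
#' @param channel_names Optional channel labels; defaults to the array's
#'   `channel_names` attribute.
#' @param bin_px Axial bin width in pixels (default 1).
#' @return A `profile_trace`: list with `positions` (bin centers, px),
#'   `channels` (named list of numeric vectors), `nuclear_spans`
#'   (data frame `start`/`end`, empty until [evict_nuclear_signal()]),
#'   `junctions` (empty until [locate_junctions()]).
#' @export
extract_band_profile <- function(img, band_polygon, axis = c("x", "y"),
                                 channel_names = NULL, bin_px = 1) {
  axis <- match.arg(axis)
  if (is.matrix(img)) {
    dn <- dim(img)
    dim(img) <- c(1L, dn)
  }
  stopifnot(length(dim(img)) == 3L, bin_px > 0)
  if (is.null(channel_names))
    channel_names <- attr(img, "channel_names") %||%
      paste0("ch", seq_len(dim(img)[1L]))
  poly <- as_polygon(band_polygon)
  ny <- dim(img)[2L]; nx <- dim(img)[3L]
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  ix <- max(1L, floor(xr[1L])):min(nx, ceiling(xr[2L]))
  iy <- max(1L, floor(yr[1L])):min(ny, ceiling(yr[2L]))
  if (xr[1L] > nx || xr[2L] < 1 || yr[1L] > ny || yr[2L] < 1 ||
      !length(ix) || !length(iy))
    stop("band polygon lies outside the image")
  gx <- rep(ix, each = length(iy))
  gy <- rep(iy, times = length(ix))
  inside <- point_in_polygon(gx, gy, poly)
  if (!any(inside)) stop("band polygon covers no pixel centers (zero-width band)")
  gx <- gx[inside]; gy <- gy[inside]
  along <- if (axis == "x") gx else gy
  bin <- floor((along - min(along)) / bin_px)
  # position of each bin = mean coordinate of its pixels (robust for any bin_px)
  positions <- as.numeric(tapply(along, bin, mean))
  chans <- vector("list", dim(img)[1L])
  names(chans) <- channel_names
  for (ci in seq_len(dim(img)[1L])) {
    v <- img[cbind(ci, gy, gx)]
    chans[[ci]] <- as.numeric(tapply(v, bin, mean))
  }
  structure(list(positions = positions, channels = chans,
                 nuclear_spans = data.frame(start = numeric(0),
                                            end = numeric(0)),
                 junctions = numeric(0), axis = axis),
            class = "profile_trace")
}

#' @export
print.profile_trace <- function(x, ...) {
  cat(sprintf("profile_trace: %d bins along %s, channels: %s\n",
              length(x$positions), x$axis,
              paste(names(x$channels), collapse = ", ")))
  if (nrow(x$nuclear_spans))
    cat("  nuclear spans:",
        paste(sprintf("[%g, %g]", x$nuclear_spans$start, x$nuclear_spans$end),
              collapse = " "), "\n")
  if (length(x$junctions))
    cat("  junctions at:", paste(round(x$junctions, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Remove nuclear signal from the mRNA profile channel
#'
#' Transcription-site signal inside nuclei is not informative for
#' junctional localization, so axial bins whose DNA (DAPI) intensity
#' exceeds a threshold are flagged as nuclear spans and the mRNA channel
#' is set to missing (`NA`, never zero) there; other channels are left
#' untouched. The default threshold is Otsu's threshold computed on the
#' DNA trace. The operation is idempotent.
#'
#' @param trace A `profile_trace`.
#' @param dna_threshold Positive intensity threshold, or `NULL` for Otsu
#'   on the DNA channel trace.
#' @param dna_channel,mrna_channel Channel names in the trace.
#' @return The trace with `nuclear_spans` filled and the mRNA channel
#'   masked.
#' @export
evict_nuclear_signal <- function(trace, dna_threshold = NULL,
                                 dna_channel = "DAPI", mrna_channel = "mRNA") {
  stopifnot(inherits(trace, "profile_trace"))
  dna <- trace$channels[[dna_channel]]
  if (is.null(dna)) stop("DNA channel '", dna_channel, "' not present in trace")
  if (is.null(trace$channels[[mrna_channel]]))
    stop("mRNA channel '", mrna_channel, "' not present in trace")
  if (is.null(dna_threshold)) {
    rng <- range(dna)
    if (diff(rng) == 0) {
      dna_threshold <- rng[1L] + 1  # flat DNA trace: nothing to evict
    } else {
      scaled <- (dna - rng[1L]) / diff(rng)
      dna_threshold <- rng[1L] +
        diff(rng) * EBImage::otsu(EBImage::Image(matrix(scaled)), range = c(0, 1))
    }
  }
  if (dna_threshold <= 0) stop("dna_threshold must be positive")
  over <- dna > dna_threshold
  trace$channels[[mrna_channel]][over] <- NA_real_
  runs <- rle(over)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values)
  trace$nuclear_spans <- data.frame(start = trace$positions[starts[hit]],
                                    end = trace$positions[ends[hit]])
  trace$dna_threshold <- dna_threshold
  trace
}

# peaks of v at x: plateau-centered local maxima with prominence and
# separation filtering; NA bins split the trace into independent segments
find_trace_peaks <- function(x, v, min_prominence_frac, min_sep,
                             refine = TRUE) {
  stopifnot(length(x) == length(v))
  segs <- split(seq_along(v), cumsum(is.na(v)))
  peaks <- data.frame(pos = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  vmax <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(vmax)) return(numeric(0))
  for (idx in segs) {
    idx <- idx[!is.na(v[idx])]
    if (length(idx) < 3L) next
    vv <- v[idx]; xx <- x[idx]
    n <- length(vv)
    for (i in 2:(n - 1L)) {
      # plateau-aware strict maximum: first index of a plateau whose
      # nearest differing neighbors are both lower
      if (vv[i] < vv[i - 1L]) next
      if (vv[i] == vv[i - 1L]) next          # not the plateau start
      j <- i
      while (j < n && vv[j + 1L] == vv[i]) j <- j + 1L
      if (j == n || vv[j + 1L] > vv[i]) next
      ctr <- (i + j) / 2
      # prominence: drop to the highest saddle separating this peak from
      # any higher point (or the segment end)
      left <- vv[seq_len(i)]
      higher_l <- which(left > vv[i])
      sad_l <- min(left[if (length(higher_l)) (max(higher_l)):i else 1:i])
      right <- vv[j:n]
      higher_r <- which(right > vv[i])
      sad_r <- min(right[if (length(higher_r)) 1:(min(higher_r)) else seq_along(right)])
      prom <- vv[i] - max(sad_l, sad_r)
      pos <- if (abs(ctr - round(ctr)) < 1e-9) xx[round(ctr)] else
        (xx[floor(ctr)] + xx[ceiling(ctr)]) / 2
      if (refine && i == j && i > 1L && i < n) {
        # 3-point parabolic subpixel refinement
        denom <- vv[i - 1L] - 2 * vv[i] + vv[i + 1L]
        if (denom < 0) {
          delta <- 0.5 * (vv[i - 1L] - vv[i + 1L]) / denom
          pos <- xx[i] + max(-0.5, min(0.5, delta)) * (xx[min(i + 1L, n)] - xx[i])
        }
      }
      peaks <- rbind(peaks, data.frame(pos = pos, height = vv[i],
                                       prominence = prom))
    }
  }
  peaks <- peaks[peaks$prominence >= min_prominence_frac * vmax, , drop = FALSE]
  if (!nrow(peaks)) return(numeric(0))
  peaks <- peaks[order(-peaks$height, peaks$pos), , drop = FALSE]
  kept <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    if (!length(kept) || all(abs(kept - peaks$pos[i]) >= min_sep))
      kept <- c(kept, peaks$pos[i])
  }
  sort(kept)
}

#' Locate apical junctions from AJM-1 intensity peaks
#'
#' Junction (CeAJ) positions are the local maxima of the AJM-1 trace that
#' pass a prominence filter (relative to the trace maximum, so calls are
#' invariant under uniform intensity scaling) and a minimum-separation
#' filter that deduplicates the shared junction between adjacent cells.
#' Peak positions are refined to subpixel by parabolic interpolation.
#'
#' @param trace A `profile_trace`.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   trace maximum (default 0.2).
#' @param min_separation Minimum distance between called junctions in
#'   pixels (default 3).
#' @param channel AJM-1 channel name.
#' @return The trace with `junctions` filled (axis coordinates, ascending).
#' @export
locate_junctions <- function(trace, min_prominence = 0.2, min_separation = 3,
                             channel = "AJM1") {
  stopifnot(inherits(trace, "profile_trace"))
  v <- trace$channels[[channel]]
  if (is.null(v)) stop("channel '", channel, "' not present in trace")
  pk <- find_trace_peaks(trace$positions, v, min_prominence, min_separation)
  if (!length(pk)) warning("no junction peaks found (flat trace?)")
  trace$junctions <- pk
  trace
}

#' Overlap of mRNA and protein peaks with called junctions
#'
#' Quantifies how much of the peri-junctional signal actually sits at the
#' junction: the fraction of mRNA peaks (after nuclear eviction) and of
#' junction-protein peaks lying within a tolerance of a called junction
#' position.
#'
#' @param trace A `profile_trace` with junctions called.
#' @param tol_px Matching tolerance in pixels.
#' @param mrna_channel,protein_channel Channel names.
#' @param min_prominence,min_separation Peak parameters for the mRNA and
#'   protein channels (as in [locate_junctions()]).
#' @return A list with `mrna_overlap` and `protein_overlap` (fractions in
#'   `[0, 1]`, `NA` when a channel has no peaks), and the peak positions
#'   `mrna_peaks`, `protein_peaks`.
#' @export
peak_overlap_summary <- function(trace, tol_px = 2,
                                 mrna_channel = "mRNA",
                                 protein_channel = "DLG1_GFP",
                                 min_prominence = 0.2, min_separation = 3) {
  stopifnot(inherits(trace, "profile_trace"))
  if (!length(trace$junctions))
    stop("no junctions called; run locate_junctions() first")
  frac_near <- function(pk) {
    if (!length(pk)) return(NA_real_)
    mean(vapply(pk, function(p) any(abs(trace$junctions - p) <= tol_px),
                logical(1L)))
  }
  mp <- find_trace_peaks(trace$positions, trace$channels[[mrna_channel]],
                         min_prominence, min_separation)
  pp <- find_trace_peaks(trace$positions, trace$channels[[protein_channel]],
                         min_prominence, min_separation)
  list(mrna_overlap = frac_near(mp), protein_overlap = frac_near(pp),
       mrna_peaks = mp, protein_peaks = pp)
}
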