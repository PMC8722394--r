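#' Assign spot mRNA counts to subcellular compartments
#'
#' Implements the three-outline quantification scheme: per cell, spot
#' units are summed by boundary-inclusive point-in-polygon membership
#' against the `total` (cell border), `interior` (outline drawn parallel
#' to the border) and `nuclear` outlines, plus the `apical` outline where
#' present. Membrane mRNA is never measured directly: it is the difference
#' `total - interior` ("cytoplasmic+nuclear"), i.e. signal at or near the
#' lateral cell membrane. Spots inside the nuclear outline count toward
#' interior and total as well (containment chain), and spots outside every
#' total outline land in an "unassigned" bucket.
#'
#' @param spots A `spot_set` carrying `units` (see [count_mrna()]), or any
#'   data frame with `y`, `x` and (if `use_units`) `units` plus `retained`.
#' @param rois A [roi_set]; cell `total` outlines must not overlap.
#' @param use_units Sum per-spot mRNA units (default) or raw dot counts.
#' @return A `compartment_counts` data frame with one row per cell:
#'   labels, `total`, `interior`, `nuclear`, `apical`, `membrane`, and
#'   `n_spots`. Attribute `unassigned_units` holds the bucket of spots
#'   outside all cells.
#' @export
assign_spots <- function(spots, rois, use_units = TRUE) {
  stopifnot(is.data.frame(spots), inherits(rois, "roi_set"))
  if ("retained" %in% names(spots)) spots <- spots[spots$retained, , drop = FALSE]
  if (use_units) {
    if (!"units" %in% names(spots) || anyNA(spots$units))
      stop("spots must carry mRNA units (run count_mrna), ",
           "or set use_units = FALSE for raw dot counts")
    wt <- as.numeric(spots$units)
  } else {
    wt <- rep(1, nrow(spots))
  }
  n_cells <- length(rois$cells)
  member <- matrix(FALSE, nrow(spots), n_cells)
  for (j in seq_len(n_cells)) {
    member[, j] <- point_in_polygon(spots$x, spots$y,
                                    rois$cells[[j]]$polygons$total)
  }
  hits <- rowSums(member)
  for (i in which(hits > 1L)) {
    # adjacent cells share border edges, and a spot sitting exactly on the
    # shared edge is "inside" both under the boundary-inclusive rule; nudge
    # the point to tell a shared-edge tie from genuinely overlapping outlines
    js <- which(member[i, ])
    eps <- 1e-6
    nudged <- vapply(js, function(j) {
      poly <- rois$cells[[j]]$polygons$total
      sum(point_in_polygon(spots$x[i] + c(-eps, eps, eps, -eps),
                           spots$y[i] + c(-eps, -eps, eps, eps), poly))
    }, numeric(1L))
    if (sum(nudged > 2) > 1L) {
      ids <- vapply(rois$cells[js], `[[`, character(1L), "cell_id")
      stop("spot at (x=", round(spots$x[i], 2), ", y=", round(spots$y[i], 2),
           ") falls inside overlapping total outlines: ",
           paste(ids, collapse = ", "))
    }
    keep_j <- js[which.max(nudged)]
    member[i, setdiff(js, keep_j)] <- FALSE
  }
  rows <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    cell <- rois$cells[[j]]
    inc <- member[, j]
    s <- spots[inc, , drop = FALSE]
    w <- wt[inc]
    p <- cell$polygons
    in_nuc <- if (!is.null(p$nuclear) && nrow(s))
      point_in_polygon(s$x, s$y, p$nuclear) else rep(FALSE, nrow(s))
    in_int <- if (!is.null(p$interior) && nrow(s))
      point_in_polygon(s$x, s$y, p$interior) | in_nuc else in_nuc
    in_api <- if (!is.null(p$apical) && nrow(s))
      point_in_polygon(s$x, s$y, p$apical) else rep(FALSE, nrow(s))
    tot <- sum(w)
    interior <- sum(w[in_int])
    rows[[j]] <- data.frame(
      cell_id = cell$cell_id, embryo_id = cell$embryo_id,
      condition = cell$condition, stage = cell$stage,
      n_spots = nrow(s), total = tot, interior = interior,
      nuclear = sum(w[in_nuc]), membrane = tot - interior,
      apical = sum(w[in_api]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("compartment_counts", "data.frame")
  attr(out, "unassigned_units") <- sum(wt[hits == 0L])
  attr(out, "unassigned_spots") <- sum(hits == 0L)
  out
}

#' Per-cell localization fractions
#'
#' Three read-outs of subcellular enrichment:
#' \describe{
#'   \item{standard}{membrane / total — the default for all seam-cell
#'     analyses.}
#'   \item{txn_corrected}{membrane / (total - nuclear) — used when a high
#'     transcriptional (nuclear) signal would otherwise deflate the
#'     fraction; note it overestimates localization in all conditions and
#'     must be selected explicitly.}
#'   \item{apical}{apical / total — the pharynx-style read-out.}
#' }
#' Cells with an undefined denominator yield `NA` with a message and
#' should be excluded from condition summaries.
#'
#' @param counts A `compartment_counts` data frame from [assign_spots()].
#' @param mode One of `"standard"`, `"txn_corrected"`, `"apical"`.
#' @return Numeric vector of fractions in `[0, 1]`, one per cell.
#' @export
localized_fraction <- function(counts,
                               mode = c("standard", "txn_corrected", "apical")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(counts),
            all(c("total", "interior", "nuclear", "membrane") %in% names(counts)))
  num <- switch(mode, standard = counts$membrane,
                txn_corrected = counts$membrane, apical = counts$apical)
  den <- switch(mode, standard = counts$total,
                txn_corrected = counts$total - counts$nuclear,
                apical = counts$total)
  bad <- !is.finite(den) | den <= 0
  if (any(bad))
    message(sum(bad), " cell(s) excluded (undefined ", mode,
            " fraction): ", paste(counts$cell_id[bad], collapse = ", "))
  out <- num / den
  out[bad] <- NA_real_
  out
}

#' Build the long per-cell fraction table for condition-level statistics
#'
#' @param counts A `compartment_counts` data frame (rows from one or more
#'   embryos/conditions can be `rbind`ed first).
#' @param mode Fraction mode passed to [localized_fraction()].
#' @return A `cell_fraction_table` data frame with columns `embryo_id`,
#'   `cell_id`, `condition`, `stage`, `fraction_percent`, `mode`; rows
#'   with undefined fractions are dropped.
#' @export
cell_fraction_table <- function(counts, mode = "standard") {
  fr <- localized_fraction(counts, mode)
  out <- data.frame(embryo_id = counts$embryo_id, cell_id = counts$cell_id,
                    condition = counts$condition, stage = counts$stage,
                    fraction_percent = 100 * fr, mode = mode,
                    stringsAsFactors = FALSE)
  out <- out[is.finite(out$fraction_percent), , drop = FALSE]
  key <- with(out, paste(embryo_id, cell_id, condition, stage, mode))
  if (anyDuplicated(key))
    stop("duplicate (embryo, cell, condition, stage, mode) keys in fraction table")
  if (any(out$fraction_percent < 0 | out$fraction_percent > 100))
    stop("fractions outside [0, 100]%: check compartment counts")
  rownames(out) <- NULL
  class(out) <- c("cell_fraction_table", "data.frame")
  out
}
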