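flat_trace <- function(v = 5, n = 30, channels = c("mRNA", "AJM1", "DAPI")) {
  img <- array(v, c(length(channels), 20, n))
  attr(img, "channel_names") <- channels
  extract_band_profile(img, rect_polygon(1, 5, n, 15))
}

gauss1d <- function(x, mu, sigma = 1.5, amp = 1) amp * exp(-(x - mu)^2 / (2 * sigma^2))

# build a profile_trace directly from per-channel vectors
make_trace <- function(..., positions = NULL) {
  ch <- list(...)
  n <- length(ch[[1]])
  structure(list(positions = positions %||% seq_len(n), channels = ch,
                 nuclear_spans = data.frame(start = numeric(0), end = numeric(0)),
                 junctions = numeric(0), axis = "x"),
            class = "profile_trace")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a uniform image yields a flat trace on every channel", {
  tr <- flat_trace(v = 7)
  expect_true(all(vapply(tr$channels, function(v) all(v == 7), logical(1))))
  expect_identical(length(tr$positions), 30L)
})

test_that("a one-pixel stripe produces a single maximal bin at its column", {
  img <- matrix(1, 20, 30)
  img[, 12] <- 50
  tr <- extract_band_profile(img, rect_polygon(2, 5, 29, 15),
                             channel_names = "ch1")
  expect_equal(tr$positions[which.max(tr$channels$ch1)], 12)
  expect_identical(sum(tr$channels$ch1 > 1), 1L)
})

test_that("band polygons outside the image are rejected", {
  img <- matrix(1, 20, 30)
  expect_error(extract_band_profile(img, rect_polygon(40, 5, 50, 15)),
               "outside")
  expect_error(extract_band_profile(img, rect_polygon(5.2, 5.2, 5.4, 5.4)),
               "zero-width")
})

test_that("nuclear eviction masks exactly the DNA-thresholded bins", {
  dna <- rep(1, 20); dna[8:12] <- 10
  tr <- make_trace(mRNA = rnorm(20, 50), DAPI = dna)
  ev <- evict_nuclear_signal(tr, dna_threshold = 5)
  expect_identical(which(is.na(ev$channels$mRNA)), 8:12)
  expect_true(all(!is.na(ev$channels$DAPI)))
  expect_equal(ev$nuclear_spans, data.frame(start = 8, end = 12))
})

test_that("eviction is idempotent and no-ops below threshold", {
  dna <- c(rep(1, 7), rep(10, 4), rep(1, 9))
  tr <- make_trace(mRNA = runif(20, 40, 60), DAPI = dna)
  once <- evict_nuclear_signal(tr, dna_threshold = 5)
  twice <- evict_nuclear_signal(once, dna_threshold = 5)
  expect_identical(once$channels, twice$channels)
  expect_identical(once$nuclear_spans, twice$nuclear_spans)
  # Otsu default is idempotent too (threshold recomputed on intact DNA)
  o1 <- evict_nuclear_signal(tr)
  o2 <- evict_nuclear_signal(o1)
  expect_identical(o1$channels, o2$channels)
  clean <- evict_nuclear_signal(make_trace(mRNA = runif(20), DAPI = rep(1, 20)),
                                dna_threshold = 5)
  expect_true(all(!is.na(clean$channels$mRNA)))
  expect_identical(nrow(clean$nuclear_spans), 0L)
  expect_error(evict_nuclear_signal(tr, dna_threshold = -1), "positive")
})

test_that("junction calls hit rendered peaks within a pixel", {
  x <- 0:20
  ajm <- 2 + gauss1d(x, 2, amp = 30) + gauss1d(x, 18, amp = 25)
  tr <- make_trace(mRNA = rep(1, 21), AJM1 = ajm, positions = x)
  tr <- locate_junctions(tr)
  expect_length(tr$junctions, 2L)
  expect_lt(abs(tr$junctions[1] - 2), 1)
  expect_lt(abs(tr$junctions[2] - 18), 1)
})

test_that("flat traces yield no junctions, with a warning", {
  tr <- make_trace(mRNA = rep(1, 20), AJM1 = rep(3, 20))
  expect_warning(tr <- locate_junctions(tr), "no junction peaks")
  expect_length(tr$junctions, 0L)
})

test_that("junction calls are invariant under intensity scaling", {
  set.seed(4)
  x <- 1:60
  ajm <- 5 + gauss1d(x, 12, amp = 40) + gauss1d(x, 47, amp = 28) + runif(60)
  t1 <- locate_junctions(make_trace(mRNA = rep(1, 60), AJM1 = ajm))
  t2 <- locate_junctions(make_trace(mRNA = rep(1, 60), AJM1 = 5 * ajm))
  expect_identical(t1$junctions, t2$junctions)
})

test_that("three simulated cells give four junctions at the cell borders", {
  p <- test_scene_params(n_cells = 3L, seed = 8L)
  sc <- simulate_embryo(p)
  img <- project_channels(sc$stack)
  cy <- p$margin_px + p$cell_height_px / 2
  band <- rect_polygon(p$margin_px - 4, cy - p$profile_halfwidth_px,
                       p$margin_px + 3 * p$cell_width_px + 4,
                       cy + p$profile_halfwidth_px)
  tr <- locate_junctions(extract_band_profile(img, band))
  truth <- p$margin_px + (0:3) * p$cell_width_px
  expect_length(tr$junctions, 4L)
  expect_true(all(abs(tr$junctions - truth) <= 1))
})

test_that("evicted spans cover the nuclei projected onto the band", {
  p <- test_scene_params(n_cells = 3L, seed = 8L)
  sc <- simulate_embryo(p)
  img <- project_channels(sc$stack)
  cy <- p$margin_px + p$cell_height_px / 2
  band <- rect_polygon(p$margin_px, cy - p$profile_halfwidth_px,
                       p$margin_px + 3 * p$cell_width_px,
                       cy + p$profile_halfwidth_px)
  # a permissive threshold (a quarter of the way up from the floor) maps
  # the full blurred nuclear footprint; bins counted as truly nuclear are
  # those the nucleus covers across the whole band height
  dna <- extract_band_profile(img, band)$channels$DAPI
  thr <- min(dna) + 0.25 * diff(range(dna))
  tr <- evict_nuclear_signal(extract_band_profile(img, band),
                             dna_threshold = thr)
  centers <- p$margin_px + (1:3 - 0.5) * p$cell_width_px
  chord <- sqrt(p$nucleus_radius_px^2 - p$profile_halfwidth_px^2)
  true_bins <- tr$positions[vapply(tr$positions, function(px)
    any(abs(px - centers) <= chord), logical(1))]
  evicted <- tr$positions[is.na(tr$channels$mRNA)]
  coverage <- mean(true_bins %in% evicted)
  expect_gte(coverage, 0.95)
})

test_that("peak overlap fractions match a brute-force distance check", {
  x <- 1:80
  junc <- c(15, 50, 70)
  ajm <- 2 + rowSums(sapply(junc, function(m) gauss1d(x, m, amp = 30)))
  mrna <- 2 + gauss1d(x, 15, amp = 20) + gauss1d(x, 35, amp = 18) +
    gauss1d(x, 51, amp = 22)
  prot <- 2 + gauss1d(x, 15, amp = 25) + gauss1d(x, 50, amp = 25) +
    gauss1d(x, 70, amp = 25)
  tr <- locate_junctions(make_trace(mRNA = mrna, DLG1_GFP = prot, AJM1 = ajm))
  ov <- peak_overlap_summary(tr, tol_px = 2)
  brute <- function(peaks) mean(vapply(peaks, function(p)
    any(abs(tr$junctions - p) <= 2), logical(1)))
  expect_equal(ov$mrna_overlap, brute(ov$mrna_peaks))
  expect_equal(ov$protein_overlap, brute(ov$protein_peaks))
  expect_equal(ov$mrna_overlap, 2 / 3)
  expect_equal(ov$protein_overlap, 1)
  # all peaks exactly on junctions -> 1; all far -> 0
  tr2 <- locate_junctions(make_trace(mRNA = ajm, DLG1_GFP = prot, AJM1 = ajm))
  expect_equal(peak_overlap_summary(tr2, tol_px = 2)$mrna_overlap, 1)
  far <- 2 + gauss1d(x, 30, amp = 20)
  tr3 <- locate_junctions(make_trace(mRNA = far, DLG1_GFP = prot, AJM1 = ajm))
  expect_equal(peak_overlap_summary(tr3, tol_px = 2)$mrna_overlap, 0)
  # no peaks in a channel -> NA
  tr4 <- locate_junctions(make_trace(mRNA = rep(1, 80), DLG1_GFP = prot,
                                     AJM1 = ajm))
  expect_true(is.na(peak_overlap_summary(tr4, tol_px = 2)$mrna_overlap))
})

test_that("junction-adjacent mRNA beats mid-cell mRNA for localized scenes", {
  p <- test_scene_params(n_cells = 3L, membrane_fraction = 0.8,
                         n_spots_per_cell = 40L, seed = 10L)
  sc <- simulate_embryo(p)
  img <- project_channels(sc$stack)
  cy <- p$margin_px + p$cell_height_px / 2
  band <- rect_polygon(p$margin_px - 4, cy - p$profile_halfwidth_px,
                       p$margin_px + 3 * p$cell_width_px + 4,
                       cy + p$profile_halfwidth_px)
  tr <- locate_junctions(extract_band_profile(img, band))
  mrna <- tr$channels$mRNA
  near <- vapply(tr$positions, function(px) any(abs(tr$junctions - px) <= 4),
                 logical(1))
  mid <- vapply(tr$positions, function(px) all(abs(tr$junctions - px) > 15),
                logical(1))
  expect_gt(mean(mrna[near]), mean(mrna[mid]))
})
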