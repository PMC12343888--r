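# Helper: draw disks at given centers onto a dark field.
disk_field <- function(H, W, centers, r, lo = 10, hi = 500) {
  img <- matrix(lo, H, W)
  for (i in seq_len(nrow(centers))) {
    g <- expand.grid(y = (centers[i, 1] - r):(centers[i, 1] + r),
                     x = (centers[i, 2] - r):(centers[i, 2] + r))
    g <- g[(g$y - centers[i, 1])^2 + (g$x - centers[i, 2])^2 <= r^2, ]
    img[cbind(g$y, g$x)] <- hi
  }
  img
}

test_that("nucleus segmentation finds separated disks with exact counts and centroids", {
  ctrs <- rbind(c(20, 20), c(20, 60), c(60, 40))
  img <- disk_field(80, 80, ctrs, 6)
  seg <- segment_nuclei(img)
  expect_identical(nrow(seg$centroids), 3L)
  got <- seg$centroids[order(seg$centroids$y, seg$centroids$x), ]
  want <- ctrs[order(ctrs[, 1], ctrs[, 2]), ]
  expect_equal(got$y, want[, 1], tolerance = 0.02)
  expect_equal(got$x, want[, 2], tolerance = 0.02)
  expect_true(all(got$area_px > 100 & got$area_px < 120))  # pi * 36 ~ 113
  blank <- segment_nuclei(matrix(5, 32, 32))
  expect_identical(nrow(blank$centroids), 0L)
})

test_that("small debris is removed by the area floor", {
  ctrs <- rbind(c(30, 30))
  img <- disk_field(64, 64, ctrs, 8)
  img[5, 5] <- 500; img[50, 12] <- 500    # 1-px specks
  seg <- segment_nuclei(img, min_area_px = 50)
  expect_identical(nrow(seg$centroids), 1L)
})

test_that("the cytoplasmic ring is an annulus that avoids neighbouring nuclei", {
  ctrs <- rbind(c(40, 40))
  img <- disk_field(96, 96, ctrs, 8)
  seg <- segment_nuclei(img)
  ring <- cytoplasm_ring(1, seg$labels, gap_px = 1, width_px = 4)
  expect_false(any(ring & (seg$labels == 1)))
  # area close to the ideal annulus between radii 9 and 13
  ideal <- pi * (13^2 - 9^2)
  expect_lt(abs(sum(ring) - ideal) / ideal, 0.12)
  # distances of ring pixels from the centre lie in (9, 13] up to rasterization
  p <- which(ring)
  d <- sqrt(((p - 1) %% 96 + 1 - 40)^2 + ((p - 1) %/% 96 + 1 - 40)^2)
  expect_true(all(d > 8 & d < 14.2))
  # a close neighbour carves a bite out of the ring
  two <- disk_field(96, 96, rbind(c(40, 40), c(40, 68)), 8)
  seg2 <- segment_nuclei(two)
  lab_left <- seg2$labels[40, 40]
  ring2 <- cytoplasm_ring(lab_left, seg2$labels, gap_px = 1, width_px = 12)
  other <- seg2$labels > 0 & seg2$labels != lab_left
  expect_false(any(ring2 & other))
  expect_error(cytoplasm_ring(99, seg$labels), "label 99")
})

test_that("CNR is median-based and scale invariant", {
  img <- matrix(0, 20, 20)
  nuc <- matrix(FALSE, 20, 20); nuc[8:12, 8:12] <- TRUE
  ring <- matrix(FALSE, 20, 20); ring[5, 5:15] <- TRUE
  img[nuc] <- c(rep(100, 12), rep(200, 13))   # median 200
  img[ring] <- 50
  v <- compute_cnr(img, nuc, ring)
  expect_identical(v$nuc_median, 200)
  expect_identical(v$cyto_median, 50)
  expect_identical(v$cnr, 0.25)
  expect_identical(v$log2_cnr, -2)
  s <- compute_cnr(img * 7.3, nuc, ring)
  expect_equal(s$cnr, v$cnr)
  expect_error(compute_cnr(img, nuc & FALSE, ring), "non-empty")
})

test_that("tracking links drifting cells by identity and opens new tracks when needed", {
  f1 <- data.frame(label = 1:3, y = c(10, 50, 90), x = c(10, 50, 90))
  f2 <- data.frame(label = 1:3, y = c(12, 52, 92), x = c(11, 49, 90))
  tr <- track_cells(list(f1, f2), max_displacement_px = 10)
  t2 <- tr[tr$frame == 2, ]
  expect_identical(t2$track_id[order(t2$y)], 1:3)
  # a cell jumping farther than the limit becomes a new track
  f3 <- data.frame(label = 1:3, y = c(12, 52, 40), x = c(11, 49, 40))
  tr2 <- track_cells(list(f1, f2, f3), max_displacement_px = 10)
  t3 <- tr2[tr2$frame == 3, ]
  expect_identical(sort(t3$track_id), c(1L, 2L, 4L))
  # an appearing cell opens a track without stealing an existing one
  f2b <- rbind(f2, data.frame(label = 4, y = 30, x = 70))
  tr3 <- track_cells(list(f1, f2b), max_displacement_px = 10)
  expect_identical(sort(tr3$track_id[tr3$frame == 2]), 1:4)
  expect_error(track_cells(list(f1)), "2 frames")
})

test_that("trace normalization zeroes the baseline frame and is idempotent", {
  tab <- data.frame(cell_id = rep(1:2, each = 4), frame = rep(1:4, 2),
                    t_min = rep(c(0, 2, 4, 6), 2), channel = "akt",
                    nuc_median = 100, cyto_median = 100,
                    cnr = 1, log2_cnr = c(0.1, 0.2, 0.5, 0.9,
                                          -0.3, -0.1, 0.2, 0.4))
  nt <- normalize_traces(tab, baseline_frame = 2)
  expect_identical(nt$delta_log2_cnr[nt$frame == 2], c(0, 0))
  expect_equal(nt$delta_log2_cnr[nt$cell_id == 1],
               c(0.1, 0.2, 0.5, 0.9) - 0.2)
  nt2 <- normalize_traces(nt, baseline_frame = 2)
  expect_identical(nt2$delta_log2_cnr, nt$delta_log2_cnr)
  # a cell missing the baseline frame is excluded and counted
  tab3 <- rbind(tab, data.frame(cell_id = 3, frame = 3:4, t_min = c(4, 6),
                                channel = "akt", nuc_median = 100,
                                cyto_median = 100, cnr = 1,
                                log2_cnr = c(1, 1)))
  nt3 <- normalize_traces(tab3, baseline_frame = 2)
  expect_false(3 %in% nt3$cell_id)
  expect_identical(attr(nt3, "excluded"), 1L)
  # only the contiguous run containing the baseline survives a gap
  tab4 <- tab[tab$cell_id == 1 & tab$frame != 3, ]
  nt4 <- normalize_traces(tab4, baseline_frame = 2)
  expect_identical(nt4$frame, 1:2)
})

test_that("population summaries aggregate per frame with hand-checked means", {
  nt <- data.frame(cell_id = rep(1:3, each = 2), frame = rep(1:2, 3),
                   t_min = rep(c(0, 2), 3), channel = "erk",
                   nuc_median = 1, cyto_median = 1, cnr = 1, log2_cnr = 0,
                   delta_log2_cnr = c(0, 0.3, 0, 0.6, 0, 0.9))
  s <- summarize_population(nt, stim_frame = 1)
  pf <- s$per_frame
  expect_equal(pf$mean[pf$frame == 2], 0.6)
  expect_equal(pf$sd[pf$frame == 2], sd(c(0.3, 0.6, 0.9)))
  expect_identical(pf$n[pf$frame == 2], 3L)
  m <- s$matrix$erk
  expect_identical(dim(m), c(3L, 2L))
  expect_equal(m[, 2], c(0.9, 0.6, 0.3), ignore_attr = TRUE)  # descending order
})

test_that("the full KTR pipeline recovers designed responses without heterogeneity", {
  k <- simulate_ktr(n_cells = 9, timestamps_min = seq(0, 20, 2), stim_frame = 3,
                    amplitude = c(0.8, 0.4), tau_min = 4,
                    cell_sd = 0, frame_sd = 0, noise = list(gaussian_sd = 2),
                    seed = 33)
  tab <- ktr_cnr_table(k$stack)
  expect_identical(length(unique(tab$cell_id)), 9L)
  expect_identical(sort(unique(tab$channel)), c("akt", "erk"))
  nt <- normalize_traces(tab, baseline_frame = 3)
  expect_true(all(nt$delta_log2_cnr[nt$frame == 3] == 0))
  s <- summarize_population(nt, stim_frame = 3)
  last <- s$per_frame[s$per_frame$frame == 11, ]
  designed_last <- function(A) A * (1 - exp(-(20 - 4) / 4))
  expect_equal(last$mean[last$channel == "akt"], designed_last(0.8),
               tolerance = 0.08)
  expect_equal(last$mean[last$channel == "erk"], designed_last(0.4),
               tolerance = 0.15)
  expect_identical(last$n, c(9L, 9L))
})

test_that("migration stratification bands are exclusive and validated", {
  cents <- data.frame(y = rep(10, 5), x = c(5, 60, 128, 200, 250))
  cls <- stratify_migration(cents, wound_edge_x = 250, band_px = 40,
                            field_width_px = 256)
  expect_identical(as.character(cls),
                   c("non_migratory", "neither", "neither", "neither",
                     "migratory"))
  expect_error(stratify_migration(cents, 250, 130, 256), "overlap")
})
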