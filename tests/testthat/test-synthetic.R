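test_that("cell-field generation is deterministic in the seed and leaves the RNG alone", {
  a <- make_cell_field(8, field_size = 192, seed = 9)
  b <- make_cell_field(8, field_size = 192, seed = 9)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$gt$seeds, b$gt$seeds)
  d <- make_cell_field(8, field_size = 192, seed = 10)
  expect_false(identical(a$stack$data, d$stack$data))
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(make_cell_field(6, field_size = 160, seed = 1))
  expect_identical(rnorm(3), before)
})

test_that("cell-field ground truth is internally consistent", {
  cf <- make_cell_field(10, field_size = 224, n_puncta = 15, seed = 13)
  gt <- cf$gt
  img <- gt$noiseless
  # the stated membrane fraction is the brute-force ratio of sums
  above <- img > gt$background
  expect_equal(gt$membrane_signal_fraction,
               sum(img[gt$junction_mask] - gt$background) /
                 sum(img[above] - gt$background))
  # ridges lie inside the colony; labels partition the colony
  expect_true(all(gt$colony_mask[gt$junction_mask]))
  expect_identical(gt$label_image > 0, gt$colony_mask)
  expect_identical(sort(unique(as.vector(gt$label_image[gt$label_image > 0]))),
                   1:10)
  # puncta sit strictly inside cells, away from ridges
  pc <- gt$puncta$centers
  expect_identical(nrow(pc), 15L)
  for (i in seq_len(15)) {
    expect_true(gt$colony_mask[pc[i, "y"], pc[i, "x"]])
    expect_false(gt$junction_mask[pc[i, "y"], pc[i, "x"]])
  }
  expect_error(make_cell_field(1000, field_size = 64), "infeasible")
})

test_that("internalization series conserves total signal and follows the designed kinetics", {
  cf <- make_cell_field(10, field_size = 224, seed = 17)
  tt <- c(0, 5, 10, 20, 30)
  sim <- simulate_internalization(cf, tt, f_int = 0.6, k_int = 0.1,
                                  c_transfer = 1, seed = 18)
  gt <- sim$gt
  el <- tt
  expect_equal(gt$fold_change, 0.4 + 0.6 * exp(-0.1 * el))
  # with c_transfer = 1, every noiseless frame has the same total intensity
  totals <- vapply(seq_along(tt),
                   function(i) sum(sim$stack$data[i, 1, 1, , ]), numeric(1))
  expect_equal(max(totals) - min(totals), 0, tolerance = 1e-6 * totals[1])
  # k_int = 0 freezes the scene completely
  still <- simulate_internalization(cf, tt, k_int = 0, seed = 18)
  expect_identical(still$gt$fold_change, rep(1, length(tt)))
  expect_identical(still$stack$data[1, 1, 1, , ], still$stack$data[5, 1, 1, , ])
  expect_error(simulate_internalization(cf, c(5, 10), stim_time_min = 0),
               "stim_time_min")
  expect_error(simulate_internalization(cf, tt, f_int = 1.2), "f_int")
})

test_that("KTR scenes realize their designed log2 CNR via reporter conservation", {
  k <- simulate_ktr(n_cells = 4, timestamps_min = seq(0, 10, 2), stim_frame = 2,
                    amplitude = 0.8, cell_sd = 0, frame_sd = 0,
                    noise = list(gaussian_sd = 0), seed = 5)
  gt <- k$gt
  # designed curve: flat at baseline through the stimulus frame, then rising
  expect_identical(gt$designed_log2cnr[, 1:2, ], array(0, c(4, 2, 2)))
  expect_true(all(apply(gt$designed_log2cnr[, 2:6, 1], 1, diff) > 0))
  expect_equal(gt$designed_log2cnr, gt$observed_log2cnr)
  # pixel-level check: ratio of cyto to nuclear plateau equals 2^designed
  f <- 6
  nuc <- gt_nucleus_mask(gt, 1, f)
  img <- k$stack$data[f, 1, 2, , ]
  ctr <- gt$centers[1, f, ]
  H <- gt$field_dim[1]; W <- gt$field_dim[2]
  yy <- matrix(seq_len(H), H, W); xx <- t(matrix(seq_len(W), W, H))
  cell <- (yy - ctr["y"])^2 + (xx - ctr["x"])^2 <= gt$cyto_radius^2
  cyto <- cell & !nuc
  expect_equal(log2(median(img[cyto]) / median(img[nuc])),
               gt$designed_log2cnr[1, f, 1], tolerance = 1e-9)
  # reporter is conserved over time for each cell
  tot <- vapply(seq_len(6), function(fr) {
    nucm <- gt_nucleus_mask(gt, 1, fr)
    c2 <- gt$centers[1, fr, ]
    cellm <- (yy - c2["y"])^2 + (xx - c2["x"])^2 <= gt$cyto_radius^2
    sum(k$stack$data[fr, 1, 2, , ][cellm])
  }, numeric(1))
  expect_equal(max(tot) - min(tot), 0, tolerance = 1e-6 * tot[1])
})

test_that("wound scenes realize closure fractions exactly up to pixel quantization", {
  for (cl in c(0, 0.75, 1)) {
    w <- simulate_wound(field_size = 128, wound_width_px = 40,
                        closure_fraction = cl, seed = 3)
    expect_identical(w$gt$closure_fraction_realized, cl)
    expect_identical(w$gt$area_48h_px, (1 - cl) * 40 * 128)
  }
  expect_error(simulate_wound(closure_fraction = 1.5), "closure_fraction")
  expect_error(simulate_wound(field_size = 64, wound_width_px = 80,
                              closure_fraction = 0), "wider")
})

test_that("laurdan scenes have the designed GP pixel-exactly when noiseless", {
  l <- simulate_laurdan(field_size = 96, target_gp = 0.3, seed = 2)
  io <- l$stack$data[1, 1, 1, , ]; id <- l$stack$data[1, 1, 2, , ]
  gp <- (io[l$mask] - id[l$mask]) / (io[l$mask] + id[l$mask])
  expect_equal(unique(round(gp, 12)), 0.3)
  expect_identical(sum(l$mask), l$gt$mask_px)
  expect_false(any(io[!l$mask] != 0))
  expect_error(simulate_laurdan(target_gp = 1), "target_gp")
})

test_that("flow samples carry a realized positive fraction computed by the gate rule", {
  fl <- simulate_flow(n_isotype = 2000, n_sample = 2000,
                      shift_fraction_positive = 0.4, seed = 8)
  gate <- as.numeric(quantile(fl$isotype, 0.99, type = 7))
  expect_identical(fl$gt$gate, gate)
  expect_identical(fl$gt$realized_positive_fraction, mean(fl$stained > gate))
  expect_lt(abs(fl$gt$realized_positive_fraction - 0.4), 0.05)
  expect_error(simulate_flow(n_isotype = 50), "100 events")
})

test_that("ground-truth records survive a JSON round trip including masks", {
  cf <- make_cell_field(6, field_size = 160, n_puncta = 5, seed = 19)
  f <- tempfile(fileext = ".json")
  write_ground_truth(cf$gt, f)
  gt2 <- read_ground_truth(f)
  expect_identical(gt2$junction_mask, cf$gt$junction_mask)
  expect_identical(gt2$label_image, cf$gt$label_image)
  expect_equal(gt2$membrane_signal_fraction, cf$gt$membrane_signal_fraction)
  expect_equal(gt2$seeds, cf$gt$seeds)
})
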