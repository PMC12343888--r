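# Helper: draw a filled disk into a matrix, returning linear indices.
disk_idx <- function(H, cy, cx, r) {
  g <- expand.grid(y = (cy - r):(cy + r), x = (cx - r):(cx + r))
  g <- g[(g$y - cy)^2 + (g$x - cx)^2 <= r^2, ]
  (g$x - 1) * H + g$y
}

test_that("adaptive thresholding detects a local step and validates its block size", {
  img <- matrix(1, 64, 64)
  img[30:34, 30:34] <- 5
  mask <- adaptive_threshold(img, 21, 1)
  expect_true(all(mask[30:34, 30:34]))
  expect_false(any(mask[1:20, 1:20]))
  expect_error(adaptive_threshold(img, 20, 1), "odd")
  expect_error(adaptive_threshold(img, 65, 1), "odd")
  expect_false(any(adaptive_threshold(matrix(3, 32, 32), 11, 0.5)))
})

test_that("objects are classified into puncta and membrane by size and shape", {
  H <- 160
  img <- matrix(1, H, H)
  img[disk_idx(H, 30, 30, 3)] <- 8            # small round -> punctum
  img[70:72, 10:150] <- 8                     # long thin -> membrane (423 px)
  img[110:129, 60:79] <- 8                    # 20x20 square: neither class
  img[70:72, 10:150] <- 8
  mask <- img > 1.5
  crit <- default_config()
  crit$membrane_min_area <- 400L
  seg <- classify_objects(mask, img, crit)
  ob <- seg$objects
  expect_identical(sort(ob$class), c("membrane", "punctum"))
  pun <- ob[ob$class == "punctum", ]
  mem <- ob[ob$class == "membrane", ]
  expect_identical(pun$area_px, length(disk_idx(H, 30, 30, 3)) + 0)
  expect_gt(pun$circularity, 0.7)             # rasterized r = 3 disk is round
  expect_identical(mem$area_px, 3 * 141 + 0)
  expect_lt(mem$circularity, 0.3)
  # the square blob was discarded and zeroed out of the label image
  expect_identical(sum(seg$label_image == 0),
                   as.integer(H * H - pun$area_px - mem$area_px))
  # intensities are sums over the component on the provided image
  expect_equal(mem$integrated_intensity, 8 * mem$area_px)
  expect_equal(pun$mean_intensity, 8)
})

test_that("an empty mask yields an empty segmentation", {
  seg <- classify_objects(matrix(FALSE, 16, 16), matrix(1, 16, 16))
  expect_identical(nrow(seg$objects), 0L)
  expect_true(all(seg$label_image == 0))
})

test_that("marching-squares circularity is close to 1 for disks and scale-stable", {
  H <- 128
  for (r in c(3, 5, 10)) {
    img <- matrix(0, H, H)
    img[disk_idx(H, 64, 64, r)] <- 1
    seg <- classify_objects(img > 0.5, img,
                            modifyList(default_config(),
                                       list(punctum_area_max = 500L,
                                            membrane_min_area = 600L)))
    expect_gt(seg$objects$circularity[1], 0.7)
    expect_lt(seg$objects$circularity[1], 1.05)
  }
})

test_that("the significance filter rejects weak noise clumps but keeps noiseless objects", {
  set.seed(77)
  H <- 128
  img <- matrix(rnorm(H * H, 1, 0.3), H, H)
  img[disk_idx(H, 64, 64, 4)] <- img[disk_idx(H, 64, 64, 4)] + 6
  mask <- adaptive_threshold(img, 51, 0.3)
  cfg <- default_config()
  cfg$threshold_offset <- 0.3
  seg <- classify_objects(mask, img, cfg)
  pun <- seg$objects[seg$objects$class == "punctum", ]
  expect_identical(nrow(pun), 1L)             # only the real spot survives
  cfg0 <- cfg
  cfg0$detection_min_z <- 0
  seg0 <- classify_objects(mask, img, cfg0)
  expect_gt(sum(seg0$objects$class == "punctum"), 1L)  # filter was doing work
})

test_that("quantification aggregates classes with brute-force sums", {
  H <- 120
  img <- matrix(1, H, H)
  p1 <- disk_idx(H, 20, 20, 3); p2 <- disk_idx(H, 20, 100, 3)
  img[p1] <- 5; img[p2] <- 7
  img[60:62, 5:115] <- 9
  seg <- classify_objects(img > 2, img,
                          modifyList(default_config(),
                                     list(membrane_min_area = 300L)))
  q <- quantify_segmentation(seg, img)
  expect_identical(q$puncta$count, 2L)
  expect_equal(q$puncta$integrated_total, 5 * length(p1) + 7 * length(p2))
  expect_equal(q$membrane$area, 3 * 111)
  expect_equal(q$membrane$mean, 9)
})

test_that("percent membrane fluorescence matches the ground-truth fraction exactly on clean scenes", {
  for (f in c(0.2, 0.5)) {
    cf <- make_cell_field(10, field_size = 224, target_membrane_fraction = f,
                          seed = 31)
    expect_equal(cf$gt$membrane_signal_fraction, f)
    img <- cf$stack$data[1, 1, 1, , ]
    bg <- estimate_background(img)
    nm <- normalize_to_background(img, bg)
    seg <- classify_objects(adaptive_threshold(nm), nm)
    pm <- percent_membrane_fluorescence(nm, seg)
    expect_lt(abs(pm - 100 * f), 1)
    # brute-force identity: the function is exactly the ratio of sums
    above <- pmax(nm - 1, 0)
    memb <- seg$label_image %in%
      seg$objects$label[seg$objects$class == "membrane"]
    expect_equal(pm, 100 * sum(above[memb]) / sum(above))
  }
  expect_error(percent_membrane_fluorescence(
    matrix(0.5, 8, 8),
    list(label_image = matrix(0L, 8, 8),
         objects = data.frame(label = integer(), class = character()))),
    "signal")
})

test_that("the full series pipeline recovers first-order internalization kinetics", {
  cf <- make_cell_field(10, field_size = 224, seed = 41)
  tt <- c(0, 10, 20, 30)
  sim <- simulate_internalization(cf, tt, f_int = 0.6, k_int = 0.1, seed = 42)
  res <- internalization_series(sim$stack)
  expect_equal(res$frames$fold_change, sim$gt$fold_change, tolerance = 0.02)
  expect_identical(res$frames$fold_change[1], 1)
  expect_equal(res$auc, auc_trapezoid(res$frames$fold_change, tt))
  # puncta appear as membrane signal internalizes
  expect_identical(res$frames$puncta_count[1], 0)
  expect_gt(res$frames$puncta_count[4], 0)
  expect_error(internalization_series(cf$stack), "2 frames")
})

test_that("membrane fold-change AUC decreases monotonically with the internalization rate", {
  cf <- make_cell_field(10, field_size = 224, seed = 51)
  tt <- c(0, 15, 30)
  aucs <- vapply(c(0, 0.05, 0.1, 0.2), function(k) {
    sim <- simulate_internalization(cf, tt, k_int = k, seed = 52)
    internalization_series(sim$stack)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
  expect_equal(aucs[1], 30, tolerance = 0.01)
})
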