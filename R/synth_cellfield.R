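# Synthetic receptor-fusion scenes: a confluent polygonal cell colony whose
# shared boundaries carry bright membrane ridges, optional endosomal puncta,
# and first-order ligand-induced transfer of ridge signal into puncta.

#' Generate a synthetic confluent cell field with bright junction ridges
#'
#' Emulates a single-channel image of adherent cells expressing a
#' membrane-localized receptor fusion: a colony of polygonal cells (the
#' nearest-seed tessellation of randomly placed, minimum-separated seed
#' points) on a darker background, with bright ridges of width
#' `membrane_width` along all shared cell-cell boundaries and optional round
#' endosomal puncta in cell interiors.  The returned ground truth records the
#' exact ridge mask, cell label image, and the realized fraction of
#' above-background signal residing on ridges.
#'
#' @param n_cells number of cells (>= 1)
#' @param field_size image side length \[px\]; must satisfy
#'   `field_size^2 >= 400 * n_cells`
#' @param membrane_width ridge width \[px\]
#' @param intensity_ratio_membrane_to_interior ridge value as a multiple of
#'   the interior value (> 1); ignored when `target_membrane_fraction` is set
#' @param interior_level,background_level noiseless interior and background
#'   intensities
#' @param target_membrane_fraction optional value in (0, 1): the ridge value
#'   is solved so that the ridge share of total above-background signal equals
#'   this fraction exactly in the noiseless scene
#' @param n_puncta number of static puncta to add in cell interiors
#' @param punctum_radius punctum disk radius \[px\]
#' @param punctum_amplitude intensity added per punctum pixel on top of the
#'   interior level
#' @param noise list with `gaussian_sd` (additive read noise sd) and
#'   `poisson_scale` (photon scaling; 0 disables); both default 0 so scenes
#'   are exact by construction
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output
#'
#' @return a list with elements `stack` (single-frame `ImageStack`) and `gt`
#'   (ground-truth list: `junction_mask`, `label_image`, `seeds`, levels,
#'   `membrane_signal_fraction`, `puncta`, `noise`, `seed`)
#' @export
make_cell_field <- function(n_cells, field_size = 256, membrane_width = 3,
                            intensity_ratio_membrane_to_interior = 4,
                            interior_level = 100, background_level = 50,
                            target_membrane_fraction = NULL,
                            n_puncta = 0, punctum_radius = 3,
                            punctum_amplitude = 5 * interior_level,
                            noise = list(gaussian_sd = 0, poisson_scale = 0),
                            seed = 1) {
  stopifnot(n_cells >= 1, interior_level > background_level,
            background_level > 0,
            intensity_ratio_membrane_to_interior > 1)
  if (field_size^2 < 400 * n_cells)
    stop("infeasible geometry: field_size^2 must be >= 400 * n_cells")
  with_seed(seed, {
    geo <- tessellate_colony(n_cells, field_size, membrane_width)
    ridge_value <- intensity_ratio_membrane_to_interior * interior_level
    n_ridge <- sum(geo$ridge)
    n_int <- sum(geo$colony & !geo$ridge)
    if (!is.null(target_membrane_fraction)) {
      f <- target_membrane_fraction
      stopifnot(f > 0, f < 1)
      sig_int <- n_int * (interior_level - background_level)
      ridge_value <- background_level +
        f / (1 - f) * sig_int / n_ridge
    }
    img <- matrix(background_level, field_size, field_size)
    img[geo$colony] <- interior_level
    img[geo$ridge] <- ridge_value
    puncta <- NULL
    if (n_puncta > 0) {
      pk <- place_puncta(geo, n_puncta, punctum_radius)
      for (i in seq_len(nrow(pk$centers)))
        img[pk$disks[[i]]] <- img[pk$disks[[i]]] + punctum_amplitude
      puncta <- list(centers = pk$centers, radius = punctum_radius,
                     amplitude = punctum_amplitude,
                     disk_area_px = length(pk$disks[[1]]))
    }
    above <- img > background_level
    frac <- sum(img[geo$ridge] - background_level) /
      sum(img[above] - background_level)
    noisy <- apply_noise(img, noise)
    gt <- list(kind = "cellfield", seed = seed, field_size = field_size,
               background = background_level, interior = interior_level,
               ridge_value = ridge_value, membrane_width = membrane_width,
               junction_mask = geo$ridge, label_image = geo$labels,
               colony_mask = geo$colony, seeds = geo$seeds,
               membrane_signal_fraction = frac, puncta = puncta,
               noise = noise, noiseless = img)
    list(stack = image_stack(array(noisy, c(1, 1, 1, field_size, field_size)),
                             channel_names = "receptor", timestamps_min = 0),
         gt = gt)
  })
}

#' Simulate a ligand-induced receptor internalization time series
#'
#' Starting from a cell field produced by [make_cell_field()], generates one
#' frame per timestamp in which the membrane ridge amplitude above background
#' follows first-order loss kinetics after the stimulus,
#' \deqn{M(t) = M_0\,[(1 - f_{int}) + f_{int}\, e^{-k_{int} (t - t_{stim})}],}
#' and the lost membrane signal reappears (scaled by `c_transfer`) as round
#' endosomal puncta at fixed random interior positions, so total signal is
#' conserved between the two compartments when `c_transfer = 1`.  Setting
#' `k_int = 0` emulates the soft-substrate condition (no internalization).
#'
#' @param cellfield result of [make_cell_field()] (its noise settings are
#'   ignored; per-frame noise is controlled by `noise` here)
#' @param timestamps_min frame times \[min\], strictly increasing, including
#'   `stim_time_min`
#' @param stim_time_min stimulus-addition time \[min\]
#' @param f_int fraction of membrane signal internalized as t -> Inf, in
#'   \[0, 1\]
#' @param k_int internalization rate constant \[1/min\], >= 0
#' @param c_transfer fraction of lost membrane signal recovered in puncta
#' @param n_puncta number of puncta receiving the internalized signal
#' @param punctum_radius punctum disk radius \[px\]
#' @param noise per-frame noise model as in [make_cell_field()]
#' @param seed integer seed for punctum placement and noise
#'
#' @return list with `stack` (T-frame `ImageStack`) and `gt` (adds to the
#'   cell-field ground truth: `internalization` parameters, per-frame
#'   `membrane_amplitude`, expected `fold_change`, and `puncta_schedule`)
#' @export
simulate_internalization <- function(cellfield, timestamps_min = c(0, 15, 30),
                                     stim_time_min = 0,
                                     f_int = 0.6, k_int = 0.1, c_transfer = 1,
                                     n_puncta = 25, punctum_radius = 3,
                                     noise = list(gaussian_sd = 0,
                                                  poisson_scale = 0),
                                     seed = 1) {
  gt <- cellfield$gt
  stopifnot(gt$kind == "cellfield")
  if (f_int < 0 || f_int > 1) stop("f_int must lie in [0, 1]")
  if (k_int < 0) stop("k_int must be >= 0")
  if (any(diff(timestamps_min) <= 0))
    stop("timestamps_min must be strictly increasing")
  if (!any(abs(timestamps_min - stim_time_min) < 1e-9))
    stop("timestamps_min must include stim_time_min")
  with_seed(seed, {
    fs <- gt$field_size
    ridge <- gt$junction_mask
    n_ridge <- sum(ridge)
    M0 <- gt$ridge_value - gt$background
    geo <- list(colony = gt$colony_mask, ridge = ridge, labels = gt$label_image)
    pk <- place_puncta(geo, n_puncta, punctum_radius)
    disk_area <- length(pk$disks[[1]])
    tt <- timestamps_min
    el <- pmax(tt - stim_time_min, 0)
    M <- M0 * ((1 - f_int) + f_int * exp(-k_int * el))
    M[tt < stim_time_min] <- M0
    arr <- array(0, c(length(tt), 1, 1, fs, fs))
    sched <- vector("list", length(tt))
    for (i in seq_along(tt)) {
      img <- matrix(gt$background, fs, fs)
      img[gt$colony_mask] <- gt$interior
      img[ridge] <- gt$background + M[i]
      gain <- c_transfer * (M0 - M[i]) * n_ridge
      amp <- gain / (n_puncta * disk_area)
      if (amp > 0) for (d in pk$disks) img[d] <- img[d] + amp
      sched[[i]] <- list(centers = pk$centers, radius = punctum_radius,
                         amplitude_per_px = amp,
                         integrated_total = gain)
      arr[i, 1, 1, , ] <- apply_noise(img, noise)
    }
    gt$internalization <- list(f_int = f_int, k_int = k_int,
                               c_transfer = c_transfer,
                               stim_time_min = stim_time_min)
    gt$membrane_amplitude <- M
    gt$fold_change <- M / M0
    gt$puncta_schedule <- sched
    gt$timestamps_min <- tt
    gt$noise <- noise
    gt$seed <- seed
    list(stack = image_stack(arr, channel_names = "receptor",
                             timestamps_min = tt),
         gt = gt)
  })
}

# --- internals --------------------------------------------------------------

# Nearest-seed tessellation of a roughly disk-shaped colony with minimum
# seed separation; ridges are pixels within (w-1)/2 of an interior
# label-change crack.
#' @keywords internal
tessellate_colony <- function(n_cells, field_size, membrane_width) {
  ctr <- (field_size - 1) / 2
  R_col <- 0.24 * field_size
  r_eq <- R_col / sqrt(n_cells)
  min_sep <- 1.5 * r_eq
  seeds <- matrix(NA_real_, n_cells, 2)
  placed <- 0L
  for (attempt in seq_len(5000L)) {
    u <- runif(1); th <- runif(1, 0, 2 * pi)
    p <- ctr + R_col * sqrt(u) * c(sin(th), cos(th))  # (y, x)
    if (placed == 0L ||
        min(sqrt(rowSums(sweep(seeds[seq_len(placed), , drop = FALSE],
                               2, p)^2))) >= min_sep) {
      placed <- placed + 1L
      seeds[placed, ] <- p
      if (placed == n_cells) break
    }
  }
  if (placed < n_cells)
    stop("infeasible geometry: could not place ", n_cells,
         " seeds with the required separation")
  yy <- matrix(seq_len(field_size) - 1, field_size, field_size)
  xx <- t(yy)
  best <- matrix(Inf, field_size, field_size)
  labels <- matrix(0L, field_size, field_size)
  for (i in seq_len(n_cells)) {
    d2 <- (yy - seeds[i, 1])^2 + (xx - seeds[i, 2])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    labels[upd] <- i
  }
  r_max <- 1.6 * r_eq
  colony <- best <= r_max^2
  labels[!colony] <- 0L
  # interior crack: label differs from right/down neighbor, both in colony
  fs <- field_size
  crack <- matrix(FALSE, fs, fs)
  dif_d <- labels[-fs, ] != labels[-1, ] & labels[-fs, ] > 0 & labels[-1, ] > 0
  dif_r <- labels[, -fs] != labels[, -1] & labels[, -fs] > 0 & labels[, -1] > 0
  crack[-fs, ][dif_d] <- TRUE
  crack[, -fs][dif_r] <- TRUE
  if (!any(crack)) stop("infeasible geometry: no shared cell-cell boundaries")
  d2crack <- EBImage::distmap(matrix(as.numeric(!crack), fs, fs))
  ridge <- colony & as.matrix(d2crack) <= (membrane_width - 1) / 2
  list(seeds = seeds, labels = labels, colony = colony, ridge = ridge,
       d2colony_edge = EBImage::distmap(matrix(as.numeric(colony), fs, fs)))
}

# Sample punctum centers in cell interiors, away from ridges, the colony rim
# and each other; returns centers plus linear pixel indices of each disk.
#' @keywords internal
place_puncta <- function(geo, n_puncta, radius) {
  fs <- nrow(geo$colony)
  d2ridge <- as.matrix(EBImage::distmap(matrix(as.numeric(!geo$ridge), fs, fs)))
  d2edge <- as.matrix(EBImage::distmap(matrix(as.numeric(geo$colony), fs, fs)))
  ok <- geo$colony & !geo$ridge & d2ridge > radius + 2 & d2edge > radius + 2
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) < n_puncta)
    stop("infeasible geometry: not enough interior room for ", n_puncta,
         " puncta")
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  centers <- matrix(NA_real_, n_puncta, 2)
  taken <- 0L
  min_sep <- 2 * radius + 4
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (taken == 0L ||
        min(sqrt(rowSums(sweep(centers[seq_len(taken), , drop = FALSE],
                               2, p)^2))) >= min_sep) {
      taken <- taken + 1L
      centers[taken, ] <- p
      if (taken == n_puncta) break
    }
  }
  if (taken < n_puncta)
    stop("infeasible geometry: could not separate ", n_puncta, " puncta")
  disks <- lapply(seq_len(n_puncta), function(i) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    ys <- max(1, cy - radius):min(fs, cy + radius)
    xs <- max(1, cx - radius):min(fs, cx + radius)
    g <- expand.grid(y = ys, x = xs)
    g <- g[(g$y - cy)^2 + (g$x - cx)^2 <= radius^2, ]
    (g$x - 1) * fs + g$y  # linear indices, column-major
  })
  colnames(centers) <- c("y", "x")
  list(centers = centers, disks = disks)
}

# Poisson shot noise (scaled) plus additive Gaussian read noise, clipped at 0.
#' @keywords internal
apply_noise <- function(img, noise) {
  g <- noise$gaussian_sd %||% 0
  p <- noise$poisson_scale %||% 0
  out <- img
  if (p > 0) out <- matrix(rpois(length(out), as.vector(out) / p) * p,
                           nrow(out), ncol(out))
  if (g > 0) out <- out + matrix(rnorm(length(out), 0, g), nrow(out), ncol(out))
  pmax(out, 0)
}
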