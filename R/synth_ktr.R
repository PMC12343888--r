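# Synthetic kinase-translocation-reporter (KTR) time-lapse scenes: a nuclear
# H2B marker channel plus reporter channels whose cytoplasm/nucleus
# partitioning follows a designed log2 CNR time course per cell.

#' Simulate a three-channel KTR time-lapse series
#'
#' Cells are laid out on a jittered grid, each with an elliptical nucleus
#' inside a circular cell body, and drift with a constant per-cell velocity.
#' The nuclear marker channel is bright over nuclei only.  In each reporter
#' channel the per-cell reporter amount is conserved over time and partitions
#' between nucleus and cytoplasm so that the designed
#' \eqn{\log_2(\mathrm{cyto}/\mathrm{nuc})} equals
#' `baseline + A_i (1 - e^{-(t - t_{stim})/\tau})` after the stimulus, with
#' per-cell amplitudes \eqn{A_i \sim N(A, \mathrm{cell\_sd}^2)} and optional
#' per-cell-per-frame jitter of sd `frame_sd` on the realized log2 CNR.
#'
#' @param n_cells number of cells
#' @param timestamps_min frame times \[min\]; default 36 frames every 2 min
#'   (six frames before the stimulus, then 60 min after, 70 min total)
#' @param stim_frame 1-based index of the last pre-stimulus frame
#' @param baseline_log2cnr pre-stimulus log2 CNR
#' @param amplitude plateau response amplitude `A` (log2 units); length 1 or
#'   one value per reporter channel
#' @param tau_min response rise time constant \[min\], > 0
#' @param cell_sd sd of the per-cell amplitude heterogeneity (log2 units)
#' @param frame_sd sd of per-cell-per-frame log2 CNR jitter (log2 units);
#'   this is the measurement-scale noise knob
#' @param reporter_channels names of the reporter channels
#' @param drift_px_per_frame magnitude of the field's constant drift \[px\]
#'   (shared by all cells, like slow stage drift, so cells never collide)
#' @param drift_cell_sd sd of an additional per-cell constant velocity
#'   component \[px/frame\]; keep small relative to the cell spacing over the
#'   series length
#' @param nucleus_axes mean nucleus semi-axes \[px\]
#' @param cyto_radius cell-body disk radius \[px\]; must exceed
#'   `max(nucleus_axes) + ring reach` so cytoplasmic rings stay inside cells
#' @param noise list with `gaussian_sd` for additive pixel noise
#' @param seed integer seed
#'
#' @return list with `stack` (an `ImageStack`, channels `h2b` then the
#'   reporters) and `gt` (per-cell parameters, per-frame centers, designed
#'   and realized log2 CNR arrays `cells x frames x channels`, and scene
#'   intensity levels)
#' @export
simulate_ktr <- function(n_cells = 25,
                         timestamps_min = seq(0, 70, by = 2),
                         stim_frame = 6,
                         baseline_log2cnr = 0,
                         amplitude = 0.5,
                         tau_min = 6,
                         cell_sd = 0.1,
                         frame_sd = 0.05,
                         reporter_channels = c("akt", "erk"),
                         drift_px_per_frame = 0.5,
                         drift_cell_sd = 0,
                         nucleus_axes = c(8, 6),
                         cyto_radius = 16,
                         noise = list(gaussian_sd = 2),
                         seed = 1) {
  if (tau_min <= 0) stop("tau_min must be positive")
  nf <- length(timestamps_min)
  if (stim_frame < 1 || stim_frame > nf)
    stop("stim_frame must index a frame of the series")
  nch <- length(reporter_channels)
  amplitude <- rep_len(amplitude, nch)
  with_seed(seed, {
    spacing <- 2 * cyto_radius + 8
    ncol_g <- ceiling(sqrt(n_cells))
    nrow_g <- ceiling(n_cells / ncol_g)
    margin <- cyto_radius + 6 +
      ceiling((drift_px_per_frame + 3 * drift_cell_sd) * nf)
    H <- nrow_g * spacing + 2 * margin
    W <- ncol_g * spacing + 2 * margin
    idx <- seq_len(n_cells) - 1L
    gy <- margin + spacing * (idx %/% ncol_g + 0.5) + runif(n_cells, -3, 3)
    gx <- margin + spacing * (idx %% ncol_g + 0.5) + runif(n_cells, -3, 3)
    a <- runif(n_cells, nucleus_axes[1] - 1, nucleus_axes[1] + 1)
    b <- runif(n_cells, nucleus_axes[2] - 1, nucleus_axes[2] + 1)
    theta <- runif(n_cells, 0, pi)
    vth <- runif(1, 0, 2 * pi)
    vy <- drift_px_per_frame * sin(vth) + rnorm(n_cells, 0, drift_cell_sd)
    vx <- drift_px_per_frame * cos(vth) + rnorm(n_cells, 0, drift_cell_sd)
    A <- matrix(rnorm(n_cells * nch, rep(amplitude, each = n_cells), cell_sd),
                n_cells, nch)
    t_stim <- timestamps_min[stim_frame]
    el <- pmax(timestamps_min - t_stim, 0)
    rise <- 1 - exp(-el / tau_min)        # 0 at and before the stimulus frame
    designed <- array(baseline_log2cnr, c(n_cells, nf, nch))
    for (ch in seq_len(nch))
      designed[, , ch] <- baseline_log2cnr + outer(A[, ch], rise)
    observed <- designed +
      array(rnorm(n_cells * nf * nch, 0, frame_sd), c(n_cells, nf, nch))
    levels <- list(bg_h2b = 20, h2b = 800, bg_reporter = 10,
                   reporter_per_px = 300)
    centers <- array(NA_real_, c(n_cells, nf, 2),
                     dimnames = list(NULL, NULL, c("y", "x")))
    arr <- array(0, c(nf, 1, 1 + nch, H, W))
    for (f in seq_len(nf)) {
      h2b <- matrix(levels$bg_h2b, H, W)
      rep_ch <- lapply(seq_len(nch),
                       function(i) matrix(levels$bg_reporter, H, W))
      for (i in seq_len(n_cells)) {
        cy <- round(gy[i] + vy[i] * (f - 1))
        cx <- round(gx[i] + vx[i] * (f - 1))
        centers[i, f, ] <- c(cy, cx)
        m <- cell_masks(cy, cx, a[i], b[i], theta[i], cyto_radius, H, W)
        h2b[m$nucleus] <- levels$h2b
        area_n <- length(m$nucleus); area_c <- length(m$cyto)
        total <- levels$reporter_per_px * (area_n + area_c)
        for (ch in seq_len(nch)) {
          ratio <- 2^observed[i, f, ch]
          nv <- total / (area_n + ratio * area_c)
          rep_ch[[ch]][m$nucleus] <- nv
          rep_ch[[ch]][m$cyto] <- ratio * nv
        }
      }
      arr[f, 1, 1, , ] <- apply_noise(h2b, noise)
      for (ch in seq_len(nch))
        arr[f, 1, 1 + ch, , ] <- apply_noise(rep_ch[[ch]], noise)
    }
    gt <- list(kind = "ktr", seed = seed, n_cells = n_cells,
               stim_frame = stim_frame, timestamps_min = timestamps_min,
               baseline_log2cnr = baseline_log2cnr, amplitude = amplitude,
               tau_min = tau_min, cell_sd = cell_sd, frame_sd = frame_sd,
               cell_amplitude = A, designed_log2cnr = designed,
               observed_log2cnr = observed, centers = centers,
               nucleus_params = data.frame(cell = seq_len(n_cells),
                                           a = a, b = b, theta = theta),
               cyto_radius = cyto_radius, levels = levels, noise = noise,
               field_dim = c(H, W))
    list(stack = image_stack(arr,
                             channel_names = c("h2b", reporter_channels),
                             timestamps_min = timestamps_min),
         gt = gt)
  })
}

# Rasterize one cell: elliptical nucleus plus cell-body disk minus nucleus,
# as linear pixel indices (column-major), clipped to the image.
#' @keywords internal
cell_masks <- function(cy, cx, a, b, theta, cyto_radius, H, W) {
  r <- ceiling(cyto_radius)
  ys <- max(1, cy - r):min(H, cy + r)
  xs <- max(1, cx - r):min(W, cx + r)
  g <- expand.grid(y = ys, x = xs)
  dy <- g$y - cy; dx <- g$x - cx
  in_cell <- dy^2 + dx^2 <= cyto_radius^2
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  in_nuc <- (u / a)^2 + (v / b)^2 <= 1
  lin <- (g$x - 1) * H + g$y
  list(nucleus = lin[in_nuc], cyto = lin[in_cell & !in_nuc])
}

#' Rasterize a ground-truth nucleus mask
#'
#' Reconstructs the exact elliptical nucleus mask of one simulated cell at one
#' frame from a KTR ground-truth record, for segmentation-fidelity checks.
#'
#' @param gt ground truth from [simulate_ktr()]
#' @param cell cell index
#' @param frame frame index
#' @return logical `Y x X` matrix
#' @export
gt_nucleus_mask <- function(gt, cell, frame) {
  stopifnot(gt$kind == "ktr")
  p <- gt$nucleus_params[cell, ]
  ctr <- gt$centers[cell, frame, ]
  H <- gt$field_dim[1]; W <- gt$field_dim[2]
  m <- matrix(FALSE, H, W)
  cm <- cell_masks(ctr["y"], ctr["x"], p$a, p$b, p$theta, gt$cyto_radius, H, W)
  m[cm$nucleus] <- TRUE
  m
}
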