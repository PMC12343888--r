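# Synthetic endpoint-assay inputs: scratch-wound image pairs, two-channel
# laurdan scenes with a designed generalized polarization, and
# flow-cytometry intensity samples with a known positive fraction.

#' Simulate a scratch-wound image pair
#'
#' The 0 h image is a field of high-variance cell texture with a smooth,
#' cell-free vertical band of the given width; the 48 h image has the band
#' narrowed so its area equals `(1 - closure_fraction)` times the original
#' band area, within the discretization of one pixel column.
#'
#' @param field_size image side length \[px\]
#' @param wound_width_px initial cell-free band width \[px\]
#' @param closure_fraction fraction of the band area closed by 48 h, in
#'   \[0, 1\]
#' @param seed integer seed
#' @param texture_range intensity range of the uniform cell speckle
#' @param background_level band intensity
#' @param band_noise_sd additive noise sd inside the band
#'
#' @return list with `stack_0h`, `stack_48h` (single-frame `ImageStack`s) and
#'   `gt` (band geometry, areas, realized closure fraction)
#' @export
simulate_wound <- function(field_size = 512, wound_width_px = 100,
                           closure_fraction, seed = 1,
                           texture_range = c(100, 400),
                           background_level = 50, band_noise_sd = 2) {
  if (closure_fraction < 0 || closure_fraction > 1)
    stop("closure_fraction must lie in [0, 1]")
  if (wound_width_px >= field_size)
    stop("wound wider than the field")
  with_seed(seed, {
    draw <- function(width) {
      img <- matrix(runif(field_size^2, texture_range[1], texture_range[2]),
                    field_size, field_size)
      if (width > 0) {
        c0 <- round((field_size - width) / 2) + 1
        cols <- c0:(c0 + width - 1)
        img[, cols] <- pmax(background_level +
                              rnorm(field_size * width, 0, band_noise_sd), 0)
        attr(img, "band_cols") <- cols
      }
      img
    }
    w48 <- round(wound_width_px * (1 - closure_fraction))
    img0 <- draw(wound_width_px)
    img48 <- draw(w48)
    area0 <- wound_width_px * field_size
    area48 <- w48 * field_size
    gt <- list(kind = "wound", seed = seed, field_size = field_size,
               wound_width_px = wound_width_px, width_48h_px = w48,
               band_cols_0h = attr(img0, "band_cols"),
               band_cols_48h = attr(img48, "band_cols"),
               area_0h_px = area0, area_48h_px = area48,
               closure_fraction_target = closure_fraction,
               closure_fraction_realized =
                 if (area0 > 0) (area0 - area48) / area0 else NA_real_)
    list(stack_0h = image_stack(array(img0, c(1, 1, 1, field_size, field_size)),
                                channel_names = "phase", timestamps_min = 0),
         stack_48h = image_stack(array(img48, c(1, 1, 1, field_size, field_size)),
                                 channel_names = "phase", timestamps_min = 0),
         gt = gt)
  })
}

#' Simulate a two-channel laurdan scene with a designed GP
#'
#' Over a circular cell mask, each pixel's expected ordered- and
#' disordered-phase intensities satisfy
#' \eqn{(I_o - I_d)/(I_o + I_d) = } `target_gp` with constant total
#' `total_intensity`; outside the mask both channels are zero.  Optional
#' Gaussian noise (sd expressed as a fraction of `total_intensity`) is added
#' per channel and clipped at zero.
#'
#' @param field_size image side length \[px\]; the default mask holds over
#'   10^4 pixels
#' @param target_gp designed generalized polarization, in (-1, 1)
#' @param total_intensity per-pixel channel sum
#' @param noise_sd_frac per-channel Gaussian noise sd as a fraction of
#'   `total_intensity`
#' @param seed integer seed
#'
#' @return list with `stack` (2-channel `ImageStack`, channels `ordered`,
#'   `disordered`), `mask` (logical matrix), and `gt`
#' @export
simulate_laurdan <- function(field_size = 128, target_gp = 0.3,
                             total_intensity = 300, noise_sd_frac = 0,
                             seed = 1) {
  if (abs(target_gp) >= 1) stop("target_gp must lie strictly inside (-1, 1)")
  with_seed(seed, {
    ctr <- (field_size + 1) / 2
    yy <- matrix(seq_len(field_size), field_size, field_size)
    xx <- t(yy)
    mask <- (yy - ctr)^2 + (xx - ctr)^2 <= (0.45 * field_size)^2
    io <- matrix(0, field_size, field_size)
    id <- matrix(0, field_size, field_size)
    io[mask] <- total_intensity * (1 + target_gp) / 2
    id[mask] <- total_intensity * (1 - target_gp) / 2
    ns <- list(gaussian_sd = noise_sd_frac * total_intensity)
    io <- apply_noise(io, ns)
    id <- apply_noise(id, ns)
    arr <- array(0, c(1, 1, 2, field_size, field_size))
    arr[1, 1, 1, , ] <- io
    arr[1, 1, 2, , ] <- id
    gt <- list(kind = "laurdan", seed = seed, target_gp = target_gp,
               total_intensity = total_intensity,
               noise_sd_frac = noise_sd_frac, mask_px = sum(mask))
    list(stack = image_stack(arr, channel_names = c("ordered", "disordered"),
                             timestamps_min = 0),
         mask = mask, gt = gt)
  })
}

#' Simulate flow-cytometry intensity samples with a known positive fraction
#'
#' The isotype-control sample is log-normal.  The stained sample is a mixture
#' in which a `shift_fraction_positive` share of events is drawn from a
#' log-normal shifted well above the control, and the rest from the control
#' distribution.  The ground truth stores the realized positive fraction as a
#' direct count of stained events above the realized gate (the
#' `gate_quantile` order statistic of the isotype sample, type-7
#' interpolation) — the same counting rule [flow_percent_positive()] applies.
#'
#' @param n_isotype,n_sample event counts (>= 100 each; the gate percentile
#'   is unstable below that)
#' @param shift_fraction_positive mixture weight of the shifted component,
#'   in \[0, 1\]
#' @param seed integer seed
#' @param meanlog,sdlog log-normal parameters of the control population
#' @param shift_log meanlog increment of the shifted (positive) component
#' @param gate_quantile isotype quantile defining the gate
#'
#' @return list with `isotype`, `stained` (numeric vectors) and `gt`
#'   (`gate`, `realized_positive_fraction`, parameters)
#' @export
simulate_flow <- function(n_isotype = 10000, n_sample = 10000,
                          shift_fraction_positive = 0.5, seed = 1,
                          meanlog = 4, sdlog = 0.5, shift_log = 2.5,
                          gate_quantile = 0.99) {
  if (n_isotype < 100 || n_sample < 100)
    stop("at least 100 events per sample are required for a stable gate")
  if (shift_fraction_positive < 0 || shift_fraction_positive > 1)
    stop("shift_fraction_positive must lie in [0, 1]")
  with_seed(seed, {
    isotype <- rlnorm(n_isotype, meanlog, sdlog)
    pos <- rbinom(n_sample, 1, shift_fraction_positive) == 1
    stained <- numeric(n_sample)
    stained[!pos] <- rlnorm(sum(!pos), meanlog, sdlog)
    stained[pos] <- rlnorm(sum(pos), meanlog + shift_log, sdlog)
    gate <- as.numeric(quantile(isotype, gate_quantile, type = 7))
    gt <- list(kind = "flow", seed = seed,
               shift_fraction_positive = shift_fraction_positive,
               meanlog = meanlog, sdlog = sdlog, shift_log = shift_log,
               gate = gate, gate_quantile = gate_quantile,
               realized_positive_fraction = mean(stained > gate),
               n_true_shifted = sum(pos))
    list(isotype = isotype, stained = stained, gt = gt)
  })
}
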