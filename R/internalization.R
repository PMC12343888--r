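#' Quantify a receptor internalization time series
#'
#' Runs the full membrane/puncta pipeline on every frame of a receptor image
#' series: maximum-intensity z-projection, median denoising (when
#' `config$denoise_median_px > 0`), background estimation and
#' normalization, adaptive thresholding, object classification, and
#' quantification.  Membrane signal per frame is the integrated
#' above-background intensity (`value - 1` on the normalized image, floored
#' at 0) over membrane-class pixels; fold change is relative to the first
#' frame (the frame at stimulus addition), and the area under the
#' fold-change curve is computed by the trapezoidal rule over the observed
#' timestamps.
#'
#' @param stack an `ImageStack` with one receptor channel (extra z slices
#'   are max-projected)
#' @param config a `stiffquant_config` list (see [default_config()])
#' @param channel 1-based channel index of the receptor signal
#' @return an `InternalizationSeries` list: `timestamps_min`, `frames` (data
#'   frame with per-frame `t_min`, `membrane_intensity`, `fold_change`,
#'   `puncta_count`, `puncta_intensity`, `background`), `auc`, and
#'   `segmentations` (per-frame `Segmentation`s)
#' @export
internalization_series <- function(stack, config = default_config(),
                                   channel = 1L) {
  validate_stack(stack)
  d <- dim(stack$data)
  if (d[1] < 2) stop("an internalization series needs at least 2 frames")
  proj <- max_project(stack)
  tt <- proj$timestamps_min
  nT <- d[1]
  mem <- pun_int <- pun_n <- bgs <- numeric(nT)
  segs <- vector("list", nT)
  for (f in seq_len(nT)) {
    img <- proj$data[f, 1, channel, , ]
    if (config$denoise_median_px > 0)
      img <- median_denoise(img, config$denoise_median_px)
    bg <- estimate_background(img)
    norm <- normalize_to_background(img, bg)
    mask <- adaptive_threshold(norm, config$threshold_block_px,
                               config$threshold_offset)
    seg <- classify_objects(mask, norm, config)
    above <- pmax(norm - 1, 0)
    mem_px <- seg$label_image %in%
      seg$objects$label[seg$objects$class == "membrane"]
    pun_px <- seg$label_image %in%
      seg$objects$label[seg$objects$class == "punctum"]
    mem[f] <- sum(above[mem_px])
    pun_int[f] <- sum(above[pun_px])
    pun_n[f] <- sum(seg$objects$class == "punctum")
    bgs[f] <- as.numeric(bg)
    segs[[f]] <- seg
  }
  if (mem[1] <= 0)
    stop("no membrane signal detected at the first frame; fold change undefined")
  fold <- mem / mem[1]
  list(timestamps_min = tt,
       frames = data.frame(t_min = tt, membrane_intensity = mem,
                           fold_change = fold, puncta_count = pun_n,
                           puncta_intensity = pun_int, background = bgs),
       auc = auc_trapezoid(fold, tt),
       segmentations = segs)
}
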