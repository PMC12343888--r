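# Scalar endpoint assays: wound closure, laurdan generalized polarization,
# and flow-cytometry percent positive above an isotype gate.

#' Cell-free area of a wound image
#'
#' Classifies pixels whose local intensity standard deviation (over a centred
#' `texture_window_px` square) falls below `texture_sd_threshold` as
#' cell-free, dilates the cell-free mask by half the window (compensating the
#' window's reach into the band edges), and returns the area of the largest
#' connected cell-free component.
#'
#' @param img 2-D numeric matrix (phase or fluorescence) with textured cell
#'   regions and a smooth cell-free band
#' @param texture_window_px odd window size \[px\]
#' @param texture_sd_threshold local sd below which a pixel is cell-free
#' @return list with `area_px`, `mask` (logical, the largest cell-free
#'   component) and `degenerate` (`TRUE` when the whole image is classified
#'   cell-free)
#' @export
wound_area <- function(img, texture_window_px = 9, texture_sd_threshold = 20) {
  sdmap <- box_sd(img, texture_window_px)
  core <- sdmap < texture_sd_threshold
  if (!any(core))
    return(list(area_px = 0,
                mask = matrix(FALSE, nrow(img), ncol(img)),
                degenerate = FALSE))
  r <- (texture_window_px - 1) / 2
  brush <- EBImage::makeBrush(2 * r + 1, shape = "box")
  dil <- EBImage::dilate(matrix(as.numeric(core), nrow(img)), brush) > 0
  lab <- EBImage::bwlabel(matrix(as.numeric(dil), nrow(img)))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  areas <- tabulate(lab[lab > 0], max(lab))
  big <- which.max(areas)
  mask <- lab == big
  list(area_px = areas[big], mask = mask,
       degenerate = all(mask))
}

#' Wound closure percentage
#'
#' `100 * (area_0h - area_48h) / area_0h`; may be negative if the cell-free
#' area grows, and never exceeds 100.
#'
#' @param area_0h,area_48h cell-free areas \[px\]; `area_0h` must be positive
#' @return percentage
#' @export
wound_closure <- function(area_0h, area_48h) {
  if (area_0h <= 0) stop("area_0h must be positive")
  100 * (area_0h - area_48h) / area_0h
}

#' Laurdan generalized polarization
#'
#' Per-pixel \eqn{GP = (I_o - I_d)/(I_o + I_d)} where the channel sum is
#' positive; pixels with zero channel sum are undefined and excluded.  The
#' mean is taken over defined pixels inside `cell_mask`.  Swapping the
#' channels negates every defined pixel's GP exactly.
#'
#' @param I_ordered,I_disordered nonnegative matrices of equal shape
#' @param cell_mask logical matrix; defaults to the full image
#' @return a `GPResult` list: `gp_image` (matrix with `NA` where undefined)
#'   and `mean_gp`
#' @export
laurdan_gp <- function(I_ordered, I_disordered, cell_mask = NULL) {
  if (!all(dim(I_ordered) == dim(I_disordered)))
    stop("channel images must have identical shape")
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(I_ordered), ncol(I_ordered))
  if (!any(cell_mask)) stop("empty analysis mask")
  s <- I_ordered + I_disordered
  gp <- matrix(NA_real_, nrow(I_ordered), ncol(I_ordered))
  ok <- s > 0
  gp[ok] <- (I_ordered[ok] - I_disordered[ok]) / s[ok]
  use <- ok & cell_mask
  if (!any(use)) stop("no defined GP pixels inside the mask")
  list(gp_image = gp, mean_gp = mean(gp[use]))
}

#' Percent positive above an isotype-control gate
#'
#' The gate is the `gate_quantile` order statistic of the isotype sample
#' (type-7 interpolation, i.e. a 1 percent positive control gate at the
#' default); percent positive is 100 times the fraction of stained events
#' strictly above the gate.
#'
#' @param isotype,stained numeric intensity samples, each with at least 100
#'   events
#' @param gate_quantile isotype quantile defining the gate
#' @return list `gate_value`, `percent_positive`
#' @export
flow_percent_positive <- function(isotype, stained, gate_quantile = 0.99) {
  if (length(isotype) < 100 || length(stained) < 100)
    stop("at least 100 events per sample are required")
  gate <- as.numeric(quantile(isotype, gate_quantile, type = 7))
  list(gate_value = gate,
       percent_positive = 100 * mean(stained > gate))
}
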