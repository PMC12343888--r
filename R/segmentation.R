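# Membrane-versus-puncta segmentation: adaptive thresholding picks up sharp
# fluorescence increases; connected components are then classified by size
# and shape into junction-ridge networks (large, non-round) and endosomal
# puncta (small, round).

#' Adaptive (local mean) threshold
#'
#' A pixel is foreground iff its value exceeds the mean over the centred
#' `block_size_px` square (edge-truncated at borders) by more than `offset`.
#'
#' @param img numeric matrix; for receptor images this is the
#'   background-normalized image, and `offset` is then in
#'   fold-over-background units
#' @param block_size_px odd block edge, `3 <= block <= min(dim(img))`
#' @param offset scalar added to the local mean
#' @return logical matrix
#' @export
adaptive_threshold <- function(img, block_size_px = 51, offset = 1) {
  if (block_size_px %% 2 == 0 || block_size_px < 3 ||
      block_size_px > min(dim(img)))
    stop("block_size_px must be odd, >= 3, and <= the smallest image dimension")
  img > box_mean(img, block_size_px) + offset
}

#' Classify thresholded objects into membrane ridges and puncta
#'
#' Labels the connected components of `mask` and classifies each by area and
#' circularity (\eqn{4\pi A / P^2}, perimeter from a marching-squares contour
#' length): small round components are puncta, large non-round components are
#' membrane (junction-ridge networks), everything else is discarded.
#'
#' Before classification, each component must pass a detection-significance
#' test.  Membership in the threshold mask already guarantees every pixel's
#' residual over the local mean (the same `threshold_block_px` surface used
#' for thresholding) exceeds the threshold offset, so the unbiased statistic
#' conditional on selection is the component's summed residual above that
#' floor; it must exceed `detection_min_z` times \eqn{\sigma \sqrt{A}},
#' where \eqn{\sigma} is the robust (MAD) spread of off-object residuals.
#' On a noiseless image \eqn{\sigma = 0} and every component passes; on a
#' noisy image this rejects barely-threshold-crossing noise clumps while
#' real structures exceed the bound by orders of magnitude.
#'
#' @param mask logical matrix from [adaptive_threshold()]
#' @param img numeric matrix the mask was derived from (for intensities)
#' @param criteria list with `punctum_area_min`, `punctum_area_max`,
#'   `punctum_min_circularity`, `membrane_min_area`,
#'   `membrane_max_circularity`, `threshold_block_px`, `detection_min_z`;
#'   defaults from [default_config()]
#' @return a `Segmentation` list: `label_image` (integer matrix, zero where
#'   discarded or background) and `objects` (data frame with `label`,
#'   `class`, `area_px`, `integrated_intensity`, `mean_intensity`,
#'   `perimeter`, `circularity`, `eccentricity`)
#' @export
classify_objects <- function(mask, img, criteria = default_config()) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  empty <- data.frame(label = integer(), class = character(),
                      area_px = numeric(), integrated_intensity = numeric(),
                      mean_intensity = numeric(), perimeter = numeric(),
                      circularity = numeric(), eccentricity = numeric())
  if (n == 0L)
    return(list(label_image = lab, objects = empty))
  pix <- which(lab > 0)
  ord <- order(lab[pix])
  pix <- pix[ord]
  labs <- lab[pix]
  bounds <- c(0, cumsum(tabulate(labs, n)))
  H <- nrow(mask)
  objs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pix[(bounds[i] + 1):bounds[i + 1]]
    area <- length(p)
    integ <- sum(img[p])
    ys <- (p - 1) %% H + 1
    xs <- (p - 1) %/% H + 1
    per <- ms_perimeter(ys, xs)
    circ <- 4 * pi * area / per^2
    ecc <- mask_eccentricity(ys, xs)
    objs[[i]] <- c(area, integ, integ / area, per, circ, ecc)
  }
  m <- do.call(rbind, objs)
  z_min <- criteria$detection_min_z %||% 5
  significant <- rep(TRUE, n)
  if (z_min > 0) {
    loc <- box_mean(img, criteria$threshold_block_px %||% 51L)
    resid <- img - loc
    sigma <- stats::mad(resid[lab == 0])
    if (sigma > 0) {
      floor_off <- criteria$threshold_offset %||% 1
      for (i in seq_len(n)) {
        p <- pix[(bounds[i] + 1):bounds[i + 1]]
        significant[i] <- sum(resid[p] - floor_off) >
          z_min * sigma * sqrt(length(p))
      }
    }
  }
  df <- data.frame(label = seq_len(n), class = NA_character_,
                   area_px = m[, 1], integrated_intensity = m[, 2],
                   mean_intensity = m[, 3], perimeter = m[, 4],
                   circularity = m[, 5], eccentricity = m[, 6])
  is_punct <- df$area_px >= criteria$punctum_area_min &
    df$area_px <= criteria$punctum_area_max &
    df$circularity >= criteria$punctum_min_circularity
  is_memb <- df$area_px >= criteria$membrane_min_area &
    df$circularity <= criteria$membrane_max_circularity
  df$class[is_punct & significant] <- "punctum"
  df$class[is_memb & !is_punct & significant] <- "membrane"
  drop <- which(is.na(df$class))
  if (length(drop)) lab[lab %in% drop] <- 0L
  df <- df[!is.na(df$class), , drop = FALSE]
  rownames(df) <- NULL
  list(label_image = lab, objects = df)
}

#' Quantify a segmentation
#'
#' Aggregates the membrane class (area, integrated and mean intensity over
#' all membrane-class pixels) and the punctum class (count and total
#' integrated intensity).
#'
#' @param seg a `Segmentation` from [classify_objects()]
#' @param img the image the segmentation was derived from
#' @return list with elements `membrane` (`area`, `integrated`, `mean`) and
#'   `puncta` (`count`, `integrated_total`)
#' @export
quantify_segmentation <- function(seg, img) {
  ob <- seg$objects
  mem <- ob[ob$class == "membrane", , drop = FALSE]
  pun <- ob[ob$class == "punctum", , drop = FALSE]
  mem_area <- sum(mem$area_px)
  mem_int <- sum(mem$integrated_intensity)
  list(membrane = list(area = mem_area, integrated = mem_int,
                       mean = if (mem_area > 0) mem_int / mem_area else NA_real_),
       puncta = list(count = nrow(pun),
                     integrated_total = sum(pun$integrated_intensity)))
}

#' Percentage of quantifiable fluorescence at cell-cell junctions
#'
#' On a background-normalized image, the above-background signal of a pixel
#' is `max(value - 1, 0)`.  Returns 100 times the above-background signal on
#' membrane-class pixels divided by the above-background signal of the whole
#' image.
#'
#' @param img background-normalized numeric matrix
#' @param seg a `Segmentation` from [classify_objects()] on `img`
#' @return percentage in \[0, 100\]
#' @export
percent_membrane_fluorescence <- function(img, seg) {
  above <- pmax(img - 1, 0)
  total <- sum(above)
  if (total <= 0) stop("image has no above-background signal")
  mem_px <- seg$label_image %in%
    seg$objects$label[seg$objects$class == "membrane"]
  100 * sum(above[mem_px]) / total
}

# Marching-squares contour length of a pixel set given by (row, col)
# coordinates: iso-0.5 contour segment lengths summed over all 2x2 cells.
#' @keywords internal
ms_perimeter <- function(ys, xs) {
  h <- max(ys) - min(ys) + 3L; w <- max(xs) - min(xs) + 3L
  m <- matrix(0L, h, w)
  m[cbind(ys - min(ys) + 2L, xs - min(xs) + 2L)] <- 1L
  a <- m[-h, -w]; b <- m[-h, -1]; cc <- m[-1, -w]; d <- m[-1, -1]
  code <- a + 2L * b + 4L * cc + 8L * d + 1L
  s2 <- sqrt(2) / 2
  len <- c(0, s2, s2, 1, s2, 1, sqrt(2), s2, s2, sqrt(2), 1, s2, 1, s2, s2, 0)
  sum(len[code])
}

# Eccentricity from central second moments of the pixel set.
#' @keywords internal
mask_eccentricity <- function(ys, xs) {
  my <- mean(ys); mx <- mean(xs)
  u20 <- mean((ys - my)^2); u02 <- mean((xs - mx)^2)
  u11 <- mean((ys - my) * (xs - mx))
  disc <- sqrt(((u20 - u02) / 2)^2 + u11^2)
  l1 <- (u20 + u02) / 2 + disc
  l2 <- (u20 + u02) / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(pmax(1 - l2 / l1, 0))
}
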