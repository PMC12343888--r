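# Integral-image box statistics with edge-truncated windows: each pixel's
# window is the intersection of the centred block with the image, and sums
# are divided by the actual pixel count, so borders need no padding.

#' @keywords internal
box_mean <- function(img, block) {
  box_sum(img, block) / box_sum(matrix(1, nrow(img), ncol(img)), block)
}

#' @keywords internal
box_sd <- function(img, block) {
  n <- box_sum(matrix(1, nrow(img), ncol(img)), block)
  m <- box_sum(img, block) / n
  m2 <- box_sum(img * img, block) / n
  sqrt(pmax(m2 - m^2, 0))
}

#' @keywords internal
box_sum <- function(img, block) {
  r <- (block - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  S <- matrix(0, H + 1, W + 1)
  cs <- apply(img, 2, cumsum)          # cumsum down rows
  cs <- t(apply(cs, 1, cumsum))        # then across columns
  S[-1, -1] <- cs
  y0 <- pmax(seq_len(H) - r, 1); y1 <- pmin(seq_len(H) + r, H)
  x0 <- pmax(seq_len(W) - r, 1); x1 <- pmin(seq_len(W) + r, W)
  S[y1 + 1, x1 + 1, drop = FALSE] - S[y0, x1 + 1, drop = FALSE] -
    S[y1 + 1, x0, drop = FALSE] + S[y0, x0, drop = FALSE]
}
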