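# Conversion of raw stacks into the normalized 2-D images and line profiles
# the quantification stages consume.

#' Maximum-intensity z-projection
#'
#' Collapses the z axis of an `ImageStack` by taking, for every
#' `(t, c, y, x)`, the maximum over z.  Idempotent and invariant under
#' permutation of the z slices.
#'
#' @param stack an `ImageStack`
#' @return an `ImageStack` with `Z = 1`
#' @export
max_project <- function(stack) {
  validate_stack(stack)
  d <- dim(stack$data)
  if (d[2] == 1L) return(stack)
  out <- array(stack$data[, 1, , , , drop = FALSE], c(d[1], 1, d[3], d[4], d[5]))
  for (z in seq_len(d[2])[-1])
    out[, 1, , , ] <- pmax(out[, 1, , , , drop = FALSE],
                           stack$data[, z, , , , drop = FALSE])
  image_stack(out, channel_names = stack$channel_names,
              timestamps_min = stack$timestamps_min,
              pixel_size_um = stack$pixel_size_um)
}

#' Median denoising filter
#'
#' Exact running median over a centred `size_px` square window with
#' replicated borders, computed by a vectorized compare-exchange sorting
#' network over the window's shifted copies.  Removes isolated noise pixels
#' while preserving plateaus and edges of structures at least
#' `(size_px + 1) / 2` pixels wide; a piecewise-constant image maps onto
#' values from its own level set.
#'
#' @param img numeric matrix
#' @param size_px odd window edge >= 3 (keep small; cost grows as
#'   `size_px^4`)
#' @return numeric matrix of the same shape
#' @export
median_denoise <- function(img, size_px = 3) {
  if (size_px %% 2 == 0 || size_px < 3)
    stop("size_px must be odd and >= 3")
  H <- nrow(img); W <- ncol(img)
  r <- (size_px - 1) / 2
  off <- -r:r
  cols <- vector("list", size_px^2)
  k <- 0L
  for (dy in off) for (dx in off) {
    k <- k + 1L
    cols[[k]] <- img[pmin(pmax(seq_len(H) + dy, 1), H),
                     pmin(pmax(seq_len(W) + dx, 1), W)]
  }
  m <- length(cols)
  for (i in seq_len(m - 1)) for (j in seq_len(m - i)) {
    a <- cols[[j]]; b <- cols[[j + 1]]
    cols[[j]] <- pmin(a, b)
    cols[[j + 1]] <- pmax(a, b)
  }
  matrix(cols[[(m + 1) / 2]], H, W)
}

#' Estimate the background intensity of a 2-D image
#'
#' Splits the intensity histogram at the global threshold maximizing the
#' between-class variance (an Otsu-style bimodal split) and returns the
#' median intensity of the below-threshold class.  A constant image is
#' returned as-is with a `degenerate` attribute set.
#'
#' @param img numeric matrix
#' @param nbins number of histogram bins for the split
#' @return background intensity (scalar), with attributes `threshold` and
#'   `degenerate`
#' @export
estimate_background <- function(img, nbins = 256) {
  v <- as.vector(img)
  rng <- range(v)
  if (diff(rng) == 0) {
    out <- rng[1]
    attr(out, "threshold") <- rng[1]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  thr <- otsu_split(v, nbins)
  bgv <- v[v <= thr]
  out <- median(bgv)
  attr(out, "threshold") <- thr
  attr(out, "degenerate") <- FALSE
  out
}

# Between-class-variance-maximizing histogram split; returns the intensity
# at the upper edge of the chosen split bin.
#' @keywords internal
otsu_split <- function(v, nbins = 256) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- as.numeric(tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE),
                                nbins), nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  s1 <- cumsum(h * mids)
  mu1 <- s1 / w1
  mu2 <- (sum(h * mids) - s1) / w2
  bcv <- w1 * w2 * (mu1 - mu2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  br[which.max(bcv) + 1]
}

#' Divide an image by its background level
#'
#' Returns `img / background`, so background regions read as about 1 and
#' structures as fold-over-background.  Scales linearly: doubling `img`
#' doubles the output exactly.
#'
#' @param img numeric matrix
#' @param background positive scalar (e.g. from [estimate_background()])
#' @return numeric matrix
#' @export
normalize_to_background <- function(img, background) {
  if (!is.numeric(background) || length(background) != 1 || background <= 0)
    stop("background must be a positive scalar")
  img / as.numeric(background)
}

#' Sample an intensity profile along a line
#'
#' Samples the image at unit-pixel spacing along the segment from `p0` to
#' `p1` (0-based `(y, x)` pixel-centre coordinates), averaging each sample
#' over `width_px` bilinear samples spaced one pixel apart perpendicular to
#' the line.
#'
#' @param img numeric matrix
#' @param p0,p1 numeric `(y, x)` endpoints, 0-based pixel centres; must be
#'   distinct and inside the image
#' @param width_px perpendicular averaging width (>= 1)
#' @return a `LineProfile` list: `endpoints`, `width_px`, `positions_px`
#'   (strictly increasing distances from `p0`), `values`
#' @export
line_profile <- function(img, p0, p1, width_px = 1) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (isTRUE(all.equal(p0, p1))) stop("p0 and p1 must be distinct")
  H <- nrow(img); W <- ncol(img)
  inb <- function(p) p[1] >= 0 && p[1] <= H - 1 && p[2] >= 0 && p[2] <= W - 1
  if (!inb(p0) || !inb(p1)) stop("line endpoints fall outside the image")
  L <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / L                 # unit direction (dy, dx)
  nvec <- c(-u[2], u[1])             # unit normal
  pos <- seq(0, L, by = 1)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  vals <- vapply(pos, function(s) {
    pt <- p0 + s * u
    mean(vapply(offs, function(o) {
      bilinear_at(img, pt[1] + o * nvec[1], pt[2] + o * nvec[2])
    }, numeric(1)))
  }, numeric(1))
  list(endpoints = rbind(p0 = p0, p1 = p1), width_px = width_px,
       positions_px = pos, values = vals)
}

# Bilinear interpolation at a 0-based (y, x) position, clamped to the image.
#' @keywords internal
bilinear_at <- function(img, y, x) {
  H <- nrow(img); W <- ncol(img)
  y <- min(max(y, 0), H - 1)
  x <- min(max(x, 0), W - 1)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
  fy <- y - y0; fx <- x - x0
  (1 - fy) * ((1 - fx) * img[y0 + 1, x0 + 1] + fx * img[y0 + 1, x1 + 1]) +
    fy * ((1 - fx) * img[y1 + 1, x0 + 1] + fx * img[y1 + 1, x1 + 1])
}
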