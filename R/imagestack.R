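#' Construct an ImageStack
#'
#' An `ImageStack` is the package's in-memory image container: a 5-D
#' nonnegative intensity array ordered `(T, Z, C, Y, X)` with channel labels,
#' per-frame timestamps in minutes, and a pixel size in micrometres.
#' Degenerate axes (`T = 1`, `Z = 1`, `C = 1`) are permitted throughout.
#'
#' @param data numeric array with up to 5 dimensions. Arrays of lower rank are
#'   promoted by inserting leading length-1 axes: a `Y x X` matrix becomes
#'   `(1, 1, 1, Y, X)`; 3-D input is interpreted according to `axes`
#'   (default `"ZYX"` for 3-D, `"TZYX"`/`"TCYX"` ambiguity must be resolved
#'   explicitly for 4-D input).
#' @param channel_names character vector, one name per channel.
#' @param timestamps_min strictly increasing numeric vector, one per frame.
#' @param pixel_size_um positive scalar, pixel edge length in micrometres.
#' @param axes axis string describing `dim(data)` when `data` has fewer than
#'   5 dimensions, using letters from `"TZCYX"` (e.g. `"ZYX"`, `"TCYX"`).
#'
#' @return an object of class `ImageStack`: a list with elements `data`
#'   (5-D array), `channel_names`, `timestamps_min`, `pixel_size_um`.
#' @export
image_stack <- function(data, channel_names = NULL, timestamps_min = NULL,
                        pixel_size_um = 0.65, axes = NULL) {
  if (!is.array(data) && !is.matrix(data)) {
    if (is.numeric(data)) data <- as.matrix(data) else stop("data must be a numeric array")
  }
  data <- promote_axes(data, axes)
  d <- dim(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[3]))
  if (is.null(timestamps_min)) timestamps_min <- as.numeric(seq_len(d[1]) - 1L)
  x <- structure(list(data = data,
                      channel_names = as.character(channel_names),
                      timestamps_min = as.numeric(timestamps_min),
                      pixel_size_um = pixel_size_um),
                 class = "ImageStack")
  validate_stack(x)
  x
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: T=%d Z=%d C=%d Y=%d X=%d (%s)\n",
              d[1], d[2], d[3], d[4], d[5],
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  t = %s min; pixel size %.3g um; intensity range [%g, %g]\n",
              paste(signif(range(x$timestamps_min), 4), collapse = ".."),
              x$pixel_size_um, min(x$data), max(x$data)))
  invisible(x)
}

#' @keywords internal
validate_stack <- function(x) {
  stopifnot(inherits(x, "ImageStack"))
  d <- dim(x$data)
  if (length(d) != 5L) stop("ImageStack data must be 5-D (T, Z, C, Y, X)")
  if (any(x$data < 0)) stop("ImageStack intensities must be nonnegative")
  if (length(x$channel_names) != d[3])
    stop("length(channel_names) must equal the channel dimension")
  if (length(x$timestamps_min) != d[1])
    stop("length(timestamps_min) must equal the time dimension")
  if (d[1] > 1 && any(diff(x$timestamps_min) <= 0))
    stop("timestamps_min must be strictly increasing")
  if (!is.numeric(x$pixel_size_um) || length(x$pixel_size_um) != 1 ||
      x$pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  invisible(TRUE)
}

# Insert missing axes so dim order is (T, Z, C, Y, X). Idempotent on 5-D input.
#' @keywords internal
promote_axes <- function(data, axes = NULL) {
  d <- dim(data)
  nd <- length(d)
  if (nd == 5L) return(data)
  if (is.null(axes)) {
    axes <- switch(as.character(nd),
                   "2" = "YX",
                   "3" = "ZYX",
                   stop("4-D input is ambiguous: supply an axis string such as \"TZYX\" or \"TCYX\""))
  }
  axes <- toupper(axes)
  letters5 <- c("T", "Z", "C", "Y", "X")
  ax <- strsplit(axes, "")[[1]]
  if (length(ax) != nd || anyDuplicated(ax) || !all(ax %in% letters5))
    stop("axes must name each dimension once using letters from TZCYX")
  if (!all(c("Y", "X") %in% ax)) stop("axes must include Y and X")
  full <- setNames(rep(1L, 5), letters5)
  full[ax] <- d
  out <- array(0, unname(full))
  perm <- match(letters5, c(ax, setdiff(letters5, ax)))
  src <- array(data, c(d, rep(1L, 5 - nd)))  # pad trailing singleton dims
  out[] <- aperm(src, perm)
  out
}

#' Number of frames, slices, channels of an ImageStack
#' @param x an `ImageStack`
#' @return integer vector `c(T, Z, C, Y, X)`
#' @export
stack_dim <- function(x) {
  validate_stack(x)
  dim(x$data)
}

#' Extract one 2-D plane from an ImageStack
#'
#' @param x an `ImageStack`
#' @param t,z,c 1-based frame, slice and channel indices
#' @return a `Y x X` numeric matrix
#' @export
stack_plane <- function(x, t = 1L, z = 1L, c = 1L) {
  validate_stack(x)
  x$data[t, z, c, , , drop = TRUE]
}
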