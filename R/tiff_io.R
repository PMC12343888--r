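# TIFF reading is delegated to the tiff package; writing uses a minimal
# baseline TIFF encoder because the installed reader library's writer exposes
# neither an ImageDescription tag nor out-of-range float storage, both of
# which the ImageStack contract needs (axis metadata; bit-exact round trips).

#' Write an ImageStack to a multi-page TIFF
#'
#' Pages are stored in `T`-major, then `Z`, then `C` order (channel fastest),
#' one grayscale page per `(t, z, c)` plane, uncompressed.  Integer-valued
#' stacks within `[0, 65535]` are stored as 16-bit unsigned integers; anything
#' else as 32-bit IEEE floats (the widest float sample format the reader
#' library supports), so integer data round-trips bit-exactly and non-integer
#' data at single precision.  Axis metadata (axes string, shape, channel names,
#' timestamps, pixel size, dtype) is stored as JSON in the ImageDescription
#' tag of the first page.
#'
#' @param stack an `ImageStack`
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path) {
  validate_stack(stack)
  d <- dim(stack$data)
  Tn <- d[1]; Zn <- d[2]; Cn <- d[3]; H <- d[4]; W <- d[5]
  dat <- stack$data
  is_u16 <- all(dat == round(dat)) && max(dat) <= 65535 && min(dat) >= 0
  dtype <- if (is_u16) "uint16" else "float32"
  meta <- list(axes = "TZCYX", shape = d,
               channel_names = stack$channel_names,
               timestamps_min = stack$timestamps_min,
               pixel_size_um = stack$pixel_size_um,
               dtype = dtype)
  desc <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  planes <- vector("list", Tn * Zn * Cn)
  p <- 0L
  for (t in seq_len(Tn)) for (z in seq_len(Zn)) for (c in seq_len(Cn)) {
    p <- p + 1L
    planes[[p]] <- matrix(dat[t, z, c, , ], H, W)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  tryCatch(write_baseline_tiff(con, planes, dtype, as.character(desc)),
           error = function(e) stop("failed to write TIFF '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a TIFF file into an ImageStack
#'
#' Axis identification, in order of preference: (1) the JSON metadata written
#' by [write_stack()] in the ImageDescription tag; (2) OME-style XML metadata
#' (`SizeT`/`SizeZ`/`SizeC` and `DimensionOrder`); (3) an explicit `axes`
#' string (with `shape` when more than one non-spatial axis is present);
#' (4) a single-page file, promoted to `T = Z = C = 1`.  Missing axes are
#' inserted with length 1 and the order is normalized to `(T, Z, C, Y, X)`.
#'
#' @param path TIFF file path
#' @param axes optional axis string for plain TIFFs, e.g. `"ZYX"` for a
#'   z-stack stored as pages
#' @param shape optional integer vector giving the length of each non-spatial
#'   axis named in `axes` (required when `axes` names more than one)
#' @return an `ImageStack`
#' @export
read_stack <- function(path, axes = NULL, shape = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: '", path, "' does not exist")
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  desc <- attr(pages[[1]], "description")
  meta <- NULL
  if (!is.null(desc) && nzchar(desc)) {
    if (grepl("^\\s*\\{", desc)) {
      meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    } else if (grepl("<OME|<ome", desc)) {
      meta <- parse_ome_axes(desc)
    }
  }
  if (!is.null(meta) && !is.null(meta$shape)) {
    sh <- as.integer(meta$shape)
    dims <- c(T = sh[1], Z = sh[2], C = sh[3])
    order_fastest <- meta$order_fastest %||% c("C", "Z", "T")
  } else if (!is.null(axes)) {
    ax <- setdiff(strsplit(toupper(axes), "")[[1]], c("Y", "X"))
    dims <- c(T = 1L, Z = 1L, C = 1L)
    if (length(ax) == 1L) {
      dims[ax] <- np
    } else if (length(ax) > 1L) {
      if (is.null(shape) || length(shape) != length(ax))
        stop("axes names ", length(ax),
             " non-spatial dimensions: supply 'shape' with one length per axis")
      dims[ax] <- as.integer(shape)
    }
    order_fastest <- rev(ax)
    if (length(order_fastest) == 0L) order_fastest <- c("C", "Z", "T")
    order_fastest <- c(order_fastest, setdiff(c("C", "Z", "T"), order_fastest))
  } else if (np == 1L) {
    dims <- c(T = 1L, Z = 1L, C = 1L)
    order_fastest <- c("C", "Z", "T")
  } else {
    stop("ambiguous axes: '", path, "' has ", np,
         " pages and no axis metadata; supply an explicit axes string")
  }
  if (prod(dims) != np)
    stop("axis metadata implies ", prod(dims), " pages but file has ", np)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(0, c(dims[["T"]], dims[["Z"]], dims[["C"]], H, W))
  rad <- dims[order_fastest]  # mixed-radix page index, fastest first
  for (p in seq_len(np)) {
    k <- p - 1L
    idx <- c(T = 1L, Z = 1L, C = 1L)
    for (a in seq_along(rad)) {
      idx[names(rad)[a]] <- (k %% rad[a]) + 1L
      k <- k %/% rad[a]
    }
    arr[idx[["T"]], idx[["Z"]], idx[["C"]], , ] <- pages[[p]]
  }
  image_stack(arr,
              channel_names = if (!is.null(meta)) meta$channel_names else NULL,
              timestamps_min = if (!is.null(meta)) meta$timestamps_min else NULL,
              pixel_size_um = if (!is.null(meta) && !is.null(meta$pixel_size_um))
                meta$pixel_size_um else 0.65)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal OME-XML axis extraction: sizes and dimension order only.
#' @keywords internal
parse_ome_axes <- function(desc) {
  g <- function(attrname) {
    m <- regmatches(desc, regexpr(paste0(attrname, "=\"[0-9]+\""), desc))
    if (length(m) == 0) return(NA_integer_)
    as.integer(gsub("[^0-9]", "", m))
  }
  st <- g("SizeT"); sz <- g("SizeZ"); sc <- g("SizeC")
  if (anyNA(c(st, sz, sc))) return(NULL)
  dm <- regmatches(desc, regexpr("DimensionOrder=\"[A-Z]+\"", desc))
  ord <- if (length(dm)) gsub(".*\"([A-Z]+)\".*", "\\1", dm) else "XYCZT"
  list(shape = c(st, sz, sc),
       order_fastest = setdiff(strsplit(ord, "")[[1]], c("X", "Y")))
}

# --- baseline TIFF encoder (little-endian, one strip per grayscale page) ----

#' @keywords internal
write_baseline_tiff <- function(con, planes, dtype, description) {
  np <- length(planes)
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  bps <- if (dtype == "uint16") 16L else 32L
  sfmt <- if (dtype == "uint16") 1L else 3L
  page_bytes <- H * W * (bps %/% 8L)
  if (nchar(description) %% 2L == 0L)  # keep total length even without a second NUL
    description <- paste0(description, " ")
  desc_raw <- c(charToRaw(description), as.raw(0L))
  desc_len <- length(desc_raw)
  ntags <- c(11L, rep(10L, np - 1L))  # description tag on page 1 only
  ifd_size <- 2L + 12L * ntags + 4L
  desc_off <- 8L
  data_off <- desc_off + desc_len + (seq_len(np) - 1L) * page_bytes
  ifd_base <- desc_off + desc_len + np * page_bytes
  ifd_off <- ifd_base + cumsum(c(0L, ifd_size[-np]))

  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  tag <- function(code, type, count, value) {
    u16(code); u16(type); u32(count)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }
  # header
  writeBin(charToRaw("II"), con); u16(42L); u32(ifd_off[1])
  writeBin(desc_raw, con)
  # pixel data, row-major
  for (p in seq_len(np)) {
    v <- as.vector(t(planes[[p]]))
    if (dtype == "uint16") {
      iv <- as.integer(round(v))
      writeBin(as.raw(rbind(iv %% 256L, iv %/% 256L)), con)
    } else {
      writeBin(as.double(v), con, size = 4, endian = "little")
    }
  }
  # IFDs
  for (p in seq_len(np)) {
    u16(ntags[p])
    tag(256L, 4L, 1L, W)                      # ImageWidth
    tag(257L, 4L, 1L, H)                      # ImageLength
    tag(258L, 3L, 1L, bps)                    # BitsPerSample
    tag(259L, 3L, 1L, 1L)                     # Compression: none
    tag(262L, 3L, 1L, 1L)                     # Photometric: BlackIsZero
    if (p == 1L) tag(270L, 2L, desc_len, desc_off)  # ImageDescription
    tag(273L, 4L, 1L, data_off[p])            # StripOffsets
    tag(277L, 3L, 1L, 1L)                     # SamplesPerPixel
    tag(278L, 4L, 1L, H)                      # RowsPerStrip
    tag(279L, 4L, 1L, page_bytes)             # StripByteCounts
    tag(339L, 3L, 1L, sfmt)                   # SampleFormat
    u32(if (p < np) ifd_off[p + 1L] else 0L)  # next IFD
  }
  invisible(NULL)
}
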