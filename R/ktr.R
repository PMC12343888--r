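# Single-cell kinase-translocation-reporter quantification: nucleus
# segmentation on the H2B channel, ring-based cytoplasm sampling, the log2
# cytoplasm-to-nucleus ratio (CNR), greedy tracking, normalization to the
# last pre-stimulus frame, and population summaries.

#' Segment nuclei in a nuclear-marker image
#'
#' Global bimodal (Otsu-style) threshold, hole filling, then a
#' distance-transform watershed to split touching nuclei; components smaller
#' than `min_area_px` are discarded.
#'
#' @param img 2-D numeric matrix of the nuclear channel
#' @param min_area_px minimum nucleus area kept \[px\]
#' @param watershed_tolerance minimum height separation between
#'   distance-transform peaks that yields a split
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `centroids` (data frame `label`, `y`, `x`, `area_px`); a blank image
#'   yields zero labels
#' @export
segment_nuclei <- function(img, min_area_px = 50, watershed_tolerance = 1) {
  rng <- range(img)
  if (diff(rng) == 0)
    return(list(labels = matrix(0L, nrow(img), ncol(img)),
                centroids = data.frame(label = integer(), y = numeric(),
                                       x = numeric(), area_px = numeric())))
  thr <- otsu_split(as.vector(img))
  mask <- img > thr
  mask <- EBImage::fillHull(matrix(as.numeric(mask), nrow(img), ncol(img)))
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  relabel_and_centroids(lab, min_area_px)
}

#' @keywords internal
relabel_and_centroids <- function(lab, min_area_px) {
  n <- max(lab)
  if (n == 0L)
    return(list(labels = lab, centroids = data.frame(label = integer(),
                                                     y = numeric(),
                                                     x = numeric(),
                                                     area_px = numeric())))
  areas <- tabulate(lab[lab > 0], n)
  keep <- which(areas >= min_area_px)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  H <- nrow(lab)
  cents <- lapply(seq_along(keep), function(i) {
    p <- which(out == i)
    c(y = mean((p - 1) %% H + 1), x = mean((p - 1) %/% H + 1),
      area = length(p))
  })
  cm <- do.call(rbind, cents)
  list(labels = out,
       centroids = data.frame(label = seq_along(keep),
                              y = if (length(keep)) cm[, "y"] else numeric(),
                              x = if (length(keep)) cm[, "x"] else numeric(),
                              area_px = if (length(keep)) cm[, "area"] else numeric()))
}

#' Cytoplasmic sampling ring around one nucleus
#'
#' The ring is the set of pixels farther than `gap_px` but no farther than
#' `gap_px + width_px` (Euclidean distance) from the nucleus, minus every
#' pixel within `gap_px` of any other nucleus, so it never touches its own
#' or a neighbour's nucleus.
#'
#' @param nucleus_label label of the nucleus of interest
#' @param labels integer label matrix from [segment_nuclei()]
#' @param gap_px gap between nucleus boundary and ring (>= 0)
#' @param width_px ring width (>= 1)
#' @return logical matrix; an all-`FALSE` ring is allowed and flagged with
#'   attribute `empty = TRUE`
#' @export
cytoplasm_ring <- function(nucleus_label, labels, gap_px = 1, width_px = 4) {
  if (gap_px < 0 || width_px < 1) stop("gap_px >= 0 and width_px >= 1 required")
  H <- nrow(labels); W <- ncol(labels)
  p <- which(labels == nucleus_label)
  if (!length(p)) stop("no pixels carry label ", nucleus_label)
  ys <- (p - 1) %% H + 1; xs <- (p - 1) %/% H + 1
  r <- ceiling(gap_px + width_px) + 1L
  ys0 <- max(1, min(ys) - r); ys1 <- min(H, max(ys) + r)
  xs0 <- max(1, min(xs) - r); xs1 <- min(W, max(xs) + r)
  crop <- labels[ys0:ys1, xs0:xs1, drop = FALSE]
  own <- crop == nucleus_label
  d_own <- as.matrix(EBImage::distmap(matrix(as.numeric(!own), nrow(own))))
  ring_c <- d_own > gap_px & d_own <= gap_px + width_px
  other <- crop > 0 & !own
  if (any(other)) {
    d_oth <- as.matrix(EBImage::distmap(matrix(as.numeric(!other), nrow(own))))
    ring_c <- ring_c & d_oth > gap_px
  }
  ring <- matrix(FALSE, H, W)
  ring[ys0:ys1, xs0:xs1] <- ring_c
  if (!any(ring)) attr(ring, "empty") <- TRUE
  ring
}

#' Cytoplasm-to-nucleus ratio for one cell in one frame
#'
#' Medians of the reporter image over the nucleus and ring masks; the CNR is
#' cytoplasm/nucleus and is invariant to any positive rescaling of the
#' image.
#'
#' @param ktr_img reporter-channel matrix
#' @param nucleus_mask,ring_mask logical matrices (non-empty)
#' @return list `nuc_median`, `cyto_median`, `cnr`, `log2_cnr`
#' @export
compute_cnr <- function(ktr_img, nucleus_mask, ring_mask) {
  if (!any(nucleus_mask) || !any(ring_mask))
    stop("nucleus and ring masks must both be non-empty")
  nm <- median(ktr_img[nucleus_mask])
  cm <- median(ktr_img[ring_mask])
  if (nm <= 0) stop("zero nuclear median; CNR undefined")
  list(nuc_median = nm, cyto_median = cm, cnr = cm / nm,
       log2_cnr = log2(cm / nm))
}

#' Track nuclei across frames by greedy mutual-nearest matching
#'
#' Frame-to-frame matches are accepted in order of increasing centroid
#' distance while both partners are unmatched and the distance does not
#' exceed `max_displacement_px`.  Unmatched cells end their track; new cells
#' start new tracks; tracks are never rejoined.
#'
#' @param centroids_per_frame list (one element per frame) of data frames
#'   with columns `label`, `y`, `x`
#' @param max_displacement_px maximum accepted displacement \[px\]
#' @return data frame `track_id`, `frame`, `label`, `y`, `x`
#' @export
track_cells <- function(centroids_per_frame, max_displacement_px = 10) {
  nf <- length(centroids_per_frame)
  if (nf < 2) stop("tracking needs at least 2 frames")
  out <- list()
  c1 <- centroids_per_frame[[1]]
  track_of <- seq_len(nrow(c1))          # track id per label in current frame
  next_id <- nrow(c1) + 1L
  out[[1]] <- data.frame(track_id = track_of, frame = 1L,
                         label = c1$label, y = c1$y, x = c1$x)
  prev <- c1
  for (f in 2:nf) {
    cur <- centroids_per_frame[[f]]
    m <- matrix(NA_integer_, nrow(cur), 1)
    assigned_prev <- logical(nrow(prev))
    assigned_cur <- logical(nrow(cur))
    cur_track <- integer(nrow(cur))
    if (nrow(prev) && nrow(cur)) {
      D <- outer(prev$y, cur$y, "-")^2 + outer(prev$x, cur$x, "-")^2
      ord <- order(D)
      lim2 <- max_displacement_px^2
      for (k in ord) {
        if (D[k] > lim2) break
        i <- (k - 1) %% nrow(prev) + 1
        j <- (k - 1) %/% nrow(prev) + 1
        if (!assigned_prev[i] && !assigned_cur[j]) {
          assigned_prev[i] <- assigned_cur[j] <- TRUE
          cur_track[j] <- track_of[i]
        }
      }
    }
    for (j in which(!assigned_cur)) {
      cur_track[j] <- next_id
      next_id <- next_id + 1L
    }
    out[[f]] <- data.frame(track_id = cur_track, frame = f,
                           label = cur$label, y = cur$y, x = cur$x)
    prev <- cur
    track_of <- cur_track
  }
  do.call(rbind, out)
}

#' Per-cell log2 CNR table for a KTR time-lapse stack
#'
#' For each frame: segments nuclei on the nuclear-marker channel, builds a
#' cytoplasmic ring per nucleus, computes the log2 CNR per reporter channel,
#' and links cells across frames with [track_cells()].  Cells whose ring is
#' empty in a frame are dropped for that frame.
#'
#' @param stack a multi-channel `ImageStack`
#' @param h2b_channel 1-based nuclear-marker channel index
#' @param reporter_channels 1-based reporter channel indices (named or not)
#' @param config a `stiffquant_config` list
#' @return data frame with `cell_id`, `frame`, `t_min`, `channel`,
#'   `nuc_median`, `cyto_median`, `cnr`, `log2_cnr`
#' @export
ktr_cnr_table <- function(stack, h2b_channel = 1L,
                          reporter_channels = c(akt = 2L, erk = 3L),
                          config = default_config()) {
  validate_stack(stack)
  proj <- max_project(stack)
  nT <- dim(proj$data)[1]
  ch_names <- names(reporter_channels)
  if (is.null(ch_names))
    ch_names <- proj$channel_names[reporter_channels]
  cents <- vector("list", nT)
  rows <- list()
  for (f in seq_len(nT)) {
    h2b <- proj$data[f, 1, h2b_channel, , ]
    seg <- segment_nuclei(h2b, config$nucleus_min_area_px,
                          config$watershed_tolerance)
    cents[[f]] <- seg$centroids
    reporters <- lapply(reporter_channels,
                        function(ch) proj$data[f, 1, ch, , ])
    for (i in seq_len(nrow(seg$centroids))) {
      lab_i <- seg$centroids$label[i]
      nuc <- seg$labels == lab_i
      ring <- cytoplasm_ring(lab_i, seg$labels,
                             config$ring_gap_px, config$ring_width_px)
      if (isTRUE(attr(ring, "empty"))) next
      for (ci in seq_along(reporters)) {
        v <- compute_cnr(reporters[[ci]], nuc, ring)
        rows[[length(rows) + 1L]] <-
          data.frame(frame = f, t_min = proj$timestamps_min[f],
                     label = lab_i, channel = ch_names[ci],
                     nuc_median = v$nuc_median, cyto_median = v$cyto_median,
                     cnr = v$cnr, log2_cnr = v$log2_cnr)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tracks <- track_cells(cents, config$track_max_displacement_px)
  key <- paste(tracks$frame, tracks$label)
  tab$cell_id <- tracks$track_id[match(paste(tab$frame, tab$label), key)]
  tab[, c("cell_id", "frame", "t_min", "channel",
          "nuc_median", "cyto_median", "cnr", "log2_cnr")]
}

#' Normalize KTR traces to the last pre-stimulus frame
#'
#' Adds `delta_log2_cnr = log2_cnr - log2_cnr[baseline_frame]` per cell and
#' channel.  Cells not observed at the baseline frame, and trace segments
#' not contiguous with it, are excluded; the number of excluded cells is
#' reported in the `excluded` attribute.  Idempotent: normalizing an already
#' normalized table changes nothing.
#'
#' @param cnr_table data frame from [ktr_cnr_table()]
#' @param baseline_frame 1-based index of the last pre-stimulus frame
#' @return the table with a `delta_log2_cnr` column, baseline rows exactly 0
#' @export
normalize_traces <- function(cnr_table, baseline_frame = 6) {
  sp <- split(cnr_table, list(cnr_table$cell_id, cnr_table$channel),
              drop = TRUE)
  excluded <- 0L
  kept <- lapply(sp, function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (!(baseline_frame %in% tr$frame)) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    # keep only the contiguous run of frames containing the baseline
    runs <- cumsum(c(1, diff(tr$frame) != 1))
    tr <- tr[runs == runs[tr$frame == baseline_frame], , drop = FALSE]
    tr$delta_log2_cnr <- tr$log2_cnr - tr$log2_cnr[tr$frame == baseline_frame]
    tr
  })
  kept <- kept[!vapply(kept, is.null, logical(1))]
  if (!length(kept)) stop("no trace covers the baseline frame")
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Population summary of normalized KTR traces
#'
#' Frame-wise mean, SD, SEM and n of `delta_log2_cnr` over available cells,
#' per channel, plus a cells-by-frames response matrix ordered by each
#' cell's mean post-stimulus response (descending, the usual heatmap
#' convention).
#'
#' @param norm_table data frame from [normalize_traces()]
#' @param stim_frame 1-based last pre-stimulus frame; frames after it count
#'   as post-stimulus for the ordering
#' @return list with `per_frame` (data frame `channel`, `frame`, `t_min`,
#'   `mean`, `sd`, `sem`, `n`) and `matrix` (named list per channel of
#'   cells x frames matrices, rownames = cell ids)
#' @export
summarize_population <- function(norm_table, stim_frame = 6) {
  if (!nrow(norm_table)) stop("empty input")
  per_channel <- split(norm_table, norm_table$channel)
  per_frame <- list()
  mats <- list()
  for (ch in names(per_channel)) {
    d <- per_channel[[ch]]
    ag <- split(d$delta_log2_cnr, d$frame)
    fr <- as.integer(names(ag))
    tmin <- vapply(split(d$t_min, d$frame), function(x) x[1], numeric(1))
    stats <- t(vapply(ag, function(x)
      c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
        n = length(x)), numeric(3)))
    per_frame[[ch]] <- data.frame(channel = ch, frame = fr, t_min = tmin,
                                  mean = stats[, "mean"], sd = stats[, "sd"],
                                  sem = stats[, "sd"] / sqrt(stats[, "n"]),
                                  n = as.integer(stats[, "n"]))
    cells <- sort(unique(d$cell_id))
    frames <- sort(unique(d$frame))
    m <- matrix(NA_real_, length(cells), length(frames),
                dimnames = list(cells, frames))
    m[cbind(match(d$cell_id, cells), match(d$frame, frames))] <-
      d$delta_log2_cnr
    post <- frames > stim_frame
    ord <- order(-rowMeans(m[, post, drop = FALSE], na.rm = TRUE))
    mats[[ch]] <- m[ord, , drop = FALSE]
  }
  pf <- do.call(rbind, per_frame)
  rownames(pf) <- NULL
  list(per_frame = pf, matrix = mats)
}

#' Stratify cells into migratory and non-migratory bands
#'
#' Migratory cells lie within `band_px` (in x) of the wound edge;
#' non-migratory cells lie within `band_px` of the image edge farthest from
#' the wound; all others are `neither`.
#'
#' @param centroids data frame with columns `y`, `x`
#' @param wound_edge_x x position of the wound leading edge \[px\]
#' @param band_px band width \[px\]
#' @param field_width_px image width \[px\]
#' @return factor with levels `migratory`, `non_migratory`, `neither`
#' @export
stratify_migration <- function(centroids, wound_edge_x, band_px,
                               field_width_px) {
  far_edge <- if (wound_edge_x > field_width_px / 2) 0 else field_width_px
  if (abs(wound_edge_x - far_edge) <= 2 * band_px)
    stop("band_px so large that the migratory and non-migratory bands overlap")
  d_wound <- abs(centroids$x - wound_edge_x)
  d_far <- abs(centroids$x - far_edge)
  cls <- rep("neither", nrow(centroids))
  cls[d_far <= band_px] <- "non_migratory"
  cls[d_wound <= band_px] <- "migratory"
  factor(cls, levels = c("migratory", "non_migratory", "neither"))
}
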