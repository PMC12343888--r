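#' Default run configuration
#'
#' All tunables of the downstream pipeline stages, with their defaults.
#' Values live in one flat named list so a single YAML/JSON document can
#' drive an entire analysis.
#'
#' @details Tunables (units in brackets):
#' \describe{
#'   \item{denoise_median_px}{odd median-filter window applied to each raw
#'     frame before background estimation and thresholding \[px\]; 0
#'     disables; default 3 (removes isolated noise pixels while preserving
#'     ridges and puncta at least 2 px wide).}
#'   \item{threshold_block_px}{odd local-mean window for adaptive
#'     thresholding \[px\]; default 51.}
#'   \item{detection_min_z}{detection-significance threshold: an object's
#'     summed intensity above the local mean must exceed this many times
#'     \eqn{\sigma \sqrt{A}} (robust noise spread times root area); 0
#'     disables; default 5, the conventional 5-sigma detection rule.}
#'   \item{threshold_offset}{offset above the local mean, in units of the
#'     background-normalized image; default 1.}
#'   \item{punctum_area_min, punctum_area_max}{object area bounds for the
#'     punctum class \[px\]; defaults 4 and 200.}
#'   \item{punctum_min_circularity}{minimum circularity
#'     (\eqn{4\pi A/P^2}) for puncta; default 0.6.}
#'   \item{membrane_min_area}{minimum area for the membrane (junction-ridge
#'     network) class \[px\]; default 500.}
#'   \item{membrane_max_circularity}{maximum circularity for membrane
#'     objects; default 0.3.}
#'   \item{nucleus_min_area_px}{minimum nucleus area kept after watershed
#'     splitting \[px\]; default 50.}
#'   \item{watershed_tolerance}{minimum object-height separation for the
#'     distance-transform watershed; default 1.}
#'   \item{ring_gap_px, ring_width_px}{gap between the nucleus boundary and
#'     the cytoplasmic sampling ring, and the ring width \[px\];
#'     defaults 1 and 4.}
#'   \item{track_max_displacement_px}{maximum frame-to-frame centroid
#'     displacement accepted by tracking \[px\]; default 10.}
#'   \item{baseline_frame}{1-based index of the last pre-stimulus frame used
#'     to normalize KTR traces; default 6 (six images before stimulus).}
#'   \item{texture_window_px}{odd window for the local-variance wound-area
#'     texture filter \[px\]; default 9.}
#'   \item{texture_sd_threshold}{local intensity standard deviation below
#'     which a pixel counts as cell-free; default 20.}
#'   \item{flow_gate_quantile}{isotype-control quantile defining the positive
#'     gate; default 0.99 (a 1 percent positive control gate).}
#'   \item{pixel_size_um}{pixel edge length \[um\]; default 0.65.}
#'   \item{bit_depth}{camera bit depth used when scaling synthetic scenes;
#'     default 16.}
#'   \item{seed}{integer random seed; default 1.}
#' }
#'
#' @return a named list of class `stiffquant_config`
#' @export
default_config <- function() {
  structure(list(
    denoise_median_px = 3L,
    threshold_block_px = 51L,
    threshold_offset = 1.0,
    detection_min_z = 5,
    punctum_area_min = 4L,
    punctum_area_max = 200L,
    punctum_min_circularity = 0.6,
    membrane_min_area = 500L,
    membrane_max_circularity = 0.3,
    nucleus_min_area_px = 50L,
    watershed_tolerance = 1.0,
    ring_gap_px = 1L,
    ring_width_px = 4L,
    track_max_displacement_px = 10,
    baseline_frame = 6L,
    texture_window_px = 9L,
    texture_sd_threshold = 20,
    flow_gate_quantile = 0.99,
    pixel_size_um = 0.65,
    bit_depth = 16L,
    seed = 1L
  ), class = "stiffquant_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a YAML (or JSON, which YAML subsumes) document, fills absent keys
#' with the defaults from [default_config()], rejects unknown keys, and
#' validates value bounds.
#'
#' @param path file path of the configuration document, or `NULL` for pure
#'   defaults
#' @return a validated `stiffquant_config` list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc)) doc <- list()
    if (!is.list(doc)) stop("configuration document must be a mapping")
    unknown <- setdiff(names(doc), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, doc)
    class(cfg) <- "stiffquant_config"
  }
  validate_config(cfg)
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(cfg$denoise_median_px == 0 ||
        (cfg$denoise_median_px >= 3 && cfg$denoise_median_px %% 2 == 1),
      "denoise_median_px must be 0 (off) or an odd integer >= 3")
  chk(cfg$threshold_block_px >= 3 && cfg$threshold_block_px %% 2 == 1,
      "threshold_block_px must be an odd integer >= 3")
  chk(cfg$detection_min_z >= 0, "detection_min_z must be >= 0")
  chk(cfg$punctum_area_min >= 1 && cfg$punctum_area_max > cfg$punctum_area_min,
      "punctum area range must satisfy 1 <= min < max")
  chk(cfg$punctum_min_circularity > 0 && cfg$punctum_min_circularity <= 1.5,
      "punctum_min_circularity must lie in (0, 1.5]")
  chk(cfg$membrane_min_area > cfg$punctum_area_max,
      "membrane_min_area must exceed punctum_area_max so the classes cannot overlap")
  chk(cfg$membrane_max_circularity > 0 &&
        cfg$membrane_max_circularity < cfg$punctum_min_circularity,
      "membrane_max_circularity must be below punctum_min_circularity")
  chk(cfg$nucleus_min_area_px >= 1, "nucleus_min_area_px must be >= 1")
  chk(cfg$ring_gap_px >= 0, "ring_gap_px must be >= 0")
  chk(cfg$ring_width_px >= 1, "ring_width_px must be >= 1")
  chk(cfg$track_max_displacement_px > 0, "track_max_displacement_px must be > 0")
  chk(cfg$baseline_frame >= 1, "baseline_frame must be >= 1")
  chk(cfg$texture_window_px >= 3 && cfg$texture_window_px %% 2 == 1,
      "texture_window_px must be an odd integer >= 3")
  chk(cfg$texture_sd_threshold > 0, "texture_sd_threshold must be > 0")
  chk(cfg$flow_gate_quantile > 0 && cfg$flow_gate_quantile < 1,
      "flow_gate_quantile must lie in (0, 1)")
  chk(cfg$pixel_size_um > 0, "pixel_size_um must be > 0")
  chk(cfg$bit_depth %in% c(8L, 12L, 16L), "bit_depth must be 8, 12 or 16")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a scalar")
  invisible(TRUE)
}
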