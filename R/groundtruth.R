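# Ground-truth records travel in memory as plain lists; on disk they are
# JSON.  Logical masks and integer label images are run-length encoded so the
# JSON stays small and exact.

#' Write a ground-truth record to JSON
#'
#' Matrices (masks, label images, per-frame arrays) are stored run-length
#' encoded with their dimensions, everything else verbatim, so
#' [read_ground_truth()] reconstructs the record exactly.
#'
#' @param gt a ground-truth list from one of the `simulate_*`/`make_*`
#'   generators
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(gt, path) {
  enc <- encode_matrices(gt)
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth record from JSON
#'
#' @param path JSON path written by [write_ground_truth()]
#' @return the reconstructed ground-truth list
#' @export
read_ground_truth <- function(path) {
  decode_matrices(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' @keywords internal
encode_matrices <- function(x) {
  if (is.matrix(x) || (is.array(x) && length(dim(x)) > 1)) {
    v <- as.vector(x)
    r <- rle(v)
    list(`_rle` = TRUE, dim = dim(x),
         storage = storage.mode(x),
         lengths = r$lengths, values = r$values)
  } else if (is.data.frame(x)) {
    list(`_df` = TRUE, columns = lapply(as.list(x), identity))
  } else if (is.list(x)) {
    lapply(x, encode_matrices)
  } else x
}

#' @keywords internal
decode_matrices <- function(x) {
  if (is.list(x) && isTRUE(x$`_rle`)) {
    v <- inverse.rle(structure(list(lengths = x$lengths, values = x$values),
                               class = "rle"))
    storage.mode(v) <- x$storage
    array(v, unlist(x$dim))
  } else if (is.list(x) && isTRUE(x$`_df`)) {
    as.data.frame(x$columns, stringsAsFactors = FALSE)
  } else if (is.list(x)) {
    lapply(x, decode_matrices)
  } else x
}
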