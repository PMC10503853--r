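PATCH_LEN <- 5L  # the fixed pixel-sequence / tile side length

# Normalize 16-bit counts to [0, 1] for network input.
normalize_counts <- function(x) x / 65535

#' Extract 1x5 pixel sequences from an image
#'
#' Slides a horizontal window of 5 pixels along every row at the given stride
#' and collects the per-channel intensities (normalized to `[0, 1]` by
#' dividing by 65,535) as network input sequences. When a ground-truth field
#' is supplied, the matching 5 temperatures are attached as targets.
#' No padding is used: windows lie fully inside the image.
#'
#' @param image A [fluorescent_image()].
#' @param field Optional [temperature_field()] of matching shape (targets).
#' @param stride Window stride in pixels (>= 1; 1 = dense extraction).
#' @param center_targets Subtract `target_center` from targets (off by
#'   default; stored so predictions can be un-centered).
#' @param target_center Centre value used when `center_targets = TRUE`
#'   (default the midpoint of the field's declared `t_range`, else its mean).
#' @return A `sequence_batch`: list with `inputs` (array `N x 5 x C`),
#'   `targets` (`N x 5` matrix or `NULL`), `origins` (tibble `row`,
#'   `start_col`), `image_shape`, `target_center`.
#' @examples
#' img <- fluorescent_image(array(0, c(6, 8, 2)))
#' b <- extract_sequences(img)
#' dim(b$inputs)
#' @export
extract_sequences <- function(image, field = NULL, stride = 1L,
                              center_targets = FALSE, target_center = NULL) {
  stopifnot(inherits(image, "fluorescent_image"))
  d <- dim(image$channels)
  if (d[2] < PATCH_LEN) abort("image width must be at least 5 pixels")
  stride <- as.integer(stride)
  if (stride < 1L) abort("stride must be >= 1")
  starts <- seq.int(1L, d[2] - PATCH_LEN + 1L, by = stride)
  rows <- seq_len(d[1])
  origins <- tibble(
    row = rep(rows, each = length(starts)),
    start_col = rep(starts, times = length(rows))
  )
  n <- nrow(origins)
  inputs <- array(0, c(n, PATCH_LEN, d[3]))
  for (k in seq_len(PATCH_LEN)) {
    cols <- origins$start_col + k - 1L
    # gather pixel (row, col) for all channels at once
    inputs[, k, ] <- matrix(
      image$channels[cbind(rep(origins$row, d[3]),
                           rep(cols, d[3]),
                           rep(seq_len(d[3]), each = n))],
      n, d[3]
    )
  }
  inputs <- normalize_counts(inputs)
  targets <- NULL
  tc <- 0
  if (!is.null(field)) {
    stopifnot(inherits(field, "temperature_field"))
    if (!identical(dim(field$values), d[1:2])) abort("field shape must match image")
    targets <- matrix(0, n, PATCH_LEN)
    for (k in seq_len(PATCH_LEN)) {
      targets[, k] <- field$values[cbind(origins$row, origins$start_col + k - 1L)]
    }
    if (center_targets) {
      tc <- target_center %||%
        (if (!is.null(field$meta$t_range)) mean(field$meta$t_range) else mean(field$values))
      targets <- targets - tc
    }
  }
  structure(
    list(inputs = inputs, targets = targets, origins = origins,
         image_shape = d[1:2], target_center = tc),
    class = "sequence_batch"
  )
}

#' Extract 5x5 tiles from an image
#'
#' Slides a 5x5 window over the image at the given stride; inputs are
#' normalized to `[0, 1]`; targets (when a field is given) are the matching
#' 5x5 temperature tiles.
#'
#' @inheritParams extract_sequences
#' @return A `tile_batch`: list with `inputs` (`N x 5 x 5 x C`), `targets`
#'   (`N x 5 x 5` or `NULL`), `origins` (tibble `top_row`, `left_col`),
#'   `image_shape`, `target_center`.
#' @export
extract_tiles <- function(image, field = NULL, stride = 1L,
                          center_targets = FALSE, target_center = NULL) {
  stopifnot(inherits(image, "fluorescent_image"))
  d <- dim(image$channels)
  if (d[1] < PATCH_LEN || d[2] < PATCH_LEN) abort("image must be at least 5x5 pixels")
  stride <- as.integer(stride)
  if (stride < 1L) abort("stride must be >= 1")
  row_starts <- seq.int(1L, d[1] - PATCH_LEN + 1L, by = stride)
  col_starts <- seq.int(1L, d[2] - PATCH_LEN + 1L, by = stride)
  origins <- tibble(
    top_row = rep(row_starts, each = length(col_starts)),
    left_col = rep(col_starts, times = length(row_starts))
  )
  n <- nrow(origins)
  inputs <- array(0, c(n, PATCH_LEN, PATCH_LEN, d[3]))
  for (i in seq_len(PATCH_LEN)) for (j in seq_len(PATCH_LEN)) {
    r <- origins$top_row + i - 1L
    cc <- origins$left_col + j - 1L
    inputs[, i, j, ] <- matrix(
      image$channels[cbind(rep(r, d[3]), rep(cc, d[3]), rep(seq_len(d[3]), each = n))],
      n, d[3]
    )
  }
  inputs <- normalize_counts(inputs)
  targets <- NULL
  tc <- 0
  if (!is.null(field)) {
    stopifnot(inherits(field, "temperature_field"))
    if (!identical(dim(field$values), d[1:2])) abort("field shape must match image")
    targets <- array(0, c(n, PATCH_LEN, PATCH_LEN))
    for (i in seq_len(PATCH_LEN)) for (j in seq_len(PATCH_LEN)) {
      targets[, i, j] <- field$values[cbind(origins$top_row + i - 1L,
                                            origins$left_col + j - 1L)]
    }
    if (center_targets) {
      tc <- target_center %||%
        (if (!is.null(field$meta$t_range)) mean(field$meta$t_range) else mean(field$values))
      targets <- targets - tc
    }
  }
  structure(
    list(inputs = inputs, targets = targets, origins = origins,
         image_shape = d[1:2], target_center = tc),
    class = "tile_batch"
  )
}

#' Decompose a 5x5 tile into its row and column sequences
#'
#' Row `i` is `tile[i, , ]`, column `j` is `tile[, j, ]`; element `k` of row
#' `i` and element `i` of column `k` both reference source pixel `(i, k)`, so
#' reassembling the rows reproduces the tile exactly. This is the
#' decomposition fed to the per-direction scans of the multi-directional
#' network.
#'
#' @param tile A `5 x 5 x C` numeric array.
#' @return A list with `rows` and `cols`, each a `5 x 5 x C` array whose first
#'   index enumerates the sequences and second index the position along the
#'   sequence.
#' @export
tile_rows_cols <- function(tile) {
  d <- dim(tile)
  if (length(d) != 3L || d[1] != PATCH_LEN || d[2] != PATCH_LEN) {
    abort("tile must be a 5 x 5 x C array")
  }
  list(rows = tile, cols = aperm(tile, c(2, 1, 3)))
}

#' Stitch per-patch predictions into a full temperature field
#'
#' Places every patch prediction at its source location and averages where
#' patches overlap (the per-pixel mean of all covering predictions). The
#' coverage-count map is retained in the result's meta. Errors if any pixel
#' is left uncovered.
#'
#' @param predictions For sequences, an `N x 5` matrix; for tiles, an
#'   `N x 5 x 5` array.
#' @param origins The `origins` tibble from the matching extract call.
#' @param image_shape `c(rows, cols)` of the source image.
#' @param pitch_um Pixel pitch forwarded to the output field.
#' @param fill `NULL` (default): uncovered pixels are an error. A number, or
#'   `"mean"`: uncovered pixels take that placeholder value instead —
#'   partial stitching for mask-restricted reconstruction, where patches
#'   exist only inside a region of interest. Consult `meta$coverage` to see
#'   which pixels are real predictions.
#' @return A [temperature_field()]; `meta$coverage` holds the count map.
#' @export
stitch <- function(predictions, origins, image_shape, pitch_um = 1,
                   fill = NULL) {
  nr <- image_shape[1]; nc <- image_shape[2]
  acc <- matrix(0, nr, nc)
  cov <- matrix(0L, nr, nc)
  if (is.matrix(predictions)) {
    if (!all(c("row", "start_col") %in% names(origins))) {
      abort("sequence predictions need origins with `row`, `start_col`")
    }
    for (k in seq_len(PATCH_LEN)) {
      ix <- cbind(origins$row, origins$start_col + k - 1L)
      # accumulate with possible duplicate indices: aggregate first
      agg <- rowsum(predictions[, k], group = (ix[, 2] - 1L) * nr + ix[, 1])
      lin <- as.integer(rownames(agg))
      acc[lin] <- acc[lin] + agg[, 1]
      cnt <- rowsum(rep(1L, nrow(ix)), group = (ix[, 2] - 1L) * nr + ix[, 1])
      cov[lin] <- cov[lin] + cnt[, 1]
    }
  } else if (length(dim(predictions)) == 3L) {
    if (!all(c("top_row", "left_col") %in% names(origins))) {
      abort("tile predictions need origins with `top_row`, `left_col`")
    }
    for (i in seq_len(PATCH_LEN)) for (j in seq_len(PATCH_LEN)) {
      ix <- cbind(origins$top_row + i - 1L, origins$left_col + j - 1L)
      lin_all <- (ix[, 2] - 1L) * nr + ix[, 1]
      agg <- rowsum(predictions[, i, j], group = lin_all)
      lin <- as.integer(rownames(agg))
      acc[lin] <- acc[lin] + agg[, 1]
      cnt <- rowsum(rep(1L, nrow(ix)), group = lin_all)
      cov[lin] <- cov[lin] + cnt[, 1]
    }
  } else {
    abort("predictions must be N x 5 (sequences) or N x 5 x 5 (tiles)")
  }
  if (any(cov == 0L)) {
    if (is.null(fill)) {
      miss <- which(cov == 0L, arr.ind = TRUE)
      abort(sprintf("%d pixel(s) uncovered by any patch, e.g. (%d, %d)",
                    nrow(miss), miss[1, 1], miss[1, 2]))
    }
    covered <- cov > 0L
    out <- matrix(if (identical(fill, "mean")) mean(acc[covered] / cov[covered])
                  else as.numeric(fill), nr, nc)
    out[covered] <- acc[covered] / cov[covered]
    return(temperature_field(out, pitch_um = pitch_um,
                             meta = list(generator = "stitch", coverage = cov,
                                         partial = TRUE)))
  }
  temperature_field(acc / cov, pitch_um = pitch_um,
                    meta = list(generator = "stitch", coverage = cov))
}
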