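#' Write / read a temperature field as TIFF + JSON sidecar
#'
#' The field is stored as a single-channel 32-bit float TIFF (values affinely
#' mapped to `[0, 1]` over the stored `t_min`/`t_max`) plus a JSON sidecar
#' (`<path>.json`) carrying the scaling, pixel pitch and provenance record,
#' so `read_field(write_field(f))` reproduces `f` to 32-bit float precision.
#'
#' @param field A [temperature_field()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"))
  t_min <- min(field$values); t_max <- max(field$values)
  scale <- if (t_max > t_min) t_max - t_min else 1
  v01 <- (field$values - t_min) / scale
  tiff::writeTIFF(v01, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(
    kind = "temperature_field", t_min = t_min, t_max = t_max,
    pitch_um = field$pitch_um, meta = field$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_field
#' @return For `read_field()`: the restored [temperature_field()].
#' @export
read_field <- function(path) {
  v01 <- tiff::readTIFF(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- v01 * (sc$t_max - sc$t_min) + sc$t_min
  temperature_field(vals, pitch_um = sc$pitch_um, meta = as.list(sc$meta))
}

#' Write / read a multi-channel image as multi-page TIFF + JSON sidecar
#'
#' One 16-bit grayscale page per channel; the sidecar carries channel names
#' and the provenance record. Counts survive the round trip exactly when the
#' image is integer-quantized.
#'
#' @param image A [fluorescent_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "fluorescent_image"))
  pages <- lapply(seq_len(dim(image$channels)[3]), function(j) {
    image$channels[, , j] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    kind = "fluorescent_image", channel_names = image$channel_names,
    bit_depth = 16L, meta = image$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_image
#' @return For `read_image()`: the restored [fluorescent_image()].
#' @export
read_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ch <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (j in seq_along(pages)) {
    pg <- pages[[j]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    ch[, , j] <- round(pg * 65535)
  }
  fluorescent_image(ch, channel_names = sc$channel_names, meta = as.list(sc$meta))
}

#' Write / read a calibration model as JSON
#'
#' @param cal A `calibration_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_model"))
  obj <- list(
    kind = "calibration_model",
    coefficients = as.data.frame(cal$coefficients),
    t_range = cal$t_range, scale = cal$scale,
    channel_names = cal$channel_names
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @return For `read_calibration()`: the restored `calibration_model`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coefficients = as_tibble(obj$coefficients),
         t_range = as.numeric(obj$t_range),
         scale = list(i_min = as.numeric(obj$scale$i_min),
                      i_max = as.numeric(obj$scale$i_max),
                      anchors = obj$scale$anchors %||% "global"),
         channel_names = obj$channel_names),
    class = "calibration_model"
  )
}

#' Save / load a trained model checkpoint
#'
#' A portable single-file JSON archive: config, normalization constants,
#' training lineage and every parameter tensor (flattened with dimensions
#' recorded). Text-based so checkpoints survive version control and code
#' review; fine at desk scale.
#'
#' @param model An `ft_model`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ft_model"))
  pack <- function(p) {
    if (is.numeric(p)) return(list(.dim = dim(p) %||% length(p), .val = as.numeric(p)))
    lapply(p, pack)
  }
  obj <- list(
    kind = "ft_model_checkpoint", version = 1L,
    variant = model$variant,
    config = unclass(model$config),
    norm = model$norm,
    lineage = model$lineage,
    params = pack(model$params)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return For `load_checkpoint()`: the restored `ft_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "ft_model_checkpoint")) abort("not a model checkpoint")
  unpack <- function(p) {
    if (!is.null(p$.val)) {
      v <- as.numeric(p$.val)
      if (length(p$.dim) == 2L) v <- matrix(v, p$.dim[1], p$.dim[2])
      return(v)
    }
    lapply(p, unpack)
  }
  cfg <- obj$config
  config <- net_config(cfg$variant, channels_in = cfg$channels_in,
                       hidden1 = cfg$hidden1, hidden2 = cfg$hidden2,
                       dropout = cfg$dropout, tie_directions = cfg$tie_directions,
                       tie_orientations = cfg$tie_orientations,
                       flat_head = cfg$flat_head, seed = cfg$seed)
  structure(
    list(variant = obj$variant, config = config, params = unpack(obj$params),
         norm = as.list(obj$norm), lineage = as.list(obj$lineage)),
    class = "ft_model"
  )
}

#' Write a chip scene to disk
#'
#' Field as TIFF + sidecar, mask as a portable text PGM (0/1), and a JSON
#' record of the probe.
#'
#' @param scene A [chip_scene()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the files.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  stopifnot(inherits(scene, "chip_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_field(scene$field, file.path(dir, paste0(name, "_field.tiff")))
  m <- scene$mask * 1L
  con <- file(file.path(dir, paste0(name, "_mask.pgm")), "w")
  writeLines(c("P2", paste(ncol(m), nrow(m)), "1",
               apply(m, 1, paste, collapse = " ")), con)
  close(con)
  jsonlite::write_json(
    list(probe_xy = scene$probe_xy, probe_t = scene$probe_t),
    file.path(dir, paste0(name, "_probe.json")), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
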