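#' Construct a fluorescence frame stack
#'
#' The raw object every stage consumes: an ordered set of 2-D fluorescence
#' frames with their acquisition times and the pixel size needed to convert
#' displacements to physical units. Frames are stored as a rows x cols x
#' n_frames array (row-major image convention: origin top-left, row =
#' image y), times in seconds from the first frame.
#'
#' @param frames Numeric array `rows x cols x n_frames` (A.U.), or a list of
#'   equally sized matrices.
#' @param times Numeric vector of frame times (s), strictly increasing, one
#'   per frame.
#' @param pixel_size_mm Pixel size in mm/pixel (> 0).
#' @param meta Named list of acquisition metadata (subject, group, limb,
#'   side, condition, ...). Free-form; carried through the pipeline.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(frames, times, pixel_size_mm, meta = list()) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must share dimensions", call. = FALSE)
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L) stop("`frames` must be a 3-D array", call. = FALSE)
  times <- as.numeric(times)
  if (dim(frames)[3] != length(times)) {
    stop("frame count does not match the number of frame times", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("`pixel_size_mm` must be a single positive number", call. = FALSE)
  }
  structure(list(frames = frames, times = times,
                 pixel_size_mm = pixel_size_mm, meta = meta),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d x %d px, %d frames, t = [%g, %g] s, %g mm/px\n",
              d[1], d[2], d[3], x$times[1], x$times[d[3]], x$pixel_size_mm))
  invisible(x)
}

#' Write a frame stack as multi-page TIFF plus YAML sidecar
#'
#' Intensities are stored normalized by a scale factor recorded in the
#' sidecar (`intensity_scale`), since TIFF samples live on a [0, 1] grid.
#' 32-bit storage quantizes at ~2e-10 of the scale — negligible against
#' fluorescence noise but not strictly bit-identical; 16-bit storage is
#' offered for compactness at ~1.5e-5 of the scale.
#'
#' @param stack A [frame_stack()].
#' @param tiff_path Output TIFF path.
#' @param sidecar_path Output YAML path (default: `tiff_path` with `.yaml`).
#' @param bits 32 (default) or 16 bits per sample.
#' @return Invisibly, the two paths.
#' @export
write_stack <- function(stack, tiff_path,
                        sidecar_path = paste0(tiff_path, ".yaml"),
                        bits = 32L) {
  stopifnot(inherits(stack, "frame_stack"), bits %in% c(16L, 32L))
  lo <- min(stack$frames)
  if (lo < 0) stop("negative intensities cannot be stored", call. = FALSE)
  scale <- max(stack$frames)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_along(stack$times),
                  function(i) stack$frames[, , i] / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = bits,
                  compression = "deflate")
  sidecar <- list(frame_times_s = as.numeric(stack$times),
                  pixel_size_mm = stack$pixel_size_mm,
                  intensity_scale = scale,
                  meta = stack$meta)
  yaml::write_yaml(sidecar, sidecar_path)
  invisible(c(tiff = tiff_path, sidecar = sidecar_path))
}

#' Read a frame stack written by [write_stack()]
#'
#' @param tiff_path Multi-page TIFF of frames.
#' @param sidecar_path YAML sidecar with `frame_times_s`, `pixel_size_mm`
#'   and `intensity_scale`.
#' @return A [frame_stack()].
#' @export
read_stack <- function(tiff_path, sidecar_path = paste0(tiff_path, ".yaml")) {
  sc <- yaml::read_yaml(sidecar_path)
  if (is.null(sc$pixel_size_mm)) {
    stop("sidecar is missing `pixel_size_mm`", call. = FALSE)
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  times <- as.numeric(sc$frame_times_s)
  if (length(pages) != length(times)) {
    stop(sprintf("TIFF has %d pages but sidecar lists %d frame times",
                 length(pages), length(times)), call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("sidecar frame times are not strictly increasing", call. = FALSE)
  }
  scale <- if (is.null(sc$intensity_scale)) 1 else sc$intensity_scale
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(dim(pages[[1]]), length(pages))) * scale
  frame_stack(frames, times, sc$pixel_size_mm,
              meta = if (is.null(sc$meta)) list() else sc$meta)
}

#' Write a parameter map as multi-page 32-bit TIFF
#'
#' One page per parameter plus a final validity page; invalid pixels are
#' stored as 0 on the value pages and restored to `NaN` on reading. Page
#' order and per-page scales go in the YAML sidecar.
#'
#' @param map A `parameter_map` from [map_stack()].
#' @param tiff_path Output TIFF path.
#' @param sidecar_path Output YAML path.
#' @return Invisibly, the two paths.
#' @export
write_parameter_map <- function(map, tiff_path,
                                sidecar_path = paste0(tiff_path, ".yaml")) {
  stopifnot(inherits(map, "parameter_map"))
  pages <- list()
  scales <- numeric(0)
  for (p in map_param_names) {
    m <- map[[p]]
    m[!map$valid] <- 0
    s <- max(abs(m), 1e-300)
    pages[[p]] <- m / s
    scales[p] <- s
  }
  pages$valid <- map$valid + 0
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L,
                  compression = "deflate")
  yaml::write_yaml(list(pages = c(map_param_names, "valid"),
                        scales = as.list(scales)), sidecar_path)
  invisible(c(tiff = tiff_path, sidecar = sidecar_path))
}

#' Read a parameter map written by [write_parameter_map()]
#' @param tiff_path,sidecar_path Paths written by [write_parameter_map()].
#' @return A `parameter_map`-like list (value matrices with `NaN` at invalid
#'   pixels, plus the `valid` matrix).
#' @export
read_parameter_map <- function(tiff_path, sidecar_path = paste0(tiff_path, ".yaml")) {
  sc <- yaml::read_yaml(sidecar_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  names(pages) <- unlist(sc$pages)
  valid <- pages$valid > 0.5
  out <- list()
  for (p in setdiff(names(pages), "valid")) {
    m <- pages[[p]] * sc$scales[[p]]
    m[!valid] <- NaN
    out[[p]] <- m
  }
  out$valid <- valid
  structure(out, class = "parameter_map")
}
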