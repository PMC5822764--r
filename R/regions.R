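#' Construct a digit/dorsum region set
#'
#' The limb image is divided into two compartments: the digits (toes or
#' fingers), taken as the peripheral arterial input, and the dorsum, taken
#' as the microvascular (capillary) circulation.
#'
#' @param labels Integer matrix with codes 0 (background), 1 (digits),
#'   2 (dorsum).
#' @param limb `"hand"` or `"foot"`.
#' @param side `"left"` or `"right"`.
#' @return Object of class `region_set` with logical `digit_mask`,
#'   `dorsum_mask`, the original `labels`, `limb`, `side`, and a `flags`
#'   character vector (empty-region warnings).
#' @export
region_set <- function(labels, limb = c("foot", "hand"),
                       side = c("left", "right")) {
  limb <- match.arg(limb)
  side <- match.arg(side)
  labels <- round(labels)
  storage.mode(labels) <- "integer"
  codes <- sort(unique(as.vector(labels)))
  if (!all(codes %in% c(0, 1, 2))) {
    stop("unknown region labels: expected codes {0, 1, 2}, found ",
         paste(setdiff(codes, 0:2), collapse = ", "), call. = FALSE)
  }
  digit_mask <- labels == 1
  dorsum_mask <- labels == 2
  if (!any(digit_mask) && !any(dorsum_mask)) {
    stop("no regions: label image contains only background", call. = FALSE)
  }
  flags <- character(0)
  for (r in c("digit", "dorsum")) {
    if (!any(labels == match(r, c("digit", "dorsum")))) {
      warning(sprintf("region '%s' is empty", r), call. = FALSE)
      flags <- c(flags, sprintf("empty-%s", r))
    }
  }
  structure(list(digit_mask = digit_mask, dorsum_mask = dorsum_mask,
                 labels = labels, limb = limb, side = side, flags = flags),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s %s: %d digit px, %d dorsum px%s\n",
              x$side, x$limb, sum(x$digit_mask), sum(x$dorsum_mask),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Load a region set from a label image
#'
#' @param path 8-bit TIFF or PNG label image with codes \{0 background,
#'   1 digits, 2 dorsum\} (stored as value/255).
#' @param limb,side Passed to [region_set()].
#' @return A [region_set()].
#' @export
load_region_set <- function(path, limb = c("foot", "hand"),
                            side = c("left", "right")) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported label image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  region_set(round(img * 255), limb = limb, side = side)
}

#' Write a region label image
#'
#' @param rset A [region_set()] (or a raw label matrix).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_region_labels <- function(rset, path) {
  labels <- if (inherits(rset, "region_set")) rset$labels else rset
  img <- labels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
         stop("unsupported label image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Region-level kinetic parameters from a frame stack
#'
#' The region time-intensity vector is the per-frame spatial mean over the
#' region's pixels (one vector per region per limb); kinetic parameters are
#' extracted from that mean curve. A per-pixel dispersion summary (mean and
#' SD of each parameter over the region's individually valid pixels) is
#' attached so map-level heterogeneity is not lost.
#'
#' @param stack A [frame_stack()].
#' @param mask Logical or 0/1 matrix selecting the region's pixels.
#' @param config A [kinetics_config()].
#' @param pixel_dispersion If `TRUE` (default), also extract per-pixel
#'   parameters for the dispersion summary (slower).
#' @param min_valid_pixels Regions with fewer individually valid pixels are
#'   flagged `low-confidence` (default 10).
#' @return List of class `region_params`: `params` (a `kinetic_params` for
#'   the mean curve), `n_pixels`, `dispersion` (data frame of per-pixel
#'   mean/sd per parameter, or NULL), `n_valid_pixels`, `flags`.
#' @export
region_params <- function(stack, mask, config = kinetics_config(),
                          pixel_dispersion = TRUE, min_valid_pixels = 10L) {
  stopifnot(inherits(stack, "frame_stack"))
  dm <- dim(stack$frames)[1:2]
  mask <- mask_as_logical(mask, dm)
  n_px <- sum(mask)
  if (n_px == 0L) stop("region mask is empty", call. = FALSE)

  mean_curve <- region_mean_curve(stack, mask)
  params <- extract_params(intensity_curve(stack$times, mean_curve), config)

  dispersion <- NULL
  n_valid <- NA_integer_
  flags <- character(0)
  if (pixel_dispersion) {
    pm <- map_stack(stack, mask, config)
    n_valid <- sum(pm$valid)
    vals <- lapply(map_param_names, function(p) pm[[p]][pm$valid])
    dispersion <- data.frame(
      parameter = map_param_names,
      mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, 0),
      sd = vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, 0),
      stringsAsFactors = FALSE)
    if (n_valid < min_valid_pixels) flags <- c(flags, "low-confidence")
  }
  structure(list(params = params, n_pixels = n_px, dispersion = dispersion,
                 n_valid_pixels = n_valid, flags = flags),
            class = "region_params")
}

# Per-frame spatial mean over masked pixels: the region's "single vector".
region_mean_curve <- function(stack, mask) {
  dm <- dim(stack$frames)
  Y <- matrix(stack$frames, nrow = dm[1] * dm[2], ncol = dm[3])
  colMeans(Y[as.vector(mask), , drop = FALSE])
}
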