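# Purple-stain intensity extraction along digit polylines.
#
# Images are plain numeric arrays [rows, cols, 3] with channel values in
# [0, 1].  Stain amount per pixel is quantified as Beer-Lambert optical
# density, -log10 of per-channel transmittance relative to the background
# tissue color, projected onto a unit "purple absorbance" vector.  The
# projection direction is a configuration parameter: the original
# measurement protocol does not specify its color-to-intensity mapping, so
# the OD projection is this package's documented operationalization of
# "intensity of purple color".

#' Stain color model
#'
#' @param stain_rgb Per-channel absorbance direction of the stain;
#'   normalized to unit length internally. The default absorbs most in green,
#'   then red, least in blue -- i.e. a purple-looking deposit.
#' @param background_rgb Background (unstained tissue) color in `[0, 1]`;
#'   all channels must be positive.
#' @param epsilon Small constant stabilizing the log at near-zero pixels.
#' @return A `stain_model` object.
#' @export
stain_model <- function(stain_rgb = c(0.59, 0.74, 0.33),
                        background_rgb = c(0.96, 0.93, 0.88),
                        epsilon = 1e-3) {
  if (length(stain_rgb) != 3 || any(stain_rgb < 0) || sum(stain_rgb) <= 0) {
    stop("stain_rgb must be a non-negative, non-zero 3-vector", call. = FALSE)
  }
  if (length(background_rgb) != 3 || any(background_rgb <= 0)) {
    stop("background_rgb channels must be > 0", call. = FALSE)
  }
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  structure(list(stain_rgb_unit = stain_rgb / sqrt(sum(stain_rgb^2)),
                 background_rgb = background_rgb, epsilon = epsilon),
            class = "stain_model")
}

#' Intensity profile container
#'
#' Ordered stain-intensity samples (OD units, all finite and >= 0) along a
#' digit, distal end first, with specimen metadata.
#'
#' @param samples Numeric vector of OD values, distal to proximal.
#' @param meta List with (at least) `specimen`, `stage`, `limb`, `digit`.
#' @return An `intensity_profile` object with fields `samples`, `n_raw`,
#'   `meta`.
#' @export
intensity_profile <- function(samples, meta = list()) {
  if (length(samples) < 32) {
    stop("an intensity profile needs at least 32 samples", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples)) || any(samples < 0)) {
    stop("profile samples must be finite and >= 0", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 n_raw = length(samples), meta = meta),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity profile: %d samples, OD range [%.3f, %.3f]\n",
              x$n_raw, min(x$samples), max(x$samples)))
  invisible(x)
}

check_polyline <- function(line) {
  line <- as.matrix(line[, 1:2])
  if (nrow(line) < 2) stop("polyline needs >= 2 points", call. = FALSE)
  seg <- sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
  if (sum(seg) <= 0) stop("polyline has zero arclength", call. = FALSE)
  line
}

#' Sample RGB values along a polyline
#'
#' Walks the polyline (distal end first) in unit-arclength steps, reading
#' the nearest pixel at each step, so the number of samples is
#' `floor(arclength) + 1` -- one sample per pixel step, within one of the
#' Euclidean arclength.
#'
#' @param image Numeric array `[rows, cols, 3]`, values in `[0, 1]`.
#' @param line Two-column matrix or data frame of `(x, y)` pixel
#'   coordinates (x = column, y = row), distal point first.
#' @return Matrix `n x 3` of RGB samples in path order.
#' @export
sample_line <- function(image, line) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  line <- check_polyline(line)
  seg <- sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, floor(total))
  xs <- stats::approx(cum, line[, 1], xout = s)$y
  ys <- stats::approx(cum, line[, 2], xout = s)$y
  cols <- round(xs)
  rows <- round(ys)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (any(cols < 1 | cols > w | rows < 1 | rows > h)) {
    stop("polyline extends outside the image bounds", call. = FALSE)
  }
  cbind(image[cbind(rows, cols, 1)],
        image[cbind(rows, cols, 2)],
        image[cbind(rows, cols, 3)])
}

#' Convert RGB samples to purple optical density
#'
#' Per sample, computes the per-channel Beer-Lambert absorbance relative to
#' the background color, projects it onto the stain's unit absorbance
#' vector, and clips at zero. Background-colored pixels map to ~0.
#'
#' @param rgb_samples Matrix `n x 3` as returned by [sample_line()].
#' @param model A [stain_model()].
#' @return Numeric vector of OD values, same order as the input.
#' @export
purple_od <- function(rgb_samples, model = stain_model()) {
  stopifnot(inherits(model, "stain_model"))
  rgb_samples <- as.matrix(rgb_samples)
  eps <- model$epsilon
  absorb <- -log10(sweep(rgb_samples + eps, 2, model$background_rgb + eps, "/"))
  pmax(as.numeric(absorb %*% model$stain_rgb_unit), 0)
}

#' Extract a stain-intensity profile from an image
#'
#' Composition of [sample_line()] and [purple_od()] with metadata attached,
#' plus optional moving-average smoothing.
#'
#' @inheritParams sample_line
#' @param model A [stain_model()].
#' @param meta Metadata list stored on the profile.
#' @param smooth Moving-average window in samples (default 1 = off).
#' @return An [intensity_profile()].
#' @export
extract_profile <- function(image, line, model = stain_model(),
                            meta = list(), smooth = 1) {
  od <- purple_od(sample_line(image, line), model)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    sm <- stats::filter(od, k, sides = 2)
    od <- ifelse(is.na(sm), od, as.numeric(sm))
  }
  intensity_profile(od, meta = meta)
}

#' Write an image as plain-text PPM (P3)
#'
#' The package reads and writes the uncompressed, plain-text PPM format so
#' that synthetic datasets remain text-only and dependency-free; any image
#' viewer or converter understands it.
#'
#' @param image Numeric array `[rows, cols, 3]`, values in `[0, 1]`.
#' @param path Output path.
#' @param maxval Quantization ceiling (default 255).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(image, path, maxval = 255) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  q <- round(pmin(pmax(image, 0), 1) * maxval)
  # interleave channels pixel by pixel, row-major
  flat <- aperm(q, c(3, 2, 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), as.character(maxval)), con)
  writeLines(paste(as.integer(flat), collapse = " "), con)
  invisible(path)
}

#' Read a plain-text PPM (P3) image
#'
#' @param path Path to a P3 PPM file.
#' @return Numeric array `[rows, cols, 3]` with values in `[0, 1]`.
#' @export
read_ppm <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tokens[1] != "P3") stop("not a plain-text (P3) PPM file", call. = FALSE)
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.numeric(tokens[4])
  vals <- as.numeric(tokens[-(1:4)]) / maxval
  if (length(vals) != w * h * 3) {
    stop("corrupt PPM: expected ", w * h * 3, " values, got ", length(vals),
         call. = FALSE)
  }
  aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
}

#' Write an intensity profile to CSV
#'
#' Columns `position_px`, `od`; metadata stored as leading `# key: value`
#' comment lines.
#'
#' @param profile An [intensity_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(profile$meta)) {
    writeLines(sprintf("# %s: %s", k, profile$meta[[k]]), con)
  }
  writeLines("position_px,od", con)
  writeLines(sprintf("%d,%.10g", seq_along(profile$samples) - 1L,
                     profile$samples), con)
  invisible(path)
}

#' Read an intensity profile written by [write_profile()]
#'
#' @param path Path to a profile CSV.
#' @return An [intensity_profile()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in hdr) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  intensity_profile(body$od, meta = meta)
}
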