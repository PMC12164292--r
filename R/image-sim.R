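# Whole-mount-like autopod image renderer.
#
# Digits are drawn as straight, tapering rays fanning out from a palm disc
# on a uniform pale background -- the minimal geometry from which the line
# measurement can be exercised.  Stain is deposited along each ray from its
# render_profile OD field and mixed into the background with Beer-Lambert
# attenuation, so extract_profile() is the exact inverse of the renderer up
# to pixel quantization.

#' Render a synthetic stained autopod image
#'
#' @param digit_params List of [clock_params()], one per digit (1-5),
#'   anterior to posterior.
#' @param stage Rendering stage.
#' @param cfg A [render_config()]; `profile_length_px` (or the drawn length)
#'   sets the digit ray length in pixels.
#' @param fan_deg Total angular spread of the digit fan, degrees.
#' @param ray_lengths Optional vector of per-digit lengths in px; defaults
#'   to `cfg$profile_length_px` or draws per digit from `cfg$length_range`.
#' @param w_base,w_tip Ray half-width at base and tip in px.
#' @return List with `image` (numeric array `[rows, cols, 3]`), `polylines`
#'   (per digit, two-column `(x, y)` matrices, distal point first),
#'   `ground_truth` (per digit, as in [render_profile()] plus the OD
#'   samples actually deposited), and `stage`.
#' @export
render_autopod_image <- function(digit_params, stage, cfg = render_config(),
                                 fan_deg = 80, ray_lengths = NULL,
                                 w_base = 7, w_tip = 3) {
  n_d <- length(digit_params)
  if (n_d < 1 || n_d > 5) stop("1-5 digits required", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(ray_lengths)) {
    ray_lengths <- if (!is.null(cfg$profile_length_px)) {
      rep(cfg$profile_length_px, n_d)
    } else {
      sample(seq(cfg$length_range[1], cfg$length_range[2]), n_d,
             replace = TRUE)
    }
  }
  # fan geometry: rays point "up" from a palm center, angles spread evenly
  angles <- if (n_d == 1) 0 else seq(-fan_deg / 2, fan_deg / 2,
                                     length.out = n_d) * pi / 180
  # reject layouts whose rays come closer than their combined widths
  if (n_d > 1) {
    min_gap <- min(diff(angles)) * min(ray_lengths) / 2
    if (min_gap < 2 * w_base) {
      stop("digit rays overlap: widen the fan or shorten/thicken less",
           call. = FALSE)
    }
  }
  margin <- ceiling(w_base + 4)
  palm_r <- 12
  tips_x <- (palm_r + ray_lengths) * sin(angles)
  tips_y <- -(palm_r + ray_lengths) * cos(angles)
  x0 <- min(c(tips_x, 0)) - margin
  x1 <- max(c(tips_x, 0)) + margin
  cx <- 1 - x0
  W <- ceiling(x1 - x0) + 1
  H <- ceiling(-min(tips_y)) + 2 * margin + palm_r
  cy <- H - margin
  bg <- cfg$background_rgb
  od_field <- matrix(0, H, W)
  polylines <- vector("list", n_d)
  gt <- vector("list", n_d)
  noise_cfg <- cfg
  noise_cfg$seed <- NULL
  for (i in seq_len(n_d)) {
    p <- digit_params[[i]]
    sched <- make_schedule(p)
    L <- ray_lengths[i]
    prof_cfg <- noise_cfg
    prof_cfg$profile_length_px <- L
    prof <- render_profile(sched, p, stage, prof_cfg)
    ux <- sin(angles[i]); uy <- -cos(angles[i])
    base <- c(cx + palm_r * ux, cy + palm_r * uy)
    tip <- c(cx + (palm_r + L) * ux, cy + (palm_r + L) * uy)
    polylines[[i]] <- rbind(tip, base)  # distal end first
    dimnames(polylines[[i]]) <- list(NULL, c("x", "y"))
    gt[[i]] <- c(attr(prof, "ground_truth"),
                 list(length_px = L, od = prof$samples))
    # rasterize: pixels within the tapering half-width of the ray axis
    bbx <- range(c(base[1], tip[1]))
    bby <- range(c(base[2], tip[2]))
    colr <- max(1, floor(bbx[1] - w_base)):min(W, ceiling(bbx[2] + w_base))
    rowr <- max(1, floor(bby[1] - w_base)):min(H, ceiling(bby[2] + w_base))
    px <- outer(rep(1, length(rowr)), colr)
    py <- outer(rowr, rep(1, length(colr)))
    relx <- px - tip[1]; rely <- py - tip[2]
    # axial coordinate from the tip toward the base, in px
    t_ax <- relx * (-ux) + rely * (-uy)
    d_perp <- abs(relx * (-uy) - rely * (-ux))
    tt <- t_ax / L
    hw <- w_tip + (w_base - w_tip) * tt
    inside <- tt >= 0 & tt <= 1 & d_perp <= hw
    idx <- pmin(pmax(round(tt * (L - 1)) + 1L, 1L), L)
    od_vals <- matrix(prof$samples[idx], nrow(px), ncol(px))
    sub <- od_field[rowr, colr]
    sub[inside] <- sub[inside] + od_vals[inside]
    od_field[rowr, colr] <- sub
  }
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- bg[ch] * 10^(-od_field * cfg$stain_rgb[ch])
  }
  list(image = img, polylines = polylines, ground_truth = gt, stage = stage)
}

#' Write a polyline to CSV
#'
#' Two columns `x`, `y`, one row per vertex, distal point first.
#'
#' @param line Two-column matrix of `(x, y)` coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polyline <- function(line, path) {
  utils::write.csv(data.frame(x = line[, 1], y = line[, 2]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a polyline CSV written by [write_polyline()]
#'
#' @param path Path to a polyline CSV.
#' @return Two-column matrix of `(x, y)` coordinates, distal point first.
#' @export
read_polyline <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("x", "y")])
}
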