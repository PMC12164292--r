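# Stage and digit identity helpers shared by all analysis stages.
#
# All species are placed on the chicken Hamburger-Hamilton (HH) stage axis,
# quantized to half stages; all dynamics in this package are expressed in
# stage units, never in hours or days.

#' Validate Hamburger-Hamilton stages
#'
#' Stages are real numbers on the chicken HH axis, restricted to a half-stage
#' grid (multiples of 0.5). Values must be positive and finite.
#'
#' @param stage Numeric vector of candidate stages.
#' @return The input, invisibly, after validation.
#' @export
check_stage <- function(stage) {
  if (!is.numeric(stage) || anyNA(stage) || any(!is.finite(stage))) {
    stop("stages must be finite numeric values", call. = FALSE)
  }
  if (any(stage <= 0)) {
    stop("stages must be positive", call. = FALSE)
  }
  off_grid <- abs(stage * 2 - round(stage * 2)) > 1e-8
  if (any(off_grid)) {
    stop(
      "stages must lie on the half-stage grid (multiples of 0.5): offending value(s) ",
      paste(stage[off_grid], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(stage)
}

# Continuous stage check: clock dynamics (joint formation, phase) live on a
# continuous stage axis; only observed/reported stages are half-stage
# quantized.
check_stage_cont <- function(stage) {
  if (!is.numeric(stage) || anyNA(stage) || any(!is.finite(stage)) ||
      any(stage <= 0)) {
    stop("stages must be positive finite numbers", call. = FALSE)
  }
  invisible(stage)
}

#' Snap values to the half-stage grid
#'
#' @param stage Numeric vector.
#' @return Numeric vector rounded to the nearest multiple of 0.5.
#' @export
snap_stage <- function(stage) {
  round(stage * 2) / 2
}

#' Digit identifier
#'
#' A digit is addressed by its limb (forelimb or hindlimb) and index 1-5,
#' numbered anterior to posterior (reported as Roman numerals I-V).
#'
#' @param limb `"forelimb"` or `"hindlimb"`.
#' @param index Integer digit index in 1..5.
#' @return A `digit_id` object.
#' @export
digit_id <- function(limb, index) {
  limb <- match.arg(limb, c("forelimb", "hindlimb"))
  if (length(index) != 1 || is.na(index) || index != as.integer(index) ||
      index < 1 || index > 5) {
    stop("digit index must be a single integer in 1..5", call. = FALSE)
  }
  structure(list(limb = limb, index = as.integer(index)), class = "digit_id")
}

#' @export
format.digit_id <- function(x, ...) {
  paste0(x$limb, " digit ", digit_roman(x$index))
}

#' @export
print.digit_id <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Roman numeral for a digit index
#'
#' @param index Integer vector in 1..5.
#' @return Character vector of Roman numerals.
#' @export
digit_roman <- function(index) {
  c("I", "II", "III", "IV", "V")[index]
}

#' Parse a Roman digit label back to an index
#'
#' @param label Character vector of labels among I..V.
#' @return Integer vector of indices.
#' @export
digit_index <- function(label) {
  idx <- match(toupper(label), c("I", "II", "III", "IV", "V"))
  if (anyNA(idx)) {
    stop("unknown digit label(s): ", paste(label[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Phalanx-formation window
#'
#' The developmental window in which phalanges are specified, on the chicken
#' HH stage axis. The default window opens at stage 29 (onset of joint
#' marker expression in the metapodial-phalangeal joint) and closes at stage
#' 36 (the phalanx-claw transition).
#'
#' @param s_on Window opening stage (default 29).
#' @param s_off Window closing stage (default 36).
#' @return A `clock_window` object.
#' @export
clock_window <- function(s_on = 29, s_off = 36) {
  check_stage(c(s_on, s_off))
  if (s_on >= s_off) {
    stop("window must satisfy s_on < s_off", call. = FALSE)
  }
  structure(list(s_on = s_on, s_off = s_off), class = "clock_window")
}

#' @export
print.clock_window <- function(x, ...) {
  cat(sprintf("phalanx-formation window: HH %.1f -> %.1f\n", x$s_on, x$s_off))
  invisible(x)
}
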