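# Joint-domain detection and scoring.
#
# A stained digit shows one expression domain per formed joint plus,
# depending on the clock phase, a domain at the very tip (the PFR, the
# cycling read-out).  The most recently formed joint is therefore the count
# of non-tip domains, and phalanx elements are read off the unstained gaps
# between and distal to those domains.  Per-gene binary on/off stage series
# at the tip are classified as cyclical/constitutive/silent by run-length
# structure.

#' Detect expression domains along a normalized profile
#'
#' Finds maximal runs of samples above a relative threshold (a fraction of
#' the 95th-percentile OD, tolerant of stain-depth differences between
#' specimens). Runs shorter than `min_len` are discarded; the distal-most
#' run starting within `tip_margin` of the tip is flagged as the tip (PFR)
#' domain.
#'
#' @param nprofile A [normalize_length()] result.
#' @param threshold_frac Threshold as a fraction of the 95th-percentile OD
#'   (default 0.5).
#' @param min_len Minimum domain length as a fraction of the profile
#'   (default 0.02).
#' @param tip_margin Tip zone as a fraction of the profile (default 0.05).
#' @return A data frame of domains ordered distal to proximal: `start`,
#'   `end` (normalized arclength), `peak_od`, `is_tip`. A flat or
#'   all-subthreshold profile yields zero rows.
#' @export
detect_domains <- function(nprofile, threshold_frac = 0.5, min_len = 0.02,
                           tip_margin = 0.05) {
  stopifnot(inherits(nprofile, "normalized_profile"))
  y <- nprofile$samples
  N <- length(y)
  thr <- threshold_frac * stats::quantile(y, 0.95, names = FALSE)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      peak_od = numeric(0), is_tip = logical(0))
  if (thr <= 0) return(empty)
  above <- y >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len * N
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  x <- seq(0, 1, length.out = N)
  dom <- data.frame(
    start = x[starts],
    end = x[ends],
    peak_od = mapply(function(a, b) max(y[a:b]), starts, ends),
    is_tip = FALSE
  )
  dom <- dom[order(dom$start), ]
  if (dom$start[1] < tip_margin) dom$is_tip[1] <- TRUE
  rownames(dom) <- NULL
  dom
}

#' Score the most recent joint and phalanx elements from domains
#'
#' Joints are numbered 1..K proximal to distal, so the most recently formed
#' joint index equals the count of non-tip domains. Phalanx elements are
#' the unstained gaps between, and distal to, the non-tip domains (the gap
#' proximal to the most proximal joint is not an element).
#'
#' @param domains A data frame from [detect_domains()], ordered distal to
#'   proximal.
#' @param min_gap Minimum gap width (normalized arclength) to count as
#'   unstained tissue (default 0.005).
#' @return List with `most_recent_joint` and `phalanx_elements`.
#' @export
score_joints <- function(domains, min_gap = 0.005) {
  if (!nrow(domains)) {
    return(list(most_recent_joint = 0L, phalanx_elements = 0L))
  }
  if (is.unsorted(domains$start)) {
    stop("domains must be ordered distal to proximal", call. = FALSE)
  }
  if (any(domains$start[-1] < domains$end[-nrow(domains)])) {
    stop("overlapping domains", call. = FALSE)
  }
  joints <- domains[!domains$is_tip, , drop = FALSE]
  k <- nrow(joints)
  if (k == 0) return(list(most_recent_joint = 0L, phalanx_elements = 0L))
  # distal boundary of each non-tip domain: end of the preceding domain
  # (tip or joint), or the digit tip itself
  gaps <- 0L
  for (i in seq_len(nrow(domains))) {
    if (domains$is_tip[i]) next
    prev_end <- if (i == 1) 0 else domains$end[i - 1]
    if (domains$start[i] - prev_end >= min_gap) gaps <- gaps + 1L
  }
  list(most_recent_joint = as.integer(k), phalanx_elements = gaps)
}

#' Assemble a per-stage, per-digit joint table
#'
#' @param scores Data frame with columns `stage`, `digit` (Roman label),
#'   `most_recent_joint`, one row per (stage, digit).
#' @return A data frame ordered by stage, one column per digit, mirroring
#'   the whole-mount survey tables. Within-series decreases of the joint
#'   count across stages are reported as QC warnings (attribute
#'   `qc_warnings`), never altered: specimens at different stages are
#'   independent individuals.
#' @export
build_joint_table <- function(scores) {
  need <- c("stage", "digit", "most_recent_joint")
  if (!all(need %in% names(scores))) {
    stop("scores needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(scores[, c("stage", "digit")])) {
    stop("duplicate (stage, digit) entries", call. = FALSE)
  }
  check_stage(scores$stage)
  stages <- sort(unique(scores$stage))
  digits <- c("I", "II", "III", "IV", "V")
  digits <- digits[digits %in% scores$digit]
  tab <- data.frame(stage = stages)
  for (d in digits) {
    sub <- scores[scores$digit == d, ]
    tab[[d]] <- sub$most_recent_joint[match(stages, sub$stage)]
  }
  qc <- character(0)
  for (d in digits) {
    v <- tab[[d]]
    ok <- !is.na(v)
    if (sum(ok) >= 2 && any(diff(v[ok]) < 0)) {
      qc <- c(qc, sprintf("digit %s: joint count decreases across stages", d))
    }
  }
  if (length(qc)) {
    warning("joint-table QC: ", paste(qc, collapse = "; "), call. = FALSE)
  }
  attr(tab, "qc_warnings") <- qc
  tab
}

#' Classify a binary on/off expression stage series
#'
#' Classification by run-length structure of the tip expression state:
#' `cyclical` when there are >= 2 maximal on-runs separated by >= 1 off
#' stage; `constitutive` when all stages are on; `silent` when all off;
#' `monotone_off` when a single on-run ends before the final stage;
#' `monotone_on` when a single on-run reaches the final stage but the
#' series is not all-on.
#'
#' @param stages Strictly increasing stage vector (>= 3 stages).
#' @param state Logical vector, same length: tip expression on/off.
#' @return List with `class` and `n_on_runs`.
#' @export
classify_cyclical <- function(stages, state) {
  check_stage(stages)
  if (length(stages) < 3) {
    stop("need >= 3 stages to classify a series", call. = FALSE)
  }
  if (length(state) != length(stages)) {
    stop("stages and state must have equal length", call. = FALSE)
  }
  if (is.unsorted(stages, strictly = TRUE)) {
    stop("stages must be strictly increasing", call. = FALSE)
  }
  state <- as.logical(state)
  r <- rle(state)
  n_on <- sum(r$values)
  cls <- if (n_on >= 2) {
    "cyclical"
  } else if (n_on == 0) {
    "silent"
  } else if (all(state)) {
    "constitutive"
  } else if (!state[length(state)]) {
    "monotone_off"
  } else {
    "monotone_on"
  }
  list(class = cls, n_on_runs = as.integer(n_on))
}
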