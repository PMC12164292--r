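# Phalanx-claw transition calling.
#
# At the end of the phalanx-formation window (~HH 36) the phalanx-forming
# region shuts down: PFR genes go off at the digit tip while claw genes
# become tip-restricted -- synchronously across clawed digits.  Clawless
# digits either keep the PFR program running past the window
# (clawless_persistent; the configuration permitting hyperphalangy) or shut
# it down early with no claw program at all (reduced digits).  The calling
# rule is a majority vote over observed PFR markers combined with
# tip-restricted claw-marker evidence; the exact marker combination used in
# narrative descriptions is not formulaic, so every knob is configurable.

#' Marker panel for transition calling
#'
#' @param pfr_markers Genes expressed in the phalanx-forming region and
#'   downregulated at the transition.
#' @param claw_markers Genes upregulated (tip-restricted) at claw onset.
#' @return A `marker_panel` object.
#' @export
marker_panel <- function(pfr_markers = c("Sox9", "Gdf5", "Wnt9a", "Ackr3",
                                         "Hes1", "Hes4", "Id4", "Bmpr1b"),
                         claw_markers = c("Bambi", "Msx1", "Msx2")) {
  if (!length(pfr_markers) || !length(claw_markers)) {
    stop("both marker sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(pfr_markers, claw_markers))) {
    stop("PFR and claw marker sets must be disjoint", call. = FALSE)
  }
  structure(list(pfr_markers = pfr_markers, claw_markers = claw_markers),
            class = "marker_panel")
}

#' Call the phalanx-claw transition for one digit
#'
#' The transition stage is the earliest stage at which (a) the majority of
#' observed PFR markers are off at the tip and (b) the observed claw
#' markers show tip-restricted expression (a `claw_majority` vote) at that
#' stage or the following half-stage; such a digit is `clawed`. A digit
#' whose PFR markers remain on at or beyond `s_off + persist_margin` with
#' no claw-program evidence anywhere is `clawless_persistent`. A digit
#' whose PFR markers go off `reduced_margin` or more stages before `s_off`
#' with no claw program is `reduced`. Anything else is `indeterminate`.
#'
#' @param calls Expression-call data frame for one digit (columns `gene`,
#'   `stage`, `location`, `state`).
#' @param panel A [marker_panel()].
#' @param s_off Window closing stage (default 36).
#' @param majority Fraction of observed PFR markers that must be off
#'   (strictly exceeded; default 0.5).
#' @param claw_majority Fraction of observed claw markers that must be
#'   tip-restricted at one stage to count as claw-program evidence
#'   (strictly exceeded; default 0.5). Set to 0 to accept a single marker,
#'   at the cost of robustness to miscalled states.
#' @param min_claw_stages Number of stages with claw-majority evidence
#'   required before a claw program is believed (default 2): a real claw
#'   program, once initiated, keeps its markers on, so a single-stage blip
#'   is discounted. Set to 1 for very sparse series.
#' @param persist_margin Stages past `s_off` that PFR persistence must
#'   reach (default 1.0, separating off-at-36 +/- 0.5 from on-at-37).
#' @param reduced_margin Early-shutdown margin in stages (default 2).
#' @return A `transition_call`: list with `digit`, `class`,
#'   `transition_stage` (or `NA`), and `evidence` (per-marker first-off and
#'   first-tip-restricted stages).
#' @export
call_transition <- function(calls, panel = marker_panel(), s_off = 36,
                            majority = 0.5, claw_majority = 0.5,
                            min_claw_stages = 2, persist_margin = 1,
                            reduced_margin = 2) {
  stopifnot(inherits(panel, "marker_panel"))
  stages <- sort(unique(calls$stage))
  if (length(stages) < 3) {
    stop("calls must span >= 3 stages", call. = FALSE)
  }
  pfr <- calls[calls$gene %in% panel$pfr_markers, ]
  claw <- calls[calls$gene %in% panel$claw_markers, ]
  if (!nrow(pfr) || !nrow(claw)) {
    stop("calls must include at least one PFR and one claw marker",
         call. = FALSE)
  }
  digit <- unique(calls$digit)
  if (length(digit) != 1) {
    stop("call_transition expects calls for exactly one digit", call. = FALSE)
  }

  pfr_on <- function(s) {
    obs <- pfr[pfr$stage == s, ]
    if (!nrow(obs)) return(NA)
    mean(obs$state & obs$location == "tip_PFR")
  }
  claw_tip_on <- function(s) {
    obs <- claw[claw$stage == s, ]
    if (!nrow(obs)) return(FALSE)
    mean(obs$state & obs$location == "tip_PFR") > claw_majority
  }

  pfr_on_frac <- vapply(stages, pfr_on, numeric(1))
  claw_on <- vapply(stages, claw_tip_on, logical(1))

  # evidence: per-marker first stage off at tip / first tip-restricted stage
  first_off <- vapply(panel$pfr_markers, function(g) {
    obs <- pfr[pfr$gene == g, ]
    off <- sort(obs$stage[!(obs$state & obs$location == "tip_PFR")])
    if (length(off)) off[1] else NA_real_
  }, numeric(1))
  first_claw <- vapply(panel$claw_markers, function(g) {
    obs <- claw[claw$gene == g, ]
    on <- sort(obs$stage[obs$state & obs$location == "tip_PFR"])
    if (length(on)) on[1] else NA_real_
  }, numeric(1))
  evidence <- list(pfr_first_off = first_off,
                   claw_first_tip_restricted = first_claw)

  observed <- !is.na(pfr_on_frac)
  claw_program <- sum(claw_on) >= min_claw_stages
  transition <- NA_real_
  if (claw_program) {
    for (i in which(observed)) {
      s <- stages[i]
      if (1 - pfr_on_frac[i] <= majority) next
      nxt <- claw_on[stages %in% c(s, s + 0.5)]
      if (any(nxt)) {
        transition <- s
        break
      }
    }
  }

  cls <- if (!is.na(transition)) {
    "clawed"
  } else {
    late_on <- any(observed & stages >= s_off + persist_margin &
                     pfr_on_frac > majority)
    never_claw <- !claw_program
    off_stages <- stages[observed & (1 - pfr_on_frac) > majority]
    early_off <- length(off_stages) > 0 &&
      min(off_stages) <= s_off - reduced_margin
    if (late_on && never_claw) {
      "clawless_persistent"
    } else if (early_off && never_claw) {
      "reduced"
    } else {
      "indeterminate"
    }
  }
  structure(list(digit = digit, class = cls, transition_stage = transition,
                 evidence = evidence),
            class = "transition_call")
}

#' @export
print.transition_call <- function(x, ...) {
  cat(sprintf("digit %s: %s%s\n", x$digit, x$class,
              if (!is.na(x$transition_stage)) {
                sprintf(" (transition at HH %.1f)", x$transition_stage)
              } else ""))
  invisible(x)
}

#' Cross-digit synchrony of the transition within one limb
#'
#' @param transition_calls List of [call_transition()] results for one limb.
#' @param tol Maximum spread in stages still counted as synchronous
#'   (default 0.5).
#' @return List with `applicable`, `synchronous`, `spread`, and
#'   `n_clawed`. With fewer than two clawed digits the question is not
#'   applicable and `synchronous` is `NA`.
#' @export
limb_synchrony <- function(transition_calls, tol = 0.5) {
  ts <- unlist(lapply(transition_calls, function(x) {
    if (x$class == "clawed") x$transition_stage else NULL
  }))
  if (length(ts) < 2) {
    return(list(applicable = FALSE, synchronous = NA, spread = NA_real_,
                n_clawed = length(ts)))
  }
  spread <- max(ts) - min(ts)
  list(applicable = TRUE, synchronous = spread <= tol, spread = spread,
       n_clawed = length(ts))
}

#' Flag a digit as hyperphalangic
#'
#' A digit is flagged when it is classed `clawless_persistent` (the
#' transition never fired, lifting the constraint on phalanx number) and
#' its phalanx count exceeds that of the homologous ancestral digit.
#'
#' @param transition_call A [call_transition()] result.
#' @param record Phenotype row for the digit (see [phenotype_record()]).
#' @param ancestral_record Phenotype row for the homologous ancestral digit.
#' @return Logical flag.
#' @export
hyperphalangy_flag <- function(transition_call, record, ancestral_record) {
  if (is.null(ancestral_record) || !nrow(ancestral_record)) {
    stop("ancestral phenotype record missing", call. = FALSE)
  }
  transition_call$class == "clawless_persistent" &&
    record$phalanx_max > ancestral_record$phalanx_max
}
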