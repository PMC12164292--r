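# Digit-clock synthetic data generator.
#
# The model: each digit carries an autonomous oscillator ("digit clock")
# that runs inside a fixed developmental window (HH 29-36 by default).  The
# oscillation frequency is digit-specific and set by the final phalanx
# number P: a digit destined to make P phalanges forms its P joints at
# equally spaced stages across the window, so digits with equal P are in
# the same phase of the cycle at every shared stage (isomorphy).  Clawless
# digits that miss the phalanx-claw transition keep the same inter-joint
# spacing and simply continue forming joints past the window's end
# (hyperphalangy).  Linear spacing in stage units is the minimal model
# consistent with a fixed window and digit-specific frequency.

#' Clock parameters for one digit
#'
#' @param digit A [digit_id()].
#' @param phalanx_count Final phalanx number `P` (>= 1). Clawless digits may
#'   carry a `P` exceeding the ancestral count (hyperphalangy).
#' @param window A [clock_window()].
#' @param claw Does the digit undergo the phalanx-claw transition at the end
#'   of the window?
#' @param p_window Number of joints that fit inside the window; sets the
#'   inter-joint spacing `(s_off - s_on) / (p_window - 1)`. Defaults to
#'   `phalanx_count`; clawed digits must keep the default (their clock stops
#'   at the transition). A clawless hyperphalangic digit passes its ancestral
#'   count here so the surplus joints fall beyond the window.
#' @return A `clock_params` object.
#' @export
clock_params <- function(digit, phalanx_count, window = clock_window(),
                         claw = TRUE, p_window = phalanx_count) {
  stopifnot(inherits(digit, "digit_id"), inherits(window, "clock_window"))
  if (length(phalanx_count) != 1 || is.na(phalanx_count) ||
      phalanx_count != as.integer(phalanx_count) || phalanx_count < 1) {
    stop("phalanx_count must be an integer >= 1 for a present digit",
         call. = FALSE)
  }
  if (p_window < 1 || p_window != as.integer(p_window)) {
    stop("p_window must be an integer >= 1", call. = FALSE)
  }
  if (claw && p_window != phalanx_count) {
    stop("clawed digits must have p_window == phalanx_count", call. = FALSE)
  }
  if (!claw && p_window > phalanx_count) {
    stop("p_window cannot exceed phalanx_count", call. = FALSE)
  }
  structure(list(digit = digit, phalanx_count = as.integer(phalanx_count),
                 window = window, claw = claw,
                 p_window = as.integer(p_window)),
            class = "clock_params")
}

# inter-joint spacing in stage units; NA for the degenerate single-joint digit
joint_spacing <- function(params) {
  w <- params$window
  if (params$p_window >= 2) (w$s_off - w$s_on) / (params$p_window - 1) else NA_real_
}

#' Joint-formation schedule of a digit
#'
#' Places `K = P` joints (the metapodial-phalangeal joint plus `P - 1`
#' interphalangeal joints, numbered 1..K proximal to distal) at equally
#' spaced stages starting at the window opening. For clawed digits the last
#' joint lands exactly at the window closing stage; clawless digits with
#' more joints than fit the window continue the same spacing past it.
#'
#' @param params A [clock_params()].
#' @return A `joint_schedule`: list with `digit` and `formation_stages`.
#' @examples
#' p <- clock_params(digit_id("forelimb", 4), 5)
#' make_schedule(p)$formation_stages  # 29 30.75 32.5 34.25 36
#' @export
make_schedule <- function(params) {
  stopifnot(inherits(params, "clock_params"))
  P <- params$phalanx_count
  s_on <- params$window$s_on
  stages <- if (P == 1) s_on else s_on + (seq_len(P) - 1) * joint_spacing(params)
  if (params$claw && P >= 2 && abs(stages[P] - params$window$s_off) > 1e-9) {
    stop("internal error: clawed schedule must end at s_off", call. = FALSE)
  }
  structure(list(digit = params$digit, formation_stages = stages),
            class = "joint_schedule")
}

#' Oscillator phase of a digit at a stage
#'
#' The phase is the fractional progress through the current expression
#' cycle: `phi = frac((stage - s_on) / spacing)`, zero exactly at each
#' joint-formation stage. For clawed digits the clock halts after the
#' transition (`phi = 0` past `s_off`). Digits with equal phalanx number
#' have identical phase at every shared stage.
#'
#' @param params A [clock_params()].
#' @param stage Stage at or after the window opening.
#' @return A `phase_state`: list with `digit`, `stage`, `phi` in [0, 1).
#' @export
phase_at <- function(params, stage) {
  stopifnot(inherits(params, "clock_params"))
  check_stage_cont(stage)
  s_on <- params$window$s_on
  if (stage < s_on) {
    stop("phase undefined before the window opening (stage ", stage, " < ",
         s_on, ")", call. = FALSE)
  }
  phi <- if (params$p_window < 2 ||
             (params$claw && stage > params$window$s_off)) {
    0
  } else {
    ((stage - s_on) / joint_spacing(params)) %% 1
  }
  structure(list(digit = params$digit, stage = stage, phi = phi),
            class = "phase_state")
}

#' Rendering configuration for synthetic profiles and images
#'
#' @param profile_length_px Number of raw samples along a digit; `NULL`
#'   draws uniformly from `length_range` (the span of digit lengths the
#'   line-measurement protocol encounters).
#' @param length_range Two-element range for drawn lengths, default
#'   `c(184, 1195)` pixels.
#' @param noise_sd Additive Gaussian noise, OD units (default 0.1).
#' @param bump_amp Peak OD of an expression domain (default 0.8).
#' @param bump_sd Gaussian domain half-width as a fraction of digit length
#'   (default 0.02).
#' @param tip_pos Center of the tip (PFR) domain on normalized arclength
#'   (default 0.02, i.e. essentially at the tip).
#' @param duty Duty fraction of the cycle during which the tip domain is on
#'   (on when `phi < duty`; default 0.5, matching binary on/off reporting).
#' @param background_rgb Background tissue color, values in `[0, 1]`.
#' @param stain_rgb Absorbance direction of the purple stain (normalized
#'   internally).
#' @param seed Integer seed for the profile/image noise stream, or `NULL` to
#'   draw from the ambient RNG stream (useful when a caller seeds a whole
#'   simulation once and renders many digits).
#' @return A `render_config` object.
#' @export
render_config <- function(profile_length_px = NULL,
                          length_range = c(184, 1195),
                          noise_sd = 0.1, bump_amp = 0.8, bump_sd = 0.02,
                          tip_pos = 0.02, duty = 0.5,
                          background_rgb = c(0.96, 0.93, 0.88),
                          stain_rgb = c(0.59, 0.74, 0.33),
                          seed = 1L) {
  if (!is.null(profile_length_px) && profile_length_px < 32) {
    stop("profile_length_px must be >= 32", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]", call. = FALSE)
  structure(list(profile_length_px = profile_length_px,
                 length_range = length_range, noise_sd = noise_sd,
                 bump_amp = bump_amp, bump_sd = bump_sd, tip_pos = tip_pos,
                 duty = duty, background_rgb = background_rgb,
                 stain_rgb = stain_rgb / sqrt(sum(stain_rgb^2)),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "render_config")
}

# Is the tip (PFR) domain stained at this stage?  Gated by the oscillator
# phase; permanently off in clawed digits once the transition has passed.
tip_is_on <- function(params, stage, duty) {
  if (params$claw && stage > params$window$s_off + 1e-9) return(FALSE)
  phase_at(params, stage)$phi < duty
}

# Continuous OD along normalized arclength x (0 = distal tip, 1 = proximal
# base) for a digit with m formed joints.  Joint j (proximal->distal
# numbering) sits at distal coordinate 1 - j / (m + 1), so domains and the
# unstained gaps between them tile the digit.
profile_od <- function(x, n_formed, tip_on, cfg) {
  od <- numeric(length(x))
  if (n_formed > 0) {
    centers <- 1 - seq_len(n_formed) / (n_formed + 1)
    for (ct in centers) {
      od <- od + cfg$bump_amp * exp(-(x - ct)^2 / (2 * cfg$bump_sd^2))
    }
  }
  if (tip_on) {
    od <- od + cfg$bump_amp * exp(-(x - cfg$tip_pos)^2 / (2 * cfg$bump_sd^2))
  }
  od
}

#' Render a synthetic stain-intensity profile for one digit
#'
#' Produces the distal-to-proximal optical-density profile a line
#' measurement would recover from a whole-mount stained digit: one Gaussian
#' domain per formed joint, a tip (PFR) domain gated on/off by the clock
#' phase, and additive Gaussian noise. Ground truth (domain centers, tip
#' state, most recently formed joint) is attached for benchmarking.
#'
#' @param schedule A [make_schedule()] result for the digit.
#' @param params The matching [clock_params()].
#' @param stage Rendering stage (>= window opening).
#' @param cfg A [render_config()].
#' @return An `intensity_profile` with attribute `ground_truth`: list of
#'   `joint_centers` (normalized distal coordinates, proximal->distal joint
#'   numbering), `tip_on`, `most_recent_joint`.
#' @export
render_profile <- function(schedule, params, stage, cfg = render_config()) {
  stopifnot(inherits(schedule, "joint_schedule"),
            inherits(params, "clock_params"))
  check_stage_cont(stage)
  if (stage < params$window$s_on) {
    stop("cannot render before the window opening", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$profile_length_px
  if (is.null(L)) {
    L <- sample(seq(cfg$length_range[1], cfg$length_range[2]), 1)
  }
  m <- sum(schedule$formation_stages <= stage + 1e-9)
  tip_on <- tip_is_on(params, stage, cfg$duty)
  x <- seq(0, 1, length.out = L)
  od <- profile_od(x, m, tip_on, cfg)
  if (cfg$noise_sd > 0) od <- od + stats::rnorm(L, 0, cfg$noise_sd)
  od <- pmax(od, 0)
  gt <- list(
    joint_centers = if (m > 0) 1 - seq_len(m) / (m + 1) else numeric(0),
    tip_on = tip_on,
    most_recent_joint = m
  )
  prof <- intensity_profile(od, meta = list(
    specimen = NA_character_, stage = stage, limb = params$digit$limb,
    digit = params$digit$index
  ))
  attr(prof, "ground_truth") <- gt
  prof
}

#' Simulate marker on/off expression calls for digits
#'
#' Emulates the whole-mount survey feeding the transition analysis: markers
#' of the phalanx-forming region (PFR) are expressed at the digit tip until
#' the phalanx-claw transition, at which point claw markers become
#' tip-restricted -- in clawed digits only. Three digit archetypes are
#' supported: `"clawed"` (transition at the window closing stage),
#' `"clawless_persistent"` (PFR markers persist past the window, claw
#' markers never on), and `"reduced"` (PFR markers shut down two stages
#' early with no claw program, like the reduced avian wing digit).
#'
#' @param archetypes Named character vector or list mapping digit labels to
#'   archetypes; names are used as the `digit` column (Roman labels).
#' @param stages Stages sampled (default the half-stage grid 29-37).
#' @param panel A [marker_panel()].
#' @param species,limb Metadata columns for the output.
#' @param window A [clock_window()].
#' @param mislabel Probability that a call's on/off state is flipped.
#' @param seed Integer seed.
#' @return A data frame of expression calls: `gene`, `species`, `limb`,
#'   `digit`, `stage`, `location`, `state`, with ground-truth archetypes in
#'   attribute `ground_truth`.
#' @export
simulate_calls <- function(archetypes, stages = seq(29, 37, by = 0.5),
                           panel = marker_panel(), species = "synthetic",
                           limb = "forelimb", window = clock_window(),
                           mislabel = 0, seed = 1L) {
  check_stage(stages)
  if (any(stages < 28 | stages > 38)) {
    stop("stages must lie within 28-38", call. = FALSE)
  }
  arch <- unlist(archetypes)
  bad <- !arch %in% c("clawed", "clawless_persistent", "reduced")
  if (any(bad)) {
    stop("unknown archetype(s): ", paste(arch[bad], collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  s_off <- window$s_off
  rows <- list()
  for (d in names(arch)) {
    a <- arch[[d]]
    pfr_on <- switch(a,
      clawed = stages < s_off,
      clawless_persistent = rep(TRUE, length(stages)),
      reduced = stages < s_off - 2
    )
    claw_on <- if (a == "clawed") stages >= s_off else rep(FALSE, length(stages))
    for (g in panel$pfr_markers) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, species = species, limb = limb, digit = d, stage = stages,
        state = pfr_on, stringsAsFactors = FALSE
      )
    }
    for (g in panel$claw_markers) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, species = species, limb = limb, digit = d, stage = stages,
        state = claw_on, stringsAsFactors = FALSE
      )
    }
  }
  calls <- do.call(rbind, rows)
  if (mislabel > 0) {
    flip <- stats::runif(nrow(calls)) < mislabel
    calls$state[flip] <- !calls$state[flip]
  }
  calls$location <- ifelse(calls$state, "tip_PFR", "absent")
  calls <- calls[, c("gene", "species", "limb", "digit", "stage",
                     "location", "state")]
  attr(calls, "ground_truth") <- list(
    archetypes = arch,
    transition_stage = ifelse(arch == "clawed", s_off, NA_real_)
  )
  calls
}

#' Simulate a digit-tip TPM matrix
#'
#' Emulates the bulk RNA-seq design of the candidate screen: four digit
#' groups with three biological replicates each. Background genes share a
#' gene-specific mean across all digits (log-normal replicate noise);
#' planted genes are elevated by `effect_tpm` in exactly one digit group,
#' cycling through the groups.
#'
#' @param n_genes Total number of genes (default 2000).
#' @param n_planted Number of genes with a planted digit-specific effect.
#' @param effect_tpm Additive TPM elevation of a planted gene in its group.
#' @param base_mean Background expression shared by all genes, TPM
#'   (default 50).
#' @param base_sdlog Log-scale spread of gene baseline means (default 0:
#'   background genes share one common mean; raise for a long-tailed
#'   baseline).
#' @param cv Replicate coefficient of variation (default 0.1).
#' @param n_reps Replicates per digit group (default 3).
#' @param groups Digit group labels (default `c("I","II","III","IV")`).
#' @param seed Integer seed.
#' @return A numeric matrix, genes x samples, columns labeled
#'   `digit<group>_rep<r>`, with attribute `ground_truth` (planted gene
#'   names and their target groups).
#' @export
simulate_tpm <- function(n_genes = 2000, n_planted = 0, effect_tpm = 100,
                         base_mean = 50, base_sdlog = 0, cv = 0.1,
                         n_reps = 3, groups = c("I", "II", "III", "IV"),
                         seed = 1L) {
  stopifnot(n_genes >= 1, n_planted >= 0, n_planted <= n_genes, n_reps >= 2)
  set.seed(seed)
  n_samp <- length(groups) * n_reps
  gene_mean <- if (base_sdlog > 0) {
    stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = base_sdlog)
  } else {
    rep(base_mean, n_genes)
  }
  sdlog_rep <- sqrt(log(1 + cv^2))
  mu <- matrix(gene_mean, n_genes, n_samp)
  planted_group <- character(0)
  planted_genes <- character(0)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  if (n_planted > 0) {
    idx <- seq_len(n_planted)
    planted_genes <- genes[idx]
    planted_group <- groups[((idx - 1) %% length(groups)) + 1]
    for (k in idx) {
      cols <- rep(groups, each = n_reps) == planted_group[k]
      mu[k, cols] <- mu[k, cols] + effect_tpm
    }
  }
  noise <- matrix(stats::rlnorm(n_genes * n_samp, -sdlog_rep^2 / 2, sdlog_rep),
                  n_genes, n_samp)
  tpm <- mu * noise
  dimnames(tpm) <- list(genes, paste0(
    "digit", rep(groups, each = n_reps), "_rep", rep(seq_len(n_reps),
                                                     length(groups))
  ))
  attr(tpm, "ground_truth") <- list(planted = planted_genes,
                                    group = planted_group)
  tpm
}
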