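# Independent oracles and small simulation helpers shared across tests.

# Two-pass covariance Pearson correlation, written from the product-moment
# definition and independent of stats::cor.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Brute-force BH step-up: for each p, q_i = min over j with p_j >= p_i of
# m * p_(j) / j, evaluated by explicit search over the sorted vector.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Brute-force run-length classifier for binary stage series, written as an
# explicit state machine rather than via rle().
cyclic_oracle <- function(state) {
  runs <- 0
  prev <- FALSE
  for (s in state) {
    if (s && !prev) runs <- runs + 1
    prev <- s
  }
  cls <- if (runs >= 2) "cyclical"
  else if (runs == 0) "silent"
  else if (all(state)) "constitutive"
  else if (!state[length(state)]) "monotone_off"
  else "monotone_on"
  list(class = cls, n_on_runs = as.integer(runs))
}

# Clock parameter sets for a whole limb.
limb_params <- function(counts, limb = "forelimb", claws = rep(TRUE,
                                                               length(counts))) {
  lapply(seq_along(counts), function(i) {
    clock_params(digit_id(limb, i), counts[i], claw = claws[i])
  })
}

# Render and normalize profiles for every digit of a limb at one stage.
limb_profiles <- function(params, stage, cfg, N = 500) {
  lapply(params, function(p) {
    prof <- render_profile(make_schedule(p), p, stage, cfg)
    normalize_length(prof, N = N)
  })
}

# One replicate of the isomorphic-digit recovery experiment: simulate
# n_specimens autopods across the window, correlate, aggregate, and return
# the top-ranked digit pair(s).
isomorphy_rep <- function(counts, noise_sd, seed, n_specimens = 18,
                          species = "bearded_dragon", limb = "forelimb") {
  set.seed(seed)
  stages <- snap_stage(seq(29, 36, length.out = n_specimens))
  cfg <- render_config(noise_sd = noise_sd, seed = NULL)
  params <- limb_params(counts, limb = limb)
  mats <- lapply(stages, function(s) {
    pairwise_correlation(limb_profiles(params, s, cfg))
  })
  summ <- aggregate_correlations(mats, limb = limb)
  rank_isomorphic(summ, load_phenotypes(), species, limb)
}
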