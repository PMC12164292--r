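test_that("joint schedules follow linear spacing in the window", {
  d <- digit_id("forelimb", 3)
  expect_equal(make_schedule(clock_params(d, 1))$formation_stages, 29)
  expect_equal(make_schedule(clock_params(d, 5))$formation_stages,
               c(29, 30.75, 32.5, 34.25, 36))
  s2 <- make_schedule(clock_params(d, 2))$formation_stages
  s5 <- make_schedule(clock_params(d, 5))$formation_stages
  expect_equal(diff(s2), 7)
  expect_equal(unique(round(diff(s5), 10)), 1.75)
  expect_error(clock_params(d, 0), "integer >= 1")
})

test_that("clawless digits continue the ancestral spacing past the window", {
  d <- digit_id("hindlimb", 4)
  p <- clock_params(d, 6, claw = FALSE, p_window = 5)
  st <- make_schedule(p)$formation_stages
  expect_length(st, 6)
  expect_equal(diff(st), rep(1.75, 5))
  expect_gt(st[6], 36)
  expect_error(clock_params(d, 5, claw = TRUE, p_window = 4), "p_window")
})

test_that("phase is zero at joint formation and shared by isomorphic digits", {
  d <- digit_id("forelimb", 2)
  expect_equal(phase_at(clock_params(d, 4), 29)$phi, 0)
  for (P in 2:6) {
    p <- clock_params(d, P, claw = FALSE, p_window = P)
    st <- make_schedule(p)$formation_stages
    for (s in st) {
      phi <- phase_at(p, s)$phi
      expect_lt(min(phi, 1 - phi), 1e-9)
    }
  }
  # equal P, any stage within the window: identical phase
  a <- clock_params(digit_id("forelimb", 2), 3)
  b <- clock_params(digit_id("forelimb", 5), 3)
  for (s in seq(29, 36, by = 0.5)) {
    expect_identical(phase_at(a, s)$phi, phase_at(b, s)$phi)
  }
  # clawed clocks halt after the transition
  expect_equal(phase_at(a, 37)$phi, 0)
  expect_error(phase_at(a, 28), "before the window")
})

test_that("render_profile is seeded-deterministic and matches ground truth", {
  d <- digit_id("forelimb", 4)
  p <- clock_params(d, 5)
  sc <- make_schedule(p)
  cfg <- render_config(profile_length_px = 300, noise_sd = 0.1, seed = 11)
  p1 <- render_profile(sc, p, 33, cfg)
  p2 <- render_profile(sc, p, 33, cfg)
  expect_identical(p1$samples, p2$samples)

  # noise 0, just after joint 1: one interior domain plus the gated tip
  cfg0 <- render_config(profile_length_px = 300, noise_sd = 0, seed = 1)
  pr <- render_profile(make_schedule(clock_params(d, 5)),
                       clock_params(d, 5), 29, cfg0)
  gt <- attr(pr, "ground_truth")
  expect_equal(gt$most_recent_joint, 1)
  expect_true(gt$tip_on)
  dom <- detect_domains(normalize_length(pr, 500))
  expect_equal(sum(dom$is_tip), 1)
  expect_equal(sum(!dom$is_tip), 1)
})

test_that("isomorphic digits give correlation 1 on noise-free profiles", {
  a <- clock_params(digit_id("forelimb", 2), 3)
  b <- clock_params(digit_id("forelimb", 5), 3)
  for (s in c(29, 31.5, 34, 36)) {
    pa <- render_profile(make_schedule(a), a, s,
                         render_config(profile_length_px = 200,
                                       noise_sd = 0, seed = 1))
    pb <- render_profile(make_schedule(b), b, s,
                         render_config(profile_length_px = 700,
                                       noise_sd = 0, seed = 2))
    r <- stats::cor(normalize_length(pa, 500)$samples,
                    normalize_length(pb, 500)$samples)
    expect_gt(r, 0.999)
  }
})

test_that("Beer-Lambert mixing is log-linear in OD", {
  d <- digit_id("forelimb", 3)
  p <- clock_params(d, 2)
  mk <- function(amp) {
    cfg <- render_config(profile_length_px = 120, noise_sd = 0, seed = 5,
                         bump_amp = amp)
    render_autopod_image(list(p), 36, cfg)
  }
  s1 <- mk(0.4); s2 <- mk(0.8)
  bg <- render_config()$background_rgb
  for (ch in 1:3) {
    l1 <- log10(s1$image[, , ch] / bg[ch])
    l2 <- log10(s2$image[, , ch] / bg[ch])
    expect_equal(l2, 2 * l1, tolerance = 1e-9)
  }
})

test_that("simulate_calls encodes the three digit archetypes", {
  arch <- c(I = "clawed", II = "clawless_persistent", III = "reduced")
  calls <- simulate_calls(arch, seed = 3)
  c1 <- subset(calls, digit == "I" & gene == "Sox9")
  expect_true(all(c1$state[c1$stage < 36]))
  expect_true(all(!c1$state[c1$stage >= 36]))
  b1 <- subset(calls, digit == "I" & gene == "Bambi")
  expect_equal(min(b1$stage[b1$state]), 36)

  c2 <- subset(calls, digit == "II" & gene == "Sox9")
  expect_true(c2$state[c2$stage == 37])
  expect_true(all(!subset(calls, digit == "II" &
                            gene %in% c("Bambi", "Msx1", "Msx2"))$state))

  c3 <- subset(calls, digit == "III" & gene == "Sox9")
  expect_true(all(!c3$state[c3$stage >= 34]))

  # determinism at mislabel 0
  expect_identical(simulate_calls(arch, seed = 3), simulate_calls(arch, seed = 3))
  # state FALSE implies location absent
  expect_true(all(calls$location[!calls$state] == "absent"))
})

test_that("simulate_tpm plants effects in single digit groups", {
  tpm <- simulate_tpm(n_genes = 60, n_planted = 4, effect_tpm = 100,
                      cv = 0.05, seed = 9)
  gt <- attr(tpm, "ground_truth")
  expect_length(gt$planted, 4)
  groups <- tpm_groups(colnames(tpm))
  for (k in seq_along(gt$planted)) {
    v <- tpm[gt$planted[k], ]
    in_mean <- mean(v[groups == gt$group[k]])
    out_mean <- mean(v[groups != gt$group[k]])
    expect_gt(in_mean - out_mean, 50)
  }
  # null matrix: no between-digit structure beyond noise
  null <- simulate_tpm(n_genes = 200, n_planted = 0, cv = 0.05, seed = 2)
  gm <- sapply(unique(groups), function(g) {
    rowMeans(null[, tpm_groups(colnames(null)) == g])
  })
  rel_spread <- (apply(gm, 1, max) - apply(gm, 1, min)) / rowMeans(gm)
  expect_lt(stats::median(rel_spread), 0.2)
  expect_identical(simulate_tpm(n_genes = 50, seed = 4),
                   simulate_tpm(n_genes = 50, seed = 4))
})
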