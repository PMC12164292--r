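nprof <- function(samples) {
  structure(list(samples = samples, N = length(samples), meta = list()),
            class = "normalized_profile")
}

test_that("detect_domains finds threshold runs and flags the tip", {
  # flat / all-subthreshold profiles give no domains
  expect_equal(nrow(detect_domains(nprof(rep(0, 500)))), 0)

  x <- seq(0, 1, length.out = 500)
  bump <- function(c0) 0.8 * exp(-(x - c0)^2 / (2 * 0.02^2))
  y <- bump(0.02) + bump(0.3) + bump(0.6) + bump(0.9)
  dom <- detect_domains(nprof(y))
  expect_equal(sum(dom$is_tip), 1)
  expect_equal(sum(!dom$is_tip), 3)

  # a run shorter than min_len is discarded: a 1%-wide spike
  spike <- rep(0, 500)
  spike[250:253] <- 1
  spike[100:160] <- 1  # the surviving wide domain
  dom2 <- detect_domains(nprof(spike))
  expect_equal(nrow(dom2), 1)
  expect_gt(dom2$start, 0.15)
})

test_that("score_joints counts non-tip domains and unstained gaps", {
  expect_equal(score_joints(data.frame(start = numeric(0), end = numeric(0),
                                       peak_od = numeric(0),
                                       is_tip = logical(0))),
               list(most_recent_joint = 0L, phalanx_elements = 0L))

  # one joint plus tip: 1 joint, 1 element (the gap between tip and joint)
  d1 <- data.frame(start = c(0, 0.4), end = c(0.05, 0.5),
                   peak_od = 0.8, is_tip = c(TRUE, FALSE))
  expect_equal(score_joints(d1),
               list(most_recent_joint = 1L, phalanx_elements = 1L))

  # hand-built oracle: count gaps between/distal to non-tip domains
  d5 <- data.frame(
    start = c(0, 0.14, 0.31, 0.47, 0.64, 0.80),
    end = c(0.05, 0.19, 0.36, 0.52, 0.69, 0.85),
    peak_od = 0.8,
    is_tip = c(TRUE, rep(FALSE, 5))
  )
  s5 <- score_joints(d5)
  expect_equal(s5$most_recent_joint, 5L)
  expect_equal(s5$phalanx_elements, 5L)

  # abutting tip and first joint: the distal gap disappears
  d_ab <- data.frame(start = c(0, 0.05), end = c(0.05, 0.2),
                     peak_od = 0.8, is_tip = c(TRUE, FALSE))
  expect_equal(score_joints(d_ab)$phalanx_elements, 0L)

  over <- data.frame(start = c(0.1, 0.15), end = c(0.2, 0.3),
                     peak_od = 0.8, is_tip = FALSE)
  expect_error(score_joints(over), "overlap")
})

test_that("phalanx elements never exceed joints + 1 on rendered digits", {
  set.seed(13)
  for (i in 1:25) {
    P <- sample(1:6, 1)
    stage <- snap_stage(stats::runif(1, 29, 36))
    p <- clock_params(digit_id("forelimb", 1), P, claw = FALSE, p_window = P)
    cfg <- render_config(profile_length_px = 300, noise_sd = 0.1,
                         seed = NULL)
    prof <- render_profile(make_schedule(p), p, stage, cfg)
    sc <- score_joints(detect_domains(normalize_length(prof, 500)))
    expect_lte(sc$phalanx_elements, sc$most_recent_joint + 1)
  }
})

test_that("build_joint_table lays out stages by digit with QC warnings", {
  one <- build_joint_table(data.frame(stage = 30,
                                      digit = c("I", "II", "III", "IV", "V"),
                                      most_recent_joint = 1:5))
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one[1, -1], use.names = FALSE), 1:5)

  expect_error(build_joint_table(data.frame(stage = c(30, 30),
                                            digit = "I",
                                            most_recent_joint = 1:2)),
               "duplicate")

  expect_warning(build_joint_table(data.frame(stage = c(30, 31),
                                              digit = "I",
                                              most_recent_joint = c(2, 1))),
                 "decreases")
})

test_that("a full simulated hindlimb series ends at the phalanx counts", {
  counts <- c(2, 3, 4, 5, 4)  # ancestor hindlimb
  params <- limb_params(counts, limb = "hindlimb")
  cfg <- render_config(noise_sd = 0, seed = NULL, profile_length_px = 400)
  set.seed(3)
  rows <- list()
  for (s in 29:36) {
    for (i in seq_along(params)) {
      prof <- render_profile(make_schedule(params[[i]]), params[[i]], s, cfg)
      sc <- score_joints(detect_domains(normalize_length(prof, 500)))
      rows[[length(rows) + 1]] <- data.frame(
        stage = s, digit = digit_roman(i),
        most_recent_joint = sc$most_recent_joint)
    }
  }
  tab <- build_joint_table(do.call(rbind, rows))
  # at the window opening only the metapodial-phalangeal joint has formed
  expect_equal(unlist(tab[tab$stage == 29, -1], use.names = FALSE),
               rep(1L, 5))
  # by the window closing every digit has formed all its joints
  expect_equal(unlist(tab[tab$stage == 36, -1], use.names = FALSE),
               as.integer(counts))
})

test_that("classify_cyclical matches the run-length oracle", {
  # the published example series: digit II, stages 30-37
  ex <- classify_cyclical(30:37, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                                   TRUE, FALSE))
  expect_equal(ex$class, "cyclical")
  expect_equal(ex$n_on_runs, 3L)

  expect_equal(classify_cyclical(30:33, rep(TRUE, 4))$class, "constitutive")
  expect_equal(classify_cyclical(30:34,
                                 c(TRUE, TRUE, FALSE, FALSE, FALSE))$class,
               "monotone_off")
  expect_equal(classify_cyclical(30:32, rep(FALSE, 3))$class, "silent")

  expect_error(classify_cyclical(30:31, c(TRUE, FALSE)), ">= 3 stages")
  expect_error(classify_cyclical(c(30, 30, 31), rep(TRUE, 3)),
               "strictly increasing")

  # exhaustive: all 256 length-8 series against the brute-force oracle
  for (k in 0:255) {
    state <- as.logical(bitwAnd(bitwShiftR(k, 0:7), 1))
    got <- classify_cyclical(30:37, state)
    want <- cyclic_oracle(state)
    expect_equal(got$class, want$class)
    expect_equal(got$n_on_runs, want$n_on_runs)
  }
})
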