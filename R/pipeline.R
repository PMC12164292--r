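# End-to-end pipeline plumbing: a single config object, a simulate command
# that writes a fully ground-truthed synthetic dataset to disk, and a run
# command that executes extract -> normalize -> correlate -> score ->
# transition -> screen over on-disk inputs.  Everything is deterministic
# given the config seeds; a MANIFEST file lists each artifact with the seed
# that produced it.

#' Pipeline configuration
#'
#' @param out_dir Output directory.
#' @param species Species label for simulated specimens.
#' @param limb Limb label.
#' @param phalanx_counts Per-digit phalanx numbers for the simulated limb.
#' @param claws Per-digit claw flags (same length).
#' @param stages Specimen stages, one simulated autopod per entry.
#' @param window A [clock_window()].
#' @param render A [render_config()].
#' @param stain A [stain_model()].
#' @param n_resample Profile resample length for correlation (default 500).
#' @param screen A [screen_thresholds()].
#' @param n_genes,n_planted,effect_tpm TPM simulation settings.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param stages_enabled Which analysis stages `cmd_run()` executes.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            species = "bearded_dragon",
                            limb = "forelimb",
                            phalanx_counts = c(2, 3, 4, 5, 3),
                            claws = rep(TRUE, length(phalanx_counts)),
                            stages = snap_stage(seq(29, 36,
                                                    length.out = 18)),
                            window = clock_window(),
                            render = render_config(seed = NULL),
                            stain = stain_model(),
                            n_resample = 500,
                            screen = screen_thresholds(),
                            n_genes = 500, n_planted = 5, effect_tpm = 100,
                            seed = 1L,
                            stages_enabled = c("profile", "correlate",
                                               "score", "transition",
                                               "screen")) {
  stopifnot(length(claws) == length(phalanx_counts))
  structure(list(out_dir = out_dir, species = species, limb = limb,
                 phalanx_counts = phalanx_counts, claws = claws,
                 stages = stages, window = window, render = render,
                 stain = stain, n_resample = n_resample, screen = screen,
                 n_genes = n_genes, n_planted = n_planted,
                 effect_tpm = effect_tpm, seed = as.integer(seed),
                 stages_enabled = stages_enabled),
            class = "pipeline_config")
}

log_stage <- function(...) {
  message(sprintf(...))
}

digit_params_of <- function(config) {
  lapply(seq_along(config$phalanx_counts), function(i) {
    clock_params(digit_id(config$limb, i), config$phalanx_counts[i],
                 window = config$window, claw = config$claws[i])
  })
}

#' Simulate a synthetic dataset on disk
#'
#' Writes, under `config$out_dir`: one PPM image plus polyline and
#' ground-truth CSVs per specimen, a marker-call table, a TPM matrix, and a
#' MANIFEST listing every artifact with the seed that produced it.
#'
#' @param config A [pipeline_config()].
#' @return The manifest data frame, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$out_dir, 2) != 0) {
    stop("output directory is not writable: ", config$out_dir, call. = FALSE)
  }
  manifest <- data.frame(file = character(0), seed = integer(0))
  add <- function(f, s) {
    manifest <<- rbind(manifest, data.frame(file = f, seed = s))
  }
  if (!length(config$stages)) {
    warning("empty specimen stage list: writing an empty dataset",
            call. = FALSE)
  }
  dparams <- digit_params_of(config)
  for (k in seq_along(config$stages)) {
    seed_k <- config$seed + k
    cfg <- config$render
    cfg$seed <- seed_k
    scene <- render_autopod_image(dparams, config$stages[k], cfg)
    base <- sprintf("specimen_%02d", k)
    write_ppm(scene$image, file.path(config$out_dir,
                                     paste0(base, ".ppm")))
    add(paste0(base, ".ppm"), seed_k)
    for (i in seq_along(scene$polylines)) {
      f <- sprintf("%s_digit%s_line.csv", base, digit_roman(i))
      write_polyline(scene$polylines[[i]], file.path(config$out_dir, f))
      add(f, seed_k)
      gtf <- sprintf("%s_digit%s_truth.csv", base, digit_roman(i))
      gt <- scene$ground_truth[[i]]
      utils::write.csv(
        data.frame(stage = config$stages[k],
                   most_recent_joint = gt$most_recent_joint,
                   tip_on = gt$tip_on,
                   joint_centers = paste(signif(gt$joint_centers, 8),
                                         collapse = ";")),
        file.path(config$out_dir, gtf), row.names = FALSE)
      add(gtf, seed_k)
    }
  }
  arch <- ifelse(config$claws, "clawed", "clawless_persistent")
  names(arch) <- digit_roman(seq_along(arch))
  calls <- simulate_calls(arch, species = config$species, limb = config$limb,
                          window = config$window, seed = config$seed + 1000L)
  utils::write.csv(calls, file.path(config$out_dir, "calls.csv"),
                   row.names = FALSE)
  add("calls.csv", config$seed + 1000L)
  tpm <- simulate_tpm(n_genes = config$n_genes, n_planted = config$n_planted,
                      effect_tpm = config$effect_tpm,
                      seed = config$seed + 2000L)
  write_tpm(tpm, file.path(config$out_dir, "tpm.tsv"))
  add("tpm.tsv", config$seed + 2000L)
  manifest <- manifest[order(manifest$file), ]
  utils::write.csv(manifest, file.path(config$out_dir, "MANIFEST"),
                   row.names = FALSE, quote = FALSE)
  log_stage("simulate: wrote %d artifacts to %s", nrow(manifest),
            config$out_dir)
  invisible(manifest)
}

#' Run the analysis pipeline over a simulated or user-provided dataset
#'
#' Executes, as enabled in `config$stages_enabled`: profile extraction from
#' images and polylines, length normalization and correlation aggregation,
#' joint scoring, transition calling, and the TPM screen. Reports are
#' written as CSV/TSV next to the inputs; a machine-readable run summary
#' goes to `run_summary.json`.
#'
#' @param config A [pipeline_config()] whose `out_dir` holds the inputs.
#' @return List of in-memory results, invisibly.
#' @export
cmd_run <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dirp <- config$out_dir
  enabled <- config$stages_enabled
  results <- list()
  summary <- list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (any(c("profile", "correlate", "score") %in% enabled)) {
    images <- sort(list.files(dirp, pattern = "^specimen_[0-9]+\\.ppm$"))
    profiles <- list()
    if ("profile" %in% enabled) {
      run_stage("profile", function() {
        for (img_f in images) {
          base <- sub("\\.ppm$", "", img_f)
          img <- read_ppm(file.path(dirp, img_f))
          lines_f <- sort(list.files(
            dirp, pattern = paste0("^", base, "_digit[IV]+_line\\.csv$")))
          if (!length(lines_f)) {
            stop("no polyline sidecars found for ", img_f)
          }
          truth <- utils::read.csv(file.path(
            dirp, sub("_line", "_truth", lines_f[1])))
          for (lf in lines_f) {
            dlab <- sub(".*_digit([IV]+)_line\\.csv$", "\\1", lf)
            line <- read_polyline(file.path(dirp, lf))
            prof <- extract_profile(img, line, config$stain,
                                    meta = list(specimen = base,
                                                stage = truth$stage[1],
                                                limb = config$limb,
                                                digit = dlab))
            write_profile(prof, file.path(
              dirp, sprintf("%s_digit%s_profile.csv", base, dlab)))
            profiles[[paste(base, dlab)]] <<- prof
          }
        }
        log_stage("profile: extracted %d profiles from %d images",
                  length(profiles), length(images))
      })
    } else {
      prof_files <- sort(list.files(dirp,
                                    pattern = "_profile\\.csv$"))
      for (pf in prof_files) {
        profiles[[pf]] <- read_profile(file.path(dirp, pf))
      }
    }
    results$profiles <- profiles

    if ("correlate" %in% enabled && length(profiles)) {
      run_stage("correlate", function() {
        specs <- unique(vapply(profiles,
                               function(p) p$meta$specimen, character(1)))
        mats <- lapply(specs, function(s) {
          ps <- Filter(function(p) identical(p$meta$specimen, s), profiles)
          pairwise_correlation(lapply(ps, normalize_length,
                                      N = config$n_resample))
        })
        summ <- aggregate_correlations(mats, limb = config$limb)
        utils::write.csv(summ, file.path(dirp, "correlation_summary.csv"),
                         row.names = FALSE)
        results$correlation <<- summ
        log_stage("correlate: %d specimens, %d digit pairs", length(mats),
                  nrow(summ))
      })
    }

    if ("score" %in% enabled && length(profiles)) {
      run_stage("score", function() {
        rows <- lapply(profiles, function(p) {
          sc <- score_joints(detect_domains(normalize_length(
            p, N = config$n_resample)))
          data.frame(specimen = p$meta$specimen, stage = p$meta$stage,
                     digit = p$meta$digit,
                     most_recent_joint = sc$most_recent_joint,
                     phalanx_elements = sc$phalanx_elements)
        })
        scored <- do.call(rbind, rows)
        utils::write.csv(scored, file.path(dirp, "joint_scores.csv"),
                         row.names = FALSE)
        results$joint_scores <<- scored
        log_stage("score: %d digit scores", nrow(scored))
      })
    }
  }

  if ("transition" %in% enabled &&
      file.exists(file.path(dirp, "calls.csv"))) {
    run_stage("transition", function() {
      calls <- utils::read.csv(file.path(dirp, "calls.csv"))
      tcs <- lapply(split(calls, calls$digit), call_transition,
                    s_off = config$window$s_off)
      rep <- do.call(rbind, lapply(tcs, function(x) {
        data.frame(species = config$species, limb = config$limb,
                   digit = x$digit, class = x$class,
                   transition_stage = x$transition_stage,
                   evidence = as.character(jsonlite::toJSON(
                     x$evidence, auto_unbox = TRUE, digits = NA)))
      }))
      utils::write.csv(rep, file.path(dirp, "transition_report.csv"),
                       row.names = FALSE)
      results$transitions <<- tcs
      log_stage("transition: %d digits called", length(tcs))
    })
  }

  if ("screen" %in% enabled && file.exists(file.path(dirp, "tpm.tsv"))) {
    run_stage("screen", function() {
      tpm <- read_tpm(file.path(dirp, "tpm.tsv"))
      res <- screen_tpm(tpm, config$screen)
      utils::write.table(res, file.path(dirp, "screen_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$screen <<- res
      log_stage("screen: %d genes, %d candidates", nrow(res),
                sum(res$candidate))
    })
  }

  summary$stages <- enabled
  summary$n_profiles <- length(results$profiles)
  summary$n_candidates <- if (!is.null(results$screen)) {
    sum(results$screen$candidate)
  } else NA
  jsonlite::write_json(summary, file.path(dirp, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` and `run`, both driven by a JSON config file
#' whose keys mirror [pipeline_config()] arguments (`out_dir`, `species`,
#' `limb`, `phalanx_counts`, `claws`, `stages`, `seed`, ...); CLI flags of
#' the form `--key=value` override config entries.
#'
#' @param args Character vector of CLI arguments (default: the actual
#'   command line).
#' @return Exit status, invisibly.
#' @export
dcp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: digitclock <simulate|run> --config=FILE [--key=value ...]"
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  if (!cmd %in% c("simulate", "run")) {
    stop("unknown subcommand '", cmd, "'; ", usage, call. = FALSE)
  }
  opts <- list()
  for (a in args[-1]) {
    if (!grepl("^--[^=]+=", a)) stop("bad argument: ", a, call. = FALSE)
    key <- sub("^--([^=]+)=.*$", "\\1", a)
    val <- sub("^--[^=]+=", "", a)
    opts[[key]] <- val
  }
  cfg_list <- list()
  if (!is.null(opts$config)) {
    cfg_list <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    opts$config <- NULL
  }
  for (k in names(opts)) {
    num <- suppressWarnings(as.numeric(opts[[k]]))
    cfg_list[[k]] <- if (!is.na(num)) num else opts[[k]]
  }
  # convenience renderer overrides that are awkward to express in JSON
  render <- render_config(
    profile_length_px = cfg_list$profile_length_px,
    noise_sd = if (is.null(cfg_list$noise_sd)) 0.1 else cfg_list$noise_sd,
    seed = NULL
  )
  allowed <- names(formals(pipeline_config))
  cfg_list <- cfg_list[names(cfg_list) %in% allowed]
  cfg_list$render <- render
  config <- do.call(pipeline_config, cfg_list)
  switch(cmd, simulate = cmd_simulate(config), run = cmd_run(config))
  invisible(0L)
}
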