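# Phase correlation of digit stain profiles.
#
# Digits of one autopod differ in length, so profiles are first linearly
# "stretched" onto a common number of points of normalized arclength; the
# per-autopod Pearson correlation matrix between digit profiles is then
# averaged across replicate specimens.  Under the digit-clock model,
# isomorphic digits (equal final phalanx number) are at the same phase of
# the expression cycle at every stage, and so show the strongest mean
# correlation.

#' Length-normalize an intensity profile
#'
#' Linear interpolation of the raw profile onto `N` equally spaced points
#' of normalized arclength in `[0, 1]` (distal to proximal); endpoints are
#' preserved.
#'
#' @param profile An [intensity_profile()].
#' @param N Number of resample points (default 500, chosen inside the
#'   184-1195 range of raw digit lengths).
#' @return A `normalized_profile`: list with `samples` (length `N`), `N`,
#'   `meta`.
#' @export
normalize_length <- function(profile, N = 500) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (N < 8) stop("N must be >= 8", call. = FALSE)
  x <- seq(0, 1, length.out = profile$n_raw)
  out <- stats::approx(x, profile$samples, xout = seq(0, 1, length.out = N))$y
  structure(list(samples = out, N = as.integer(N), meta = profile$meta),
            class = "normalized_profile")
}

digit_label_of <- function(p) {
  d <- p$meta$digit
  if (is.null(d)) NA_character_ else if (is.character(d)) d else digit_roman(d)
}

#' Pairwise Pearson correlation between digit profiles of one autopod
#'
#' @param profiles List of >= 2 `normalized_profile`s with equal `N`,
#'   labeled by their `meta$digit`.
#' @return Symmetric correlation matrix with unit diagonal, dimnames set to
#'   digit labels. Zero-variance profiles are excluded from pairing: their
#'   rows/columns are `NA` and a warning is raised.
#' @export
pairwise_correlation <- function(profiles) {
  if (length(profiles) < 2) stop(">= 2 profiles required", call. = FALSE)
  Ns <- vapply(profiles, function(p) p$N, integer(1))
  if (length(unique(Ns)) != 1) {
    stop("all profiles must share the same N", call. = FALSE)
  }
  labs <- vapply(profiles, digit_label_of, character(1))
  if (anyNA(labs)) labs[is.na(labs)] <- paste0("p", which(is.na(labs)))
  mat <- sapply(profiles, function(p) p$samples)
  vars <- apply(mat, 2, stats::var)
  r <- matrix(NA_real_, length(profiles), length(profiles),
              dimnames = list(labs, labs))
  ok <- vars > 0
  if (any(!ok)) {
    warning("zero-variance profile(s) excluded from correlation: ",
            paste(labs[!ok], collapse = ", "), call. = FALSE)
  }
  if (sum(ok) >= 2) {
    r[ok, ok] <- stats::cor(mat[, ok, drop = FALSE])
  }
  diag(r)[ok] <- 1
  r
}

#' Aggregate per-specimen correlation matrices
#'
#' Arithmetic mean of each digit pair's correlation across replicate
#' specimens, pairwise-complete: a pair contributes wherever both digits
#' were measured, and the per-pair specimen count is reported.
#'
#' @param matrices List of correlation matrices from
#'   [pairwise_correlation()], one per specimen, with digit-labeled
#'   dimnames.
#' @param limb Optional limb label carried into the summary.
#' @return A `correlation_summary` data frame: `limb`, `digit_a`,
#'   `digit_b`, `mean_r`, `n` (one row per unordered pair; `mean_r` is `NA`
#'   when `n = 0`).
#' @export
aggregate_correlations <- function(matrices, limb = NA_character_) {
  if (!length(matrices)) stop(">= 1 specimen required", call. = FALSE)
  digits <- sort(unique(unlist(lapply(matrices, rownames))))
  pairs <- utils::combn(digits, 2)
  out <- data.frame(limb = limb, digit_a = pairs[1, ], digit_b = pairs[2, ],
                    mean_r = NA_real_, n = 0L, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    rs <- unlist(lapply(matrices, function(m) {
      if (a %in% rownames(m) && b %in% rownames(m)) m[a, b] else NA_real_
    }))
    rs <- rs[!is.na(rs)]
    out$n[k] <- length(rs)
    if (length(rs)) out$mean_r[k] <- mean(rs)
  }
  class(out) <- c("correlation_summary", "data.frame")
  out
}

#' Rank digit pairs and test the isomorphy prediction
#'
#' Orders digit pairs by mean correlation and asks whether the top-ranked
#' pair is isomorphic (equal phalanx counts in the phenotype table). Exact
#' ties at the top are all reported as co-leaders.
#'
#' @param summary A [aggregate_correlations()] result.
#' @param phenotypes A `phenotype_table`.
#' @param species,limb Which phenotype rows to compare against.
#' @return List with `ranking` (the summary reordered, plus an
#'   `isomorphic` column), `top_pairs` (character vector like `"II-V"`),
#'   and `top_is_isomorphic`.
#' @export
rank_isomorphic <- function(summary, phenotypes, species, limb) {
  phen <- phenotypes[phenotypes$species == species &
                       phenotypes$limb == limb, ]
  if (!nrow(phen)) {
    stop("phenotype table does not cover ", species, "/", limb,
         call. = FALSE)
  }
  count_of <- function(lab) {
    row <- phen[phen$digit == lab, ]
    if (!nrow(row) || !row$present) NA_integer_ else row$phalanx_max
  }
  ranking <- summary[order(-summary$mean_r, na.last = TRUE), ]
  pa <- vapply(ranking$digit_a, count_of, integer(1))
  pb <- vapply(ranking$digit_b, count_of, integer(1))
  ranking$isomorphic <- !is.na(pa) & !is.na(pb) & pa == pb
  top_r <- max(ranking$mean_r, na.rm = TRUE)
  top <- ranking[!is.na(ranking$mean_r) & ranking$mean_r == top_r, ]
  list(
    ranking = ranking,
    top_pairs = paste(top$digit_a, top$digit_b, sep = "-"),
    top_is_isomorphic = all(top$isomorphic)
  )
}
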