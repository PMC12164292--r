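# Candidate screen over digit-tip TPM matrices.
#
# A deliberately minimal reconstruction of the filtering logic used for
# digit-tip bulk RNA-seq: each digit group is contrasted against all other
# digits, significance comes from a two-sided Welch t-test on
# log2(TPM + pseudocount), p-values are Benjamini-Hochberg adjusted across
# the whole gene x contrast family, and candidates must clear the adjusted-p,
# |L2FC| and between-group TPM-difference cutoffs jointly.  This replaces a
# limma-voom pipeline by design: the object of interest is the screen's
# logic, not the variance model.

#' Screen thresholds
#'
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @param min_l2fc Minimum |log2 fold change| (default 1).
#' @param min_tpm_diff Minimum between-group mean TPM difference
#'   (default 25; the rule is strict: difference must exceed it).
#' @param pseudocount TPM pseudocount for logs and fold changes (default 1).
#' @return A `screen_thresholds` object.
#' @export
screen_thresholds <- function(alpha = 0.05, min_l2fc = 1, min_tpm_diff = 25,
                              pseudocount = 1) {
  vals <- c(alpha, min_l2fc, min_tpm_diff, pseudocount)
  if (any(vals <= 0)) stop("all thresholds must be positive", call. = FALSE)
  structure(list(alpha = alpha, min_l2fc = min_l2fc,
                 min_tpm_diff = min_tpm_diff, pseudocount = pseudocount),
            class = "screen_thresholds")
}

#' Parse digit groups from TPM sample labels
#'
#' Labels follow `digit<group>_rep<r>`, e.g. `digitII_rep3`.
#'
#' @param labels Character vector of sample labels.
#' @return Character vector of group names.
#' @export
tpm_groups <- function(labels) {
  m <- regmatches(labels, regexec("^digit([IVX]+)_rep([0-9]+)$", labels))
  bad <- lengths(m) != 3
  if (any(bad)) {
    stop("unparseable sample label(s): ", paste(labels[bad], collapse = ", "),
         call. = FALSE)
  }
  vapply(m, `[`, character(1), 2)
}

check_tpm <- function(tpm) {
  if (is.null(dimnames(tpm)) || is.null(rownames(tpm)) ||
      is.null(colnames(tpm))) {
    stop("TPM matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (any(tpm < 0)) stop("TPM values must be >= 0", call. = FALSE)
  groups <- tpm_groups(colnames(tpm))
  if (any(table(groups) < 2)) {
    stop("every digit group needs >= 2 replicates", call. = FALSE)
  }
  groups
}

# Vectorized Welch t statistics over genes for one contrast.
# Returns two-sided p-values; genes with zero variance in both groups get
# p = 1 and a QC flag.
welch_p <- function(logm, in_group) {
  x <- logm[, in_group, drop = FALSE]
  y <- logm[, !in_group, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, 0, (mx - my) / sqrt(se2))
  df <- ifelse(degenerate, 1,
               se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1))))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df))
  list(p = p, degenerate = degenerate)
}

#' Contrast statistics for one gene and digit group
#'
#' `l2fc = log2((mean_group + pc) / (mean_rest + pc))`; the p-value comes
#' from a two-sided Welch t-test on `log2(TPM + pc)`. When both groups have
#' zero within-group variance the p-value is undefined and reported as 1
#' with `qc_degenerate = TRUE`.
#'
#' @param tpm TPM matrix (genes x samples, labeled columns).
#' @param gene Gene rowname.
#' @param group Digit group label (e.g. `"II"`).
#' @param pseudocount TPM pseudocount (default 1).
#' @return List with `l2fc`, `p`, `qc_degenerate`.
#' @export
contrast_stats <- function(tpm, gene, group, pseudocount = 1) {
  groups <- check_tpm(tpm)
  if (!gene %in% rownames(tpm)) stop("unknown gene: ", gene, call. = FALSE)
  if (!group %in% groups) stop("unknown group: ", group, call. = FALSE)
  v <- tpm[gene, , drop = FALSE]
  in_group <- groups == group
  l2fc <- log2((mean(v[, in_group]) + pseudocount) /
                 (mean(v[, !in_group]) + pseudocount))
  w <- welch_p(log2(v + pseudocount), in_group)
  list(l2fc = unname(l2fc), p = unname(w$p),
       qc_degenerate = unname(w$degenerate))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, computes `q_i = min_{j >= i} (m * p_j / j)`
#' clipped at 1, and maps the result back to the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  ord <- order(pvals)
  q <- pvals[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Run the per-digit candidate screen
#'
#' For every gene and every digit-vs-rest contrast, computes L2FC and a
#' Welch p-value on log2(TPM + pseudocount); BH-adjusts across the full
#' gene x contrast family; keeps, per gene, the contrast with the smallest
#' raw p. A gene is a candidate when its best contrast clears the adjusted
#' p-value cutoff, the |L2FC| cutoff, and the gene's maximum pairwise
#' between-group mean TPM difference exceeds the TPM cutoff.
#'
#' @param tpm TPM matrix (genes x samples, labeled columns).
#' @param thresholds A [screen_thresholds()].
#' @return A `screen_result` data frame: `gene`, `best_contrast`, `l2fc`,
#'   `p`, `p_adj`, `max_tpm_diff`, `qc_degenerate`, `candidate`.
#' @export
screen_tpm <- function(tpm, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  groups <- check_tpm(tpm)
  glabs <- unique(groups)
  pc <- thresholds$pseudocount
  logm <- log2(tpm + pc)
  genes <- rownames(tpm)
  n_g <- length(genes)

  l2fc <- p <- matrix(NA_real_, n_g, length(glabs),
                      dimnames = list(genes, glabs))
  degen <- matrix(FALSE, n_g, length(glabs), dimnames = list(genes, glabs))
  gmeans <- matrix(NA_real_, n_g, length(glabs),
                   dimnames = list(genes, glabs))
  for (g in glabs) gmeans[, g] <- rowMeans(tpm[, groups == g, drop = FALSE])
  for (g in glabs) {
    in_group <- groups == g
    l2fc[, g] <- log2((gmeans[, g] + pc) /
                        (rowMeans(tpm[, !in_group, drop = FALSE]) + pc))
    w <- welch_p(logm, in_group)
    p[, g] <- w$p
    degen[, g] <- w$degenerate
  }
  p_adj <- matrix(bh_adjust(as.numeric(p)), n_g, length(glabs),
                  dimnames = dimnames(p))
  best <- glabs[apply(p, 1, which.min)]
  bi <- cbind(seq_len(n_g), match(best, glabs))
  # max pairwise |difference| of group means is just range width
  cols <- lapply(seq_len(ncol(gmeans)), function(j) gmeans[, j])
  max_diff <- do.call(pmax, cols) - do.call(pmin, cols)
  res <- data.frame(
    gene = genes,
    best_contrast = best,
    l2fc = l2fc[bi],
    p = p[bi],
    p_adj = p_adj[bi],
    max_tpm_diff = max_diff,
    qc_degenerate = degen[bi],
    stringsAsFactors = FALSE
  )
  res$candidate <- res$p_adj < thresholds$alpha &
    abs(res$l2fc) >= thresholds$min_l2fc &
    res$max_tpm_diff > thresholds$min_tpm_diff
  rownames(res) <- NULL
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Write a TPM matrix as TSV
#'
#' @param tpm TPM matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm <- function(tpm, path) {
  df <- data.frame(gene = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TPM matrix written by [write_tpm()]
#'
#' @param path Path to the TSV.
#' @return Numeric TPM matrix.
#' @export
read_tpm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
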