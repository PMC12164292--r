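# Amniote digit phenotype table: per (species, limb, digit) phalanx counts,
# claw presence and digit presence for the reconstructed ancestral amniote
# autopod and the 13 study species.  The table is shipped as a versioned CSV
# inside the package and validated on load.
#
# Conventions:
#   * digits are labeled I-V anterior to posterior;
#   * lost digits are kept as rows with present = FALSE and zero phalanges;
#   * digits with intraspecifically variable phalanx numbers (soft-shelled
#     turtle digits IV and V) carry a [phalanx_min, phalanx_max] range;
#   * records whose published description is incomplete (e.g. the rhea wing)
#     are flagged provisional = TRUE.

.pheno_cols <- c("species", "limb", "digit", "phalanx_min", "phalanx_max",
                 "claw", "present", "provisional")

#' Load the amniote digit phenotype table
#'
#' Reads and validates the packaged phenotype table: one row per
#' (species, limb, digit) with the phalanx count (a `[min, max]` range for
#' variable digits), claw presence, and digit presence. Covers the inferred
#' ancestral amniote plus the 13 study species, both limbs, digits I-V.
#'
#' @param path Path to a phenotype CSV. Defaults to the packaged table.
#' @return A data frame of class `phenotype_table` with columns
#'   `species`, `limb`, `digit` (Roman I-V), `digit_index`, `phalanx_min`,
#'   `phalanx_max`, `claw`, `present`, `provisional`.
#' @examples
#' phen <- load_phenotypes()
#' subset(phen, species == "ancestor" & limb == "forelimb")$phalanx_max
#' @export
load_phenotypes <- function(path = system.file("extdata", "phenotypes.csv",
                                               package = "digitclock")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("phenotype table not found at '", path, "'", call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.pheno_cols, names(tab))
  if (length(missing_cols)) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$claw <- as.logical(tab$claw)
  tab$present <- as.logical(tab$present)
  tab$provisional <- as.logical(tab$provisional)
  tab$digit_index <- digit_index(tab$digit)

  row_id <- function(i) {
    sprintf("row %d (%s/%s/digit %s)", i, tab$species[i], tab$limb[i],
            tab$digit[i])
  }
  for (i in seq_len(nrow(tab))) {
    if (!tab$limb[i] %in% c("forelimb", "hindlimb")) {
      stop("malformed phenotype table at ", row_id(i), ": bad limb '",
           tab$limb[i], "'", call. = FALSE)
    }
    if (is.na(tab$phalanx_min[i]) || is.na(tab$phalanx_max[i]) ||
        tab$phalanx_min[i] < 0 || tab$phalanx_max[i] < tab$phalanx_min[i]) {
      stop("malformed phenotype table at ", row_id(i),
           ": phalanx range must satisfy 0 <= min <= max", call. = FALSE)
    }
    if (!tab$present[i] &&
        (tab$phalanx_min[i] != 0 || tab$phalanx_max[i] != 0 || tab$claw[i])) {
      stop("malformed phenotype table at ", row_id(i),
           ": absent digits must have zero phalanges and no claw",
           call. = FALSE)
    }
  }
  # every species carries exactly 5 digits per limb
  counts <- table(tab$species, tab$limb)
  if (any(counts != 5)) {
    bad <- which(counts != 5, arr.ind = TRUE)
    stop("malformed phenotype table: ",
         rownames(counts)[bad[1, 1]], "/", colnames(counts)[bad[1, 2]],
         " has ", counts[bad[1]], " digit rows instead of 5", call. = FALSE)
  }
  if (anyDuplicated(tab[, c("species", "limb", "digit")])) {
    stop("malformed phenotype table: duplicated (species, limb, digit) rows",
         call. = FALSE)
  }
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Look up one phenotype record
#'
#' @param species Species name as used in the table.
#' @param limb `"forelimb"` or `"hindlimb"`.
#' @param digit Digit index 1-5 or Roman label.
#' @param phenotypes A `phenotype_table` (default: packaged table).
#' @return A single-row data frame.
#' @export
phenotype_record <- function(species, limb, digit,
                             phenotypes = load_phenotypes()) {
  if (is.character(digit)) digit <- digit_index(digit)
  hit <- phenotypes$species == species & phenotypes$limb == limb &
    phenotypes$digit_index == digit
  if (sum(hit) != 1) {
    stop("no phenotype record for ", species, "/", limb, "/digit ",
         digit_roman(digit), call. = FALSE)
  }
  phenotypes[hit, , drop = FALSE]
}

#' Total phalanx count of a limb
#'
#' Sums `phalanx_max` over present digits of one (species, limb). Digits with
#' variable phalanx counts contribute their maximum; when any such digit is
#' included the result carries attribute `has_variable = TRUE`.
#'
#' @inheritParams phenotype_record
#' @return Integer total, with logical attribute `has_variable`.
#' @examples
#' total_phalanges("ancestor", "forelimb")  # 17
#' @export
total_phalanges <- function(species, limb, phenotypes = load_phenotypes()) {
  rows <- phenotypes[phenotypes$species == species & phenotypes$limb == limb, ]
  if (!nrow(rows)) {
    stop("unknown species/limb: ", species, "/", limb, call. = FALSE)
  }
  rows <- rows[rows$present, ]
  total <- as.integer(sum(rows$phalanx_max))
  structure(total, has_variable = any(rows$phalanx_min < rows$phalanx_max))
}

#' Write a phenotype table back to CSV
#'
#' Serializes with the same column set as the packaged table, so a
#' write/load round trip reproduces the records exactly.
#'
#' @param phenotypes A `phenotype_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(as.data.frame(phenotypes)[, .pheno_cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
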