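# Fluorescence signal-class model for biallelic KASP-style assays scored on
# accessions of ploidy 2, 3 or 4.
#
# A genotype at a biallelic locus is an allelic dosage alt:ref (copies of the
# alternate allele Y and the reference allele X, summing to the ploidy).  The
# two-channel fluorescence of a call depends only on the alternate-allele
# fraction alt/(alt+ref), so dosages of different ploidies with the same
# fraction are indistinguishable (all homozygotes 0:2 = 0:3 = 0:4 give one
# signal).  Across ploidies 2-4 there are seven distinct fractions
# (0, 1/4, 1/3, 1/2, 2/3, 3/4, 1) - the "theoretical" classes - but assay
# resolution cannot separate 1/4 from 1/3 nor 2/3 from 3/4, leaving five
# "observed" classes.  Observed classes 2 and 4 (unbalanced heterozygotes) are
# impossible for a diploid and are therefore flagged "polyploid-like"; the
# per-accession rate of such calls among heterozygotes is the ploidy-inference
# statistic used downstream.

# exact fraction bookkeeping: alt/ploidy * 12 is an integer for ploidy 2:4
.frac12 <- function(alt, ploidy) as.integer(round(alt * 12L / ploidy))

.THEO_FRAC12 <- c(0L, 3L, 4L, 6L, 8L, 9L, 12L) # 0, 1/4, 1/3, 1/2, 2/3, 3/4, 1
.OBS_FROM_THEO <- c(1L, 2L, 2L, 3L, 4L, 4L, 5L)

#' Enumerate theoretical fluorescence classes
#'
#' Enumerates every valid allelic dosage `alt:ref` with `alt + ref` equal to a
#' ploidy in `2:max_ploidy` and returns the distinct alternate-allele
#' fractions, indexed consecutively from 1 in increasing order.  Each fraction
#' is one theoretically distinguishable fluorescence signal.
#'
#' @param max_ploidy Highest ploidy present in the collection (2, 3 or 4).
#' @return A tibble with columns `theoretical_index` and `alt_fraction`.
#' @examples
#' theoretical_classes(4) # seven classes
#' theoretical_classes(2) # hom/het/hom only
#' @export
theoretical_classes <- function(max_ploidy = 4) {
  if (length(max_ploidy) != 1L || !max_ploidy %in% 2:4) {
    stop("`max_ploidy` must be 2, 3 or 4", call. = FALSE)
  }
  fr <- sort(unique(unlist(lapply(2:max_ploidy, function(p) (0:p) / p))))
  tibble(theoretical_index = seq_along(fr), alt_fraction = fr)
}

#' Merge theoretical classes into observed fluorescence classes
#'
#' Applies the resolution limit of the assay: the 1/4 and 1/3 alternate-allele
#' fractions produce one indistinguishable signal, as do 2/3 and 3/4.  Classes
#' are re-indexed consecutively from 1.
#'
#' @param theoretical A tibble as returned by [theoretical_classes()].
#' @return The input with an `observed_index` column appended; the mapping is
#'   total and surjective onto `1:max(observed_index)`.
#' @export
merge_observed_classes <- function(theoretical) {
  stopifnot(is.data.frame(theoretical), "alt_fraction" %in% names(theoretical))
  fr <- theoretical$alt_fraction
  key <- fr
  key[abs(fr - 1 / 4) < 1e-9 | abs(fr - 1 / 3) < 1e-9] <- 0.3
  key[abs(fr - 2 / 3) < 1e-9 | abs(fr - 3 / 4) < 1e-9] <- 0.7
  dplyr::mutate(theoretical, observed_index = match(key, sort(unique(key))))
}

#' Map an allelic dosage to its fluorescence signal class
#'
#' Vectorised over `alt_count`/`ploidy`.  `alt_count` is the number of copies
#' of the alternate (Y) allele; the reference (X) allele fills the remaining
#' `ploidy - alt_count` copies.
#'
#' @param alt_count Integer vector, copies of the alternate allele (0..ploidy).
#' @param ploidy Integer vector (recycled), total ploidy in `{2, 3, 4}`.
#' @return A tibble with columns `alt_count`, `ploidy`, `alt_fraction`,
#'   `theoretical_index` (1-7), `observed_index` (1-5) and `polyploid_like`
#'   (`TRUE` for unbalanced heterozygous signals, observed classes 2 and 4).
#' @examples
#' dosage_to_signal(1, 3) # triploid 1:2, theoretical 3, observed 2
#' @export
dosage_to_signal <- function(alt_count, ploidy) {
  if (length(alt_count) == 0L) stop("empty dosage", call. = FALSE)
  n <- max(length(alt_count), length(ploidy))
  alt_count <- rep_len(alt_count, n)
  ploidy <- rep_len(ploidy, n)
  if (anyNA(alt_count) || anyNA(ploidy)) {
    stop("MISSING dosage has no signal class", call. = FALSE)
  }
  if (!all(ploidy %in% 2:4)) stop("ploidy must be in {2, 3, 4}", call. = FALSE)
  if (!all(alt_count == round(alt_count)) || any(alt_count < 0) ||
      any(alt_count > ploidy)) {
    stop("`alt_count` must be an integer in 0..ploidy", call. = FALSE)
  }
  theo <- match(.frac12(alt_count, ploidy), .THEO_FRAC12)
  obs <- .OBS_FROM_THEO[theo]
  tibble(
    alt_count = as.integer(alt_count),
    ploidy = as.integer(ploidy),
    alt_fraction = alt_count / ploidy,
    theoretical_index = theo,
    observed_index = obs,
    polyploid_like = obs %in% c(2L, 4L)
  )
}

#' Full dosage-to-signal reference table
#'
#' All twelve valid dosages for ploidies 2-4 with their genotype type
#' (diploid-like signals are those a diploid can produce; polyploid-like are
#' the unbalanced heterozygotes), allelic composition and signal indices.
#'
#' @return A tibble with one row per dosage.
#' @export
fluorescence_class_table <- function() {
  rows <- dplyr::bind_rows(lapply(2:4, function(p) dosage_to_signal(0:p, p)))
  rows |>
    mutate(
      dosage = paste0(.data$alt_count, ":", .data$ploidy - .data$alt_count),
      composition = vapply(
        seq_len(nrow(rows)),
        function(i) {
          paste(c(
            rep("X", rows$ploidy[i] - rows$alt_count[i]),
            rep("Y", rows$alt_count[i])
          ), collapse = ":")
        },
        character(1)
      ),
      genotype_type = if_else(.data$polyploid_like, "polyploid-like",
                              "diploid-like")
    ) |>
    select("genotype_type", "ploidy", "dosage", "composition",
           "theoretical_index", "observed_index", "polyploid_like")
}

#' Parse dosage strings
#'
#' Parses `"alt:ref"` dosage strings (e.g. `"1:2"` = one alternate, two
#' reference copies, a triploid unbalanced heterozygote) into alternate-allele
#' counts and ploidies.
#'
#' @param x Character vector of `"alt:ref"` strings; `NA` passes through.
#' @return A tibble with columns `alt_count` and `ploidy`.
#' @export
parse_dosage <- function(x) {
  ok <- is.na(x) | grepl("^[0-9]+:[0-9]+$", x)
  if (!all(ok)) {
    stop("malformed dosage string(s): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  alt <- vapply(parts, function(p) if (length(p) == 2L)
    as.integer(p[1]) else NA_integer_, integer(1))
  ref <- vapply(parts, function(p) if (length(p) == 2L)
    as.integer(p[2]) else NA_integer_, integer(1))
  tibble(alt_count = alt, ploidy = alt + ref)
}
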