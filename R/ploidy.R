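# Ploidy inference from the polyploid-like ratio R.
#
# Among heterozygous calls (observed classes 2, 3, 4), the unbalanced classes
# 2 and 4 cannot be produced by a diploid.  The per-accession fraction R of
# heterozygous calls that are polyploid-like therefore separates ploidies:
# a diploid's R is the miscall rate (~0.09 on the validation collection), a
# triploid - whose heterozygotes are all unbalanced - sits at ~0.83 (1 minus
# its miscall rate), and a tetraploid lands in between because its balanced
# 2:2 heterozygotes are genuinely not polyploid-like (~4/7 at intermediate
# allele frequency).

#' Polyploid-like ratio per accession
#'
#' Counts, for every accession, heterozygous calls (observed classes 2, 3, 4)
#' and polyploid-like calls (classes 2 and 4) and forms their ratio `R`.
#' Accessions with fewer than `min_het_calls` heterozygous calls are reported
#' with `R = NA` (uncallable) rather than a noisy estimate.
#'
#' @param panel A [genotype_panel()].
#' @param min_het_calls Minimum heterozygous calls needed to report `R`.
#' @return A `ploidy_report` tibble with columns `accession`, `n_het`,
#'   `n_polyploid_like`, `ratio`, `declared_ploidy`.
#' @export
polyploid_like_ratio <- function(panel, min_het_calls = 10) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  n_het <- rowSums(!is.na(calls) & calls %in% c(2L, 3L, 4L))
  n_pl <- rowSums(!is.na(calls) & calls %in% c(2L, 4L))
  out <- tibble(
    accession = panel$accessions$accession,
    n_het = unname(as.integer(n_het)),
    n_polyploid_like = unname(as.integer(n_pl)),
    ratio = unname(if_else(n_het >= min_het_calls, n_pl / n_het, NA_real_)),
    declared_ploidy = panel$accessions$declared_ploidy
  )
  class(out) <- c("ploidy_report", class(out))
  out
}

#' Classify ploidy from the polyploid-like ratio
#'
#' Applies the two thresholds separating the theoretical expectations of the
#' three ploidy levels: `ratio < t_low` is diploid, `t_low <= ratio < t_high`
#' tetraploid, `ratio >= t_high` triploid.  Uncallable accessions
#' (`ratio = NA`) stay unclassified.
#'
#' @param report A `ploidy_report` from [polyploid_like_ratio()].
#' @param t_low,t_high Classification thresholds in (0, 1), `t_low < t_high`.
#' @return The report with an `inferred_ploidy` column (2, 3, 4 or `NA`).
#' @export
classify_ploidy <- function(report, t_low = 0.35, t_high = 0.70) {
  stopifnot(t_low > 0, t_high < 1, t_low < t_high)
  out <- report |>
    mutate(inferred_ploidy = dplyr::case_when(
      is.na(.data$ratio) ~ NA_integer_,
      .data$ratio < t_low ~ 2L,
      .data$ratio < t_high ~ 4L,
      TRUE ~ 3L
    ))
  class(out) <- unique(c("ploidy_report", class(out)))
  out
}

#' Assign ploidy to accessions of unknown ploidy
#'
#' Runs [polyploid_like_ratio()] and [classify_ploidy()] on the panel and
#' fills in the ploidy of accessions whose declared ploidy is unknown.
#' Declared ploidies are never overwritten; where a declared ploidy disagrees
#' with the inference the report flags a conflict (a warning sign for a
#' mislabelled or mixed sample, not a failure).
#'
#' @inheritParams polyploid_like_ratio
#' @inheritParams classify_ploidy
#' @return A list with `panel` (declared-unknown accessions now carrying their
#'   inferred ploidy in `accessions$ploidy`) and `report` (a `ploidy_report`
#'   with `inferred_ploidy`, resolved `ploidy` and `conflict` columns).
#' @export
assign_unknowns <- function(panel, min_het_calls = 10, t_low = 0.35,
                            t_high = 0.70) {
  report <- classify_ploidy(polyploid_like_ratio(panel, min_het_calls),
                            t_low = t_low, t_high = t_high)
  report <- report |>
    mutate(
      ploidy = if_else(is.na(.data$declared_ploidy), .data$inferred_ploidy,
                       .data$declared_ploidy),
      conflict = !is.na(.data$declared_ploidy) &
        !is.na(.data$inferred_ploidy) &
        .data$declared_ploidy != .data$inferred_ploidy
    )
  if (any(report$conflict)) {
    warning("declared/inferred ploidy conflict for: ",
            paste(report$accession[report$conflict], collapse = ", "),
            call. = FALSE)
  }
  panel$accessions$ploidy <- report$ploidy
  class(report) <- unique(c("ploidy_report", class(report)))
  list(panel = panel, report = report)
}

#' @export
glance.ploidy_report <- function(x, ...) {
  tibble(
    n_accessions = nrow(x),
    n_uncallable = sum(is.na(x$ratio)),
    mean_ratio_diploid = mean(x$ratio[!is.na(x$declared_ploidy) &
                                        x$declared_ploidy == 2], na.rm = TRUE),
    mean_ratio_triploid = mean(x$ratio[!is.na(x$declared_ploidy) &
                                         x$declared_ploidy == 3],
                               na.rm = TRUE),
    n_conflict = if ("conflict" %in% names(x)) sum(x$conflict) else NA_integer_
  )
}

#' Plot the polyploid-like ratio distribution
#'
#' One point per accession, grouped by inferred (or declared) ploidy, with the
#' classification thresholds drawn as dashed lines.
#'
#' @param object A `ploidy_report`.
#' @param t_low,t_high Thresholds to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ploidy_report <- function(object, t_low = 0.35, t_high = 0.70, ...) {
  pl <- if ("inferred_ploidy" %in% names(object)) {
    object$inferred_ploidy
  } else {
    object$declared_ploidy
  }
  df <- object |>
    mutate(ploidy_group = factor(
      if_else(is.na(pl), "uncallable", paste0(pl, "x")),
      levels = c("2x", "3x", "4x", "uncallable")
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ploidy_group, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = c(t_low, t_high), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7, na.rm = TRUE) +
    ggplot2::labs(x = "ploidy", y = "polyploid-like ratio R") +
    ggplot2::theme_minimal()
}
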