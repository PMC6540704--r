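# Genotype panel container: an N accessions x L markers grid of observed
# fluorescence classes (1-5, NA = missing call) plus accession and marker
# metadata.  Declared ploidy is NA for accessions of unknown ploidy.

#' Construct a genotype panel
#'
#' @param calls Integer matrix (accessions x markers) of observed fluorescence
#'   classes in 1..5, `NA` for missing calls.  Row names are accession names,
#'   column names marker names (supplied metadata takes precedence).
#' @param accessions Tibble with columns `accession` and `declared_ploidy`
#'   (2, 3, 4 or `NA` for unknown).  Defaults to row names with unknown ploidy.
#' @param markers Optional tibble with columns `marker`, `chromosome`,
#'   `position`; defaults to column names with unknown coordinates.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(calls, accessions = NULL, markers = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(accessions)) {
    nm <- rownames(calls)
    if (is.null(nm)) nm <- sprintf("acc%03d", seq_len(nrow(calls)))
    accessions <- tibble(accession = nm, declared_ploidy = NA_integer_)
  }
  accessions <- as_tibble(accessions)
  if (!"declared_ploidy" %in% names(accessions)) {
    accessions$declared_ploidy <- NA_integer_
  }
  accessions$declared_ploidy <- as.integer(accessions$declared_ploidy)
  if (is.null(markers)) {
    nm <- colnames(calls)
    if (is.null(nm)) nm <- sprintf("snp%03d", seq_len(ncol(calls)))
    markers <- tibble(marker = nm, chromosome = NA_character_,
                      position = NA_integer_)
  }
  markers <- as_tibble(markers)
  if (nrow(accessions) != nrow(calls) || nrow(markers) != ncol(calls)) {
    stop("grid dimensions do not match accession/marker metadata",
         call. = FALSE)
  }
  if (anyDuplicated(accessions$accession)) {
    stop("duplicated accession names", call. = FALSE)
  }
  bad <- !is.na(calls) & !(calls %in% 1:5)
  if (any(bad)) stop("observed classes must be in 1..5 or NA", call. = FALSE)
  known <- !is.na(accessions$declared_ploidy)
  if (any(!accessions$declared_ploidy[known] %in% 2:4)) {
    stop("declared ploidy must be 2, 3, 4 or NA", call. = FALSE)
  }
  dimnames(calls) <- list(accessions$accession, markers$marker)
  structure(list(calls = calls, accessions = accessions, markers = markers),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  pl <- table(factor(x$accessions$declared_ploidy, levels = 2:4),
              useNA = "ifany")
  cat(sprintf(
    "<genotype_panel> %d accessions x %d markers (%.2f%% missing)\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))
  ))
  cat(sprintf("  declared ploidy: 2x=%d 3x=%d 4x=%d unknown=%d\n",
              pl[["2"]], pl[["3"]], pl[["4"]],
              sum(is.na(x$accessions$declared_ploidy))))
  invisible(x)
}

#' @rdname genotype_panel
#' @param x,object A `genotype_panel`.
#' @export
n_accessions <- function(x) nrow(x$calls)

#' @rdname genotype_panel
#' @export
n_markers <- function(x) ncol(x$calls)

#' Overall missing-call fraction of a panel
#' @param panel A `genotype_panel`.
#' @export
missing_fraction <- function(panel) mean(is.na(panel$calls))

#' Read a genotype panel from CSV files
#'
#' The calls file has one row per accession (first column = accession name)
#' and one column per marker; cells hold either observed class codes 1-5 or
#' `"alt:ref"` dosage strings (converted through the signal-class model), with
#' empty/`NA` cells for missing calls.  The optional metadata file carries
#' `accession, declared_ploidy` (blank or `"UNKNOWN"` ploidy becomes `NA`);
#' the optional marker file carries `marker, chromosome, position`.
#'
#' @param calls_csv Path to the calls grid CSV.
#' @param meta_csv Optional path to the accession metadata CSV.
#' @param markers_csv Optional path to the marker metadata CSV.
#' @return A `genotype_panel`.
#' @export
read_genotype_panel <- function(calls_csv, meta_csv = NULL,
                                markers_csv = NULL) {
  grid <- readr::read_csv(calls_csv, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  acc_names <- grid[[1]]
  cells <- as.matrix(grid[-1])
  cls <- matrix(NA_integer_, nrow(cells), ncol(cells),
                dimnames = dimnames(cells))
  plain <- grepl("^[1-5]$", cells)
  cls[plain] <- as.integer(cells[plain])
  dos <- !is.na(cells) & grepl(":", cells, fixed = TRUE)
  if (any(dos)) {
    parsed <- parse_dosage(cells[dos])
    cls[dos] <- dosage_to_signal(parsed$alt_count, parsed$ploidy)$observed_index
  }
  unknown <- !is.na(cells) & !plain & !dos & cells != "" & cells != "NA"
  if (any(unknown)) {
    stop("unrecognised call value(s): ",
         paste(head(unique(cells[unknown]), 5), collapse = ", "),
         call. = FALSE)
  }
  accessions <- tibble(accession = acc_names, declared_ploidy = NA_integer_)
  if (!is.null(meta_csv)) {
    meta <- readr::read_csv(meta_csv, col_types = readr::cols(
      accession = readr::col_character(),
      declared_ploidy = readr::col_character()
    ), progress = FALSE)
    pl <- toupper(trimws(meta$declared_ploidy))
    pl[pl %in% c("", "UNKNOWN", "NA")] <- NA
    meta$declared_ploidy <- as.integer(sub("X$", "", pl))
    accessions <- tibble(accession = acc_names) |>
      left_join(meta[c("accession", "declared_ploidy")], by = "accession")
  }
  markers <- NULL
  if (!is.null(markers_csv)) {
    markers <- readr::read_csv(markers_csv, col_types = readr::cols(
      marker = readr::col_character(),
      chromosome = readr::col_character(),
      position = readr::col_integer()
    ), progress = FALSE)
    markers <- tibble(marker = colnames(cells)) |>
      left_join(markers, by = "marker")
  }
  rownames(cls) <- acc_names
  genotype_panel(cls, accessions, markers)
}

#' Write a genotype panel to CSV files
#'
#' Inverse of [read_genotype_panel()]; calls are written as observed class
#' codes 1-5 and round-trip losslessly.
#'
#' @param panel A `genotype_panel`.
#' @param calls_csv,meta_csv,markers_csv Output paths (metadata/marker files
#'   optional).
#' @return Invisibly, the paths written.
#' @export
write_genotype_panel <- function(panel, calls_csv, meta_csv = NULL,
                                 markers_csv = NULL) {
  grid <- as_tibble(panel$calls, .name_repair = "minimal")
  grid <- dplyr::bind_cols(tibble(accession = panel$accessions$accession),
                           grid)
  readr::write_csv(grid, calls_csv, na = "")
  paths <- calls_csv
  if (!is.null(meta_csv)) {
    meta <- panel$accessions |>
      mutate(declared_ploidy = if_else(is.na(.data$declared_ploidy),
                                       "UNKNOWN",
                                       as.character(.data$declared_ploidy)))
    readr::write_csv(meta, meta_csv, na = "")
    paths <- c(paths, meta_csv)
  }
  if (!is.null(markers_csv)) {
    readr::write_csv(panel$markers, markers_csv, na = "")
    paths <- c(paths, markers_csv)
  }
  invisible(paths)
}

#' Mask declared ploidies to unknown
#'
#' @param panel A `genotype_panel`.
#' @param accessions Accession names whose declared ploidy is set to unknown.
#' @return The panel with masked metadata.
#' @export
mask_ploidy <- function(panel, accessions) {
  miss <- setdiff(accessions, panel$accessions$accession)
  if (length(miss)) {
    stop("unknown accession(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- panel$accessions$accession %in% accessions
  panel$accessions$declared_ploidy[idx] <- NA_integer_
  panel
}

# resolved per-accession ploidy: declared where known, else `inferred` column
# of a ploidy report if given
.resolved_ploidy <- function(panel, report = NULL) {
  pl <- panel$accessions$declared_ploidy
  if (!is.null(report)) {
    m <- match(panel$accessions$accession, report$accession)
    fill <- is.na(pl) & !is.na(m)
    pl[fill] <- report$inferred_ploidy[m[fill]]
  }
  pl
}
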