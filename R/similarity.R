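# Accession similarity and duplicate (redundancy-group) detection.
#
# Two measures are used.  Allele presence/absence compares any two accessions
# regardless of ploidy: each call contributes the set of alleles it shows
# (class 1 -> {X}, classes 2-4 -> {X,Y}, class 5 -> {Y}).  Allelic dosage
# refines the comparison within one ploidy level, after recoding observed
# classes to alternate-allele dosage codes.  The recoding absorbs the known
# confusions: a diploid call scored polyploid-like can only be a 1:1
# heterozygote (code 1), and a triploid call scored balanced is one of the
# two unbalanced dosages - coded 1.5, the midpoint of the compatible codes
# {1, 2}.  Tetraploid codes 0..4 need no correction.
#
# Duplicates: accessions within `max_mismatch` summed dosage difference
# (default 1 allele, allowing one somatic mutation) are linked, and redundancy
# groups are the connected components of that graph.  Cross-ploidy pairs are
# never linked.

.PRESENCE_CODE <- c(1L, 2L, 2L, 2L, 3L) # 1 = {X}, 2 = {X,Y}, 3 = {Y}

.DOSAGE_CODES <- list(
  `2` = c(0, 1, 1, 1, 2),
  `3` = c(0, 1, 1.5, 2, 3),
  `4` = c(0, 1, 2, 3, 4)
)

#' Recode observed classes to allelic-dosage codes
#'
#' @param panel A [genotype_panel()].
#' @param ploidy Integer vector of per-accession ploidies (defaults to the
#'   panel's declared ploidies, which must then all be known).
#' @return Numeric matrix of alternate-allele dosage codes (`NA` = missing);
#'   diploids take values in `{0,1,2}`, triploids `{0,1,1.5,2,3}`, tetraploids
#'   `{0,...,4}`.
#' @export
dosage_codes <- function(panel, ploidy = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(ploidy)) ploidy <- .resolved_ploidy(panel)
  ploidy <- rep_len(ploidy, n_accessions(panel))
  if (anyNA(ploidy)) {
    stop("all accessions need a known ploidy; run assign_unknowns() first",
         call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(panel$calls), ncol(panel$calls),
                dimnames = dimnames(panel$calls))
  for (p in c(2L, 3L, 4L)) {
    rows <- which(ploidy == p)
    if (!length(rows)) next
    sub <- panel$calls[rows, , drop = FALSE]
    out[rows, ] <- matrix(.DOSAGE_CODES[[as.character(p)]][sub],
                          nrow = length(rows))
  }
  out
}

#' Presence/absence dissimilarity between all accessions
#'
#' Per co-called locus the similarity of two accessions is the overlap of
#' their allele-presence sets (`jaccard`: intersection over union, so a
#' heterozygote vs. a homozygote scores 1/2; `dice`: 2|intersection| over the
#' summed set sizes, scoring 2/3); accession-pair similarity is the mean over
#' co-called loci and dissimilarity is its complement.
#'
#' @param panel A [genotype_panel()].
#' @param index `"jaccard"` (default) or `"dice"`.
#' @return A symmetric N x N matrix with zero diagonal; pairs sharing no
#'   co-called locus are `NA`.
#' @export
presence_absence_dissimilarity <- function(panel,
                                           index = c("jaccard", "dice")) {
  index <- match.arg(index)
  n <- n_accessions(panel)
  if (n < 2) stop("need at least two accessions", call. = FALSE)
  pres <- matrix(.PRESENCE_CODE[panel$calls], nrow = n,
                 dimnames = dimnames(panel$calls))
  half <- if (index == "jaccard") 0.5 else 2 / 3
  d <- matrix(NA_real_, n, n,
              dimnames = list(rownames(pres), rownames(pres)))
  diag(d) <- 0
  for (i in seq_len(n - 1)) {
    a <- pres[i, ]
    for (j in seq(i + 1, n)) {
      b <- pres[j, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      aa <- a[ok]; bb <- b[ok]
      s <- if_else(aa == bb, 1, if_else(aa == 2L | bb == 2L, half, 0))
      d[i, j] <- d[j, i] <- 1 - mean(s)
    }
  }
  d
}

#' Dosage-based similarity within one ploidy level
#'
#' For two accessions of ploidy `p` with alternate-dosage codes `dA`, `dB` at
#' a locus, the shared-allele fraction is
#' `(min(dA, dB) + min(p - dA, p - dB)) / p`; the pair similarity is its mean
#' over co-called loci.  The triploid 1.5 code enters arithmetically, which
#' equals averaging over the two integer dosages it may stand for.
#'
#' @param panel A [genotype_panel()].
#' @param ploidy_class The ploidy level (2, 3 or 4) to compare within.
#' @param report Optional `ploidy_report` used to resolve unknown ploidies.
#' @return A symmetric similarity matrix over the accessions of that ploidy
#'   (unit diagonal, `NA` for pairs with no co-called locus).
#' @export
dosage_similarity <- function(panel, ploidy_class, report = NULL) {
  stopifnot(ploidy_class %in% 2:4)
  pl <- .resolved_ploidy(panel, report)
  keep <- which(!is.na(pl) & pl == ploidy_class)
  if (length(keep) < 2) {
    stop("fewer than two accessions of ploidy ", ploidy_class, call. = FALSE)
  }
  codes <- dosage_codes(panel, ploidy = pl)[keep, , drop = FALSE]
  n <- nrow(codes)
  s <- matrix(NA_real_, n, n, dimnames = list(rownames(codes),
                                              rownames(codes)))
  diag(s) <- 1
  p <- ploidy_class
  for (i in seq_len(n - 1)) {
    a <- codes[i, ]
    for (j in seq(i + 1, n)) {
      b <- codes[j, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      shared <- (pmin(a[ok], b[ok]) + pmin(p - a[ok], p - b[ok])) / p
      s[i, j] <- s[j, i] <- mean(shared)
    }
  }
  s
}

#' Pairwise allele-mismatch counts
#'
#' Sum over co-called loci of the absolute difference of alternate-dosage
#' codes; the triploid 1.5 code contributes fractional differences.
#' Cross-ploidy pairs are `Inf` (never groupable).
#'
#' @param panel A [genotype_panel()].
#' @param report Optional `ploidy_report` resolving unknown ploidies.
#' @return A symmetric N x N numeric matrix with zero diagonal.
#' @export
allele_mismatch_count <- function(panel, report = NULL) {
  pl <- .resolved_ploidy(panel, report)
  if (anyNA(pl)) {
    stop("all accessions need a known ploidy; run assign_unknowns() first",
         call. = FALSE)
  }
  codes <- dosage_codes(panel, ploidy = pl)
  n <- nrow(codes)
  m <- matrix(Inf, n, n, dimnames = list(rownames(codes), rownames(codes)))
  diag(m) <- 0
  for (i in seq_len(n - 1)) {
    a <- codes[i, ]
    for (j in seq(i + 1, n)) {
      if (pl[i] != pl[j]) next
      b <- codes[j, ]
      ok <- !is.na(a) & !is.na(b)
      m[i, j] <- m[j, i] <- if (any(ok)) sum(abs(a[ok] - b[ok])) else NA_real_
    }
  }
  m
}

#' Build redundancy groups of duplicate accessions
#'
#' Links accessions of equal ploidy whose allele-mismatch count is at most
#' `max_mismatch` (default one allele: a putative somaclonal variant) and
#' takes connected components as redundancy groups, so a family of clones all
#' within one mutation of a founder groups together even if two derived
#' clones differ at two loci.  Group ids follow accession input order.
#'
#' @param panel A [genotype_panel()].
#' @param max_mismatch Maximum summed dosage difference for a duplicate link.
#' @param report Optional `ploidy_report` resolving unknown ploidies.
#' @return A `redundancy_result`: list with `groups` (tibble `accession`,
#'   `ploidy`, `group_id`, `group_size`), `n_groups`, and the `max_mismatch`
#'   used.
#' @export
build_redundancy_groups <- function(panel, max_mismatch = 1, report = NULL) {
  pl <- .resolved_ploidy(panel, report)
  mm <- allele_mismatch_count(panel, report)
  adj <- !is.na(mm) & mm <= max_mismatch
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # renumber components by first appearance in input order
  ids <- match(comp, unique(comp))
  groups <- tibble(
    accession = panel$accessions$accession,
    ploidy = pl,
    group_id = ids
  ) |>
    group_by(.data$group_id) |>
    mutate(group_size = n()) |>
    ungroup()
  structure(
    list(groups = groups, n_groups = max(ids), max_mismatch = max_mismatch),
    class = "redundancy_result"
  )
}

#' @export
print.redundancy_result <- function(x, ...) {
  cat(sprintf(
    "<redundancy_result> %d accessions in %d groups (max size %d, <=%s allele mismatch)\n",
    nrow(x$groups), x$n_groups, max(x$groups$group_size),
    format(x$max_mismatch)
  ))
  invisible(x)
}

#' @export
tidy.redundancy_result <- function(x, ...) x$groups

#' @export
glance.redundancy_result <- function(x, ...) {
  tibble(
    n_accessions = nrow(x$groups),
    n_groups = x$n_groups,
    max_group_size = max(x$groups$group_size),
    n_singletons = sum(x$groups$group_size == 1),
    max_mismatch = x$max_mismatch
  )
}

#' Per-group allele-frequency profiles
#'
#' For each redundancy group and marker, the alternate-allele frequency is the
#' summed dosage code of the co-called members divided by ploidy times the
#' number of co-called members; markers with no called member are `NA`.
#'
#' @param redundancy A `redundancy_result` (or its `groups` tibble).
#' @param panel The [genotype_panel()] the groups were built from.
#' @return A G x L numeric matrix of frequencies in `[0, 1]`, rows named
#'   `group_<id>`.
#' @export
group_allele_frequencies <- function(redundancy, panel) {
  groups <- if (inherits(redundancy, "redundancy_result")) {
    redundancy$groups
  } else {
    redundancy
  }
  codes <- dosage_codes(panel, ploidy = groups$ploidy)
  gids <- sort(unique(groups$group_id))
  out <- matrix(NA_real_, length(gids), ncol(codes),
                dimnames = list(paste0("group_", gids), colnames(codes)))
  for (k in seq_along(gids)) {
    rows <- which(groups$group_id == gids[k])
    sub <- codes[rows, , drop = FALSE]
    p <- groups$ploidy[rows[1]]
    called <- colSums(!is.na(sub))
    tot <- colSums(sub, na.rm = TRUE)
    out[k, ] <- if_else(called > 0, tot / (p * called), NA_real_)
  }
  out
}

#' @export
autoplot.redundancy_result <- function(object, ...) {
  df <- object$groups |>
    distinct(.data$group_id, .data$group_size, .data$ploidy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_size,
                                   fill = factor(.data$ploidy))) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "redundancy-group size", y = "number of groups",
                  fill = "ploidy") +
    ggplot2::theme_minimal()
}
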