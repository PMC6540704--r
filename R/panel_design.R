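# SNP panel design: native reimplementation of the variant filters used to
# derive the assay candidates, flanking-sequence extraction for assay design,
# and exact 1-D k-means selection of representative SNPs along the genome.

#' Construct a variant panel
#'
#' Holds biallelic (or multi-allelic, pre-filter) variant sites with
#' per-sample genotypes and read depths, as parsed from a multi-sample VCF.
#'
#' @param sites Tibble with columns `chromosome`, `position`, `ref`, `alt`
#'   (comma-separated for multi-allelic sites).
#' @param geno Integer matrix (sites x samples) of alternate-allele counts
#'   per diploid genotype (0, 1, 2; `NA` = missing).
#' @param depth Numeric matrix (sites x samples) of per-genotype read depths.
#' @param samples Character vector of sample names.
#' @return A `variant_panel` object.
#' @export
variant_panel <- function(sites, geno, depth, samples) {
  sites <- as_tibble(sites)
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  stopifnot(
    nrow(sites) == nrow(geno), all(dim(geno) == dim(depth)),
    ncol(geno) == length(samples)
  )
  colnames(geno) <- colnames(depth) <- samples
  structure(list(sites = sites, geno = geno, depth = depth,
                 samples = samples),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel> %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Read a multi-sample VCF into a variant panel
#'
#' Parses GT (alternate-allele count per genotype) and the per-sample DP
#' field from a VCF v4.x file.
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @return A `variant_panel`.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- tibble(
    chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = TRUE),
                  function(a) sum(a != "0" & a != "."), integer(1)))
  }
  geno <- matrix(alt_count(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  dp[is.na(dp)] <- 0
  variant_panel(sites, geno, dp, colnames(gt))
}

#' Filter variant sites
#'
#' Applies, natively, the standard hard filters used for assay-candidate
#' selection: genotypes below `min_depth` reads are set missing; only
#' biallelic SNPs are kept; the minor-allele frequency among called
#' genotypes must reach `min_maf`; at least `1 - max_missing_fraction` of
#' genotypes must be called; and finally sites are thinned so no two kept
#' sites on one chromosome are within `thin_bp` base pairs (greedy in
#' coordinate order, keeping the first site of a close run).  Thinning is
#' applied last; the other filters commute.
#'
#' @param vp A [variant_panel()], sites sorted by chromosome then position.
#' @param min_depth Minimum per-genotype read depth.
#' @param min_maf Minimum minor-allele frequency (alleles counted with full
#'   dosage weight over called genotypes).
#' @param max_missing_fraction Maximum fraction of missing genotypes per site.
#' @param thin_bp Minimum distance between kept sites on one chromosome.
#' @return The filtered `variant_panel`; an attribute `filter_log` tabulates
#'   sites dropped per rule (all-missing sites are dropped and logged too).
#' @export
filter_sites <- function(vp, min_depth = 8, min_maf = 0.1,
                         max_missing_fraction = 0.40, thin_bp = 64) {
  stopifnot(inherits(vp, "variant_panel"))
  o <- order(match(vp$sites$chromosome, unique(vp$sites$chromosome)),
             vp$sites$position)
  if (!identical(o, seq_len(nrow(vp$sites)))) {
    stop("sites must be sorted by (chromosome, position)", call. = FALSE)
  }
  geno <- vp$geno
  geno[vp$depth < min_depth] <- NA_integer_
  n_samp <- length(vp$samples)
  biallelic <- !grepl(",", vp$sites$alt, fixed = TRUE) &
    nchar(vp$sites$ref) == 1L & nchar(vp$sites$alt) == 1L
  called <- rowSums(!is.na(geno))
  alt_f <- ifelse(called > 0, rowSums(geno, na.rm = TRUE) / (2 * called),
                  NA_real_)
  maf <- pmin(alt_f, 1 - alt_f)
  all_missing <- called == 0
  keep <- biallelic & !all_missing & maf >= min_maf &
    (called / n_samp) >= (1 - max_missing_fraction)
  log <- tibble(
    rule = c("not_biallelic", "all_missing", "low_maf", "high_missing"),
    dropped = c(
      sum(!biallelic),
      sum(biallelic & all_missing),
      sum(biallelic & !all_missing & maf < min_maf),
      sum(biallelic & !all_missing & maf >= min_maf &
            (called / n_samp) < (1 - max_missing_fraction))
    )
  )
  # thinning, last: greedy scan in coordinate order per chromosome
  idx <- which(keep)
  thinned <- logical(length(keep))
  last_chr <- ""
  last_pos <- -Inf
  for (i in idx) {
    chr <- vp$sites$chromosome[i]
    pos <- vp$sites$position[i]
    if (chr != last_chr || (pos - last_pos) >= thin_bp) {
      thinned[i] <- TRUE
      last_chr <- chr
      last_pos <- pos
    }
  }
  log <- bind_rows(log, tibble(rule = "thinned",
                               dropped = sum(keep) - sum(thinned)))
  out <- variant_panel(vp$sites[thinned, , drop = FALSE],
                       geno[thinned, , drop = FALSE],
                       vp$depth[thinned, , drop = FALSE], vp$samples)
  attr(out, "filter_log") <- log
  out
}

#' Drop accessions with excessive missing data
#'
#' @param x A `variant_panel` or [genotype_panel()].
#' @param max_missing Accessions with a missing fraction strictly above this
#'   are removed; survivor order is preserved.
#' @return The filtered object.
#' @export
drop_sparse_accessions <- function(x, max_missing = 0.70) {
  UseMethod("drop_sparse_accessions")
}

#' @export
drop_sparse_accessions.variant_panel <- function(x, max_missing = 0.70) {
  frac <- colMeans(is.na(x$geno))
  keep <- frac <= max_missing
  if (!any(keep)) stop("no accessions survive the missing-data filter",
                       call. = FALSE)
  variant_panel(x$sites, x$geno[, keep, drop = FALSE],
                x$depth[, keep, drop = FALSE], x$samples[keep])
}

#' @export
drop_sparse_accessions.genotype_panel <- function(x, max_missing = 0.70) {
  frac <- rowMeans(is.na(x$calls))
  keep <- frac <= max_missing
  if (!any(keep)) stop("no accessions survive the missing-data filter",
                       call. = FALSE)
  genotype_panel(x$calls[keep, , drop = FALSE],
                 x$accessions[keep, , drop = FALSE], x$markers)
}

#' Extract flanking sequences around variant sites
#'
#' Returns up to `flank` bases either side of each variant position
#' (truncated at contig ends, with a flag) and the assay-design string
#' `LEFT[REF/ALT]RIGHT`.
#'
#' @param sites Tibble with `chromosome`, `position`, `ref`, `alt`.
#' @param reference A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param flank Flank length in bases.
#' @return A tibble with `chromosome`, `position`, `upstream`, `downstream`,
#'   `assay` and `truncated`.
#' @export
extract_flanks <- function(sites, reference, flank = 60) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  names(reference) <- sub("\\s.*$", "", names(reference))
  miss <- setdiff(unique(sites$chromosome), names(reference))
  if (length(miss)) {
    stop("chromosome(s) not in reference: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lens <- Biostrings::width(reference)[match(sites$chromosome,
                                             names(reference))]
  if (any(sites$position < 1 | sites$position > lens)) {
    stop("variant position outside its reference sequence", call. = FALSE)
  }
  up_start <- pmax(1L, sites$position - flank)
  dn_end <- pmin(lens, sites$position + flank)
  up <- character(nrow(sites))
  dn <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    seqc <- reference[[sites$chromosome[i]]]
    up[i] <- if (sites$position[i] > 1) {
      as.character(Biostrings::subseq(seqc, up_start[i],
                                      sites$position[i] - 1L))
    } else ""
    dn[i] <- if (sites$position[i] < lens[i]) {
      as.character(Biostrings::subseq(seqc, sites$position[i] + 1L,
                                      dn_end[i]))
    } else ""
  }
  trunc <- nchar(up) < flank | nchar(dn) < flank
  if (any(trunc)) {
    message(sum(trunc), " flank(s) truncated at contig ends")
  }
  tibble(
    chromosome = sites$chromosome, position = sites$position,
    upstream = up, downstream = dn,
    assay = paste0(up, "[", sites$ref, "/", sites$alt, "]", dn),
    truncated = trunc
  )
}

#' Select representative SNPs by exact 1-D k-means
#'
#' Maps every site to a single cumulative genome coordinate (its position
#' plus the summed lengths of all preceding chromosomes, in the order of
#' `chromosome_lengths`), partitions the coordinates into `k` clusters by
#' exact dynamic-programming k-means (deterministic, no seed), and picks in
#' each cluster the site nearest its centroid, ties broken by the lower
#' coordinate.
#'
#' @param sites Tibble with `chromosome` and `position` (one row per
#'   candidate SNP).
#' @param k Number of representatives.
#' @param chromosome_lengths Named numeric vector of chromosome lengths; the
#'   name order fixes the chromosome order of the cumulative coordinate.
#' @return A `panel_selection` tibble: the input rows plus `genome_coord`,
#'   `cluster`, `centroid` and `representative`.
#' @export
select_representatives <- function(sites, k = 192, chromosome_lengths) {
  sites <- as_tibble(sites)
  if (k > nrow(sites)) {
    stop("k exceeds the number of candidate sites", call. = FALSE)
  }
  miss <- setdiff(unique(sites$chromosome), names(chromosome_lengths))
  if (length(miss)) {
    stop("no length for chromosome(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  offset <- c(0, cumsum(as.numeric(chromosome_lengths)))
  names(offset) <- c(names(chromosome_lengths), "__end__")
  sites$genome_coord <- sites$position +
    unname(offset[sites$chromosome])
  o <- order(sites$genome_coord)
  x <- sites$genome_coord[o]
  cl_sorted <- kmeans1d_assign(x, as.integer(k))
  cl <- integer(nrow(sites))
  cl[o] <- cl_sorted
  sites$cluster <- cl
  sites <- sites |>
    group_by(.data$cluster) |>
    mutate(centroid = mean(.data$genome_coord)) |>
    mutate(representative = {
      d <- abs(.data$genome_coord - .data$centroid)
      best <- which(d == min(d))
      pick <- best[which.min(.data$genome_coord[best])]
      seq_along(d) == pick
    }) |>
    ungroup()
  class(sites) <- c("panel_selection", class(sites))
  sites
}

#' Exact one-dimensional k-means
#'
#' Solves 1-D k-means to global optimality by dynamic programming over the
#' sorted coordinates (optimal 1-D clusters are contiguous in sorted order).
#' Deterministic: no seed, no restarts.
#'
#' @param x Numeric coordinates (any order).
#' @param k Number of clusters, `1 <= k <= length(x)`.
#' @return Integer cluster assignment aligned with `x`, clusters numbered
#'   1..k left to right.
#' @export
kmeans_1d <- function(x, k) {
  o <- order(x)
  cl <- integer(length(x))
  cl[o] <- kmeans1d_assign(x[o], as.integer(k))
  cl
}

#' Within-cluster sum of squares of a 1-D clustering
#'
#' @param x Numeric coordinates.
#' @param cluster Integer cluster assignment.
#' @return Total within-cluster sum of squares.
#' @export
wss_1d <- function(x, cluster) {
  sum(tapply(x, cluster, function(v) sum((v - mean(v))^2)))
}
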