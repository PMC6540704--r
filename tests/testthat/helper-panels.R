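# Shared fixture builders (everything generated in code, no stored data).

# Panel from a true-dosage matrix: observed classes via the signal map.
panel_from_dosage <- function(dosage, ploidy) {
  ploidy <- rep_len(ploidy, nrow(dosage))
  obs <- dosage
  for (i in seq_len(nrow(dosage))) {
    ok <- !is.na(dosage[i, ])
    obs[i, ok] <- dosage_to_signal(dosage[i, ok], ploidy[i])$observed_index
  }
  genotype_panel(
    obs,
    accessions = tibble::tibble(
      accession = sprintf("a%02d", seq_len(nrow(dosage))),
      declared_ploidy = as.integer(ploidy)
    )
  )
}

# Panel directly from an observed-class matrix.
panel_from_classes <- function(classes, ploidy) {
  genotype_panel(
    classes,
    accessions = tibble::tibble(
      accession = sprintf("a%02d", seq_len(nrow(classes))),
      declared_ploidy = as.integer(rep_len(ploidy, nrow(classes)))
    )
  )
}

# Random same-ploidy panel of observed classes (may include missing calls).
random_class_panel <- function(n, L, ploidy = 2, missing = 0, seed = 1) {
  set.seed(seed)
  cls <- matrix(sample(1:5, n * L, replace = TRUE), n, L)
  if (missing > 0) cls[runif(n * L) < missing] <- NA_integer_
  panel_from_classes(cls, ploidy)
}

# Tiny multi-sample VCF written to a temp file; geno = alt-count matrix
# (sites x samples, NA = ./.), depth = matching DP matrix.
write_test_vcf <- function(sites, geno, depth, path = tempfile(fileext = ".vcf")) {
  n_samp <- ncol(geno)
  samples <- sprintf("S%02d", seq_len(n_samp))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno), n_samp)
  gt_str[is.na(geno)] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  for (i in seq_len(nrow(sites))) {
    cells <- paste0(gt_str[i, ], ":", depth[i, ])
    lines <- c(lines, paste(c(
      sites$chromosome[i], sites$position[i], ".", sites$ref[i],
      sites$alt[i], ".", "PASS", ".", "GT:DP", cells
    ), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Brute-force 1-D k-means over all set partitions (n <= 9), returns the
# minimal within-cluster sum of squares.  Independent of the DP under test.
brute_force_wss <- function(x, k) {
  n <- length(x)
  best <- Inf
  assign_next <- function(assigned, n_used) {
    i <- length(assigned) + 1L
    if (i > n) {
      if (n_used == k) {
        w <- sum(tapply(x, assigned, function(v) sum((v - mean(v))^2)))
        best <<- min(best, w)
      }
      return(invisible())
    }
    for (g in seq_len(min(n_used + 1L, k))) {
      assign_next(c(assigned, g), max(n_used, g))
    }
  }
  assign_next(integer(0), 0L)
  best
}

make_variant_fixture <- function() {
  # 8 sites on two chromosomes, 10 samples, engineered to exercise each rule
  sites <- tibble::tibble(
    chromosome = c("c1", "c1", "c1", "c1", "c1", "c2", "c2", "c2"),
    position = c(100L, 150L, 300L, 380L, 500L, 40L, 120L, 500L),
    ref = c("A", "C", "G", "T", "A", "C", "G", "A"),
    alt = c("T", "G", "A", "C", "G,T", "T", "A", "C")
  )
  geno <- rbind(
    rep(c(0L, 1L), 5),                 # MAF 0.25, clean         (keep)
    rep(c(0L, 1L), 5),                 # 50 bp from site 1       (thinned)
    c(rep(0L, 9), 1L),                 # MAF 0.05                (low maf)
    c(rep(NA, 5), 0L, 0L, 1L, 1L, 0L), # 50% missing             (high missing)
    rep(c(0L, 1L), 5),                 # multi-allelic           (dropped)
    rep(1L, 10),                       # MAF 0 after depth mask? no: all het
    c(rep(c(0L, 2L), 5)),              # MAF 0.5, clean          (keep)
    rep(NA_integer_, 10)               # all missing             (dropped)
  )
  depth <- matrix(20, 8, 10)
  depth[6, 1:6] <- 3                   # site 6: 6 genotypes depth-masked
  list(sites = sites, geno = geno, depth = depth)
}
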