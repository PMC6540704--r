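test_that("variant filters apply depth, biallelic, MAF, call-rate and thinning", {
  fx <- make_variant_fixture()
  vp <- variant_panel(fx$sites, fx$geno, fx$depth, sprintf("S%02d", 1:10))
  out <- filter_sites(vp, min_depth = 8, min_maf = 0.1,
                      max_missing_fraction = 0.40, thin_bp = 64)
  # site 1 kept; site 2 thinned (150-100=50 < 64); site 3 low MAF;
  # site 4 50% missing; site 5 multiallelic; site 6 fails call rate after
  # depth masking (6/10 masked -> 40% called); site 7 kept; site 8 all missing
  expect_equal(out$sites$position, c(100L, 120L))
  expect_equal(out$sites$chromosome, c("c1", "c2"))
  log <- attr(out, "filter_log")
  expect_equal(log$dropped[log$rule == "thinned"], 1L)
  expect_equal(log$dropped[log$rule == "not_biallelic"], 1L)
  # depth masking wrote missing genotypes into the output
  expect_true(all(is.na(out$geno[, 1]) | out$depth[, 1] >= 8))
  # unsorted input rejected
  expect_error(
    filter_sites(variant_panel(fx$sites[c(2, 1, 3:8), ],
                               fx$geno[c(2, 1, 3:8), ],
                               fx$depth[c(2, 1, 3:8), ],
                               sprintf("S%02d", 1:10))),
    "sorted"
  )
})

test_that("thinning keeps the first site of a close run, per chromosome", {
  sites <- tibble::tibble(
    chromosome = c("c1", "c1", "c1", "c2"),
    position = c(100L, 150L, 200L, 130L),
    ref = "A", alt = "T"
  )
  geno <- matrix(rep(c(0L, 1L), each = 4), 4)
  vp <- variant_panel(sites, geno, matrix(20, 4, 2), c("S1", "S2"))
  out <- filter_sites(vp, min_depth = 0, min_maf = 0, thin_bp = 64)
  # 100 kept, 150 dropped (50 < 64), 200 kept (100 from last kept), c2 fresh
  expect_equal(out$sites$position, c(100L, 200L, 130L))
})

test_that("VCF round-trip preserves genotypes and depths", {
  fx <- make_variant_fixture()
  path <- write_test_vcf(fx$sites[1:4, ], fx$geno[1:4, ], fx$depth[1:4, ])
  vp <- read_variant_vcf(path)
  expect_equal(vp$sites$position, fx$sites$position[1:4])
  expect_equal(unname(vp$geno), unname(fx$geno[1:4, ]))
  expect_equal(unname(vp$depth), unname(fx$depth[1:4, ]))
})

test_that("sparse accessions are dropped above 70% missing, survivors in order", {
  # 48 samples, 8 planted sparse -> 40 remain
  set.seed(31)
  n_sites <- 50
  geno <- matrix(rep(c(0L, 1L), length.out = 48 * n_sites), n_sites, 48)
  sparse_cols <- c(3, 7, 11, 20, 21, 33, 40, 48)
  for (j in sparse_cols) geno[seq_len(36), j] <- NA # 72% missing
  sites <- tibble::tibble(chromosome = "c1",
                          position = seq(1L, by = 100L, length.out = n_sites),
                          ref = "A", alt = "T")
  vp <- variant_panel(sites, geno, matrix(20, n_sites, 48),
                      sprintf("S%02d", 1:48))
  out <- drop_sparse_accessions(vp, max_missing = 0.70)
  expect_equal(length(out$samples), 40L)
  expect_equal(out$samples, setdiff(sprintf("S%02d", 1:48),
                                    sprintf("S%02d", sparse_cols)))
  # 0%-missing accession kept; boundary is strict (> 0.70)
  geno2 <- geno[, 1:2]
  geno2[seq_len(35), 2] <- NA # exactly 70%
  vp2 <- variant_panel(sites, geno2, matrix(20, n_sites, 2), c("A", "B"))
  expect_equal(length(drop_sparse_accessions(vp2)$samples), 2L)
  expect_error(drop_sparse_accessions(vp, max_missing = -1), "survive")
  # genotype panels support the same filter
  p <- random_class_panel(3, 20, ploidy = 2, seed = 1)
  p$calls[1, 1:15] <- NA
  expect_equal(n_accessions(drop_sparse_accessions(p)), 2L)
})

test_that("flank extraction returns 60 bp each side, truncating at contig ends", {
  set.seed(7)
  contig <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", contig), fa)
  sites <- tibble::tibble(chromosome = "c1", position = c(61L, 10L, 195L),
                          ref = "A", alt = "G")
  fl <- extract_flanks(sites, fa, flank = 60)
  expect_equal(nchar(fl$upstream), c(60L, 9L, 60L))
  expect_equal(nchar(fl$downstream), c(60L, 60L, 5L))
  expect_equal(fl$truncated, c(FALSE, TRUE, TRUE))
  # assay string structure LEFT[REF/ALT]RIGHT, sequence content correct
  expect_equal(fl$assay[1], paste0(substr(contig, 1, 60), "[A/G]",
                                   substr(contig, 62, 121)))
  expect_lte(nchar(fl$assay[1]), 60 + 60 + 5)
  expect_equal(fl$upstream[2], substr(contig, 1, 9))
  expect_error(extract_flanks(
    tibble::tibble(chromosome = "nope", position = 5L, ref = "A", alt = "T"),
    fa
  ), "not in reference")
  expect_error(extract_flanks(
    tibble::tibble(chromosome = "c1", position = 500L, ref = "A", alt = "T"),
    fa
  ), "outside")
})

test_that("1-D k-means DP matches exhaustive search on small instances", {
  set.seed(17)
  for (trial in 1:12) {
    n <- sample(4:8, 1)
    k <- sample(2:min(4, n), 1)
    x <- round(runif(n, 0, 100), 1)
    cl <- kmeans_1d(x, k)
    expect_equal(length(unique(cl)), k)
    expect_equal(wss_1d(x, cl), brute_force_wss(x, k), tolerance = 1e-9)
  }
  # degenerate cases
  x <- c(5, 1, 9, 3)
  expect_equal(kmeans_1d(x, length(x)), rank(x))
  expect_equal(length(unique(kmeans_1d(x, 1))), 1L)
})

test_that("the DP solution never loses to random Lloyd restarts", {
  set.seed(23)
  x <- c(rnorm(30, 0), rnorm(30, 8), rnorm(30, 30))
  dp_w <- wss_1d(x, kmeans_1d(x, 6))
  for (i in 1:100) {
    km <- suppressWarnings(kmeans(x, centers = 6, nstart = 1))
    expect_lte(dp_w, km$tot.withinss + 1e-8)
  }
})

test_that("representative selection picks nearest-to-centroid per cluster", {
  sites <- tibble::tibble(
    chromosome = c(rep("c1", 3), rep("c2", 3)),
    position = c(1L, 2L, 3L, 1L, 2L, 3L)
  )
  lens <- c(c1 = 100, c2 = 100)
  sel <- select_representatives(sites, k = 2, chromosome_lengths = lens)
  # genome coords {1,2,3} and {101,102,103}: clusters split by chromosome
  expect_equal(sel$genome_coord, c(1, 2, 3, 101, 102, 103))
  expect_equal(length(unique(sel$cluster[1:3])), 1L)
  expect_equal(length(unique(sel$cluster[4:6])), 1L)
  expect_equal(sel$position[sel$representative], c(2L, 2L))
  # k = n: every site its own representative
  sel_n <- select_representatives(sites, k = 6, chromosome_lengths = lens)
  expect_true(all(sel_n$representative))
  # k = 1: the site nearest the global mean
  sel_1 <- select_representatives(sites, k = 1, chromosome_lengths = lens)
  mean_coord <- mean(sel_1$genome_coord)
  d <- abs(sel_1$genome_coord - mean_coord)
  expect_equal(which(sel_1$representative), which(d == min(d))[1])
  # ties break to the lower coordinate
  tie <- tibble::tibble(chromosome = "c1", position = c(10L, 20L))
  sel_t <- select_representatives(tie, k = 1, chromosome_lengths = c(c1 = 50))
  expect_equal(which(sel_t$representative), 1L)
  expect_error(select_representatives(tie, k = 5,
                                      chromosome_lengths = c(c1 = 50)),
               "exceeds")
})
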