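test_that("presence/absence dissimilarity matches hand example and oracle", {
  # A = ({X},{X,Y},{Y}), B = ({X},{X},{Y}) -> sim (1 + 0.5 + 1)/3
  p <- panel_from_classes(rbind(c(1L, 3L, 5L), c(1L, 1L, 5L)), 2)
  d <- presence_absence_dissimilarity(p)
  expect_equal(d[1, 2], 1 - (1 + 0.5 + 1) / 3, tolerance = 1e-12)
  expect_equal(diag(d), c(a01 = 0, a02 = 0))
  # identical accessions -> 0; fully disjoint homozygotes -> 1
  p2 <- panel_from_classes(rbind(c(1L, 5L), c(1L, 5L), c(5L, 1L)), 2)
  d2 <- presence_absence_dissimilarity(p2)
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 3], 1)
  # dice variant on het-vs-hom
  pd <- presence_absence_dissimilarity(p, index = "dice")
  expect_equal(pd[1, 2], 1 - (1 + 2 / 3 + 1) / 3, tolerance = 1e-12)
  expect_error(presence_absence_dissimilarity(
    panel_from_classes(matrix(1L, 1, 3), 2)
  ), "two accessions")
})

test_that("dosage similarity matches worked examples and interval oracle", {
  # diploids, codes A=(2,1,0), B=(2,2,0): (1 + 0.5 + 1)/3
  p <- panel_from_dosage(rbind(c(2L, 1L, 0L), c(2L, 2L, 0L)), 2)
  s <- dosage_similarity(p, 2)
  expect_equal(s[1, 2], (1 + 0.5 + 1) / 3, tolerance = 1e-12)
  expect_equal(diag(s), c(a01 = 1, a02 = 1))

  # triploid 1.5-vs-1 locus: share (1 + 1.5)/3, equal to averaging the two
  # compatible dosages {1,2}
  clsA <- c(3L, rep(1L, 9))        # observed balanced (code 1.5) then ref-hom
  clsB <- c(2L, rep(1L, 9))        # true 1:2 (code 1)
  p3 <- panel_from_classes(rbind(clsA, clsB), 3)
  s3 <- dosage_similarity(p3, 3)
  expect_equal(s3[1, 2], ((1 + 1.5) / 3 + 9) / 10, tolerance = 1e-12)
  expect_equal(s3[1, 2], oracle_dosage_sim(c(1.5, rep(0, 9)),
                                           c(1, rep(0, 9)), 3),
               tolerance = 1e-12)
  expect_error(dosage_similarity(p3, 5), "ploidy_class")
})

test_that("similarities match brute-force oracles on random panels to 1e-12", {
  for (seed in 1:3) {
    p <- random_class_panel(6, 12, ploidy = 2, missing = 0.1, seed = seed)
    d <- presence_absence_dissimilarity(p)
    s <- dosage_similarity(p, 2)
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(1 - d[i, j],
                   oracle_presence_sim(p$calls[i, ], p$calls[j, ]),
                   tolerance = 1e-12)
      codes <- dosage_codes(p)
      expect_equal(s[i, j], oracle_dosage_sim(codes[i, ], codes[j, ], 2),
                   tolerance = 1e-12)
    }
    # symmetry, range, unit diagonal
    expect_true(isSymmetric(d))
    expect_true(all(d >= 0 & d <= 1, na.rm = TRUE))
    expect_true(all(s >= 0 & s <= 1, na.rm = TRUE))
  }
})

test_that("dosage and presence/absence similarity coincide on all-homozygous panels", {
  set.seed(4)
  cls <- matrix(sample(c(1L, 5L), 5 * 20, replace = TRUE), 5)
  p <- panel_from_classes(cls, 2)
  s_dos <- dosage_similarity(p, 2)
  s_pa <- 1 - presence_absence_dissimilarity(p)
  diag(s_pa) <- 1
  expect_equal(s_dos, s_pa, tolerance = 1e-12)
})

test_that("mismatch counts follow the dosage-difference definition", {
  # het vs hom at one locus -> 1 (groupable); hom-ref vs hom-alt -> 2
  p <- panel_from_dosage(rbind(c(1L, 0L), c(2L, 0L), c(0L, 0L)), 2)
  m <- allele_mismatch_count(p)
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 3], 2)
  expect_equal(diag(m), c(a01 = 0, a02 = 0, a03 = 0))
  # cross-ploidy pairs are infinite
  p2 <- panel_from_dosage(rbind(c(1L, 0L), c(1L, 0L)), c(2, 3))
  expect_equal(allele_mismatch_count(p2)[1, 2], Inf)
  # missing loci are excluded from the count
  cls <- rbind(c(3L, NA), c(1L, 5L))
  p3 <- panel_from_classes(cls, 2)
  expect_equal(allele_mismatch_count(p3)[1, 2], 1)
})

test_that("redundancy groups are components, order-invariant and ploidy-pure", {
  # clone family: founder + 4 clones each one step away -> one group of 5,
  # plus two distant singletons
  founder <- c(2L, 1L, 0L, 1L, 2L, 0L, 1L, 2L)
  fam <- rbind(founder, founder, founder, founder, founder)
  fam[2, 1] <- 1L; fam[3, 4] <- 2L; fam[4, 7] <- 0L; fam[5, 8] <- 1L
  far1 <- c(0L, 0L, 2L, 0L, 0L, 2L, 0L, 0L)
  far2 <- c(1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L)
  dos <- rbind(fam, far1, far2)
  p <- panel_from_dosage(dos, 2)
  red <- build_redundancy_groups(p)
  expect_equal(red$n_groups, 3L)
  expect_equal(red$groups$group_id, c(1L, 1L, 1L, 1L, 1L, 2L, 3L))
  expect_equal(red$groups$group_size[1], 5L)

  # permuting accession order permutes but never changes the partition
  set.seed(9)
  perm <- sample(nrow(dos))
  p_perm <- panel_from_dosage(dos[perm, ], 2)
  red_perm <- build_redundancy_groups(p_perm)
  expect_equal(red_perm$n_groups, 3L)
  same <- outer(red$groups$group_id[perm], red$groups$group_id[perm], "==")
  same_perm <- outer(red_perm$groups$group_id, red_perm$groups$group_id, "==")
  expect_equal(same, same_perm)

  # monotone in the threshold: raising it never splits a group
  red2 <- build_redundancy_groups(p, max_mismatch = 2)
  for (g in unique(red$groups$group_id)) {
    members <- which(red$groups$group_id == g)
    expect_length(unique(red2$groups$group_id[members]), 1L)
  }

  # mixed-ploidy identical calls never group
  pm <- panel_from_dosage(rbind(c(1L, 1L), c(1L, 1L)), c(2, 4))
  expect_equal(build_redundancy_groups(pm)$n_groups, 2L)
})

test_that("group allele frequencies are dosage-weighted and missing-aware", {
  # single diploid member, code 1 -> 0.5; two members codes 2,1 -> 0.75
  p <- panel_from_dosage(rbind(c(1L, 2L), c(1L, 1L)), 2)
  red <- build_redundancy_groups(p, max_mismatch = 1)
  expect_equal(red$n_groups, 1L)
  f <- group_allele_frequencies(red, p)
  expect_equal(unname(f[1, ]), c(0.5, 0.75))
  # a member missing at a marker drops out of that denominator
  cls <- rbind(c(3L, 5L), c(3L, NA))
  p2 <- panel_from_classes(cls, 2)
  red2 <- build_redundancy_groups(p2)
  f2 <- group_allele_frequencies(red2, p2)
  expect_equal(unname(f2[1, ]), c(0.5, 1))
  # all frequencies in [0,1] on a random panel
  p3 <- random_class_panel(8, 15, ploidy = 3, missing = 0.1, seed = 2)
  red3 <- build_redundancy_groups(p3)
  f3 <- group_allele_frequencies(red3, p3)
  expect_true(all(f3 >= 0 & f3 <= 1, na.rm = TRUE))
})
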