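test_that("ward clustering base cases and well-separated pairs", {
  # two groups: single merge at the Euclidean distance between profiles
  f2 <- rbind(g1 = c(0, 0, 0), g2 = c(1, 1, 0.5))
  hc <- ward_cluster(f2)
  expect_equal(hc$height, sqrt(1 + 1 + 0.25))
  expect_error(ward_cluster(f2[1, , drop = FALSE]), "two groups")

  # two well-separated pairs merge within pairs before across
  f4 <- rbind(a = c(0, 0), b = c(0.02, 0), c = c(1, 1), d = c(1, 0.98))
  hc4 <- ward_cluster(f4)
  first_two <- list(sort(hc4$merge[1, ]), sort(hc4$merge[2, ]))
  expect_setequal(
    vapply(first_two, paste, "", collapse = ","),
    c("-2,-1", "-4,-3")
  )
  # markers with missing frequencies are dropped with a message
  f4na <- cbind(f4, c(NA, 0, 0, 0))
  expect_message(ward_cluster(f4na), "dropping 1 marker")
})

test_that("multiscale bootstrap is seeded, and r = 1 is the plain bootstrap", {
  set.seed(1)
  f <- rbind(matrix(rnorm(3 * 20, 0), 3),
             matrix(rnorm(3 * 20, 3), 3))
  ms1 <- multiscale_bootstrap(f, boots = 100, seed = 42)
  ms2 <- multiscale_bootstrap(f, boots = 100, seed = 42)
  expect_identical(ms1$bp, ms2$bp)
  expect_equal(dim(ms1$bp), c(5L, 10L))
  expect_equal(ms1$sigma, sqrt(ceiling(seq(0.5, 1.4, 0.1) * 20) / 20))

  # two groups: the single node is in every resample at every scale
  f2 <- rbind(c(0, 0, 0, 0), c(1, 1, 1, 1))
  ms <- multiscale_bootstrap(f2, boots = 50, seed = 1)
  expect_true(all(ms$bp == 1))

  # a strongly planted split keeps BP >= 0.99 at every scale
  split_node <- which(vapply(
    clonepanel:::.node_leaf_sets(ms1$hclust),
    function(s) identical(s, 1:3), TRUE
  ))
  expect_length(split_node, 1L)
  expect_true(all(ms1$bp[split_node, ] >= 0.99))
})

test_that("AU fit recovers (v, c) from exact model-generated BP tables", {
  scales <- seq(0.5, 1.4, by = 0.1)
  L <- 100
  sigma <- sqrt(ceiling(scales * L) / L)
  for (vc in list(c(0.2, 0.1), c(-1.2, 0.4), c(0.8, -0.2))) {
    bp <- 1 - pnorm(vc[1] * sigma + vc[2] / sigma)
    fit <- au_pvalue(bp, sigma, boots = 10000)
    expect_equal(fit$v, vc[1], tolerance = 1e-6)
    expect_equal(fit$c, vc[2], tolerance = 1e-6)
    expect_equal(fit$au, 1 - pnorm(vc[1] - vc[2]), tolerance = 1e-6)
    expect_equal(fit$bp1, 1 - pnorm(vc[1] + vc[2]), tolerance = 1e-6)
    expect_false(fit$degenerate)
  }
  # v = 0.2, c = 0.1 closed form: AU = 1 - pnorm(0.1)
  bp <- 1 - pnorm(0.2 * sigma + 0.1 / sigma)
  expect_equal(au_pvalue(bp, sigma, 10000)$au, 0.4602, tolerance = 1e-4)
  # v = c means AU = 0.5
  bp_eq <- 1 - pnorm(0.3 * sigma + 0.3 / sigma)
  expect_equal(au_pvalue(bp_eq, sigma, 10000)$au, 0.5, tolerance = 1e-6)
  # degenerate tables short-circuit
  expect_equal(au_pvalue(rep(1, 10), sigma, 100)$au, 1)
  expect_equal(au_pvalue(rep(0, 10), sigma, 100)$au, 0)
  expect_true(au_pvalue(rep(1, 10), sigma, 100)$degenerate)
})

test_that("significant cluster selection is maximal, disjoint and root-free", {
  # build a fixed 4-leaf tree: ((1,2),(3,4))
  f <- rbind(a = c(0, 0), b = c(0.05, 0), c = c(2, 2), d = c(2, 2.05))
  hc <- ward_cluster(f)
  n_nodes <- 3L
  # all below threshold -> empty
  none <- significant_clusters(hc, rep(0.5, n_nodes))
  expect_length(none$nodes, 0L)
  expect_setequal(none$unassigned, c("a", "b", "c", "d"))
  # nested significant nodes: only the outermost survives, root excluded
  root_set <- which(lengths(clonepanel:::.node_leaf_sets(hc)) == 4L)
  au <- rep(0.99, n_nodes) # includes the root
  sel <- significant_clusters(hc, au)
  expect_false(root_set %in% sel$nodes)
  expect_length(sel$nodes, 2L)
  expect_setequal(
    vapply(sel$members, paste, "", collapse = ","),
    c("a,b", "c,d")
  )
})

test_that("gene pools on planted data recover the planted split and label leaves", {
  set.seed(3)
  f <- rbind(matrix(rnorm(4 * 30, 0, 0.3), 4),
             matrix(rnorm(4 * 30, 2, 0.3), 4))
  rownames(f) <- paste0("g", 1:8)
  gp <- gene_pools(f, boots = 200, seed = 5)
  expect_s3_class(gp, "genepool_result")
  labs <- gp$pools$pool
  expect_true(all(!is.na(labs)))
  expect_length(unique(labs[1:4]), 1L)
  expect_length(unique(labs[5:8]), 1L)
  expect_false(labs[1] == labs[5])
  # AU invariance under leaf relabelling (same seed, permuted rows)
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  gp2 <- gene_pools(f[perm, ], boots = 200, seed = 5)
  key <- function(g) sort(vapply(g$significant$members, function(m)
    paste(sort(m), collapse = ","), ""))
  expect_equal(key(gp2), key(gp))
  # tidy/glance surfaces
  expect_equal(nrow(tidy(gp)), 7L)
  expect_equal(glance(gp)$n_pools, length(gp$significant$nodes))
})
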