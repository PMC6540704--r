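# Synthetic mixed-ploidy clonal panel generator.
#
# Emulates the statistical structure of a clonal germplasm collection
# genotyped on a small biallelic fluorescence array: a collection of 141
# accessions (96 diploid, 36 triploid, 9 tetraploid) organised into 43 clonal
# lineages (sizes 1-24) drawn from 5 gene pools, scored on 129 markers with
# minor-allele frequencies above 5%.
#
# Allele-frequency hierarchy: each marker has a collection-wide base
# frequency.  Pools follow a star (planted-partition) design: every pool
# owns a private block of signature markers on which its frequency deviates
# from the base.  Per-pool deviation norms are chosen (least squares, with a
# coherence floor) so that the Ward merge costs of all pool pairs are as
# equal as possible: the pools form a star whose arrangement carries no
# signal - any supra-pool node of the dendrogram is a resampling artifact -
# while each pool itself is separated from the others.  Lineage founder
# frequencies diverge from their pool by Balding-Nichols beta sampling with
# divergence `lineage_fst`.
# Founder dosages are binomial in the founder frequency; clones copy their
# founder and apply at most `somatic_budget` random +/-1 dosage changes
# (somaclonal variation).
#
# Observation model: true dosage -> observed fluorescence class through the
# signal-class map, then a diploid balanced heterozygote is miscalled as an
# unbalanced class with probability `miscall_diploid` (0.09, matching the
# reported diploid polyploid-like ratio), a triploid unbalanced heterozygote
# is miscalled as the balanced class with probability `miscall_triploid`
# (0.17 = 1 - 0.83, the reported triploid ratio), and any call goes missing
# with probability `missing_rate` (0.5%).  Tetraploids get no extra flip
# rate; their 1:3/3:1 dosages are already confounded with triploid classes
# by the signal map.

.default_lineages <- function() {
  # 43 lineages summing to 141 accessions: 96 diploid, 36 triploid,
  # 9 tetraploid; sizes 1-24.  Five gene pools of mixed ploidy composition
  # and near-equal lineage counts (9/8/9/9/8): A triploid-dominated,
  # B tetraploid-dominated, C carries the largest clone families, D and E
  # smaller diploid-dominated pools; single-accession lineages are spread
  # across all pools.
  dip_sizes <- c(24, 14, 10, 6, 5, 4, 3, 3, 2, 2, 2, rep(1, 21))
  tri_sizes <- c(18, 7, 4, 3, 2, 1, 1)
  tet_sizes <- c(5, 2, 1, 1)
  dip_pool <- c("C", "C", "C", "C", "D", "D", "D", "D", "E", "E", "E",
                rep("A", 4), rep("B", 4), rep("C", 3), rep("D", 5),
                rep("E", 5))
  tri_pool <- c("A", "A", "A", "A", "A", "C", "C")
  tet_pool <- c("B", "B", "B", "B")
  tibble(
    lineage = seq_len(43),
    ploidy = c(rep(2L, length(dip_sizes)), rep(3L, length(tri_sizes)),
               rep(4L, length(tet_sizes))),
    size = c(dip_sizes, tri_sizes, tet_sizes),
    pool = c(dip_pool, tri_pool, tet_pool)
  )
}

#' Simulation configuration
#'
#' Defaults describe the emulated collection: 129 markers with alternate
#' allele frequency in (0.05, 0.5), 141 accessions (96/36/9 at ploidy
#' 2x/3x/4x) in 43 clonal lineages of sizes 1-24 drawn from 5 gene pools,
#' diploid het miscall rate 0.09, triploid het miscall rate 0.17, missing
#' rate 0.005, and at most one somatic allele change per clone.
#'
#' @param n_markers Number of biallelic markers.
#' @param maf_range Range the per-marker base alternate-allele frequency is
#'   drawn from (uniform).
#' @param lineages Tibble with columns `lineage`, `ploidy`, `size`, `pool`
#'   defining the clonal structure; the default encodes the collection
#'   geometry above.
#' @param pool_merge_cost Gene-pool separation parameter: the nominal Ward
#'   merge cost between pool pairs.  Each pool deviates from the base
#'   frequency on its own disjoint signature-marker block; the squared
#'   deviation norms are solved so that all between-pool Ward merge costs
#'   tie near this value - pools form a star with no supra-pool structure.
#' @param pool_min_drift Floor on a pool's squared deviation norm, keeping
#'   lineage-rich pools (whose 1/N drift would be weak) internally coherent
#'   relative to the binomial noise of their single-accession lineages.
#' @param lineage_fst Balding-Nichols divergence of lineage founder
#'   frequencies from their pool.
#' @param somatic_budget Maximum number of +/-1 dosage changes per clone;
#'   each non-founder clone draws its count uniformly from `0:somatic_budget`.
#' @param miscall_diploid Probability a diploid balanced het is scored as an
#'   unbalanced (polyploid-like) class.
#' @param miscall_triploid Probability a triploid unbalanced het is scored as
#'   the balanced class.
#' @param missing_rate Per-call missing probability.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_markers = 129,
                       maf_range = c(0.05, 0.5),
                       lineages = .default_lineages(),
                       pool_merge_cost = 47,
                       pool_min_drift = 5.5,
                       lineage_fst = 0.05,
                       somatic_budget = 1,
                       miscall_diploid = 0.09,
                       miscall_triploid = 0.17,
                       missing_rate = 0.005) {
  lineages <- as_tibble(lineages)
  stopifnot(
    n_markers >= 2,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    all(c("lineage", "ploidy", "size", "pool") %in% names(lineages)),
    all(lineages$ploidy %in% 2:4), all(lineages$size >= 1),
    pool_merge_cost >= 0, pool_min_drift >= 0,
    lineage_fst > 0, lineage_fst < 1,
    somatic_budget >= 0,
    miscall_diploid >= 0, miscall_diploid <= 1,
    miscall_triploid >= 0, miscall_triploid <= 1,
    missing_rate >= 0, missing_rate <= 1
  )
  structure(
    list(
      n_markers = as.integer(n_markers), maf_range = maf_range,
      lineages = lineages, pool_merge_cost = pool_merge_cost,
      pool_min_drift = pool_min_drift, lineage_fst = lineage_fst,
      somatic_budget = as.integer(somatic_budget),
      miscall_diploid = miscall_diploid,
      miscall_triploid = miscall_triploid, missing_rate = missing_rate
    ),
    class = "sim_config"
  )
}

# Choose per-pool squared drift norms u2 so that the pairwise Ward merge
# costs (n_i n_j / (n_i + n_j)) * (u2_i + u2_j) are as flat as possible
# around `cost`, subject to the coherence floor.  Deterministic.
.solve_pool_drift <- function(n, cost, floor) {
  if (length(n) == 1L) return(max(cost / n, floor))
  ut <- upper.tri(diag(length(n)))
  f <- (outer(n, n) / outer(n, n, "+"))[ut]
  obj <- function(u) {
    costs <- f * outer(u, u, "+")[ut]
    stats::var(costs) + 50 * (mean(costs) - cost)^2
  }
  res <- stats::optim(pmax(cost / n, floor), obj, method = "L-BFGS-B",
                      lower = floor, upper = cost)
  res$par
}

# Balding-Nichols draw of daughter frequencies around a vector of parents
.bn_draw <- function(parent, fst) {
  p <- pmin(pmax(parent, 0.01), 0.99)
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate a mixed-ploidy clonal genotype panel
#'
#' Draws the pool/lineage allele-frequency hierarchy, founder dosages,
#' somaclonal variants and the noisy fluorescence observation described in
#' [sim_config()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the result is fully reproducible.
#' @param mask_unknown Optional integer vector `c(n_diploid, n_triploid,
#'   n_tetraploid)`: that many accessions per ploidy (the last of each
#'   ploidy block) have their declared ploidy masked to unknown in the
#'   emitted panel metadata.
#' @return A `sim_panel` list: `panel` (a [genotype_panel()] whose declared
#'   ploidies are the true ones, minus any masking) and `truth` (list with
#'   `accessions` tibble - `accession`, `ploidy`, `lineage`, `pool` -, the
#'   true `dosage` matrix, and the `founder_freq` matrix).
#' @export
simulate_panel <- function(config = sim_config(), seed = NULL,
                           mask_unknown = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- config$n_markers
  lin <- config$lineages
  n_acc <- sum(lin$size)
  pools <- sort(unique(lin$pool))

  base_freq <- runif(L, config$maf_range[1], config$maf_range[2])
  # star design: pool k owns a disjoint signature-marker block on which its
  # frequency deviates upward from the base; squared deviation norms come
  # from .solve_pool_drift() so that all between-pool Ward merge costs tie
  # near pool_merge_cost (no supra-pool structure).  Each signature marker
  # carries a deviation proportional to its headroom (0.99 - base), so low
  # frequency markers do most of the work and blocks stay small.
  n_pool <- table(lin$pool)[pools]
  u2 <- .solve_pool_drift(as.numeric(n_pool), config$pool_merge_cost,
                          config$pool_min_drift)
  cap2 <- (0.99 - base_freq)^2
  block_of <- rep(0L, L)
  if (config$pool_merge_cost > 0) {
    i <- 1L
    for (k in order(-u2)) {
      got <- 0
      while (got < u2[k]) {
        if (i > L) {
          stop("pool_merge_cost too large: signature blocks exceed the marker count",
               call. = FALSE)
        }
        block_of[i] <- k
        got <- got + cap2[i]
        i <- i + 1L
      }
    }
  }
  pool_freq <- vapply(seq_along(pools), function(k) {
    q <- base_freq
    sig <- which(block_of == k)
    if (length(sig)) {
      scale <- sqrt(u2[k] / sum(cap2[sig]))
      q[sig] <- base_freq[sig] + scale * (0.99 - base_freq[sig])
    }
    q
  }, numeric(L))
  colnames(pool_freq) <- pools
  founder_freq <- vapply(seq_len(nrow(lin)), function(i) {
    .bn_draw(pool_freq[, lin$pool[i]], config$lineage_fst)
  }, numeric(L))

  acc <- lin[rep(seq_len(nrow(lin)), lin$size), ] |>
    mutate(
      clone_rank = unlist(lapply(lin$size, seq_len)),
      accession = sprintf("acc%03d", seq_len(n_acc))
    ) |>
    select("accession", "ploidy", "lineage", "pool", "clone_rank")

  dosage <- matrix(NA_integer_, n_acc, L,
                   dimnames = list(acc$accession,
                                   sprintf("snp%03d", seq_len(L))))
  for (i in seq_len(nrow(lin))) {
    founder <- rbinom(L, lin$ploidy[i], founder_freq[, i])
    rows <- which(acc$lineage == lin$lineage[i])
    for (r in rows) {
      d <- founder
      if (acc$clone_rank[r] > 1 && config$somatic_budget > 0) {
        n_mut <- sample.int(config$somatic_budget + 1L, 1L) - 1L
        for (m in seq_len(n_mut)) {
          j <- sample.int(L, 1L)
          step <- if (d[j] == 0L) 1L else if (d[j] == lin$ploidy[i]) -1L else
            sample(c(-1L, 1L), 1L)
          d[j] <- d[j] + step
        }
      }
      dosage[r, ] <- d
    }
  }

  # observation: dosage -> observed class, then miscalls and missingness
  obs <- matrix(NA_integer_, n_acc, L, dimnames = dimnames(dosage))
  for (p in c(2L, 3L, 4L)) {
    rows <- which(acc$ploidy == p)
    if (!length(rows)) next
    map <- dosage_to_signal(0:p, p)$observed_index
    obs[rows, ] <- matrix(map[dosage[rows, , drop = FALSE] + 1L],
                          nrow = length(rows))
  }
  dip_rows <- acc$ploidy == 2L
  if (any(dip_rows) && config$miscall_diploid > 0) {
    het <- which(dip_rows[row(obs)] & obs == 3L)
    flip <- het[runif(length(het)) < config$miscall_diploid]
    obs[flip] <- sample(c(2L, 4L), length(flip), replace = TRUE)
  }
  tri_rows <- acc$ploidy == 3L
  if (any(tri_rows) && config$miscall_triploid > 0) {
    het <- which(tri_rows[row(obs)] & obs %in% c(2L, 4L))
    flip <- het[runif(length(het)) < config$miscall_triploid]
    obs[flip] <- 3L
  }
  if (config$missing_rate > 0) {
    obs[runif(length(obs)) < config$missing_rate] <- NA_integer_
  }

  declared <- acc$ploidy
  if (!is.null(mask_unknown)) {
    mask_unknown <- rep_len(as.integer(mask_unknown), 3L)
    for (k in 1:3) {
      p <- k + 1L
      rows <- which(acc$ploidy == p)
      if (mask_unknown[k] > length(rows)) {
        stop("cannot mask more accessions than exist at ploidy ", p,
             call. = FALSE)
      }
      if (mask_unknown[k] > 0) {
        declared[utils::tail(rows, mask_unknown[k])] <- NA_integer_
      }
    }
  }

  panel <- genotype_panel(
    obs,
    accessions = tibble(accession = acc$accession,
                        declared_ploidy = declared),
    markers = tibble(marker = colnames(obs), chromosome = NA_character_,
                     position = NA_integer_)
  )
  structure(
    list(
      panel = panel,
      truth = list(
        accessions = acc, dosage = dosage,
        founder_freq = t(founder_freq), pool_freq = t(pool_freq),
        base_freq = base_freq
      ),
      config = config, seed = seed
    ),
    class = "sim_panel"
  )
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf(
    "<sim_panel> %d accessions x %d markers, %d lineages, %d pools\n",
    n_accessions(x$panel), n_markers(x$panel),
    nrow(x$config$lineages), length(unique(x$config$lineages$pool))
  ))
  invisible(x)
}

#' Write a simulated panel as a file fixture
#'
#' Emits the calls grid, accession metadata (masked ploidies written as
#' `UNKNOWN`) and a ground-truth CSV; the calls/metadata pair round-trips
#' through [read_genotype_panel()] losslessly.
#'
#' @param sim A `sim_panel` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`calls`, `meta`, `truth`).
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    calls = file.path(dir, "calls.csv"),
    meta = file.path(dir, "accessions.csv"),
    truth = file.path(dir, "ground_truth.csv")
  )
  write_genotype_panel(sim$panel, paths[["calls"]], paths[["meta"]])
  readr::write_csv(sim$truth$accessions, paths[["truth"]])
  invisible(paths)
}
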