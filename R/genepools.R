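# Gene-pool detection: Ward clustering of redundancy-group allele-frequency
# profiles with multiscale-bootstrap approximately unbiased (AU) p-values.
#
# The dendrogram is built with Ward's minimum-variance linkage (the "ward.D2"
# convention: squared-distance update on unsquared Euclidean input).  Support
# for each internal node is assessed by resampling markers (the exchangeable
# axis of a frequency profile) with replacement at several relative sizes r;
# BP(r) is the fraction of resampled dendrograms containing the node's exact
# leaf set.  Writing z(sigma) = qnorm(1 - BP) with sigma = sqrt(ceil(rL) / L)
# (the scaling convention of the multiscale-bootstrap literature: sigma^2 =
# resample size over original size), the multiscale model
# z = v*sigma + c/sigma is fitted by weighted least
# squares; the approximately unbiased p-value is AU = 1 - pnorm(v - c) and
# the plain bootstrap proportion at r = 1 is recovered as 1 - pnorm(v + c).
# Gene pools are the maximal non-root nodes with AU at or above the
# significance threshold.

# leaf sets of the internal nodes of an hclust tree, in merge order
.node_leaf_sets <- function(hc) {
  m <- hc$merge
  sets <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    a <- if (m[i, 1] < 0) -m[i, 1] else sets[[m[i, 1]]]
    b <- if (m[i, 2] < 0) -m[i, 2] else sets[[m[i, 2]]]
    sets[[i]] <- sort(c(a, b))
  }
  sets
}

.set_keys <- function(sets) {
  vapply(sets, paste, character(1), collapse = ",")
}

#' Ward dendrogram of group frequency profiles
#'
#' Euclidean distances between rows of the frequency matrix, clustered with
#' Ward's minimum-variance criterion (`ward.D2`).  Markers with any missing
#' frequency are dropped first (with a message), since Ward distances need
#' complete columns.
#'
#' @param freq A G x L numeric matrix of per-group allele frequencies, e.g.
#'   from [group_allele_frequencies()].
#' @return An [stats::hclust] object.
#' @export
ward_cluster <- function(freq) {
  freq <- as.matrix(freq)
  if (nrow(freq) < 2) stop("need at least two groups to cluster",
                           call. = FALSE)
  drop <- colSums(is.na(freq)) > 0
  if (any(drop)) {
    message("dropping ", sum(drop), " marker(s) with missing frequencies")
    freq <- freq[, !drop, drop = FALSE]
  }
  if (ncol(freq) == 0) stop("no complete markers left", call. = FALSE)
  stats::hclust(stats::dist(freq), method = "ward.D2")
}

#' Multiscale bootstrap of dendrogram nodes
#'
#' Resamples markers (columns) with replacement at each relative size in
#' `scales`, reclusters, and counts how often each internal node of the
#' original dendrogram reappears.
#'
#' @param freq A G x L frequency matrix (complete columns are used, as in
#'   [ward_cluster()]).
#' @param scales Relative resample sizes r; each resample draws `ceiling(r*L)`
#'   markers.
#' @param boots Bootstrap replicates per scale.
#' @param seed Integer seed; the whole table is reproducible bit-for-bit.
#' @return A list with `hclust` (the original tree), `bp` (nodes x scales
#'   matrix of bootstrap proportions), `sigma` (per scale,
#'   `sqrt(ceil(rL) / L)`), `boots` and `scales`.
#' @export
multiscale_bootstrap <- function(freq, scales = seq(0.5, 1.4, by = 0.1),
                                 boots = 10000, seed = NULL) {
  freq <- as.matrix(freq)
  drop <- colSums(is.na(freq)) > 0
  if (any(drop)) freq <- freq[, !drop, drop = FALSE]
  L <- ncol(freq)
  if (L < 2) stop("need at least two complete markers", call. = FALSE)
  if (is.null(rownames(freq))) {
    rownames(freq) <- paste0("g", seq_len(nrow(freq)))
  }
  if (!is.null(seed)) set.seed(seed)
  hc <- stats::hclust(stats::dist(freq), method = "ward.D2")
  keys <- .set_keys(.node_leaf_sets(hc))
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(NULL, paste0("r", scales)))
  for (s in seq_along(scales)) {
    Ls <- as.integer(ceiling(scales[s] * L))
    hits <- numeric(length(keys))
    for (b in seq_len(boots)) {
      idx <- sample.int(L, Ls, replace = TRUE)
      hb <- stats::hclust(stats::dist(freq[, idx, drop = FALSE]),
                          method = "ward.D2")
      bk <- .set_keys(.node_leaf_sets(hb))
      hits <- hits + (keys %in% bk)
    }
    bp[, s] <- hits / boots
  }
  list(hclust = hc, bp = bp, sigma = sqrt(ceiling(scales * L) / L),
       boots = boots, scales = scales)
}

#' AU p-value from a multiscale BP curve
#'
#' Fits `qnorm(1 - BP) = v*sigma + c/sigma` by weighted least squares over
#' the scales with non-degenerate BP, weighting each point by the
#' delta-method Fisher information `boots * dnorm(z)^2 / (BP * (1 - BP))`.
#'
#' @param bp Numeric vector of bootstrap proportions, one per scale.
#' @param sigma Numeric vector of sigma values (`sqrt(ceil(rL) / L)`).
#' @param boots Bootstrap replicates behind each BP.
#' @return A one-row tibble with `au`, `bp1` (fitted BP at sigma = 1), `v`,
#'   `c` and `degenerate`.  If fewer than three scales are informative the
#'   fit is not attempted: AU is 1 when the BPs sit at 1, 0 when they sit at
#'   0, and the flag is set.
#' @export
au_pvalue <- function(bp, sigma, boots) {
  use <- is.finite(bp) & bp > 0 & bp < 1
  if (sum(use) < 3) {
    deg <- mean(bp, na.rm = TRUE) >= 0.5
    return(tibble(au = as.numeric(deg), bp1 = as.numeric(deg),
                  v = NA_real_, c = NA_real_, degenerate = TRUE))
  }
  z <- qnorm(1 - bp[use])
  w <- boots * dnorm(z)^2 / (bp[use] * (1 - bp[use]))
  X <- cbind(sigma[use], 1 / sigma[use])
  fit <- lm.wfit(X, z, w)
  v <- fit$coefficients[[1]]
  cc <- fit$coefficients[[2]]
  tibble(au = 1 - pnorm(v - cc), bp1 = 1 - pnorm(v + cc),
         v = v, c = cc, degenerate = FALSE)
}

#' Maximal significant clusters of a dendrogram
#'
#' Returns the maximal (closest-to-root) internal nodes with `au >=
#' threshold` whose leaf sets are disjoint.  The root - the trivial cluster
#' of all leaves, whose BP is identically 1 - is excluded.  Leaves covered by
#' no significant node are reported unassigned.
#'
#' @param hc An [stats::hclust] over the groups.
#' @param au Numeric vector of AU p-values, one per internal node in merge
#'   order.
#' @param threshold Significance level for AU (default 0.95).
#' @return A list with `nodes` (indices of the selected internal nodes),
#'   `members` (list of leaf-label vectors) and `unassigned` (leaf labels).
#' @export
significant_clusters <- function(hc, au, threshold = 0.95) {
  sets <- .node_leaf_sets(hc)
  n_nodes <- length(sets)
  cand <- which(au >= threshold)
  cand <- setdiff(cand, n_nodes) # root excluded
  cand <- cand[order(-lengths(sets[cand]), cand)]
  taken <- integer(0)
  covered <- logical(length(hc$labels))
  for (i in cand) {
    if (any(covered[sets[[i]]])) next
    taken <- c(taken, i)
    covered[sets[[i]]] <- TRUE
  }
  taken <- sort(taken)
  list(
    nodes = taken,
    members = lapply(sets[taken], function(s) hc$labels[s]),
    unassigned = hc$labels[!covered]
  )
}

#' Detect gene pools among redundancy groups
#'
#' End-to-end wrapper: Ward dendrogram of the group frequency profiles,
#' multiscale bootstrap, per-node AU p-values, and the maximal significant
#' clusters, labelled `A`, `B`, ... in leaf order.
#'
#' @inheritParams multiscale_bootstrap
#' @param au_threshold AU significance threshold for a gene pool.
#' @return A `genepool_result`: list with `hclust`, `nodes` (tibble of
#'   per-node AU/BP/v/c), `pools` (tibble `group`, `pool`; unassigned groups
#'   get `NA`), `significant` (the [significant_clusters()] output), plus the
#'   bootstrap settings.
#' @export
gene_pools <- function(freq, boots = 10000, scales = seq(0.5, 1.4, by = 0.1),
                       au_threshold = 0.95, seed = NULL) {
  freq <- as.matrix(freq)
  ms <- multiscale_bootstrap(freq, scales = scales, boots = boots,
                             seed = seed)
  fits <- dplyr::bind_rows(lapply(seq_len(nrow(ms$bp)), function(i) {
    au_pvalue(ms$bp[i, ], ms$sigma, ms$boots)
  }))
  nodes <- dplyr::bind_cols(
    tibble(node = seq_len(nrow(ms$bp)), height = ms$hclust$height),
    fits,
    tibble(bp_raw = if ("r1" %in% colnames(ms$bp)) ms$bp[, "r1"] else
      NA_real_)
  )
  sig <- significant_clusters(ms$hclust, nodes$au, threshold = au_threshold)
  labels <- ms$hclust$labels
  pool_of <- setNames(rep(NA_character_, length(labels)), labels)
  for (k in seq_along(sig$members)) {
    pool_of[sig$members[[k]]] <- LETTERS[k]
  }
  structure(
    list(
      hclust = ms$hclust, nodes = nodes,
      pools = tibble(group = labels, pool = unname(pool_of)),
      significant = sig, boots = boots, scales = scales,
      au_threshold = au_threshold, seed = seed
    ),
    class = "genepool_result"
  )
}

#' @export
print.genepool_result <- function(x, ...) {
  cat(sprintf(
    "<genepool_result> %d groups, %d significant gene pools (AU >= %.2f, %d boots)\n",
    length(x$hclust$labels), length(x$significant$nodes), x$au_threshold,
    x$boots
  ))
  invisible(x)
}

#' @export
tidy.genepool_result <- function(x, ...) x$nodes

#' @export
glance.genepool_result <- function(x, ...) {
  tibble(
    n_groups = length(x$hclust$labels),
    n_pools = length(x$significant$nodes),
    n_unassigned = length(x$significant$unassigned),
    boots = x$boots,
    au_threshold = x$au_threshold
  )
}

#' Dendrogram plot with AU support
#'
#' Draws the Ward dendrogram with AU p-values printed at each internal node;
#' nodes at or above the significance threshold are highlighted.
#'
#' @param object A `genepool_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genepool_result <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  leaf_x <- setNames(seq_len(n), hc$order) # leaf index -> x position
  node_x <- numeric(n - 1)
  node_y <- hc$height
  segs <- NULL
  child_xy <- function(id) {
    if (id < 0) c(leaf_x[[as.character(-id)]], 0) else c(node_x[id],
                                                         node_y[id])
  }
  for (i in seq_len(n - 1)) {
    a <- child_xy(hc$merge[i, 1])
    b <- child_xy(hc$merge[i, 2])
    node_x[i] <- mean(c(a[1], b[1]))
    segs <- rbind(
      segs,
      data.frame(x = a[1], xend = a[1], y = a[2], yend = node_y[i]),
      data.frame(x = b[1], xend = b[1], y = b[2], yend = node_y[i]),
      data.frame(x = a[1], xend = b[1], y = node_y[i], yend = node_y[i])
    )
  }
  lab <- data.frame(
    x = node_x, y = node_y, au = object$nodes$au,
    sig = object$nodes$au >= object$au_threshold &
      seq_len(n - 1) != (n - 1)
  )
  leaves <- data.frame(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend)
    ) +
    ggplot2::geom_label(
      data = lab,
      ggplot2::aes(x = .data$x, y = .data$y, label = sprintf("%.2f", .data$au),
                   colour = .data$sig),
      size = 2.6, label.padding = ggplot2::unit(0.08, "lines")
    ) +
    ggplot2::geom_text(
      data = leaves,
      ggplot2::aes(x = .data$x, y = -0.02 * max(segs$yend), label = .data$label),
      angle = 90, hjust = 1, size = 2.6
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "Ward height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
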