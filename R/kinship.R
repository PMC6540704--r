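# Kinship network over redundancy groups.
#
# Pairwise kinship between groups is measured on their allele-frequency
# profiles as 1 minus the mean absolute frequency difference over co-called
# markers, so groups of different ploidy remain comparable.  Significance is
# assessed by genotype permutations: each permutation independently shuffles,
# per marker, the frequency values across groups, which breaks group identity
# while preserving every marker's frequency spectrum.  One-sided empirical
# p-values use the add-one estimator p = (1 + #{null >= observed}) /
# (B_perm + 1), so p is never exactly zero; pairs with p below the
# significance level become network edges.

#' Profile similarity between redundancy groups
#'
#' @param freq A G x L matrix of group allele frequencies.
#' @return A symmetric G x G similarity matrix (`1 - mean |freq difference|`
#'   over co-called markers), unit diagonal, `NA` where two groups share no
#'   co-called marker.
#' @export
group_similarity_matrix <- function(freq) {
  freq <- as.matrix(freq)
  G <- nrow(freq)
  s <- matrix(NA_real_, G, G, dimnames = list(rownames(freq),
                                              rownames(freq)))
  diag(s) <- 1
  for (i in seq_len(G - 1)) {
    for (j in seq(i + 1, G)) {
      ok <- !is.na(freq[i, ]) & !is.na(freq[j, ])
      if (!any(ok)) next
      s[i, j] <- s[j, i] <- 1 - mean(abs(freq[i, ok] - freq[j, ok]))
    }
  }
  s
}

#' Permutation test of group kinship
#'
#' Builds the null distribution of pairwise profile similarity by shuffling,
#' per marker, the frequency values across groups, and reports the one-sided
#' add-one p-value for every group pair.
#'
#' @param freq A G x L matrix of group allele frequencies.
#' @param n_perm Number of genotype permutations.
#' @param seed Integer seed for reproducibility.
#' @return A `kinship_test` tibble with columns `group_a`, `group_b`,
#'   `similarity`, `p_value`, and attributes `n_perm` and `null_quantiles`
#'   (per-pair 0.95/0.99 null quantiles).
#' @export
kinship_permutation_test <- function(freq, n_perm = 1000, seed = NULL) {
  freq <- as.matrix(freq)
  G <- nrow(freq)
  if (G < 3) warning("fewer than 3 groups: permutation null is nearly degenerate",
                     call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- group_similarity_matrix(freq)
  pair_idx <- which(upper.tri(obs), arr.ind = TRUE)
  ge <- numeric(nrow(pair_idx))
  null_store <- matrix(NA_real_, n_perm, nrow(pair_idx))
  for (b in seq_len(n_perm)) {
    perm <- apply(freq, 2, function(col) col[sample.int(G)])
    ns <- group_similarity_matrix(perm)
    vals <- ns[pair_idx]
    null_store[b, ] <- vals
    ge <- ge + (!is.na(vals) & vals >= obs[pair_idx])
  }
  nm <- rownames(freq)
  if (is.null(nm)) nm <- paste0("group_", seq_len(G))
  out <- tibble(
    group_a = nm[pair_idx[, 1]],
    group_b = nm[pair_idx[, 2]],
    similarity = obs[pair_idx],
    p_value = (1 + ge) / (n_perm + 1)
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "null_quantiles") <- apply(
    null_store, 2, stats::quantile, probs = c(0.95, 0.99), na.rm = TRUE
  )
  class(out) <- c("kinship_test", class(out))
  out
}

#' Build the kinship network
#'
#' @param test A `kinship_test` from [kinship_permutation_test()].
#' @param alpha Significance level; pairs with `p_value < alpha` become edges.
#' @param nodes Optional tibble of node attributes (first column = group
#'   name, e.g. ploidy and gene-pool label) attached to the graph.
#' @return A `kinship_network`: list with `graph` (an [igraph] graph whose
#'   edges carry `similarity` and `p_value`), `edges` (tibble, sorted),
#'   `nodes` and `alpha`.
#' @export
build_kinship_network <- function(test, alpha = 0.05, nodes = NULL) {
  edges <- test |>
    filter(!is.na(.data$p_value), .data$p_value < alpha) |>
    arrange(.data$group_a, .data$group_b)
  all_groups <- sort(unique(c(test$group_a, test$group_b)))
  node_tbl <- tibble(name = all_groups)
  if (!is.null(nodes)) {
    nodes <- as_tibble(nodes)
    names(nodes)[1] <- "name"
    node_tbl <- left_join(node_tbl, nodes, by = "name")
  }
  g <- igraph::graph_from_data_frame(
    edges |> select("group_a", "group_b", "similarity", "p_value"),
    directed = FALSE, vertices = node_tbl
  )
  structure(
    list(graph = g, edges = edges, nodes = node_tbl, alpha = alpha,
         n_perm = attr(test, "n_perm")),
    class = "kinship_network"
  )
}

#' @export
print.kinship_network <- function(x, ...) {
  cat(sprintf(
    "<kinship_network> %d groups, %d significant edges (p < %.3g, %s permutations)\n",
    nrow(x$nodes), nrow(x$edges), x$alpha,
    if (is.null(x$n_perm)) "?" else format(x$n_perm)
  ))
  invisible(x)
}

#' @export
tidy.kinship_network <- function(x, ...) x$edges

#' @export
glance.kinship_network <- function(x, ...) {
  tibble(
    n_groups = nrow(x$nodes),
    n_edges = nrow(x$edges),
    alpha = x$alpha,
    min_edge_similarity = if (nrow(x$edges)) min(x$edges$similarity) else
      NA_real_
  )
}

#' Plot the kinship network
#'
#' Spring-embedded layout; edge darkness encodes similarity, node colour the
#' ploidy (if present in the node table) and node label the gene-pool letter.
#'
#' @param object A `kinship_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinship_network <- function(object, seed = 1, ...) {
  g <- object$graph
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |>
    mutate(x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(g)
  edges <- NULL
  if (nrow(el)) {
    m <- match(el[, 1], nodes$name)
    m2 <- match(el[, 2], nodes$name)
    edges <- tibble(
      x = nodes$x[m], y = nodes$y[m],
      xend = nodes$x[m2], yend = nodes$y[m2],
      similarity = igraph::E(g)$similarity
    )
  }
  p <- ggplot2::ggplot()
  if (!is.null(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$similarity)
    )
  }
  aes_pt <- if ("ploidy" %in% names(nodes)) {
    ggplot2::aes(x = .data$x, y = .data$y,
                 colour = factor(.data$ploidy))
  } else {
    ggplot2::aes(x = .data$x, y = .data$y)
  }
  p <- p + ggplot2::geom_point(data = nodes, aes_pt, size = 3)
  if ("pool" %in% names(nodes)) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$pool),
      nudge_y = 0.12, size = 3, na.rm = TRUE
    )
  }
  p + ggplot2::labs(colour = "ploidy", alpha = "similarity") +
    ggplot2::theme_void()
}
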