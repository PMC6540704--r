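# End-to-end orchestration: ploidy inference -> redundancy groups -> gene
# pools -> kinship network, with file outputs and a machine-readable run
# manifest.  A single global seed derives fixed per-stage offsets so each
# stage is individually reproducible.

#' Run the full collection-analysis pipeline
#'
#' Reads a genotype panel (or takes one directly), assigns unknown ploidies,
#' builds redundancy groups and their allele-frequency profiles, detects
#' gene pools by multiscale-bootstrap Ward clustering, builds the
#' permutation-tested kinship network, and writes every stage output plus a
#' JSON manifest to `out_dir`.
#'
#' @param panel A [genotype_panel()], or the path to a calls CSV.
#' @param meta_csv Accession metadata CSV (when `panel` is a path).
#' @param out_dir Output directory; created if needed.  `NULL` skips file
#'   output.
#' @param max_mismatch Duplicate-link threshold (alleles).
#' @param boots Bootstrap replicates per scale for gene-pool support.
#' @param scales Multiscale-bootstrap relative resample sizes.
#' @param au_threshold AU significance threshold for gene pools.
#' @param n_perm Kinship permutations.
#' @param alpha Kinship edge significance level.
#' @param min_het_calls,t_low,t_high Ploidy-inference settings, see
#'   [assign_unknowns()].
#' @param seed Global seed; stage seeds are `seed + 1000` (gene pools) and
#'   `seed + 2000` (network).
#' @return A `pipeline_result` list: `panel`, `ploidy` (report), `redundancy`,
#'   `freq` (group x marker matrix), `genepools`, `network`, `manifest`.
#' @export
run_pipeline <- function(panel, meta_csv = NULL, out_dir = NULL,
                         max_mismatch = 1, boots = 10000,
                         scales = seq(0.5, 1.4, by = 0.1),
                         au_threshold = 0.95, n_perm = 1000, alpha = 0.05,
                         min_het_calls = 10, t_low = 0.35, t_high = 0.70,
                         seed = 1) {
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("calls file not found: ", panel,
                                  call. = FALSE)
    if (!is.null(meta_csv) && !file.exists(meta_csv)) {
      stop("metadata file not found: ", meta_csv, call. = FALSE)
    }
    panel <- read_genotype_panel(panel, meta_csv)
  }
  stopifnot(inherits(panel, "genotype_panel"))

  pl <- assign_unknowns(panel, min_het_calls = min_het_calls,
                        t_low = t_low, t_high = t_high)
  red <- build_redundancy_groups(pl$panel, max_mismatch = max_mismatch,
                                 report = pl$report)
  freq <- group_allele_frequencies(red, pl$panel)
  gp <- gene_pools(freq, boots = boots, scales = scales,
                   au_threshold = au_threshold, seed = seed + 1000L)
  kt <- kinship_permutation_test(freq, n_perm = n_perm,
                                 seed = seed + 2000L)
  node_attrs <- red$groups |>
    group_by(.data$group_id) |>
    summarise(ploidy = dplyr::first(.data$ploidy), size = n()) |>
    mutate(name = paste0("group_", .data$group_id)) |>
    left_join(gp$pools, by = c(name = "group")) |>
    select("name", "ploidy", "size", "pool")
  net <- build_kinship_network(kt, alpha = alpha, nodes = node_attrs)

  manifest <- list(
    package_version = as.character(utils::packageVersion("clonepanel")),
    seed = seed,
    parameters = list(
      max_mismatch = max_mismatch, boots = boots, scales = scales,
      au_threshold = au_threshold, n_perm = n_perm, alpha = alpha,
      min_het_calls = min_het_calls, t_low = t_low, t_high = t_high
    ),
    panel = list(
      n_accessions = n_accessions(panel), n_markers = n_markers(panel),
      missing_fraction = missing_fraction(panel)
    ),
    results = list(
      n_uncallable = sum(is.na(pl$report$ratio)),
      n_conflicts = sum(pl$report$conflict),
      n_groups = red$n_groups,
      n_pools = length(gp$significant$nodes),
      n_edges = nrow(net$edges)
    )
  )

  out <- structure(
    list(panel = pl$panel, ploidy = pl$report, redundancy = red,
         freq = freq, genepools = gp, network = net, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline stage outputs
#'
#' Emits `ploidy_report.csv`, `redundancy_groups.csv`,
#' `group_frequencies.csv`, `genepool_nodes.csv`, `genepool_members.csv`,
#' `kinship_edges.tsv`, the network in GML, the annotated dendrogram in
#' Newick (node labels `AU|BP`, when the ape package is available) and
#' `manifest.json`.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$ploidy, file.path(out_dir, "ploidy_report.csv"))
  readr::write_csv(result$redundancy$groups,
                   file.path(out_dir, "redundancy_groups.csv"))
  freq_tbl <- as_tibble(result$freq, rownames = "group")
  readr::write_csv(freq_tbl, file.path(out_dir, "group_frequencies.csv"))
  readr::write_csv(result$genepools$nodes,
                   file.path(out_dir, "genepool_nodes.csv"))
  readr::write_csv(result$genepools$pools,
                   file.path(out_dir, "genepool_members.csv"))
  readr::write_tsv(result$network$edges,
                   file.path(out_dir, "kinship_edges.tsv"))
  igraph::write_graph(result$network$graph,
                      file.path(out_dir, "kinship_network.gml"),
                      format = "gml")
  if (requireNamespace("ape", quietly = TRUE)) {
    hc <- result$genepools$hclust
    phy <- ape::as.phylo(hc)
    # map phylo internal nodes to hclust merge rows via their leaf sets
    keys <- .set_keys(.node_leaf_sets(hc))
    ntip <- length(phy$tip.label)
    post <- ape::reorder.phylo(phy, "postorder")
    desc <- c(as.list(seq_len(ntip)), vector("list", phy$Nnode))
    for (e in seq_len(nrow(post$edge))) {
      par <- post$edge[e, 1]
      desc[[par]] <- c(desc[[par]], desc[[post$edge[e, 2]]])
    }
    tip_idx <- match(phy$tip.label, hc$labels)
    phy$node.label <- vapply(seq_len(phy$Nnode), function(k) {
      leaves <- sort(tip_idx[desc[[ntip + k]]])
      i <- match(paste(leaves, collapse = ","), keys)
      sprintf("%.3f|%.3f", result$genepools$nodes$au[i],
              result$genepools$nodes$bp1[i])
    }, character(1))
    ape::write.tree(phy, file.path(out_dir, "genepool_dendrogram.nwk"))
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$manifest$results
  cat(sprintf(
    "<pipeline_result> %d accessions -> %d redundancy groups, %d gene pools, %d kinship edges\n",
    n_accessions(x$panel), r$n_groups, r$n_pools, r$n_edges
  ))
  invisible(x)
}
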