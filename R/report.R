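#' Fisher exact test for regionalization of unstable traits
#'
#' Tests whether unstable traits (type II in-degree zero) are unevenly
#' distributed between two groups of body regions (conventionally the
#' cranio-dental regions S/T/J versus the postcranial regions BP/FL/HL),
#' using the two-sided Fisher exact test on the 2x2 table
#' (unstable vs. not) x (group 1 vs. group 2).
#'
#' @param regions named character vector or two-column data frame mapping
#'   `node_id` to a region code; every node in `degrees` must be mapped.
#' @param degrees data frame from [type2_degrees()].
#' @param group1,group2 character vectors of region codes defining the two
#'   groups (default cranio-dental `S,T,J` vs. postcranial `BP,FL,HL`).
#' @return list with `p.value`, `table` (the 2x2 contingency table) and
#'   `n_unstable_group2`. An empty margin yields `p.value = 1` with a
#'   warning.
#' @export
fisher_regionalization <- function(regions, degrees,
                                   group1 = c("S", "T", "J"),
                                   group2 = c("BP", "FL", "HL")) {
  if (is.data.frame(regions)) {
    regions <- stats::setNames(as.character(regions[[2L]]),
                               as.character(regions[[1L]]))
  }
  reg <- regions[as.character(degrees$node_id)]
  if (anyNA(reg))
    stop("unmapped node id(s): ",
         paste(degrees$node_id[is.na(reg)], collapse = ", "))
  in_split <- reg %in% c(group1, group2)
  unstable <- degrees$in_degree == 0L
  tab <- table(
    factor(ifelse(unstable[in_split], "unstable", "other"),
           levels = c("unstable", "other")),
    factor(ifelse(reg[in_split] %in% group1, "group1", "group2"),
           levels = c("group1", "group2")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("empty margin in regionalization table; p = 1")
    return(list(p.value = 1, table = tab,
                n_unstable_group2 = tab["unstable", "group2"]))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(p.value = ft$p.value, table = tab,
       n_unstable_group2 = tab["unstable", "group2"])
}

#' Run a complete trait-network analysis
#'
#' Pipeline driver: parse -> recode -> build network -> metrics ->
#' permutation tests (when `permutations > 0`) -> nested-pair classification
#' (when a tree is given) -> regionalization test (when regions are given).
#' Writes `summary.json`, `traits.tsv`, `nodes.tsv`, `edges_type1..4.tsv`,
#' `complexes.tsv`, `multiplex.graphml`, and, as applicable,
#' `permutations.tsv`, `nested_pairs.tsv` and `run_log.txt` into `out_dir`.
#' On error, files created by the failed run are removed.
#'
#' @param matrix_file path to the character matrix (NEXUS or delimited).
#' @param out_dir output directory (created if needed).
#' @param format `"auto"` (NEXUS when the file starts with `#NEXUS`),
#'   `"nexus"`, `"csv"` or `"tsv"`.
#' @param tree_file optional newick reference tree.
#' @param regions_file optional two-column TSV mapping node_id to region.
#' @param absence,min_taxa recoding settings (see [recode_traits()]).
#' @param permutations permutation count `M` per null model (0 disables the
#'   tests).
#' @param phylo_k restriction parameter for the phylogenetic null.
#' @param alpha significance level.
#' @param seed integer seed for the permutation streams.
#' @return (invisibly) a list with the trait matrix, network, metrics and,
#'   when computed, permutation/nested-pair/regionalization results.
#' @export
run_trait_analysis <- function(matrix_file, out_dir, format = "auto",
                               tree_file = NULL, regions_file = NULL,
                               absence = NULL, min_taxa = 1L,
                               permutations = 0L, phylo_k = 1.01,
                               alpha = 0.05, seed = NULL) {
  for (f in c(matrix_file, tree_file, regions_file)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  reg <- function(...) {
    written <<- c(written, file.path(out_dir, c(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  log_lines <- c(sprintf("traitgraph run %s", format(Sys.time(), "%Y-%m-%d")),
                 sprintf("matrix=%s tree=%s regions=%s", matrix_file,
                         tree_file %||% "-", regions_file %||% "-"),
                 sprintf("min_taxa=%d permutations=%d k=%g alpha=%g seed=%s",
                         min_taxa, permutations, phylo_k, alpha,
                         if (is.null(seed)) "-" else seed))

  cm <- stage("parse", {
    is_nexus <- format == "nexus" ||
      (format == "auto" &&
         grepl("^\\s*#NEXUS", readLines(matrix_file, n = 1L),
               ignore.case = TRUE))
    if (is_nexus) parse_nexus(matrix_file)
    else parse_table(matrix_file, sep = if (format == "tsv") "\t" else ",")
  })
  tree <- NULL
  if (!is.null(tree_file)) {
    tree <- stage("tree", {
      tr <- parse_newick(tree_file)
      missing <- setdiff(cm$taxa, tr$tip.label)
      if (length(missing))
        stop("matrix taxa absent from tree: ",
             paste(missing, collapse = ", "))
      tr
    })
  }
  tm <- stage("recode", recode_traits(cm, absence = absence,
                                      min_taxa = min_taxa))
  n_missing <- sum(is.na(cm$cells))
  if (n_missing > 0L)
    log_lines <- c(log_lines, sprintf(
      "note: %d missing cell(s) treated as absence of that character's traits",
      n_missing))
  net <- stage("network", build_network(tm))
  metrics <- stage("metrics", network_metrics(net))
  deg <- metrics$degrees

  results <- list(trait_matrix = tm, network = net, metrics = metrics)

  nodes <- cbind(tm$traits[c("node_id", "character_id", "character_label",
                             "state_symbol", "state_label", "support_size",
                             "label")],
                 deg[c("in_degree", "out_degree", "status")],
                 d_centrality = metrics$d_centrality$d_centrality)

  if (permutations > 0L) {
    stats_fn <- trait_network_statistics(per_node = TRUE)
    nulls_e <- stage("nulls", null_distribution(
      cm, stats_fn, model = "equiprobable", M = permutations,
      absence = absence, min_taxa = min_taxa, seed = seed))
    nulls_p <- NULL
    if (!is.null(tree)) {
      nulls_p <- stage("nulls", null_distribution(
        cm, stats_fn, model = "phylogenetic", M = permutations, tree = tree,
        k = phylo_k, absence = absence, min_taxa = min_taxa,
        seed = if (is.null(seed)) NULL else seed + 1L))
    }
    scalar <- Filter(function(x) length(x$observed) == 1L, nulls_e)
    perm_tab <- permutation_table(c(scalar,
      if (!is.null(nulls_p)) Filter(function(x) length(x$observed) == 1L,
                                    nulls_p)),
      n_tests = length(scalar))
    reg("permutations.tsv")
    utils::write.table(perm_tab, file.path(out_dir, "permutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$nulls_equiprobable <- nulls_e
    results$nulls_phylogenetic <- nulls_p
    if (!is.null(nulls_p)) {
      stable <- significant_stable_traits(nulls_e$in_degree,
                                          nulls_p$in_degree, alpha)
      pivotal <- significant_pivotal_traits(nulls_e$d_centrality,
                                            nulls_p$d_centrality, alpha)
      nodes$significantly_stable <- nodes$node_id %in% stable
      nodes$significantly_pivotal <- nodes$node_id %in% pivotal
      results$stable_traits <- stable
      results$pivotal_traits <- pivotal
    }
  }

  if (!is.null(tree)) {
    nested <- stage("phylo", classify_nested_pairs(net, tree))
    reg("nested_pairs.tsv")
    utils::write.table(nested$table, file.path(out_dir, "nested_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$nested_pairs <- nested
  }

  if (!is.null(regions_file)) {
    rmap <- stage("regions", utils::read.table(
      regions_file, sep = "\t", header = TRUE, stringsAsFactors = FALSE))
    fr <- stage("regions", fisher_regionalization(rmap, deg))
    results$regionalization <- fr
    log_lines <- c(log_lines, sprintf(
      "regionalization: p = %.6g, unstable in postcranial group = %d",
      fr$p.value, fr$n_unstable_group2))
  }

  # outputs
  reg("traits.tsv", "nodes.tsv", "complexes.tsv", "summary.json",
      "multiplex.graphml", "run_log.txt",
      sprintf("edges_type%d.tsv", 1:4))
  stage("write", {
    write_trait_matrix(tm, file.path(out_dir, "traits.tsv"))
    utils::write.table(nodes, file.path(out_dir, "nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cx <- metrics$complex_members
    cx_df <- data.frame(
      complex_id = seq_along(cx),
      size = lengths(cx),
      members = vapply(cx, paste, "", collapse = ","),
      shared_support = vapply(cx, function(s)
        paste(tm$taxa[tm$incidence[s[1L], ]], collapse = ","), ""))
    utils::write.table(cx_df, file.path(out_dir, "complexes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_edge_tables(net, out_dir)
    write_graphml(net, file.path(out_dir, "multiplex.graphml"))
    summ <- list(
      schema_version = "1.0",
      settings = list(min_taxa = min_taxa, permutations = permutations,
                      phylo_k = phylo_k, alpha = alpha,
                      seed = seed %||% NA),
      metrics = jsonlite::parse_json(metrics_to_json(metrics)))
    if (!is.null(results$stable_traits)) {
      summ$n_significantly_stable <- length(results$stable_traits)
      summ$n_significantly_pivotal <- length(results$pivotal_traits)
    }
    if (!is.null(results$nested_pairs))
      summ$nested_pair_counts <- as.list(results$nested_pairs$counts)
    if (!is.null(results$regionalization))
      summ$regionalization_p <- results$regionalization$p.value
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  })
  ok <- TRUE
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
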