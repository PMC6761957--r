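#' Equiprobable within-column permutation of a character matrix
#'
#' Independently permutes each column's cell values (missing cells included)
#' uniformly at random across taxa, breaking any phylogenetic structure while
#' preserving every column's state multiset — hence every trait's support
#' size, and trait identity by (character, state).
#'
#' @param cm a `character_matrix`. Uses the session RNG; call [set.seed()]
#'   for reproducibility.
#' @return a permuted `character_matrix`.
#' @export
permute_equiprobable <- function(cm) {
  cm$cells <- .permute_cells_equiprobable(cm$cells)
  cm
}

.permute_cells_equiprobable <- function(cells) {
  n <- nrow(cells)
  for (j in seq_len(ncol(cells))) cells[, j] <- cells[sample.int(n), j]
  cells
}

#' Phylogenetic proximity weights for restricted permutations
#'
#' Patristic (path-length) distances between leaves are normalised to a
#' maximum of 1 and converted to weights `w_ij = k - d_ij`. With the
#' conventional `k = 1.01`, swaps between close relatives are ~100 times more
#' likely than swaps across the tree's full depth; large `k` approaches the
#' equiprobable scheme.
#'
#' @param tree a rooted `phylo` tree covering all `taxa`; trees without
#'   branch lengths get unit lengths with a warning.
#' @param taxa taxon names to cover (order defines the weight matrix order).
#' @param k restriction parameter, must exceed 1 (default 1.01).
#' @return object of class `phylo_weights`: `taxa`, `W` (symmetric matrix
#'   with diagonal `k`), `S` (the sampling weights actually used by
#'   [permute_phylogenetic()], identical to `W` except that the diagonal is
#'   set to each taxon's nearest-neighbour weight), `k`.
#' @export
patristic_weights <- function(tree, taxa, k = 1.01) {
  stopifnot(inherits(tree, "phylo"), k > 1)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  d <- ape::cophenetic.phylo(tree)[taxa, taxa, drop = FALSE]
  mx <- max(d)
  if (mx == 0) {
    warning("all patristic distances are zero; weights are uniform")
    d[] <- 0
  } else {
    d <- d / mx
  }
  W <- k - d
  # sampling weights for the restricted permutation: self-assignment is
  # treated like assignment from the taxon's nearest neighbour, so that a
  # star tree (all taxa equidistant) yields exactly uniform permutations
  S <- W
  if (length(taxa) > 1L) {
    nn <- apply(d + diag(Inf, nrow(d)), 1L, min)
    diag(S) <- k - nn
  }
  structure(list(taxa = taxa, W = W, S = S, k = k), class = "phylo_weights")
}

# One restricted permutation (bijection) of seq_len(n): visit target slots in
# random order; each draws an unused source taxon with probability
# proportional to w(target, source).
.restricted_permutation <- function(W, n) {
  pi <- integer(n)
  remaining <- seq_len(n)
  for (t in sample.int(n)) {
    if (length(remaining) == 1L) {
      pi[t] <- remaining
      break
    }
    pick <- sample(remaining, 1L, prob = W[t, remaining])
    pi[t] <- pick
    remaining <- remaining[remaining != pick]
  }
  pi
}

#' Phylogenetically restricted within-column permutation
#'
#' Per column, draws a random bijection of taxa biased toward exchanging
#' states between phylogenetically close taxa (sequential weighted assignment
#' without replacement under the `k - d` weight law), and assigns each taxon
#' the original state of its source taxon. Column state multisets — and hence
#' trait support sizes — are preserved exactly, as under the equiprobable
#' scheme.
#'
#' @param cm a `character_matrix`.
#' @param weights a `phylo_weights` object covering `cm`'s taxa.
#' @return a permuted `character_matrix`.
#' @export
permute_phylogenetic <- function(cm, weights) {
  stopifnot(inherits(weights, "phylo_weights"))
  idx <- match(cm$taxa, weights$taxa)
  if (anyNA(idx))
    stop("weights do not cover taxa: ",
         paste(cm$taxa[is.na(idx)], collapse = ", "))
  W <- weights$S[idx, idx, drop = FALSE]
  cm$cells <- .permute_cells_phylo(cm$cells, W)
  cm
}

.permute_cells_phylo <- function(cells, W) {
  n <- nrow(cells)
  for (j in seq_len(ncol(cells))) {
    pi <- .restricted_permutation(W, n)
    cells[, j] <- cells[pi, j]
  }
  cells
}

# Precompiled recoding scheme: which (column, symbol) defines each trait.
# Permutations preserve support sizes, so the observed trait set is valid for
# every replicate and incidence can be recomputed by direct comparison.
.recode_scheme <- function(tm) {
  list(col = tm$traits$character_id, sym = tm$traits$state_symbol,
       traits = tm$traits, taxa = tm$taxa)
}

.incidence_from_cells <- function(cells, scheme) {
  M <- t(cells[, scheme$col, drop = FALSE])   # N x taxa
  inc <- !is.na(M) & M == scheme$sym          # length-N vector recycles by row
  dimnames(inc) <- list(scheme$traits$node_id, scheme$taxa)
  inc
}

.network_from_cells <- function(cells, scheme) {
  inc <- .incidence_from_cells(cells, scheme)
  tm <- structure(list(taxa = scheme$taxa, traits = scheme$traits,
                       incidence = inc, N = nrow(inc)),
                  class = "trait_matrix")
  build_network(tm)
}

#' Permutation null distributions for trait-network statistics
#'
#' For each of `M` replicates: permute the character matrix under the chosen
#' null model, rebuild the trait network with the same recoding settings, and
#' evaluate every statistic. Replicates are shared across statistics (one
#' permutation stream per model). Per-node statistics remain aligned across
#' replicates because both permutation schemes preserve trait identity by
#' (character, state).
#'
#' Empirical one-sided p-values use `(b + 1) / (M + 1)`, where `b` counts
#' replicates at least as extreme as the observed value; the smallest
#' attainable p is therefore `1 / (M + 1)`.
#'
#' @param cm the observed `character_matrix`.
#' @param statistics named list of functions `trait_network -> numeric`
#'   (scalar or one value per node); see [trait_network_statistics()].
#' @param model `"equiprobable"` or `"phylogenetic"`.
#' @param M number of permutations (default 5000).
#' @param tree reference `phylo` tree, required for the phylogenetic model.
#' @param k restriction parameter for the phylogenetic model (default 1.01).
#' @param absence,min_taxa recoding settings, as in [recode_traits()].
#' @param seed optional integer seed (stored in the result).
#' @return named list of `null_result` objects: `statistic`, `observed`,
#'   `replicates` (M x length matrix), `p_high`, `p_low`, `model`, `M`,
#'   `M_effective`, `seed`.
#' @export
null_distribution <- function(cm, statistics, model = c("equiprobable",
                              "phylogenetic"), M = 5000L, tree = NULL,
                              k = 1.01, absence = NULL, min_taxa = 1L,
                              seed = NULL) {
  model <- match.arg(model)
  stopifnot(M >= 1L, is.list(statistics), !is.null(names(statistics)))
  if (!is.null(seed)) set.seed(seed)
  weights <- NULL
  if (model == "phylogenetic") {
    if (is.null(tree)) stop("phylogenetic null requested without a tree")
    weights <- patristic_weights(tree, cm$taxa, k)
    W <- weights$S
  }
  tm <- recode_traits(cm, absence = absence, min_taxa = min_taxa)
  scheme <- .recode_scheme(tm)
  net0 <- build_network(tm)
  observed <- lapply(statistics, function(f) as.numeric(f(net0)))
  reps <- lapply(observed, function(o)
    matrix(NA_real_, nrow = M, ncol = length(o)))
  for (r in seq_len(M)) {
    cells <- if (model == "equiprobable")
      .permute_cells_equiprobable(cm$cells)
    else
      .permute_cells_phylo(cm$cells, W)
    net <- .network_from_cells(cells, scheme)
    for (s in names(statistics)) {
      val <- tryCatch(as.numeric(statistics[[s]](net)), error = function(e) {
        warning(sprintf("statistic '%s' failed on replicate %d: %s",
                        s, r, conditionMessage(e)))
        rep(NA_real_, ncol(reps[[s]]))
      })
      reps[[s]][r, ] <- val
    }
  }
  out <- lapply(names(statistics), function(s) {
    R <- reps[[s]]; o <- observed[[s]]
    ok <- !apply(R, 1L, anyNA)
    Me <- sum(ok)
    b_hi <- colSums(R[ok, , drop = FALSE] >= rep(o, each = Me))
    b_lo <- colSums(R[ok, , drop = FALSE] <= rep(o, each = Me))
    structure(list(statistic = s, observed = o,
                   replicates = R, p_high = (b_hi + 1) / (Me + 1),
                   p_low = (b_lo + 1) / (Me + 1), model = model, M = M,
                   M_effective = Me, seed = seed),
              class = "null_result")
  })
  names(out) <- names(statistics)
  out
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("null_result '%s' (%s model, M=%d)\n", x$statistic, x$model,
              x$M))
  if (length(x$observed) == 1L)
    cat(sprintf("  observed %g; p_high %.6g, p_low %.6g\n", x$observed,
                x$p_high, x$p_low))
  else
    cat(sprintf("  per-node statistic over %d nodes\n", length(x$observed)))
  invisible(x)
}

#' Canonical trait-network statistics for permutation testing
#'
#' Returns the named list of statistic functions covering the standard
#' summary table (scalar layer statistics) plus the per-node type II
#' in-degree and type D centrality used to flag stable and pivotal traits.
#'
#' @param per_node include the per-node statistics (default `TRUE`).
#' @return named list of functions `trait_network -> numeric`.
#' @export
trait_network_statistics <- function(per_node = TRUE) {
  stats <- list(
    n_complexes = function(net) length(find_complexes(net)),
    n_edges_I = function(net) nrow(net$edges$I),
    n_edges_II = function(net) nrow(net$edges$II),
    n_edges_III = function(net) nrow(net$edges$III),
    n_edges_IV = function(net) nrow(net$edges$IV),
    n_triangles = function(net) type3_stats(net)$n_triangles,
    proportion_triangles = function(net) type3_stats(net)$proportion_triangles,
    density = function(net) type3_stats(net)$density,
    n_typeD = function(net) count_d_triplets(net)$total
  )
  if (per_node) {
    stats$in_degree <- function(net) type2_degrees(net)$in_degree
    stats$d_centrality <- function(net) count_d_triplets(net)$records$d_centrality
  }
  stats
}

#' Bonferroni correction
#' @param p p-value(s) in (0, 1].
#' @param n_tests size of the test family (>= 1).
#' @return `min(1, p * n_tests)`, elementwise.
#' @export
bonferroni <- function(p, n_tests) {
  stopifnot(n_tests >= 1L, all(p > 0 & p <= 1))
  pmin(1, p * n_tests)
}

# Shared flagging logic for stable/pivotal traits: upper-tail per-node
# p-values under both null models, Bonferroni over all nodes, conjunction.
.flag_significant <- function(null_equi, null_phylo, alpha) {
  stopifnot(inherits(null_equi, "null_result"),
            inherits(null_phylo, "null_result"))
  n <- length(null_equi$p_high)
  if (length(null_phylo$p_high) != n)
    stop("null results cover different node sets")
  min_p <- bonferroni(1 / (pmin(null_equi$M_effective,
                                null_phylo$M_effective) + 1), n)
  if (min_p > alpha)
    warning(sprintf(
      "M too small: minimum attainable corrected p (%.4g) exceeds alpha",
      min_p))
  flagged <- bonferroni(null_equi$p_high, n) <= alpha &
    bonferroni(null_phylo$p_high, n) <= alpha
  which(flagged)
}

#' Traits significantly stable under both null models
#'
#' A trait is significantly stable when its type II in-degree is
#' upper-tail-significant under the equiprobable *and* the phylogenetic
#' permutation null, after Bonferroni correction over all nodes.
#'
#' @param null_equi,null_phylo `null_result` objects for the per-node
#'   `in_degree` statistic under the two models.
#' @param alpha family significance level (default 0.05).
#' @return integer vector of flagged node ids.
#' @export
significant_stable_traits <- function(null_equi, null_phylo, alpha = 0.05) {
  .flag_significant(null_equi, null_phylo, alpha)
}

#' Traits significantly pivotal under both null models
#'
#' As [significant_stable_traits()], with the per-node type D centrality as
#' the statistic: flagged traits are significantly overrepresented at the
#' center of type D triplets.
#'
#' @inheritParams significant_stable_traits
#' @return integer vector of flagged node ids.
#' @export
significant_pivotal_traits <- function(null_equi, null_phylo, alpha = 0.05) {
  .flag_significant(null_equi, null_phylo, alpha)
}

#' Summarise scalar permutation tests as a table
#'
#' @param nulls list of `null_result` objects (scalar statistics only).
#' @param n_tests Bonferroni family size; defaults to the number of scalar
#'   statistics supplied.
#' @param alpha significance level for the direction label (default 0.05).
#' @return data frame with observed value, model, M, raw and corrected
#'   p-values and a direction label (`Higher`/`Lower`/`NS`), one row per
#'   statistic.
#' @export
permutation_table <- function(nulls, n_tests = NULL, alpha = 0.05) {
  nulls <- Filter(function(x) length(x$observed) == 1L, nulls)
  if (is.null(n_tests)) n_tests <- length(nulls)
  rows <- lapply(nulls, function(x) {
    p <- min(x$p_high, x$p_low)
    p_adj <- bonferroni(p, n_tests)
    dir <- if (p_adj > alpha) "NS" else if (x$p_high <= x$p_low) "Higher"
           else "Lower"
    data.frame(statistic = x$statistic, model = x$model,
               observed = x$observed, M = x$M_effective,
               p_high = x$p_high, p_low = x$p_low, p_adjusted = p_adj,
               direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
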