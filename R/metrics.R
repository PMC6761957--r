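#' Find trait complexes (type I connected components)
#'
#' A complex is a set of two or more traits, necessarily from different
#' characters, sharing an identical taxon support. Because identity is
#' transitive, type I components are cliques; this is verified and violations
#' raise an error.
#'
#' @param net a `trait_network`.
#' @return list of integer vectors (node ids), sorted by decreasing size then
#'   by smallest member id; empty list when there are no type I edges.
#' @export
find_complexes <- function(net) {
  e <- net$edges$I
  if (!nrow(e)) return(list())
  g <- .layer_graph(net, "I")
  comp <- igraph::components(g)
  sets <- split(seq_len(net$N), comp$membership)
  sets <- Filter(function(s) length(s) >= 2L, sets)
  for (s in sets) {
    m <- length(s)
    n_in <- sum(e[, 1L] %in% s & e[, 2L] %in% s)
    if (n_in != m * (m - 1L) / 2L)
      stop("type I component is not a clique: identity not transitive")
  }
  sets <- lapply(sets, as.integer)
  ord <- order(-lengths(sets), vapply(sets, min, 0L))
  unname(sets[ord])
}

#' Type II in/out degrees and stability status per trait
#'
#' The in-degree of a trait counts how many other traits have supports
#' strictly nested within its support (incoming type II edges); the
#' out-degree counts how many supports strictly contain it. Traits with zero
#' in-degree but positive out-degree are precarious/unstable; traits with
#' positive in-degree are relatively stable.
#'
#' @param net a `trait_network`.
#' @return data frame with `node_id`, `in_degree`, `out_degree`, `status`
#'   (`"unstable"`, `"stable"`, or `"isolated"` when both degrees are zero).
#' @export
type2_degrees <- function(net) {
  e <- net$edges$II
  out_d <- tabulate(e[, 1L], net$N)
  in_d <- tabulate(e[, 2L], net$N)
  status <- ifelse(in_d > 0L, "stable",
                   ifelse(out_d > 0L, "unstable", "isolated"))
  data.frame(node_id = seq_len(net$N), in_degree = in_d,
             out_degree = out_d, status = status)
}

#' Topology of the type III (overlap) layer
#'
#' Density is `2k / (N(N-1))` and the proportion of triangles is the triangle
#' count divided by the number of *possible* triplets `N(N-1)(N-2)/6`, with
#' `N` the total number of traits (not a clustering coefficient, whose
#' denominator is the number of connected triads). The diameter is the
#' longest shortest path within any connected component; single-node
#' components contribute 0.
#'
#' @param net a `trait_network`.
#' @return list with `k` (edge count), `density`, `n_triangles`,
#'   `proportion_triangles`, `diameter`.
#' @export
type3_stats <- function(net) {
  N <- net$N
  if (N < 2L) stop("density undefined for N < 2")
  if (N < 3L) stop("triangle proportion undefined for N < 3")
  g <- .layer_graph(net, "III")
  k <- nrow(net$edges$III)
  n_tri <- sum(igraph::count_triangles(g)) / 3
  diam <- if (k == 0L) 0 else
    igraph::diameter(g, directed = FALSE, unconnected = TRUE)
  list(k = k,
       density = 2 * k / (N * (N - 1)),
       n_triangles = n_tri,
       proportion_triangles = n_tri / (N * (N - 1) * (N - 2) / 6),
       diameter = diam)
}

#' Count type D triplets and per-trait centrality
#'
#' A type D triplet is an unordered triple `{s, t, u}` in which the central
#' trait `t` overlaps both `s` and `u` (two type III edges) while `s` and `u`
#' are disjoint (a type IV edge). Traits frequently central in such triplets
#' are pivotal: they take part in alternative organisations that never occur
#' together.
#'
#' @param net a `trait_network`.
#' @return list with `total` and `records`, a data frame of `node_id`,
#'   `d_centrality` (each triplet has exactly one central node, so the
#'   centralities sum to `total`).
#' @export
count_d_triplets <- function(net) {
  A3 <- .adjacency(net, "III") * 1
  A4 <- .adjacency(net, "IV") * 1
  # diag(A3 A4 A3)[t] counts ordered (s,u): halve for unordered pairs
  cent <- diag(A3 %*% A4 %*% A3) / 2
  list(total = sum(cent),
       records = data.frame(node_id = seq_len(net$N), d_centrality = cent))
}

#' Summarise a trait network
#'
#' Aggregates the scalar network statistics reported in a standard trait
#' network analysis: number and membership of complexes, edge counts for all
#' four layers, type III density/triangles/diameter, type D triplet total,
#' and per-node degree and centrality records.
#'
#' @param net a `trait_network`.
#' @return object of class `metrics_report` (a list; serialisable with
#'   [metrics_to_json()]).
#' @export
network_metrics <- function(net) {
  complexes <- find_complexes(net)
  t3 <- type3_stats(net)
  dd <- count_d_triplets(net)
  deg <- type2_degrees(net)
  structure(list(
    N = net$N,
    n_complexes = length(complexes),
    complex_members = complexes,
    n_edges = vapply(net$edges, nrow, 0L),
    n_triangles_III = t3$n_triangles,
    proportion_triangles_III = t3$proportion_triangles,
    density_III = t3$density,
    diameter_III = t3$diameter,
    n_typeD = dd$total,
    degrees = deg,
    d_centrality = dd$records
  ), class = "metrics_report")
}

#' @rdname network_metrics
#' @param object a `trait_network`.
#' @param ... ignored.
#' @export
summary.trait_network <- function(object, ...) network_metrics(object)

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("trait network metrics (N = %d)\n", x$N))
  cat(sprintf("  complexes: %d (covering %d traits)\n", x$n_complexes,
              length(unlist(x$complex_members))))
  cat(sprintf("  edges: I=%d II=%d III=%d IV=%d\n",
              x$n_edges[["I"]], x$n_edges[["II"]], x$n_edges[["III"]],
              x$n_edges[["IV"]]))
  cat(sprintf("  type III: density %.6f, triangles %s (proportion %.6f), diameter %g\n",
              x$density_III, format(x$n_triangles_III, big.mark = ","),
              x$proportion_triangles_III, x$diameter_III))
  cat(sprintf("  type D triplets: %s\n", format(x$n_typeD, big.mark = ",")))
  invisible(x)
}

#' Serialise a metrics report to JSON
#' @param report a `metrics_report`.
#' @param file optional output path; when `NULL` the JSON string is returned.
#' @export
metrics_to_json <- function(report, file = NULL) {
  x <- unclass(report)
  x$degrees <- NULL; x$d_centrality <- NULL
  x$n_edges <- as.list(x$n_edges)
  x$complex_members <- lapply(x$complex_members, as.integer)
  if (is.null(file)) {
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
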