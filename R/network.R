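#' Classify the co-occurrence relation between two taxon-support sets
#'
#' The four relation types partition all pairs of non-empty sets:
#' type I (identical supports), type II (one support strictly nested in the
#' other; directed from the nested to the inclusive trait), type III
#' (overlapping but neither nested nor disjoint) and type IV (disjoint).
#'
#' @param a,b non-empty character vectors of taxon names.
#' @return a list with `type` in `"I"`, `"II"`, `"III"`, `"IV"` and, for type
#'   II, `nested`/`inclusive` set to `1` or `2` (argument position).
#' @examples
#' classify_pair(c("a"), c("a", "b"))  # type II, 1 nested in 2
#' @export
classify_pair <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("empty support")
  o <- length(intersect(a, b))
  if (o == 0L) return(list(type = "IV"))
  if (o == length(a) && o == length(b)) return(list(type = "I"))
  if (o == length(a)) return(list(type = "II", nested = 1L, inclusive = 2L))
  if (o == length(b)) return(list(type = "II", nested = 2L, inclusive = 1L))
  list(type = "III")
}

#' Build the multiplex trait network
#'
#' Examines every pair of traits belonging to *different* characters and
#' assigns it to exactly one of the four edge sets; pairs of traits from the
#' same character receive no edge of any type. Construction is deterministic:
#' a given trait matrix yields exactly one network.
#'
#' @param tm a `trait_matrix` (see [recode_traits()]).
#' @return an object of class `trait_network` with fields `trait_matrix`, `N`,
#'   and `edges`: `I`, `III`, `IV` as two-column integer matrices with
#'   `from < to` (unordered pairs), `II` as a two-column matrix directed from
#'   the nested to the inclusive node. Edge matrices are sorted by
#'   (from, to).
#' @export
build_network <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  N <- tm$N
  X <- tm$incidence * 1L
  O <- tcrossprod(X)                      # overlap counts
  s <- rowSums(tm$incidence)
  idx <- which(upper.tri(O), arr.ind = TRUE)  # i < j
  i <- idx[, 1L]; j <- idx[, 2L]
  char <- tm$traits$character_id
  keep <- char[i] != char[j]
  i <- i[keep]; j <- j[keep]
  o <- O[cbind(i, j)]
  si <- s[i]; sj <- s[j]
  e_I  <- o == si & o == sj
  e_IV <- o == 0L
  e_II_ij <- !e_I & o == si              # i nested in j
  e_II_ji <- !e_I & !e_II_ij & o == sj   # j nested in i
  e_III <- !(e_I | e_IV | e_II_ij | e_II_ji)
  pair_mat <- function(f, t) {
    m <- cbind(from = f, to = t)
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  }
  edges <- list(
    I   = pair_mat(i[e_I], j[e_I]),
    II  = pair_mat(c(i[e_II_ij], j[e_II_ji]), c(j[e_II_ij], i[e_II_ji])),
    III = pair_mat(i[e_III], j[e_III]),
    IV  = pair_mat(i[e_IV], j[e_IV])
  )
  structure(list(trait_matrix = tm, N = N, edges = edges),
            class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  cat(sprintf(
    "trait_network: %d nodes; edges I=%d II=%d III=%d IV=%d\n", x$N,
    nrow(x$edges$I), nrow(x$edges$II), nrow(x$edges$III), nrow(x$edges$IV)))
  invisible(x)
}

# Undirected adjacency (logical N x N) for one edge type.
.adjacency <- function(net, type) {
  A <- matrix(FALSE, net$N, net$N)
  e <- net$edges[[type]]
  if (nrow(e)) {
    A[e] <- TRUE
    A[e[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

# igraph view of one layer (undirected for I/III/IV, directed for II),
# always on the full vertex set 1..N.
.layer_graph <- function(net, type) {
  e <- net$edges[[type]]
  igraph::graph_from_edgelist(e, directed = identical(type, "II")) |>
    (\(g) igraph::add_vertices(g, max(0L, net$N - igraph::vcount(g))))()
}

#' Export the multiplex network as GraphML
#'
#' One graph holding all four layers; each edge carries a `type` attribute
#' (`"I"`..`"IV"`) and a `directed` flag (true only for type II edges, which
#' run from the nested to the inclusive trait).
#'
#' @param net a `trait_network`.
#' @param file output path.
#' @export
write_graphml <- function(net, file) {
  el <- do.call(rbind, net$edges)
  type <- rep(names(net$edges), vapply(net$edges, nrow, 0L))
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, net$N - igraph::vcount(g)))
  igraph::E(g)$type <- type
  igraph::E(g)$directed <- type == "II"
  tr <- net$trait_matrix$traits
  igraph::V(g)$label <- tr$label
  igraph::V(g)$character_id <- tr$character_id
  igraph::V(g)$support_size <- tr$support_size
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Write the four edge tables as TSV files
#'
#' Creates `edges_type1.tsv` .. `edges_type4.tsv` in `dir`; each has columns
#' `from`, `to` and `directed` (type II rows run nested -> inclusive).
#'
#' @param net a `trait_network`.
#' @param dir output directory (created if needed).
#' @export
write_edge_tables <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(net$edges)) {
    type <- names(net$edges)[k]
    df <- as.data.frame(net$edges[[type]])
    df$directed <- rep(type == "II", nrow(df))
    utils::write.table(df, file.path(dir, sprintf("edges_type%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
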