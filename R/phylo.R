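#' Parse a newick reference tree
#'
#' Thin wrapper over [ape::read.tree()] enforcing the package's contracts:
#' unique leaf names, and unit branch lengths (with a warning) when the
#' source tree carries none.
#'
#' @param file path to a newick file, or `NULL` when `text` is given.
#' @param text newick string.
#' @return a rooted `phylo` object with branch lengths.
#' @export
parse_newick <- function(file = NULL, text = NULL) {
  tree <- if (is.null(file)) ape::read.tree(text = text)
          else ape::read.tree(file)
  if (is.null(tree)) stop("newick parse error")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree
}

#' Is a taxon set monophyletic on the rooted tree?
#'
#' True iff some edge of the rooted tree subtends exactly this set.
#' Singletons and the full leaf set are monophyletic by convention.
#'
#' @param taxa non-empty character vector of leaf names.
#' @param tree a `phylo` tree.
#' @return logical.
#' @export
is_monophyletic <- function(taxa, tree) {
  taxa <- unique(taxa)
  stopifnot(length(taxa) >= 1L)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L || length(taxa) == length(tree$tip.label))
    return(TRUE)
  ape::is.monophyletic(tree, taxa)
}

#' Classify nested trait pairs against a reference tree
#'
#' Every directed type II edge runs from an inner trait (nested support) to
#' an outer trait (inclusive support). Testing each endpoint's support for
#' monophyly partitions the edges into four classes: `clade_in_clade`
#' (nested synapomorphies), `clade_in_paraphyletic`, `paraphyletic_in_clade`
#' and `paraphyletic_in_paraphyletic`. "Paraphyletic" here means simply "not
#' monophyletic with respect to the sampled taxa".
#'
#' @param net a `trait_network`.
#' @param tree a `phylo` tree covering the network's taxa.
#' @return list with `counts` (named integer vector over the four classes,
#'   summing to the type II edge count) and `table` (one row per edge:
#'   `inner`, `outer`, `inner_mono`, `outer_mono`, `class`).
#' @export
classify_nested_pairs <- function(net, tree) {
  tm <- net$trait_matrix
  missing <- setdiff(tm$taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  classes <- c("clade_in_clade", "clade_in_paraphyletic",
               "paraphyletic_in_clade", "paraphyletic_in_paraphyletic")
  e <- net$edges$II
  supports <- trait_supports(tm)
  # supports recur across nodes; memoise the monophyly test per distinct set
  keys <- vapply(supports, function(s) paste(sort(s), collapse = "\r"), "")
  uniq <- !duplicated(keys)
  mono_by_key <- vapply(supports[uniq], is_monophyletic, TRUE, tree = tree)
  names(mono_by_key) <- keys[uniq]
  node_mono <- unname(mono_by_key[keys])
  if (!nrow(e)) {
    tab <- data.frame(inner = integer(0), outer = integer(0),
                      inner_mono = logical(0), outer_mono = logical(0),
                      class = character(0))
    return(list(counts = stats::setNames(integer(4), classes), table = tab))
  }
  im <- node_mono[e[, 1L]]
  om <- node_mono[e[, 2L]]
  cls <- ifelse(im & om, classes[1L],
         ifelse(im & !om, classes[2L],
         ifelse(!im & om, classes[3L], classes[4L])))
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(cls == cl), 0L), classes)
  list(counts = counts,
       table = data.frame(inner = e[, 1L], outer = e[, 2L],
                          inner_mono = im, outer_mono = om, class = cls))
}
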