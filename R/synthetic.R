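#' Random character matrix (uncoordinated evolution)
#'
#' Draws every cell independently and uniformly from the character's state
#' symbols — the data-generating process matching the equiprobable null —
#' then overwrites cells as missing at `missing_rate`.
#'
#' @param n_taxa,n_characters matrix dimensions (positive).
#' @param n_states number of states per character (single value or vector of
#'   length `n_characters`); symbols are `0, 1, ...`.
#' @param missing_rate probability a cell is missing, in `[0, 1)`.
#' @param taxa optional taxon names (default `t01, t02, ...`).
#' @param seed optional integer seed.
#' @return a [character_matrix()].
#' @export
random_matrix <- function(n_taxa, n_characters, n_states = 2L,
                          missing_rate = 0, taxa = NULL, seed = NULL) {
  stopifnot(n_taxa >= 1L, n_characters >= 1L, all(n_states >= 1L),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  n_states <- rep_len(n_states, n_characters)
  if (is.null(taxa)) taxa <- sprintf("t%02d", seq_len(n_taxa))
  cells <- vapply(seq_len(n_characters), function(j)
    as.character(sample.int(n_states[j], n_taxa, replace = TRUE) - 1L),
    character(n_taxa))
  cells <- matrix(cells, nrow = n_taxa,
                  dimnames = list(taxa, paste0("char", seq_len(n_characters))))
  if (missing_rate > 0) {
    cells[matrix(stats::runif(length(cells)) < missing_rate,
                 nrow = n_taxa)] <- NA
  }
  character_matrix(cells)
}

#' Simulate discrete characters on a tree under the Mk model
#'
#' Each character evolves independently down the tree under the symmetric
#' q-state Markov (Mk) process from a uniformly drawn root state. Branch
#' transition probabilities use the closed-form matrix exponential of the
#' symmetric rate matrix (off-diagonal rate `rate`): the probability of
#' remaining in the current state over a branch of length `t` is
#' `1/q + (q-1)/q * exp(-q * rate * t)`, all other states being equally
#' likely otherwise. Provides phylogenetically autocorrelated data for
#' exercising the phylogenetic null.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param n_characters number of characters to simulate.
#' @param n_states number of states `q` (>= 2).
#' @param rate instantaneous rate of change to each particular other state.
#' @param seed optional integer seed.
#' @return a [character_matrix()] over the tree's leaves.
#' @export
simulate_mk_on_tree <- function(tree, n_characters, n_states = 2L,
                                rate = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_characters >= 1L, n_states >= 2L,
            rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  q <- n_states
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  tree <- stats::reorder(tree)               # parents before children
  state <- matrix(NA_integer_, n_node, n_characters)
  root <- tree$edge[1L, 1L]
  state[root, ] <- sample.int(q, n_characters, replace = TRUE)
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; child <- tree$edge[i, 2L]
    len <- tree$edge.length[i]
    p_stay <- 1 / q + (q - 1) / q * exp(-q * rate * len)
    stay <- stats::runif(n_characters) < p_stay
    s <- state[par, ]
    # a change picks uniformly among the q-1 other states
    jump <- (s - 1L + sample.int(q - 1L, n_characters, replace = TRUE)) %% q + 1L
    state[child, ] <- ifelse(stay, s, jump)
  }
  cells <- matrix(as.character(state[seq_len(n_tip), , drop = FALSE] - 1L),
                  nrow = n_tip,
                  dimnames = list(tree$tip.label,
                                  paste0("char", seq_len(n_characters))))
  character_matrix(cells)
}

#' Worked four-trait fixture with overlapping and disjoint supports
#'
#' Four traits from four different characters over taxa `a`..`e`, with
#' supports `n43 = {a,b}`, `n38 = {b,c,d}`, `n2 = {c,e}`, `n12 = {d,e}`
#' (labels follow the trait numbering of the rhinocerotoid analysis this
#' pattern is drawn from: 43 = convex base of the corpus mandibulae, 38 =
#' massive symphysis, 2 = very concave dorsal skull profile, 12 = very broad
#' rostral end of the nasal bones). The resulting network has four type III
#' edges, two type IV edges, one type III triangle, and trait `n38` central
#' in exactly two type D triplets.
#'
#' @return a `trait_matrix` with four traits.
#' @export
pivotal_trait_fixture <- function() {
  trait_matrix(list(
    n43 = c("a", "b"),
    n38 = c("b", "c", "d"),
    n2  = c("c", "e"),
    n12 = c("d", "e")
  ), taxa = c("a", "b", "c", "d", "e"))
}

#' Write a character matrix as NEXUS
#'
#' Emits a TAXA + CHARACTERS document (standard datatype) with
#' `CHARSTATELABELS` carrying the character and state labels, suitable for
#' re-reading with [parse_nexus()].
#'
#' @param cm a `character_matrix`.
#' @param file output path, or `NULL` to return the document text.
#' @export
write_nexus <- function(cm, file = NULL) {
  syms <- sort(unique(unlist(lapply(cm$characters, function(ch)
    names(ch$states)))))
  quote_lab <- function(x) {
    ifelse(grepl("[^A-Za-z0-9_.]", x), paste0("'", gsub("'", "", x), "'"), x)
  }
  csl <- vapply(cm$characters, function(ch) {
    sprintf("    %d %s / %s", ch$id, quote_lab(ch$label),
            paste(quote_lab(unname(ch$states)), collapse = " "))
  }, "")
  cells <- cm$cells
  cells[is.na(cells)] <- "?"
  rows <- sprintf("    %-30s %s", gsub(" ", "_", cm$taxa),
                  apply(cells, 1L, paste, collapse = ""))
  doc <- c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", length(cm$taxa)),
    sprintf("  TAXLABELS %s;", paste(gsub(" ", "_", cm$taxa), collapse = " ")),
    "END;",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NCHAR=%d;", length(cm$characters)),
    sprintf("  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"%s\";",
            paste(syms, collapse = "")),
    "  CHARSTATELABELS",
    paste(paste(csl, collapse = ",\n"), ";", sep = ""),
    "  MATRIX",
    rows,
    "  ;",
    "END;")
  if (is.null(file)) return(paste(doc, collapse = "\n"))
  writeLines(doc, file)
  invisible(file)
}
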