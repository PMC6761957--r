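# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorised code paths: everything is plain set algebra
# and exhaustive enumeration on small instances.

# Classify two taxon sets by testing the four set predicates independently.
brute_classify <- function(a, b) {
  if (setequal(a, b)) return("I")
  if (all(a %in% b)) return("II_12")
  if (all(b %in% a)) return("II_21")
  if (!length(intersect(a, b))) return("IV")
  "III"
}

# Build edge sets for a trait_matrix by looping over all pairs.
brute_network <- function(tm) {
  supp <- trait_supports(tm)
  char <- tm$traits$character_id
  N <- tm$N
  edges <- list(I = NULL, II = NULL, III = NULL, IV = NULL)
  add <- function(type, f, t) edges[[type]] <<- rbind(edges[[type]], c(f, t))
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    if (char[i] == char[j]) next
    switch(brute_classify(supp[[i]], supp[[j]]),
           I = add("I", i, j),
           II_12 = add("II", i, j),
           II_21 = add("II", j, i),
           III = add("III", i, j),
           IV = add("IV", i, j))
  }
  lapply(edges, function(e) {
    if (is.null(e)) return(matrix(integer(0), 0, 2))
    e[order(e[, 1], e[, 2]), , drop = FALSE]
  })
}

# Exhaustive triangle and type D triplet counts over all C(N,3) triples.
brute_triangles_and_d <- function(net) {
  has <- function(type, x, y) {
    e <- net$edges[[type]]
    any(e[, 1] == min(x, y) & e[, 2] == max(x, y))
  }
  has_dir_any <- function(x, y) has("III", x, y)
  N <- net$N
  n_tri <- 0L
  d_cent <- integer(N)
  if (N >= 3L) for (s in 1:(N - 2L)) for (t in (s + 1L):(N - 1L))
    for (u in (t + 1L):N) {
      trio <- c(s, t, u)
      e3 <- c(has("III", s, t), has("III", t, u), has("III", s, u))
      if (all(e3)) n_tri <- n_tri + 1L
      # central node of a D triplet: III to both others, which are IV-linked
      for (c_idx in 1:3) {
        cen <- trio[c_idx]; rest <- trio[-c_idx]
        if (has("III", cen, rest[1]) && has("III", cen, rest[2]) &&
            has("IV", rest[1], rest[2]))
          d_cent[cen] <- d_cent[cen] + 1L
      }
    }
  list(n_triangles = n_tri, d_centrality = d_cent)
}

# Monophyly by enumerating the leaf set subtended by every internal node.
brute_monophyletic <- function(taxa, tree) {
  taxa <- unique(taxa)
  if (length(taxa) <= 1L || length(taxa) == length(tree$tip.label))
    return(TRUE)
  clades <- ape::prop.part(tree)
  labels <- attr(clades, "labels")
  any(vapply(clades, function(cl) setequal(labels[cl], taxa), TRUE))
}

# Random trait matrix whose supports may collide, nest, or overlap; each
# character contributes its non-absence states.
random_trait_matrix <- function(n_taxa, n_char, n_states = 3L) {
  cm <- random_matrix(n_taxa, n_char, n_states)
  tryCatch(recode_traits(cm), error = function(e) NULL)
}

# A ladder matrix: character j is present exactly in the first k_j taxa, so
# every trait support is a "tail" (here: head) set of the taxon order and the
# type II layer is rich in hubs. State 0 is labelled as an absence state.
ladder_matrix <- function(n_taxa, n_char, sizes = NULL) {
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  if (is.null(sizes)) sizes <- sample(seq_len(n_taxa), n_char, replace = TRUE)
  cells <- vapply(sizes, function(k)
    c(rep("1", k), rep("0", n_taxa - k)), character(n_taxa))
  rownames(cells) <- taxa
  character_matrix(cells,
                   state_labels = rep(list(c(`0` = "absent", `1` = "present")),
                                      n_char))
}

# 5-taxon, 4-character matrix whose recoding reproduces pivotal_trait_fixture().
pivotal_character_matrix <- function() {
  taxa <- c("a", "b", "c", "d", "e")
  supports <- list(n43 = c("a", "b"), n38 = c("b", "c", "d"),
                   n2 = c("c", "e"), n12 = c("d", "e"))
  cells <- vapply(supports, function(s) ifelse(taxa %in% s, "1", "0"),
                  character(5))
  rownames(cells) <- taxa
  character_matrix(cells,
                   char_labels = names(supports),
                   state_labels = rep(list(c(`0` = "absent", `1` = "present")),
                                      4))
}
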