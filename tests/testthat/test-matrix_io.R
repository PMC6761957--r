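nexus_doc <- function(matrix_lines, ntax, nchar, extra_format = "",
                      labels = "") {
  paste(c("#NEXUS",
          "BEGIN DATA;",
          sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", ntax, nchar),
          sprintf("  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"012\"%s;",
                  extra_format),
          labels,
          "  MATRIX", matrix_lines, "  ;", "END;"),
        collapse = "\n")
}

test_that("NEXUS parsing recovers taxa, states, labels and missing cells", {
  doc <- nexus_doc(c("    taxA 01?", "    taxB 120"), 2, 3,
                   labels = paste0("  CHARSTATELABELS\n",
                                   "    1 horn / absent present,\n",
                                   "    2 'tooth shape' / flat sharp curved;"))
  cm <- parse_nexus(text = doc)
  expect_s3_class(cm, "character_matrix")
  expect_equal(cm$taxa, c("taxA", "taxB"))
  expect_equal(length(cm$characters), 3L)
  expect_true(is.na(cm$cells["taxA", 3]))
  expect_equal(cm$characters[[1]]$label, "horn")
  expect_equal(unname(cm$characters[[1]]$states[c("0", "1")]),
               c("absent", "present"))
  expect_equal(unname(cm$characters[[2]]$states[["2"]]), "curved")
  # unlabeled character: states fall back to symbols
  expect_equal(unname(cm$characters[[3]]$states["0"]), "0")
})

test_that("minimal two-taxon one-character NEXUS round-trips symbols", {
  doc <- nexus_doc(c("    A 0", "    B 1"), 2, 1)
  cm <- parse_nexus(text = doc)
  expect_equal(dim(cm), c(2L, 1L))
  expect_equal(unname(cm$cells[, 1]), c("0", "1"))
})

test_that("NEXUS symbols outside the declared SYMBOLS set are rejected", {
  doc <- nexus_doc(c("    A 03", "    B 12"), 2, 2)
  expect_error(parse_nexus(text = doc), "SYMBOLS")
})

test_that("delimited tables parse with configurable missing token", {
  cm <- parse_table(text = "taxon,c1,c2\nA,0,2\nB,1,1\nC,2,0", sep = ",")
  expect_equal(cm$taxa, c("A", "B", "C"))
  expect_equal(names(cm$characters[[1]]$states), c("0", "1", "2"))
  cm2 <- parse_table(text = "t,c1\nA,-\nB,1", sep = ",", missing = "-")
  expect_true(is.na(cm2$cells["A", 1]))
  expect_error(parse_table(text = "t,c1\n"), "empty|degenerate")
  expect_error(parse_table(text = "t,c1,c2\nA,0\nB,1,2", sep = ","),
               "parse error")
})

test_that("recoding splits multistate characters into one trait per state", {
  cm <- parse_table(text = "t,c1\nA,0\nB,1\nC,2", sep = ",")
  tm <- recode_traits(cm)
  expect_equal(tm$N, 3L)
  expect_equal(tm$traits$state_symbol, c("0", "1", "2"))
  expect_equal(tm$traits$node_id, 1:3)
  expect_equal(trait_supports(tm), list(`1` = "A", `2` = "B", `3` = "C"),
               ignore_attr = TRUE)
})

test_that("absence states are excluded and min_taxa prunes rare traits", {
  cells <- matrix(c("1", "1", "0",
                    "1", "0", "0"), nrow = 3,
                  dimnames = list(c("A", "B", "C"), c("c1", "c2")))
  cm <- character_matrix(
    cells, state_labels = rep(list(c(`0` = "absent", `1` = "present")), 2))
  tm <- recode_traits(cm)
  expect_equal(tm$N, 2L)                    # only the two 'present' traits
  expect_equal(tm$traits$state_symbol, c("1", "1"))
  tm2 <- recode_traits(cm, min_taxa = 2L)
  expect_equal(tm2$N, 1L)                   # c2's singleton trait dropped
  expect_equal(tm2$traits$character_id, 1L)
  # explicit token vector also works
  tm3 <- recode_traits(cm, absence = "0")
  expect_equal(tm3$N, 2L)
  expect_error(recode_traits(cm, absence = c("0", "1")), "empty trait set")
})

test_that("missing cells contribute to no trait's support", {
  cm <- parse_table(text = "t,c1\nA,0\nB,?\nC,0", sep = ",")
  tm <- recode_traits(cm)
  expect_equal(tm$N, 1L)
  expect_equal(trait_supports(tm)[[1]], c("A", "C"))
})

test_that("recoding is lossless for non-missing, non-absence content", {
  set.seed(41)
  for (rep in 1:20) {
    cm <- random_matrix(sample(3:8, 1), sample(2:6, 1), sample(2:4, 1),
                        missing_rate = 0.1)
    tm <- recode_traits(cm)
    for (ch in cm$characters) {
      covered <- sort(unique(unlist(
        trait_supports(tm)[tm$traits$character_id == ch$id])))
      observed <- sort(cm$taxa[!is.na(cm$cells[, ch$id])])
      expect_equal(covered, observed)
    }
  }
})

test_that("trait matrix TSV round-trips through write and read", {
  tm <- recode_traits(random_matrix(5, 4, 3, seed = 11))
  txt <- write_trait_matrix(tm)
  tm2 <- read_trait_matrix(text = txt)
  expect_equal(tm2$taxa, tm$taxa)
  expect_equal(tm2$traits$character_id, tm$traits$character_id)
  expect_equal(tm2$traits$state_symbol, tm$traits$state_symbol)
  expect_equal(unname(tm2$incidence), unname(tm$incidence))
  # one presence per supported taxon in a 1-trait matrix
  tm1 <- trait_matrix(list(x = c("A")), taxa = c("A", "B"))
  lines <- strsplit(write_trait_matrix(tm1), "\n")[[1]]
  expect_equal(strsplit(lines[2], "\t")[[1]][7:8], c("1", "0"))
})

test_that("NEXUS writer round-trips generated matrices", {
  cm <- random_matrix(6, 8, 3, missing_rate = 0.05, seed = 2)
  cm2 <- parse_nexus(text = write_nexus(cm))
  expect_identical(cm2$cells[cm$taxa, ], cm$cells)
})

test_that("support sizes are invariant under within-column permutation", {
  cm <- random_matrix(8, 6, 3, missing_rate = 0.1, seed = 5)
  tm <- recode_traits(cm)
  set.seed(9)
  for (i in 1:10) {
    pm <- permute_equiprobable(cm)
    tmp <- recode_traits(pm)
    expect_equal(tmp$traits$support_size, tm$traits$support_size)
    expect_equal(tmp$traits$state_symbol, tm$traits$state_symbol)
  }
})
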