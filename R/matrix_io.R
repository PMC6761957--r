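#' Construct a character matrix
#'
#' A `character_matrix` holds a taxa-by-characters table of discrete state
#' symbols, together with per-character metadata (a label and an ordered
#' symbol-to-state-label mapping). Missing observations are stored as `NA`.
#'
#' @param cells character matrix, taxa in rows (rownames required), one column
#'   per character; `NA` marks a missing observation.
#' @param char_labels optional character vector of character (column) labels;
#'   defaults to column names or `"char<i>"`.
#' @param state_labels optional list, one element per character, each a named
#'   character vector mapping state symbol to state label. Symbols observed in
#'   `cells` but not listed are appended with the symbol as its own label.
#' @return an object of class `character_matrix` with fields `taxa`, `cells`
#'   and `characters` (a list of `id`, `label`, `states` records).
#' @export
character_matrix <- function(cells, char_labels = NULL, state_labels = NULL) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (is.null(rownames(cells))) stop("cells must have taxon rownames")
  if (nrow(cells) == 0L || ncol(cells) == 0L) stop("empty character matrix")
  taxa <- rownames(cells)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  nc <- ncol(cells)
  if (is.null(char_labels)) {
    char_labels <- colnames(cells)
    if (is.null(char_labels)) char_labels <- paste0("char", seq_len(nc))
  }
  stopifnot(length(char_labels) == nc)
  colnames(cells) <- char_labels
  characters <- vector("list", nc)
  for (j in seq_len(nc)) {
    declared <- if (!is.null(state_labels) && length(state_labels) >= j)
      state_labels[[j]] else NULL
    observed <- sort(unique(cells[, j]))
    observed <- observed[!is.na(observed)]
    states <- declared
    if (is.null(states)) states <- character(0)
    extra <- setdiff(observed, names(states))
    if (length(extra)) states[extra] <- extra
    characters[[j]] <- list(id = j, label = char_labels[[j]], states = states)
  }
  structure(
    list(taxa = taxa, characters = characters, cells = cells),
    class = "character_matrix"
  )
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters (%d missing cells)\n",
              length(x$taxa), length(x$characters), sum(is.na(x$cells))))
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

# Internal invariant check used by tests and after permutation.
validate_character_matrix <- function(cm) {
  stopifnot(inherits(cm, "character_matrix"))
  stopifnot(!anyDuplicated(cm$taxa), identical(rownames(cm$cells), cm$taxa))
  for (ch in cm$characters) {
    obs <- cm$cells[, ch$id]
    obs <- obs[!is.na(obs)]
    if (!all(obs %in% names(ch$states))) {
      stop(sprintf("character %d: undeclared state symbol(s): %s", ch$id,
                   paste(setdiff(obs, names(ch$states)), collapse = ", ")))
    }
  }
  invisible(cm)
}

# --- NEXUS ------------------------------------------------------------------

# Pull a FORMAT subcommand token (e.g. MISSING=?, SYMBOLS="012") out of the
# raw document; ape::read.nexus.data parses the matrix but drops FORMAT and
# the state-label commands, so these are recovered with a targeted scan.
.nexus_format_token <- function(text, key) {
  m <- regmatches(text, regexpr(
    paste0("(?i)", key, "\\s*=\\s*(\"[^\"]*\"|\\S+)"), text, perl = TRUE))
  if (!length(m)) return(NULL)
  val <- sub(paste0("(?i)^", key, "\\s*=\\s*"), "", m[[1]], perl = TRUE)
  gsub("\"", "", val)
}

# Parse CHARSTATELABELS (character label + state labels per character) or
# STATELABELS (state labels only). Returns list(char_labels=, state_labels=).
.nexus_state_labels <- function(text, n_char, symbols) {
  out <- list(char_labels = NULL, state_labels = vector("list", n_char))
  grab <- function(cmd) {
    m <- regmatches(text, regexpr(
      paste0("(?i)", cmd, "\\s+[^;]*;"), text, perl = TRUE))
    if (!length(m)) return(NULL)
    body <- sub(paste0("(?i)^", cmd, "\\s+"), "", sub(";$", "", m[[1]]),
                perl = TRUE)
    strsplit(body, ",")[[1]]
  }
  # tokens: quoted labels may contain spaces
  toks <- function(s) {
    m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", s, perl = TRUE)
    v <- regmatches(s, m)[[1]]
    gsub("^['\"]|['\"]$", "", v)
  }
  entries <- grab("CHARSTATELABELS")
  if (!is.null(entries)) {
    out$char_labels <- rep(NA_character_, n_char)
    for (e in entries) {
      v <- toks(e)
      if (!length(v)) next
      idx <- suppressWarnings(as.integer(v[[1]]))
      if (is.na(idx) || idx < 1L || idx > n_char) next
      rest <- v[-1]
      slash <- match("/", rest)
      if (is.na(slash)) {
        if (length(rest)) out$char_labels[idx] <- paste(rest, collapse = " ")
      } else {
        if (slash > 1L)
          out$char_labels[idx] <- paste(rest[seq_len(slash - 1L)], collapse = " ")
        labs <- rest[-seq_len(slash)]
        if (length(labs)) {
          syms <- symbols[seq_along(labs)]
          out$state_labels[[idx]] <- stats::setNames(labs, syms)
        }
      }
    }
    return(out)
  }
  entries <- grab("STATELABELS")
  if (!is.null(entries)) {
    for (e in entries) {
      v <- toks(e)
      if (length(v) < 2L) next
      idx <- suppressWarnings(as.integer(v[[1]]))
      if (is.na(idx) || idx < 1L || idx > n_char) next
      labs <- v[-1]
      out$state_labels[[idx]] <- stats::setNames(labs, symbols[seq_along(labs)])
    }
  }
  out
}

#' Parse a NEXUS character matrix
#'
#' Reads a DATA or CHARACTERS block (standard datatype) including, when
#' present, the `FORMAT` `MISSING`/`GAP`/`SYMBOLS` subcommands and
#' `CHARSTATELABELS`/`STATELABELS`. Gap symbols are treated as missing;
#' unlabeled states get their symbol as label.
#'
#' @param file path to a NEXUS file, or `NULL` when `text` is given.
#' @param text NEXUS document as a single string (alternative to `file`).
#' @return a [character_matrix()].
#' @export
parse_nexus <- function(file = NULL, text = NULL) {
  if (is.null(file)) {
    stopifnot(!is.null(text))
    file <- tempfile(fileext = ".nex")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  raw <- paste(readLines(file, warn = FALSE), collapse = "\n")
  dat <- ape::read.nexus.data(file)
  if (!length(dat)) stop("NEXUS parse error: no taxa found")
  n_char <- length(dat[[1]])
  if (any(lengths(dat) != n_char)) {
    bad <- names(dat)[lengths(dat) != n_char]
    stop("NEXUS parse error: unequal sequence length for taxa: ",
         paste(bad, collapse = ", "))
  }
  missing_tok <- .nexus_format_token(raw, "MISSING")
  if (is.null(missing_tok)) missing_tok <- "?"
  gap_tok <- .nexus_format_token(raw, "GAP")
  symbols <- .nexus_format_token(raw, "SYMBOLS")
  symbols <- if (is.null(symbols)) strsplit("0123456789", "")[[1]]
             else strsplit(gsub("\\s", "", symbols), "")[[1]]
  cells <- do.call(rbind, dat)
  rownames(cells) <- names(dat)
  bad <- nchar(cells) != 1L
  if (any(bad)) stop("polymorphic or malformed cell(s) unsupported: ",
                     paste(unique(cells[bad]), collapse = ", "))
  cells[cells == missing_tok] <- NA
  if (!is.null(gap_tok)) cells[cells == gap_tok] <- NA
  labs <- .nexus_state_labels(raw, n_char, symbols)
  state_labels <- lapply(seq_len(n_char), function(j) {
    sl <- labs$state_labels[[j]]
    # keep declared symbol order first, then any remaining declared symbols
    obs <- unique(cells[, j]); obs <- obs[!is.na(obs)]
    undeclared <- setdiff(obs, c(names(sl), symbols))
    if (length(undeclared)) {
      stop(sprintf("character %d: symbol(s) %s not in SYMBOLS", j,
                   paste(undeclared, collapse = ", ")))
    }
    ordered_syms <- c(names(sl), setdiff(intersect(symbols, obs), names(sl)))
    out <- stats::setNames(ifelse(is.na(match(ordered_syms, names(sl))),
                                  ordered_syms, sl[ordered_syms]),
                           ordered_syms)
    out
  })
  char_labels <- labs$char_labels
  if (!is.null(char_labels)) {
    char_labels[is.na(char_labels)] <-
      paste0("char", which(is.na(char_labels)))
  }
  character_matrix(cells, char_labels = char_labels,
                   state_labels = state_labels)
}

#' Parse a delimited character matrix
#'
#' Rectangular table, first column taxon names, one column per character,
#' optional header row of character labels. State labels default to symbols.
#'
#' @param file path to the table, or `NULL` when `text` is given.
#' @param text table content as a string.
#' @param sep field delimiter (default `","`).
#' @param missing missing-data token (default `"?"`).
#' @param header whether the first row holds character labels.
#' @return a [character_matrix()].
#' @export
parse_table <- function(file = NULL, text = NULL, sep = ",", missing = "?",
                        header = TRUE) {
  src <- if (is.null(file)) textConnection(text) else file
  df <- tryCatch(
    utils::read.table(src, sep = sep, header = header,
                      colClasses = "character", check.names = FALSE,
                      strip.white = TRUE, comment.char = ""),
    error = function(e) stop("table parse error: ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or degenerate table")
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- df[[1]]
  cells[cells == missing | cells == ""] <- NA
  character_matrix(cells)
}

# --- Recoding into traits ---------------------------------------------------

# Resolve the user-facing `absence` argument to a predicate(label, symbol).
.absence_predicate <- function(absence) {
  if (is.null(absence)) {
    return(function(label, symbol) grepl("absen", label, ignore.case = TRUE))
  }
  if (is.function(absence)) return(absence)
  if (is.character(absence)) {
    toks <- absence
    return(function(label, symbol) label %in% toks | symbol %in% toks)
  }
  stop("absence must be NULL, a predicate function, or a character vector")
}

#' Recode a character matrix into presence/absence traits
#'
#' Every non-absence state of every character becomes one trait (a network
#' node), supported by the set of taxa bearing that state. Missing cells
#' contribute to no trait's support. Traits are ordered by character, then by
#' the character's state-symbol order, and numbered 1..N.
#'
#' @param cm a [character_matrix()].
#' @param absence `NULL` (default: state labels matching `"absen"`,
#'   case-insensitively, are absence states), a predicate
#'   `function(label, symbol)`, or a character vector of absence
#'   symbols/labels.
#' @param min_taxa drop traits supported by fewer than this many taxa
#'   (default 1, i.e. keep single-host traits).
#' @return an object of class `trait_matrix`: fields `taxa`, `traits` (a
#'   data frame with `node_id`, `character_id`, `character_label`,
#'   `state_symbol`, `state_label`, `support_size`) and `incidence`
#'   (logical N x taxa matrix).
#' @export
recode_traits <- function(cm, absence = NULL, min_taxa = 1L) {
  stopifnot(inherits(cm, "character_matrix"), min_taxa >= 1L)
  is_absent <- .absence_predicate(absence)
  rows <- list(); inc <- list()
  for (ch in cm$characters) {
    col <- cm$cells[, ch$id]
    for (s in names(ch$states)) {
      lab <- ch$states[[s]]
      if (isTRUE(is_absent(lab, s))) next
      supp <- !is.na(col) & col == s
      if (sum(supp) < min_taxa) next
      rows[[length(rows) + 1L]] <- data.frame(
        character_id = ch$id, character_label = ch$label,
        state_symbol = s, state_label = lab,
        support_size = sum(supp), stringsAsFactors = FALSE)
      inc[[length(inc) + 1L]] <- supp
    }
  }
  if (!length(rows)) stop("empty trait set")
  traits <- do.call(rbind, rows)
  traits <- cbind(node_id = seq_len(nrow(traits)), traits)
  traits$label <- sprintf("%s|'%s'", traits$character_label,
                          traits$state_label)
  incidence <- do.call(rbind, inc)
  dimnames(incidence) <- list(traits$node_id, cm$taxa)
  new_trait_matrix(cm$taxa, traits, incidence)
}

new_trait_matrix <- function(taxa, traits, incidence) {
  stopifnot(nrow(traits) == nrow(incidence), length(taxa) == ncol(incidence))
  if (anyDuplicated(traits[c("character_id", "state_symbol")]))
    stop("duplicate (character, state) trait")
  if (any(rowSums(incidence) == 0L)) stop("trait with empty support")
  structure(list(taxa = taxa, traits = traits, incidence = incidence,
                 N = nrow(traits)),
            class = "trait_matrix")
}

#' Construct a trait matrix directly from taxon-support sets
#'
#' Convenience constructor for fixtures and examples: one trait per element of
#' `supports`, each assigned to its own character unless `character_id` says
#' otherwise.
#'
#' @param supports list of character vectors (taxon sets), optionally named
#'   (names become labels).
#' @param taxa taxon universe; defaults to the sorted union of the supports.
#' @param character_id integer vector assigning traits to characters
#'   (default: all distinct).
#' @return a `trait_matrix`.
#' @export
trait_matrix <- function(supports, taxa = NULL,
                         character_id = seq_along(supports)) {
  if (is.null(taxa)) taxa <- sort(unique(unlist(supports)))
  labs <- names(supports)
  if (is.null(labs)) labs <- paste0("trait", seq_along(supports))
  character_id <- as.integer(character_id)
  # distinct state symbols within a shared character
  sym <- as.character(stats::ave(seq_along(supports), character_id,
                                 FUN = seq_along))
  traits <- data.frame(
    node_id = seq_along(supports), character_id = character_id,
    character_label = labs, state_symbol = sym, state_label = labs,
    support_size = lengths(supports), label = labs, stringsAsFactors = FALSE)
  incidence <- t(vapply(supports, function(s) taxa %in% s,
                        logical(length(taxa))))
  dimnames(incidence) <- list(traits$node_id, taxa)
  new_trait_matrix(taxa, traits, incidence)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d traits over %d taxa\n", x$N, length(x$taxa)))
  invisible(x)
}

#' Taxon-support sets of a trait matrix
#' @param tm a `trait_matrix`.
#' @return list of character vectors, one per trait.
#' @export
trait_supports <- function(tm) {
  apply(tm$incidence, 1L, function(r) tm$taxa[r], simplify = FALSE)
}

#' Write a trait matrix as TSV
#'
#' Columns: `node_id`, `character_id`, `character_label`, `state_symbol`,
#' `state_label`, `support_size`, then one 0/1 presence column per taxon.
#'
#' @param tm a `trait_matrix`.
#' @param file output path, or `NULL` to return the TSV text.
#' @export
write_trait_matrix <- function(tm, file = NULL) {
  df <- cbind(tm$traits[c("node_id", "character_id", "character_label",
                          "state_symbol", "state_label", "support_size")],
              as.data.frame(tm$incidence * 1L, check.names = FALSE))
  if (is.null(file)) {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a trait matrix written by [write_trait_matrix()]
#' @param file path, or `NULL` with `text` given.
#' @param text TSV content as string.
#' @return a `trait_matrix`.
#' @export
read_trait_matrix <- function(file = NULL, text = NULL) {
  src <- if (is.null(file)) textConnection(text) else file
  df <- utils::read.table(src, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("node_id", "character_id", "character_label", "state_symbol",
            "state_label", "support_size")
  stopifnot(all(meta %in% names(df)))
  taxa <- setdiff(names(df), meta)
  traits <- df[meta]
  traits$state_symbol <- as.character(traits$state_symbol)
  traits$state_label <- as.character(traits$state_label)
  traits$label <- sprintf("%s|'%s'", traits$character_label,
                          traits$state_label)
  incidence <- as.matrix(df[taxa]) == 1L
  dimnames(incidence) <- list(traits$node_id, taxa)
  new_trait_matrix(taxa, traits, incidence)
}
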