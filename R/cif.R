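## Minimal CIF category reader/writer.
##
## Handles the subset of CIF used by coordinate mmCIF files (atom_site,
## struct_conn) and monomer-library restraint dictionaries (chem_comp_atom,
## chem_comp_bond, chem_comp_angle): data blocks, loop_ tables, single
## tag-value pairs, '/"-quoted values, semicolon text fields and # comments.

cif_tokenize_line <- function(line) {
  tokens <- character()
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        if (substr(line, j, j) == ch &&
            (j == n || substr(line, j + 1L, j + 1L) %in% c(" ", "\t"))) break
        j <- j + 1L
      }
      if (j > n) stop("unterminated quoted string in CIF line: ", line)
      tokens <- c(tokens, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      tokens <- c(tokens, substr(line, i, j - 1L))
      i <- j
    }
  }
  tokens
}

## Parse a CIF file into a list of data blocks; each block is a list of
## category tables (data frames of character columns, names without the
## leading "_category." prefix).
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur_block <- NULL
  cur_name <- NA_character_

  ## token stream with semicolon text fields folded into single tokens
  toks <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ";")) {
      txt <- substring(ln, 2L)
      i <- i + 1L
      while (i <= length(lines) && !startsWith(lines[[i]], ";")) {
        txt <- paste(txt, lines[[i]], sep = "\n")
        i <- i + 1L
      }
      if (i > length(lines)) stop("unterminated text field in ", path)
      toks[[length(toks) + 1L]] <- txt
      i <- i + 1L
      next
    }
    for (tk in cif_tokenize_line(ln)) toks[[length(toks) + 1L]] <- tk
    i <- i + 1L
  }
  toks <- unlist(toks, use.names = FALSE)
  if (is.null(toks)) toks <- character()

  flush_block <- function() {
    if (!is.null(cur_block)) blocks[[cur_name]] <<- cur_block
  }
  add_item <- function(tag, values) {
    parts <- strsplit(sub("^_", "", tag), ".", fixed = TRUE)[[1]]
    if (length(parts) < 2) { cat_name <- "item"; col <- parts[1] }
    else { cat_name <- parts[1]; col <- paste(parts[-1], collapse = ".") }
    tbl <- cur_block[[cat_name]]
    if (is.null(tbl)) tbl <- list()
    tbl[[col]] <- values
    cur_block[[cat_name]] <<- tbl
  }

  k <- 1L
  while (k <= length(toks)) {
    tk <- toks[[k]]
    low <- tolower(tk)
    if (startsWith(low, "data_")) {
      flush_block()
      cur_name <- substring(tk, 6L)
      cur_block <- list()
      k <- k + 1L
    } else if (low == "loop_") {
      k <- k + 1L
      tags <- character()
      while (k <= length(toks) && startsWith(toks[[k]], "_")) {
        tags <- c(tags, toks[[k]])
        k <- k + 1L
      }
      vals <- character()
      while (k <= length(toks) &&
             !startsWith(toks[[k]], "_") &&
             !tolower(toks[[k]]) %in% "loop_" &&
             !startsWith(tolower(toks[[k]]), "data_")) {
        vals <- c(vals, toks[[k]])
        k <- k + 1L
      }
      if (length(tags) == 0) stop("loop_ with no tags in ", path)
      if (length(vals) %% length(tags) != 0)
        stop("loop_ row length mismatch for ", tags[1], " in ", path)
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      if (is.null(cur_block)) { cur_name <- "unnamed"; cur_block <- list() }
      for (j in seq_along(tags)) add_item(tags[j], m[, j])
    } else if (startsWith(tk, "_")) {
      if (k + 1L > length(toks)) stop("tag without value: ", tk)
      if (is.null(cur_block)) { cur_name <- "unnamed"; cur_block <- list() }
      add_item(tk, toks[[k + 1L]])
      k <- k + 2L
    } else {
      stop("unexpected token in CIF file ", path, ": ", tk)
    }
  }
  flush_block()

  lapply(blocks, function(b)
    lapply(b, function(tbl) {
      n <- max(vapply(tbl, length, integer(1)))
      as.data.frame(lapply(tbl, rep_len, n), stringsAsFactors = FALSE)
    }))
}

cif_quote <- function(x) {
  x <- as.character(x)
  x[!nzchar(x)] <- "."
  needs <- grepl("[ \t']", x)
  x[needs] <- paste0("\"", x[needs], "\"")
  x
}

## Write one loop_ table; values are space-aligned for readability.
cif_write_loop <- function(con, category, tbl) {
  writeLines("loop_", con)
  writeLines(paste0("_", category, ".", names(tbl)), con)
  cols <- lapply(tbl, cif_quote)
  widths <- vapply(cols, function(cl) max(nchar(cl), 1L), integer(1))
  rows <- do.call(paste, c(mapply(formatC, cols, width = -widths,
                                  SIMPLIFY = FALSE), list(sep = " ")))
  writeLines(rows, con)
}
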