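#' Parse a literate source file
#'
#' Splits a literate source text into an ordered sequence of documentation
#' chunks and code chunks, following noweb conventions:
#'
#' * The file begins in documentation mode.
#' * A line that is exactly `<<name>>=` at column 0 opens a code chunk
#'   named `name`; the chunk's body runs until the next chunk boundary.
#' * A line that is exactly `@` (or starts with `@ `) returns to
#'   documentation mode; text after `@ ` belongs to the documentation chunk.
#' * Inside a code chunk, a line consisting only of whitespace followed by
#'   `<<name>>` is a reference to another chunk; `<<...>>` anywhere else in
#'   a code line is literal text. `@<<` and `@>>` escape literal `<<` / `>>`.
#' * Multiple definitions of the same chunk name are continuations and are
#'   concatenated in file order when the chunk is expanded.
#'
#' Documentation chunks may carry display-item placeholders: a line
#' `%%figure PATH :: CAPTION` (likewise `%%table`, `%%listing`), with the
#' ` :: CAPTION` part optional and `PATH` free of whitespace. Placeholders
#' are recognized only in documentation chunks.
#'
#' The parse is lossless: [serialize_source()] reproduces the input text
#' byte-for-byte (after the CRLF-to-LF normalization applied on input).
#'
#' @param text Raw file content as a single string, or `NULL` to read from
#'   `path`.
#' @param path Path of the source file (used for error messages and, when
#'   `text` is `NULL`, read with UTF-8 encoding).
#' @return An object of class `lir_source`: a list with elements `path`,
#'   `chunks` (a list of `lir_doc_chunk` / `lir_code_chunk` objects in file
#'   order) and `newline_at_eof`.
#' @seealso [serialize_source()], [scan_placeholders()], [build_chunk_graph()]
#' @examples
#' src <- parse_source("Intro\n<<hello>>=\necho hi\n@ after\n")
#' length(src$chunks)
#' @export
parse_source <- function(text = NULL, path = "<text>") {
  if (is.null(text)) {
    con <- file(path, encoding = "UTF-8")
    on.exit(close(con))
    text <- paste0(paste(readLines(con, warn = FALSE), collapse = "\n"),
                   "\n")
  }
  stopifnot(is.character(text), length(text) == 1L)
  if (!validUTF8(text)) {
    stop("source is not valid UTF-8: ", path, call. = FALSE)
  }
  text <- gsub("\r\n", "\n", text, fixed = TRUE)

  if (nchar(text) == 0L) {
    return(new_lir_source(path, list(), newline_at_eof = FALSE))
  }
  newline_at_eof <- endsWith(text, "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  # strsplit drops a trailing empty field: "a\n" -> "a"; recover "\n" -> ""
  if (length(lines) == 0L) lines <- ""

  chunks <- list()
  mode <- "doc"
  cur_lines <- character()
  cur_marker <- NA_character_   # NA = file start; "bare" = "@"; "inline" = "@ text"
  cur_name <- NULL
  cur_start <- 1L
  seen_defs <- integer()        # continuation counters per name

  flush_doc <- function() {
    chunks[[length(chunks) + 1L]] <<- new_doc_chunk(
      cur_lines, cur_marker, cur_start
    )
  }
  flush_code <- function() {
    idx <- seen_defs[cur_name]
    if (is.na(idx)) idx <- 0L
    seen_defs[cur_name] <<- idx + 1L
    chunks[[length(chunks) + 1L]] <<- new_code_chunk(
      cur_name, cur_lines, cur_start, continuation_index = idx
    )
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    hdr <- match_chunk_header(line, i)
    if (!is.null(hdr)) {
      if (mode == "doc") flush_doc() else flush_code()
      mode <- "code"
      cur_name <- hdr
      cur_lines <- character()
      cur_start <- i
      next
    }
    if (line == "@" || startsWith(line, "@ ")) {
      if (mode == "doc") flush_doc() else flush_code()
      mode <- "doc"
      cur_start <- i
      if (line == "@") {
        cur_marker <- "bare"
        cur_lines <- character()
      } else {
        cur_marker <- "inline"
        cur_lines <- substring(line, 3L)
      }
      next
    }
    cur_lines <- c(cur_lines, line)
  }
  if (mode == "doc") flush_doc() else flush_code()

  # Drop the implicit leading documentation chunk when it is empty, so that
  # a file opening directly with a code chunk has no phantom chunk -- unless
  # it is the only chunk (a whole-file empty doc still serializes losslessly).
  if (length(chunks) > 1L &&
      inherits(chunks[[1]], "lir_doc_chunk") &&
      length(chunks[[1]]$lines) == 0L &&
      is.na(chunks[[1]]$marker)) {
    chunks <- chunks[-1L]
  }

  new_lir_source(path, chunks, newline_at_eof)
}

# A column-0 line starting with "<<" is an intended chunk-definition header.
# Returns the chunk name, NULL if the line is not a header candidate, and
# raises on a malformed (unterminated) header. A lone reference line
# "<<name>>" (no "=") is not a header and is returned as NULL.
match_chunk_header <- function(line, lineno) {
  if (!startsWith(line, "<<")) return(NULL)
  if (grepl("^<<(.+)>>=$", line)) {
    name <- sub("^<<(.+)>>=$", "\\1", line)
    if (grepl(">>", name, fixed = TRUE)) {
      stop(sprintf("line %d: chunk name contains '>>': %s", lineno, line),
           call. = FALSE)
    }
    return(name)
  }
  if (grepl("^<<.*>>$", line)) return(NULL)       # reference at column 0
  if (!grepl(">>", line, fixed = TRUE)) {
    stop(sprintf("line %d: malformed chunk header (unterminated name): %s",
                 lineno, line), call. = FALSE)
  }
  NULL                                            # literal text, e.g. "<<x>> y"
}

new_lir_source <- function(path, chunks, newline_at_eof) {
  structure(
    list(path = path, chunks = chunks, newline_at_eof = newline_at_eof),
    class = "lir_source"
  )
}

new_doc_chunk <- function(lines, marker, start_line) {
  structure(
    list(
      lines = lines,
      marker = marker,
      placeholders = find_placeholders(lines, start_line, marker),
      start_line = as.integer(start_line)
    ),
    class = "lir_doc_chunk"
  )
}

new_code_chunk <- function(name, lines, start_line, continuation_index) {
  structure(
    list(
      name = name,
      lines = lines,
      references = find_references(lines),
      start_line = as.integer(start_line),
      continuation_index = as.integer(continuation_index)
    ),
    class = "lir_code_chunk"
  )
}

# References: a code line that is only whitespace followed by <<name>>.
find_references <- function(lines) {
  refs <- data.frame(
    line_index = integer(), indent = character(), name = character(),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([ \t]*)<<(.+)>>$", lines[i]))[[1]]
    if (length(m) == 3L && !grepl(">>", m[3], fixed = TRUE)) {
      refs <- rbind(refs, data.frame(
        line_index = i, indent = m[2], name = m[3], stringsAsFactors = FALSE
      ))
    }
  }
  refs
}

placeholder_re <- "^%%(figure|table|listing)[ \t]+([^ \t]+)([ \t]+::[ \t]*(.*))?$"

find_placeholders <- function(lines, start_line, marker) {
  # first physical line of an "inline" doc chunk is the marker line itself
  offset <- if (identical(marker, "bare")) 1L else 0L
  out <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec(placeholder_re, lines[i]))[[1]]
    if (length(m) == 0L) next
    caption <- if (m[4] == "") NA_character_ else m[5]
    out[[length(out) + 1L]] <- structure(
      list(
        kind = m[2], path = m[3], caption = caption,
        source_line = start_line + offset + i - 1L,
        chunk_line = i
      ),
      class = "lir_placeholder"
    )
  }
  out
}

#' Serialize a parsed literate source back to text
#'
#' The exact inverse of [parse_source()]: chunk headers and documentation
#' markers are restored so that the output is byte-identical to the parsed
#' input.
#'
#' @param src A `lir_source` object.
#' @return A single string.
#' @export
serialize_source <- function(src) {
  stopifnot(inherits(src, "lir_source"))
  lines <- character()
  for (ch in src$chunks) {
    if (inherits(ch, "lir_doc_chunk")) {
      if (is.na(ch$marker)) {
        lines <- c(lines, ch$lines)
      } else if (ch$marker == "bare") {
        lines <- c(lines, "@", ch$lines)
      } else {
        lines <- c(lines, paste0("@ ", ch$lines[1]), ch$lines[-1])
      }
    } else {
      lines <- c(lines, paste0("<<", ch$name, ">>="), ch$lines)
    }
  }
  if (length(lines) == 0L) return("")
  paste0(paste(lines, collapse = "\n"), if (src$newline_at_eof) "\n" else "")
}

#' Collect display-item placeholders from a literate source
#'
#' Returns every `%%figure` / `%%table` / `%%listing` placeholder found in
#' the documentation chunks, in file order. Placeholder-looking lines inside
#' code chunks are code, not placeholders, and are not returned. A file that
#' displays the same `(kind, path)` pair twice is allowed but flagged with a
#' warning diagnostic.
#'
#' @param src A `lir_source` object.
#' @return A data frame with columns `kind`, `path`, `caption`,
#'   `source_line`, and a `diagnostics` attribute (see [lir_diag()]).
#' @export
scan_placeholders <- function(src) {
  stopifnot(inherits(src, "lir_source"))
  phs <- list()
  for (ch in src$chunks) {
    if (inherits(ch, "lir_doc_chunk")) phs <- c(phs, ch$placeholders)
  }
  out <- data.frame(
    kind = vapply(phs, `[[`, "", "kind"),
    path = vapply(phs, `[[`, "", "path"),
    caption = vapply(phs, `[[`, "", "caption"),
    source_line = vapply(phs, `[[`, 0L, "source_line"),
    stringsAsFactors = FALSE
  )
  diags <- lir_diag_none()
  key <- paste(out$kind, out$path)
  dup <- duplicated(key)
  for (i in which(dup)) {
    diags <- rbind(diags, lir_diag(
      "warning", "duplicate-display",
      sprintf("%s '%s' is displayed more than once", out$kind[i], out$path[i]),
      out$source_line[i]
    ))
  }
  attr(out, "diagnostics") <- diags
  out
}

#' @export
print.lir_source <- function(x, ...) {
  n_doc <- sum(vapply(x$chunks, inherits, TRUE, "lir_doc_chunk"))
  n_code <- sum(vapply(x$chunks, inherits, TRUE, "lir_code_chunk"))
  cat(sprintf(
    "<lir_source> %s: %d documentation chunk(s), %d code chunk definition(s)\n",
    x$path, n_doc, n_code
  ))
  invisible(x)
}
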