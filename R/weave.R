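#' Assign numbers to code chunks and display items
#'
#' Every physical code-chunk definition receives the next integer in file
#' order (continuations of an earlier definition get their own number and a
#' back-pointer to the first definition). Display-item placeholders are
#' numbered separately per kind, each kind counting 1, 2, ... in file
#' order, so the document can say "Figure 2" and "Table 1" independently.
#'
#' @param src A `lir_source`.
#' @param graph The corresponding `lir_chunk_graph`.
#' @return An object of class `lir_numbering`: a list with
#'   * `chunks`: data frame `(number, name, start_line, continuation_of)`
#'     in file order (`continuation_of` is `NA` for first definitions);
#'   * `items`: data frame `(kind, path, caption, source_line, number)`;
#'   * `definitions`: named list, chunk name -> chunk numbers defining it;
#'   * `uses`: named list, chunk name -> sorted chunk numbers whose bodies
#'     reference it.
#' @export
assign_numbers <- function(src, graph) {
  stopifnot(inherits(src, "lir_source"), inherits(graph, "lir_chunk_graph"))
  number <- 0L
  chunks <- data.frame(
    number = integer(), name = character(), start_line = integer(),
    continuation_of = integer(), stringsAsFactors = FALSE
  )
  first_def <- integer()
  uses <- list()
  items <- data.frame(
    kind = character(), path = character(), caption = character(),
    source_line = integer(), number = integer(), stringsAsFactors = FALSE
  )
  counters <- c(figure = 0L, table = 0L, listing = 0L)

  for (ch in src$chunks) {
    if (inherits(ch, "lir_code_chunk")) {
      number <- number + 1L
      cont <- if (ch$continuation_index > 0L) first_def[[ch$name]]
              else NA_integer_
      if (ch$continuation_index == 0L) first_def[ch$name] <- number
      chunks <- rbind(chunks, data.frame(
        number = number, name = ch$name, start_line = ch$start_line,
        continuation_of = cont, stringsAsFactors = FALSE
      ))
      for (ref in unique(ch$references$name)) {
        uses[[ref]] <- c(uses[[ref]], number)
      }
    } else {
      for (ph in ch$placeholders) {
        counters[ph$kind] <- counters[ph$kind] + 1L
        items <- rbind(items, data.frame(
          kind = ph$kind, path = ph$path, caption = ph$caption,
          source_line = ph$source_line, number = counters[[ph$kind]],
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  definitions <- split(chunks$number, chunks$name)
  structure(
    list(chunks = chunks, items = items,
         definitions = definitions,
         uses = lapply(uses, function(v) sort(unique(v)))),
    class = "lir_numbering"
  )
}

display_labels <- c(figure = "Figure", table = "Table", listing = "Listing")

#' Render one display item as an HTML fragment
#'
#' A `figure` placeholder becomes an `<img>` element referencing the file
#' (or carrying it inline as a base64 data URI with `embed = TRUE`); a
#' `table` placeholder is parsed from the file (tab-delimited if the first
#' line contains a tab, comma-delimited otherwise, double quotes
#' respected) and rendered as an HTML table with the first row as header; a
#' `listing` placeholder shows the file verbatim in a preformatted block.
#' Each is wrapped with its label and number ("Figure 2.", "Table 1.", ...)
#' and the caption when present.
#'
#' A missing file does not abort the weave: a visible error box is emitted
#' and a diagnostic recorded.
#'
#' @param ph One row of the `items` data frame from [assign_numbers()] (a
#'   list or one-row data frame with `kind`, `path`, `caption`, `number`).
#' @param idx The `lir_numbering` (reserved for cross-referencing).
#' @param project_dir Directory display-file paths are relative to.
#' @param embed Inline figures as base64 data URIs?
#' @return A list `(html, diagnostics)`.
#' @export
render_display_item <- function(ph, idx, project_dir = ".", embed = FALSE) {
  kind <- ph$kind
  label <- display_labels[[kind]]
  anchor <- sprintf("%s-%d", kind, ph$number)
  cap <- sprintf("%s %d.", label, ph$number)
  if (!is.na(ph$caption) && nzchar(ph$caption)) {
    cap <- paste(cap, html_escape(ph$caption))
  }
  full <- file.path(project_dir, ph$path)
  diags <- lir_diag_none()
  if (!file.exists(full)) {
    diags <- lir_diag(
      "warning", "missing-display-file",
      sprintf("%s %d: file '%s' does not exist", label, ph$number, ph$path),
      ph$source_line
    )
    body <- sprintf(
      '<div class="lir-error">missing display file: <code>%s</code></div>',
      html_escape(ph$path)
    )
  } else if (kind == "figure") {
    src_attr <- if (embed) figure_data_uri(full) else html_escape(ph$path)
    body <- sprintf('<img src="%s" alt="%s" />', src_attr,
                    html_escape(basename(ph$path)))
  } else if (kind == "table") {
    body <- render_text_table(full)
  } else {
    body <- sprintf("<pre>%s</pre>",
                    html_escape(read_file_text(full)))
  }
  html <- sprintf(
    '<figure class="lir-display lir-%s" id="%s">\n%s\n<figcaption>%s</figcaption>\n</figure>',
    kind, anchor, body, cap
  )
  list(html = html, diagnostics = diags)
}

figure_data_uri <- function(path) {
  ext <- tolower(tools::file_ext(path))
  mime <- switch(ext,
    svg = "image/svg+xml", png = "image/png",
    jpg = , jpeg = "image/jpeg", gif = "image/gif",
    "application/octet-stream"
  )
  bytes <- readBin(path, "raw", n = file.size(path))
  sprintf("data:%s;base64,%s", mime, jsonlite::base64_enc(bytes))
}

read_file_text <- function(path) {
  paste0(paste(readLines(path, warn = FALSE), collapse = "\n"), "\n")
}

# Delimiter sniffing: tab if present in the first line, else comma.
render_text_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return("<table></table>")
  delim <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  cells <- utils::read.table(
    text = lines, sep = delim, quote = "\"", header = FALSE,
    colClasses = "character", comment.char = "", stringsAsFactors = FALSE,
    blank.lines.skip = FALSE
  )
  row_html <- function(row, tag) {
    paste0("<tr>",
           paste0("<", tag, ">", html_escape(unlist(row)), "</", tag, ">",
                  collapse = ""),
           "</tr>")
  }
  header <- row_html(cells[1, ], "th")
  body <- vapply(seq_len(nrow(cells))[-1],
                 function(i) row_html(cells[i, ], "td"), "")
  paste0("<table>\n<thead>\n", header, "\n</thead>\n<tbody>\n",
         paste(body, collapse = "\n"), "\n</tbody>\n</table>")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Weave the literate source into a cross-linked HTML document
#'
#' Produces one self-contained HTML5 document: documentation chunks are
#' rendered as CommonMark; a table of contents is generated from headings
#' of levels 1-3; each code chunk appears verbatim under a numbered header
#' (with a continuation marker when it re-opens an earlier name), with
#' every chunk reference hyperlinked to the referee's first definition and
#' a "used in" backlink line; display-item placeholders are replaced by
#' their rendered files; and a final "Generated files" section links every
#' sink that is not displayed. The built-in stylesheet can be replaced by
#' the user's CSS file. Given identical inputs the output is byte-identical.
#'
#' @param src A `lir_source`.
#' @param graph The `lir_chunk_graph`.
#' @param dataflow The `lir_dataflow` (used for the generated-files
#'   section); may be an empty dataflow.
#' @param idx The `lir_numbering` from [assign_numbers()].
#' @param style Optional path to a CSS file replacing the built-in style.
#' @param project_dir Directory display-file paths are relative to.
#' @param embed Inline figures as base64 data URIs?
#' @param title Document title; defaults to the source file's base name.
#' @return An object of class `lir_woven`: a list with `html` (the full
#'   document), `assets` (referenced result files), and `diagnostics`.
#' @export
weave_document <- function(src, graph, dataflow, idx, style = NULL,
                           project_dir = ".", embed = FALSE, title = NULL) {
  stopifnot(inherits(src, "lir_source"), inherits(graph, "lir_chunk_graph"),
            inherits(idx, "lir_numbering"))
  diags <- lir_diag_none()
  assets <- character()
  body <- character()
  headings <- data.frame(level = integer(), text = character(),
                         id = character(), stringsAsFactors = FALSE)
  slug_seen <- new.env(parent = emptyenv())
  chunk_counter <- 0L
  item_pos <- 1L

  for (ch in src$chunks) {
    if (inherits(ch, "lir_doc_chunk")) {
      res <- render_doc_chunk(ch, idx, item_pos, project_dir, embed,
                              slug_seen)
      body <- c(body, res$html)
      diags <- rbind(diags, res$diagnostics)
      headings <- rbind(headings, res$headings)
      assets <- c(assets, res$assets)
      item_pos <- res$item_pos
    } else {
      chunk_counter <- chunk_counter + 1L
      body <- c(body, render_code_chunk(ch, graph, idx, chunk_counter))
    }
  }

  sinks <- character()
  if (inherits(dataflow, "lir_dataflow")) {
    o <- dataflow$objects
    sinks <- o$path[o$role == "sink" & !o$displayed]
  }
  if (length(sinks) > 0L) {
    links <- sprintf('<li><a href="%s"><code>%s</code></a></li>',
                     html_escape(sinks), html_escape(sinks))
    body <- c(body,
      '<section id="generated-files">',
      "<h2>Generated files</h2>",
      "<ul>", links, "</ul>",
      "</section>")
    assets <- c(assets, sinks)
  }

  toc <- render_toc(headings)
  if (is.null(title)) title <- basename(src$path)
  css <- if (is.null(style)) default_stylesheet else read_file_text(style)
  html <- paste(c(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8" />',
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>", css, "</style>",
    "</head>",
    "<body>",
    toc,
    body,
    "</body>",
    "</html>"
  ), collapse = "\n")
  structure(
    list(html = html, assets = unique(assets), diagnostics = diags),
    class = "lir_woven"
  )
}

# Renders one documentation chunk: markdown prose, with placeholder lines
# replaced by rendered display items. `item_pos` indexes idx$items, which
# lists placeholders in file order.
render_doc_chunk <- function(ch, idx, item_pos, project_dir, embed,
                             slug_seen) {
  diags <- lir_diag_none()
  assets <- character()
  html <- character()
  headings <- data.frame(level = integer(), text = character(),
                         id = character(), stringsAsFactors = FALSE)
  is_ph <- grepl(placeholder_re, ch$lines)
  # walk the lines, buffering prose and flushing at each placeholder
  buf <- character()
  flush_prose <- function() {
    if (length(buf) == 0L) return()
    res <- render_markdown(buf, slug_seen)
    html <<- c(html, res$html)
    headings <<- rbind(headings, res$headings)
    buf <<- character()
  }
  for (i in seq_along(ch$lines)) {
    if (is_ph[i]) {
      flush_prose()
      ph <- as.list(idx$items[item_pos, ])
      item_pos <- item_pos + 1L
      res <- render_display_item(ph, idx, project_dir, embed)
      html <- c(html, res$html)
      diags <- rbind(diags, res$diagnostics)
      if (file.exists(file.path(project_dir, ph$path))) {
        assets <- c(assets, ph$path)
      }
    } else {
      buf <- c(buf, ch$lines[i])
    }
  }
  flush_prose()
  list(html = html, diagnostics = diags, headings = headings,
       assets = assets, item_pos = item_pos)
}

# CommonMark rendering plus heading anchor injection (levels 1-3).
render_markdown <- function(lines, slug_seen) {
  md <- paste(lines, collapse = "\n")
  out <- commonmark::markdown_html(md, smart = FALSE)
  headings <- data.frame(level = integer(), text = character(),
                         id = character(), stringsAsFactors = FALSE)
  m <- gregexpr("<h([1-3])>(.*?)</h\\1>", out, perl = TRUE)
  matches <- regmatches(out, m)[[1]]
  for (h in matches) {
    level <- as.integer(sub("^<h([1-3])>.*$", "\\1", h))
    inner <- sub("^<h[1-3]>(.*)</h[1-3]>$", "\\1", h)
    text <- gsub("<[^>]+>", "", inner)
    id <- heading_slug(text, slug_seen)
    anchored <- sprintf('<h%d id="%s">%s</h%d>', level, id, inner, level)
    out <- sub(h, anchored, out, fixed = TRUE)
    headings <- rbind(headings, data.frame(
      level = level, text = text, id = id, stringsAsFactors = FALSE
    ))
  }
  list(html = out, headings = headings)
}

heading_slug <- function(text, slug_seen) {
  base <- gsub("(^-+)|(-+$)", "", gsub("-+", "-",
           gsub("[^a-z0-9]+", "-", tolower(text))))
  if (!nzchar(base)) base <- "section"
  n <- get0(base, envir = slug_seen, ifnotfound = 0L)
  assign(base, n + 1L, envir = slug_seen)
  if (n == 0L) base else sprintf("%s-%d", base, n + 1L)
}

render_toc <- function(headings) {
  if (nrow(headings) == 0L) return(character())
  items <- sprintf(
    '<li class="toc-level-%d"><a href="#%s">%s</a></li>',
    headings$level, headings$id, html_escape(headings$text)
  )
  c('<nav id="toc">', "<h2>Contents</h2>", "<ul>", items, "</ul>", "</nav>")
}

# One physical code-chunk definition, verbatim, with reference lines
# hyperlinked and a "used in" backlink line.
render_code_chunk <- function(ch, graph, idx, number) {
  row <- idx$chunks[idx$chunks$number == number, ]
  marker <- if (!is.na(row$continuation_of)) {
    sprintf(' +&equiv; <span class="lir-cont">(continuation of <a href="#chunk-%d">%d</a>)</span>',
            row$continuation_of, row$continuation_of)
  } else {
    " &equiv;"
  }
  header <- sprintf(
    '<div class="lir-chunk-header" id="chunk-%d">&#10216;<span class="lir-chunk-name">%s</span>&#10217; <span class="lir-chunk-number">%d</span>%s</div>',
    number, html_escape(ch$name), number, marker
  )
  body_lines <- character(length(ch$lines))
  ref_by_line <- ch$references
  for (i in seq_along(ch$lines)) {
    j <- match(i, ref_by_line$line_index)
    if (!is.na(j)) {
      ref <- ref_by_line[j, ]
      defs <- idx$definitions[[ref$name]]
      if (is.null(defs)) {
        body_lines[i] <- sprintf(
          '%s&#10216;%s <span class="lir-undef">?</span>&#10217;',
          ref$indent, html_escape(ref$name)
        )
      } else {
        body_lines[i] <- sprintf(
          '%s<a href="#chunk-%d">&#10216;%s %d&#10217;</a>',
          ref$indent, defs[1], html_escape(ref$name), defs[1]
        )
      }
    } else {
      body_lines[i] <- html_escape(ch$lines[i])
    }
  }
  used_in <- idx$uses[[ch$name]]
  footer <- if (!is.null(used_in) && length(used_in) > 0L) {
    links <- sprintf('<a href="#chunk-%d">%d</a>', used_in, used_in)
    sprintf('<div class="lir-chunk-uses">used in chunk%s %s</div>',
            if (length(used_in) > 1L) "s" else "",
            paste(links, collapse = ", "))
  } else {
    character()
  }
  c(sprintf('<div class="lir-chunk">'), header,
    sprintf('<pre class="lir-code">%s</pre>',
            paste(body_lines, collapse = "\n")),
    footer, "</div>")
}

default_stylesheet <- "
body { max-width: 50em; margin: 2em auto; padding: 0 1em;
       font-family: Georgia, serif; line-height: 1.5; color: #222; }
nav#toc { background: #f7f7f7; border: 1px solid #ddd; padding: 0.5em 1em; }
nav#toc ul { list-style: none; padding-left: 0; }
nav#toc li.toc-level-2 { padding-left: 1.5em; }
nav#toc li.toc-level-3 { padding-left: 3em; }
.lir-chunk { margin: 1em 0; }
.lir-chunk-header { font-family: monospace; background: #eef;
                    padding: 0.2em 0.5em; border-left: 3px solid #88a; }
.lir-chunk-name { font-style: italic; }
pre.lir-code { background: #f4f4f8; margin: 0; padding: 0.5em;
               overflow-x: auto; }
.lir-chunk-uses { font-size: 0.85em; color: #666; padding: 0.1em 0.5em; }
figure.lir-display { margin: 1.5em 0; text-align: center; }
figure.lir-display table { margin: 0 auto; border-collapse: collapse; }
figure.lir-display th, figure.lir-display td
  { border: 1px solid #999; padding: 0.25em 0.75em; }
figure.lir-display pre { text-align: left; background: #f4f4f8;
                         padding: 0.5em; }
figcaption { font-size: 0.9em; color: #444; margin-top: 0.5em; }
.lir-error { border: 2px solid #c00; color: #c00; padding: 0.5em; }
#generated-files { border-top: 1px solid #ccc; margin-top: 2em; }
"

#' @export
print.lir_woven <- function(x, ...) {
  cat(sprintf("<lir_woven> %d byte(s) of HTML, %d asset(s), %d diagnostic(s)\n",
              nchar(x$html, type = "bytes"), length(x$assets),
              nrow(x$diagnostics)))
  invisible(x)
}
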