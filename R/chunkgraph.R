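#' Build the named-chunk reference graph
#'
#' Collects every code chunk definition from a parsed source into a graph:
#' chunk bodies (continuations of the same name concatenated in file order),
#' reference edges between chunk names, and the set of root chunks (chunks
#' not referenced by any other chunk). Root chunks are the unit that defines
#' an executable data transformation.
#'
#' References to names that are never defined are not errors here; they are
#' collected as diagnostics and become fatal at expansion/tangle time.
#'
#' @param src A `lir_source` object from [parse_source()].
#' @return An object of class `lir_chunk_graph`: a list with
#'   * `bodies`: named list, chunk name -> character vector of raw body lines;
#'   * `body_lines`: named list, chunk name -> integer vector of 1-based
#'     source line numbers, parallel to `bodies`;
#'   * `edges`: data frame `(from, to, line)` of reference edges;
#'   * `roots`: character vector of names with no incoming reference;
#'   * `def_lines`: named list, chunk name -> line numbers of its definitions;
#'   * `diagnostics`: diagnostics data frame (undefined references).
#' @export
build_chunk_graph <- function(src) {
  stopifnot(inherits(src, "lir_source"))
  bodies <- list()
  body_lines <- list()
  def_lines <- list()
  edges <- data.frame(from = character(), to = character(), line = integer(),
                      stringsAsFactors = FALSE)
  for (ch in src$chunks) {
    if (!inherits(ch, "lir_code_chunk")) next
    nm <- ch$name
    if (is.null(bodies[[nm]])) {
      bodies[[nm]] <- character()
      body_lines[[nm]] <- integer()
      def_lines[[nm]] <- integer()
    }
    bodies[[nm]] <- c(bodies[[nm]], ch$lines)
    body_lines[[nm]] <- c(body_lines[[nm]],
                          ch$start_line + seq_along(ch$lines))
    def_lines[[nm]] <- c(def_lines[[nm]], ch$start_line)
    if (nrow(ch$references) > 0L) {
      edges <- rbind(edges, data.frame(
        from = nm, to = ch$references$name,
        line = ch$start_line + ch$references$line_index,
        stringsAsFactors = FALSE
      ))
    }
  }
  diags <- lir_diag_none()
  undef <- !(edges$to %in% names(bodies))
  for (i in which(undef)) {
    diags <- rbind(diags, lir_diag(
      "fatal", "undefined-chunk",
      sprintf("reference to undefined chunk '%s'", edges$to[i]),
      edges$line[i]
    ))
  }
  roots <- setdiff(names(bodies), edges$to)
  structure(
    list(bodies = bodies, body_lines = body_lines, edges = edges,
         roots = roots, def_lines = def_lines, diagnostics = diags),
    class = "lir_chunk_graph"
  )
}

#' Root chunks of a chunk graph
#'
#' @param graph A `lir_chunk_graph`.
#' @return Character vector of chunk names with zero incoming references.
#' @export
root_chunks <- function(graph) {
  stopifnot(inherits(graph, "lir_chunk_graph"))
  graph$roots
}

#' Recursively expand a named chunk
#'
#' Depth-first substitution of chunk references: a reference line indented
#' by some whitespace prefix expands to the referee's expansion with that
#' exact prefix prepended to every produced line. The escapes `@<<` and
#' `@>>` are replaced by literal `<<` and `>>` in the output. The returned
#' text ends with a single trailing newline (an empty chunk expands to `""`).
#'
#' A cycle reachable from `name` is an error naming the chunk sequence of
#' the cycle; a reachable reference to an undefined chunk is likewise an
#' error.
#'
#' @param graph A `lir_chunk_graph`.
#' @param name Name of the chunk to expand; must be defined in `graph`.
#' @return The expanded program text as a single string.
#' @export
expand_chunk <- function(graph, name) {
  stopifnot(inherits(graph, "lir_chunk_graph"))
  lines <- expand_lines(graph, name, visiting = character())
  if (length(lines) == 0L) return("")
  paste0(paste(lines, collapse = "\n"), "\n")
}

expand_lines <- function(graph, name, visiting) {
  if (!name %in% names(graph$bodies)) {
    stop(sprintf("undefined chunk '%s'", name), call. = FALSE)
  }
  if (name %in% visiting) {
    cycle <- c(visiting[seq(match(name, visiting), length(visiting))], name)
    stop(sprintf("chunk reference cycle: %s",
                 paste(sprintf("<<%s>>", cycle), collapse = " -> ")),
         call. = FALSE)
  }
  visiting <- c(visiting, name)
  out <- character()
  for (line in graph$bodies[[name]]) {
    m <- regmatches(line, regexec("^([ \t]*)<<(.+)>>$", line))[[1]]
    if (length(m) == 3L && !grepl(">>", m[3], fixed = TRUE)) {
      sub_lines <- expand_lines(graph, m[3], visiting)
      out <- c(out, paste0(m[2], sub_lines))
    } else {
      out <- c(out, unescape_chunk_delims(line))
    }
  }
  out
}

unescape_chunk_delims <- function(line) {
  gsub("@>>", ">>", gsub("@<<", "<<", line, fixed = TRUE), fixed = TRUE)
}

#' Tangle transformation chunks into executable scripts
#'
#' Writes one executable file per named transformation under `out_dir`.
#' Each transformation must be a root chunk; its file content is the full
#' recursive expansion of the chunk. The file name is the chunk name with
#' every character outside `[A-Za-z0-9._-]` replaced by `_`; two names that
#' sanitize to the same file name are a collision error.
#'
#' If the expansion starts with a `#!` shebang line the script is run
#' directly and the shebang command is recorded as its interpreter;
#' otherwise the POSIX shell `sh` is recorded and used to run it.
#'
#' Tangling is write-if-changed: a file whose bytes would not change is
#' left untouched (content and modification time), so re-tangling an
#' unchanged source never makes downstream results stale.
#'
#' @param graph A `lir_chunk_graph`.
#' @param transformation_names Character vector of root chunk names to
#'   tangle.
#' @param out_dir Directory for the script files (created if absent).
#' @return A data frame of class `lir_tangled_scripts` with columns
#'   `chunk_name`, `file_path`, `interpreter`, `content_digest` (MD5),
#'   `changed` (logical: was the file (re)written).
#' @export
tangle_scripts <- function(graph, transformation_names, out_dir) {
  stopifnot(inherits(graph, "lir_chunk_graph"))
  transformation_names <- as.character(transformation_names)
  not_root <- setdiff(transformation_names, graph$roots)
  if (length(not_root) > 0L) {
    stop(sprintf("not a root chunk: %s",
                 paste(sprintf("'%s'", not_root), collapse = ", ")),
         call. = FALSE)
  }
  files <- vapply(transformation_names, sanitize_filename, "")
  if (anyDuplicated(files)) {
    d <- files[duplicated(files)][1]
    clash <- transformation_names[files == d]
    stop(sprintf("chunk names %s collide on file name '%s'",
                 paste(sprintf("'%s'", clash), collapse = " and "), d),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- data.frame(
    chunk_name = character(), file_path = character(),
    interpreter = character(), content_digest = character(),
    changed = logical(), stringsAsFactors = FALSE
  )
  for (i in seq_along(transformation_names)) {
    nm <- transformation_names[i]
    content <- expand_chunk(graph, nm)
    path <- file.path(out_dir, files[i])
    first <- sub("\n.*$", "", content)
    interpreter <- if (startsWith(first, "#!")) {
      trimws(substring(first, 3L))
    } else {
      "sh"
    }
    changed <- write_if_changed(path, content)
    Sys.chmod(path, mode = "0755")
    out <- rbind(out, data.frame(
      chunk_name = nm, file_path = path, interpreter = interpreter,
      content_digest = unname(tools::md5sum(path)), changed = changed,
      stringsAsFactors = FALSE
    ))
  }
  class(out) <- c("lir_tangled_scripts", class(out))
  out
}

sanitize_filename <- function(name) {
  gsub("[^A-Za-z0-9._-]", "_", name)
}

# Writes `content` to `path` only if the current bytes differ; returns TRUE
# when the file was written. Keeps mtimes stable across no-op re-tangles.
write_if_changed <- function(path, content) {
  new_bytes <- charToRaw(content)
  if (file.exists(path)) {
    old_bytes <- readBin(path, "raw", n = file.size(path))
    if (identical(old_bytes, new_bytes)) return(FALSE)
  }
  con <- file(path, open = "wb")
  writeBin(new_bytes, con)
  close(con)
  TRUE
}

#' @export
print.lir_chunk_graph <- function(x, ...) {
  cat(sprintf(
    "<lir_chunk_graph> %d chunk(s), %d reference edge(s), %d root(s)\n",
    length(x$bodies), nrow(x$edges), length(x$roots)
  ))
  if (length(x$roots) > 0L) {
    cat("roots:", paste(sprintf("<<%s>>", x$roots), collapse = ", "), "\n")
  }
  invisible(x)
}
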