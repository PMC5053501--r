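#' Extract the dataflow graph from a literate source
#'
#' The analysis definition lives in three specially named code chunks:
#'
#' * `lir:sources` — whitespace-separated paths of the declared input data
#'   files; `#` starts a comment running to end of line.
#' * `lir:sinks` — additional sink paths for results that must be generated
#'   but are not displayed in the final document (same token syntax).
#' * `lir:rules` — the rules for applying data transformations, in a strict
#'   Make-compatible subset: a rule line `targets : prerequisites` followed
#'   by exactly one tab-indented recipe line containing, verbatim, the name
#'   of the root code chunk that defines the transformation.
#'
#' Data objects (the files) are the vertices of the dataflow graph and the
#' rules are its edges. Roles are assigned from the declarations: declared
#' sources are `source`; every display-item placeholder path and every
#' `lir:sinks` entry is a `sink` (placeholder paths additionally have
#' `displayed = TRUE`); all remaining rule-touched paths are `intermediate`.
#'
#' Paths are interpreted relative to the source file's directory, with `/`
#' as separator; paths containing whitespace cannot be declared (tokens are
#' whitespace-delimited by construction).
#'
#' @param src A `lir_source`.
#' @param graph The corresponding `lir_chunk_graph`.
#' @return A list `(dataflow, diagnostics)` where `dataflow` is an object of
#'   class `lir_dataflow`: `objects` (data frame `path`, `role`,
#'   `displayed`), `rules` (list of rules, each `targets`, `prerequisites`,
#'   `transformation`, `declaration_line`), and `producer` (named integer:
#'   target path -> producing rule index).
#' @export
extract_dataflow <- function(src, graph) {
  stopifnot(inherits(src, "lir_source"), inherits(graph, "lir_chunk_graph"))
  diags <- lir_diag_none()

  sources <- parse_path_tokens(graph, "lir:sources")
  extra_sinks <- parse_path_tokens(graph, "lir:sinks")

  rules <- list()
  if (!"lir:rules" %in% names(graph$bodies)) {
    diags <- rbind(diags, lir_diag(
      "warning", "no-rules",
      "no 'lir:rules' chunk found; dataflow is empty"
    ))
  } else {
    parsed <- parse_rules(graph$bodies[["lir:rules"]],
                          graph$body_lines[["lir:rules"]])
    rules <- parsed$rules
    diags <- rbind(diags, parsed$diagnostics)
  }

  phs <- scan_placeholders(src)
  diags <- rbind(diags, attr(phs, "diagnostics"))

  producer <- integer()
  touched <- character()
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    touched <- union(touched, c(r$targets, r$prerequisites))
    for (tg in r$targets) {
      if (is.na(producer[tg])) producer[tg] <- i
      # duplicate producers are validated later; keep the first binding
    }
  }
  all_paths <- unique(c(sources, touched, extra_sinks, phs$path))
  displayed <- all_paths %in% phs$path
  role <- ifelse(
    all_paths %in% sources, "source",
    ifelse(displayed | all_paths %in% extra_sinks, "sink", "intermediate")
  )
  objects <- data.frame(
    path = all_paths, role = role, displayed = displayed,
    stringsAsFactors = FALSE
  )
  dataflow <- structure(
    list(objects = objects, rules = rules,
         producer = producer[!is.na(producer)]),
    class = "lir_dataflow"
  )
  list(dataflow = dataflow, diagnostics = diags)
}

parse_path_tokens <- function(graph, chunk_name) {
  body <- graph$bodies[[chunk_name]]
  if (is.null(body)) return(character())
  body <- sub("#.*$", "", body)
  tokens <- unlist(strsplit(body, "[ \t]+"))
  tokens[nzchar(tokens)]
}

parse_rules <- function(body, line_numbers) {
  diags <- lir_diag_none()
  rules <- list()
  i <- 1L
  n <- length(body)
  while (i <= n) {
    line <- body[i]
    lineno <- line_numbers[i]
    if (grepl("^[ \t]*$", line) || grepl("^#", line)) {
      i <- i + 1L
      next
    }
    if (startsWith(line, "\t")) {
      diags <- rbind(diags, lir_diag(
        "fatal", "rule-syntax",
        sprintf("recipe line without a preceding rule line: '%s'",
                trimws(line)), lineno
      ))
      i <- i + 1L
      next
    }
    if (!grepl(":", line, fixed = TRUE)) {
      diags <- rbind(diags, lir_diag(
        "fatal", "rule-syntax",
        sprintf("expected 'targets : prerequisites', got: '%s'", line), lineno
      ))
      i <- i + 1L
      next
    }
    colon <- regexpr(":", line, fixed = TRUE)
    targets <- strsplit(trimws(substring(line, 1L, colon - 1L)), "[ \t]+")[[1]]
    targets <- targets[nzchar(targets)]
    prereqs <- strsplit(trimws(substring(line, colon + 1L)), "[ \t]+")[[1]]
    prereqs <- prereqs[nzchar(prereqs)]
    if (length(targets) == 0L) {
      diags <- rbind(diags, lir_diag(
        "fatal", "rule-syntax", "rule with zero targets", lineno
      ))
    }
    if (anyDuplicated(targets)) {
      diags <- rbind(diags, lir_diag(
        "fatal", "rule-syntax",
        sprintf("duplicate target within one rule: '%s'",
                targets[duplicated(targets)][1]), lineno
      ))
    }
    if (i + 1L > n || !startsWith(body[i + 1L], "\t")) {
      diags <- rbind(diags, lir_diag(
        "fatal", "rule-syntax",
        "rule line must be followed by exactly one tab-indented recipe line",
        lineno
      ))
      i <- i + 1L
      next
    }
    recipe <- sub("[ \t]+$", "", substring(body[i + 1L], 2L))
    if (i + 2L <= n && startsWith(body[i + 2L], "\t")) {
      diags <- rbind(diags, lir_diag(
        "fatal", "rule-syntax",
        "rule has more than one recipe line", line_numbers[i + 2L]
      ))
      # consume the extra recipe lines
      j <- i + 2L
      while (j <= n && startsWith(body[j], "\t")) j <- j + 1L
      i <- j
      next
    }
    if (length(targets) > 0L) {
      rules[[length(rules) + 1L]] <- list(
        targets = targets, prerequisites = prereqs,
        transformation = recipe, declaration_line = lineno
      )
    }
    i <- i + 2L
  }
  list(rules = rules, diagnostics = diags)
}

#' Validate a dataflow graph
#'
#' Checks the extracted dataflow against the DAG contract. Fatal
#' violations: a dependency cycle; a path that is both a declared source and
#' a rule target; two rules producing the same target; a recipe naming an
#' unknown chunk or a non-root chunk; a sink that no rule produces and that
#' is not a declared source. Warnings: a root chunk never used by any rule
#' (excluding the `lir:*` declaration chunks); a declared source never used
#' as a prerequisite.
#'
#' A sink may also serve as a prerequisite of a later rule; results that are
#' displayed and then reused downstream are legitimate.
#'
#' @param dataflow A `lir_dataflow`.
#' @param graph The `lir_chunk_graph` the rules refer into.
#' @return A diagnostics data frame; no fatal rows means the dataflow is
#'   buildable.
#' @export
validate_dataflow <- function(dataflow, graph) {
  stopifnot(inherits(dataflow, "lir_dataflow"),
            inherits(graph, "lir_chunk_graph"))
  diags <- lir_diag_none()
  rules <- dataflow$rules
  objs <- dataflow$objects
  sources <- objs$path[objs$role == "source"]
  all_targets <- unlist(lapply(rules, `[[`, "targets"))
  all_prereqs <- unlist(lapply(rules, `[[`, "prerequisites"))

  for (p in intersect(sources, all_targets)) {
    diags <- rbind(diags, lir_diag(
      "fatal", "source-is-target",
      sprintf("'%s' is declared a source but is the target of a rule", p)
    ))
  }
  dup <- unique(all_targets[duplicated(all_targets)])
  for (p in dup) {
    diags <- rbind(diags, lir_diag(
      "fatal", "duplicate-producer",
      sprintf("target '%s' is produced by more than one rule", p)
    ))
  }
  for (r in rules) {
    tr <- r$transformation
    if (!tr %in% names(graph$bodies)) {
      diags <- rbind(diags, lir_diag(
        "fatal", "unknown-transformation",
        sprintf("recipe names unknown chunk '%s'", tr), r$declaration_line
      ))
    } else if (!tr %in% graph$roots) {
      diags <- rbind(diags, lir_diag(
        "fatal", "transformation-not-root",
        sprintf("recipe chunk '%s' is referenced by other chunks and is not a root",
                tr), r$declaration_line
      ))
    }
  }
  sinks <- objs$path[objs$role == "sink"]
  for (p in setdiff(sinks, c(all_targets, sources))) {
    diags <- rbind(diags, lir_diag(
      "fatal", "unproduced-sink",
      sprintf("sink '%s' is neither a rule target nor a declared source", p)
    ))
  }

  cyc <- find_rule_cycle(dataflow)
  if (!is.null(cyc)) {
    diags <- rbind(diags, lir_diag(
      "fatal", "dependency-cycle",
      sprintf("dataflow cycle: %s", paste(cyc, collapse = " -> "))
    ))
  }

  special <- c("lir:sources", "lir:sinks", "lir:rules")
  used <- vapply(rules, `[[`, "", "transformation")
  for (nm in setdiff(graph$roots, c(used, special))) {
    diags <- rbind(diags, lir_diag(
      "warning", "unused-transformation",
      sprintf("root chunk '%s' is not used by any rule", nm),
      graph$def_lines[[nm]][1]
    ))
  }
  for (p in setdiff(sources, all_prereqs)) {
    diags <- rbind(diags, lir_diag(
      "warning", "unused-source",
      sprintf("declared source '%s' is not used as a prerequisite", p)
    ))
  }
  diags
}

# Returns a path cycle (object paths) or NULL. Walks prerequisite -> target
# edges induced by the rules, depth-first with a visiting stack.
find_rule_cycle <- function(dataflow) {
  succ <- list()   # path -> paths it feeds (targets of rules it is a prereq of)
  for (r in dataflow$rules) {
    for (p in r$prerequisites) {
      succ[[p]] <- union(succ[[p]], r$targets)
    }
  }
  state <- new.env(parent = emptyenv())
  cycle <- NULL
  visit <- function(v, stack) {
    st <- get0(v, envir = state, ifnotfound = "new")
    if (st == "done") return()
    if (st == "visiting") {
      cycle <<- c(stack[seq(match(v, stack), length(stack))], v)
      return()
    }
    assign(v, "visiting", envir = state)
    for (w in succ[[v]] %||% character()) {
      if (is.null(cycle)) visit(w, c(stack, v))
    }
    assign(v, "done", envir = state)
  }
  for (v in names(succ)) {
    if (is.null(cycle)) visit(v, character())
  }
  cycle
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Export a makefile equivalent to the dataflow
#'
#' Emits a GNU-make makefile with `all` as the first target depending on
#' every sink, then one entry per rule in declaration order. Multi-target
#' rules use the grouped-target separator `&:` so that the recipe runs once
#' for the whole group. Recipes invoke the tangled script for the rule's
#' transformation: directly (`./path`) when the script carries a shebang,
#' through `sh` otherwise. The output is deterministic: the same dataflow
#' always yields byte-identical text.
#'
#' The resulting makefile, the tangled scripts, and the analysis tools are
#' all that is needed to build the results on another machine; this package
#' itself is not required there.
#'
#' @param dataflow A validated `lir_dataflow` (no fatal diagnostics).
#' @param scripts The `lir_tangled_scripts` data frame from
#'   [tangle_scripts()].
#' @param graph Optional `lir_chunk_graph`; when supplied the dataflow is
#'   re-validated and export refuses on fatal diagnostics.
#' @return The makefile text as a single string.
#' @export
export_makefile <- function(dataflow, scripts, graph = NULL) {
  stopifnot(inherits(dataflow, "lir_dataflow"))
  if (!is.null(graph)) {
    diags <- validate_dataflow(dataflow, graph)
    if (has_fatal(diags)) {
      stop(paste(c("cannot export makefile; fatal diagnostics:",
                   format_diags(diags[diags$severity == "fatal", ])),
                 collapse = "\n"), call. = FALSE)
    }
  }
  sinks <- dataflow$objects$path[dataflow$objects$role == "sink"]
  lines <- c(
    "# Generated makefile -- do not edit; regenerate from the literate source.",
    paste(c("all:", sinks), collapse = " "),
    ".PHONY: all",
    ""
  )
  for (r in dataflow$rules) {
    sep <- if (length(r$targets) > 1L) "&:" else ":"
    head <- paste(
      paste(r$targets, collapse = " "), sep,
      paste(r$prerequisites, collapse = " ")
    )
    s <- scripts[scripts$chunk_name == r$transformation, , drop = FALSE]
    if (nrow(s) == 0L) {
      stop(sprintf("no tangled script for transformation '%s'",
                   r$transformation), call. = FALSE)
    }
    cmd <- script_command(s$file_path[1], s$interpreter[1])
    lines <- c(lines, trimws(head, which = "right"), paste0("\t", cmd), "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# How a tangled script is invoked, both in the makefile and by the internal
# builder: shebang scripts run directly, the rest through sh.
script_command <- function(path, interpreter) {
  rel <- path
  if (identical(interpreter, "sh")) {
    paste("sh", rel)
  } else {
    if (!startsWith(rel, "/") && !startsWith(rel, "./")) rel <- paste0("./", rel)
    rel
  }
}

#' @export
print.lir_dataflow <- function(x, ...) {
  tab <- table(factor(x$objects$role,
                      levels = c("source", "intermediate", "sink")))
  cat(sprintf(
    "<lir_dataflow> %d object(s) (%d source, %d intermediate, %d sink), %d rule(s)\n",
    nrow(x$objects), tab[["source"]], tab[["intermediate"]], tab[["sink"]],
    length(x$rules)
  ))
  invisible(x)
}
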