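#' Load and analyse a literate source file
#'
#' Shared front half of every command: parse the file, build the chunk
#' graph, extract the dataflow, and validate it. All diagnostics are
#' pooled.
#'
#' @param source Path to the literate source file.
#' @return A list `(src, graph, dataflow, diagnostics, project_dir)`.
#' @keywords internal
analyse_source <- function(source) {
  if (!file.exists(source)) {
    stop(sprintf("source file '%s' does not exist", source), call. = FALSE)
  }
  src <- parse_source(path = source)
  graph <- build_chunk_graph(src)
  ext <- extract_dataflow(src, graph)
  diags <- rbind(graph$diagnostics, ext$diagnostics,
                 validate_dataflow(ext$dataflow, graph))
  list(
    src = src, graph = graph, dataflow = ext$dataflow,
    diagnostics = diags,
    project_dir = normalizePath(dirname(source), mustWork = TRUE)
  )
}

#' Check a literate source file
#'
#' Runs the parser, the chunk-graph construction, and the dataflow
#' extraction and validation, and reports every diagnostic with its line
#' number. No file is written.
#'
#' @param source Path to the literate source file.
#' @param quiet Suppress printing of diagnostics?
#' @return Invisibly, the diagnostics data frame with attribute `ok`
#'   (`TRUE` iff no fatal diagnostic).
#' @export
lir_check <- function(source, quiet = FALSE) {
  a <- analyse_source(source)
  if (!quiet) {
    for (line in format_diags(a$diagnostics)) message(line)
  }
  diags <- a$diagnostics
  attr(diags, "ok") <- !has_fatal(diags)
  invisible(diags)
}

#' Tangle: extract transformation scripts and export the makefile
#'
#' Expands every transformation chunk referenced by a rule into an
#' executable script under `.lir/scripts/` (write-if-changed, so an
#' unchanged source never refreshes script mtimes) and writes the
#' equivalent makefile to `.lir/Makefile`. Fatal diagnostics abort before
#' anything is written.
#'
#' @param source Path to the literate source file.
#' @return Invisibly, a list `(scripts, makefile, analysis)`.
#' @export
lir_tangle <- function(source) {
  a <- analyse_source(source)
  if (has_fatal(a$diagnostics)) {
    stop(paste(c("fatal diagnostics:",
                 format_diags(a$diagnostics[a$diagnostics$severity == "fatal", ])),
               collapse = "\n"), call. = FALSE)
  }
  owd <- setwd(a$project_dir)
  on.exit(setwd(owd))
  names <- unique(vapply(a$dataflow$rules, `[[`, "", "transformation"))
  scripts <- tangle_scripts(a$graph, names, file.path(".lir", "scripts"))
  mk <- export_makefile(a$dataflow, scripts)
  write_if_changed(file.path(".lir", "Makefile"), mk)
  invisible(list(scripts = scripts, makefile = mk, analysis = a))
}

#' Make: incrementally build all results
#'
#' Tangles first (a no-op on an unchanged source), then captures file
#' modification times, plans the minimal rebuild, and executes it with the
#' internal scheduler. The machine-readable build report is written to
#' `.lir/report.json` (not in a dry run).
#'
#' @param source Path to the literate source file.
#' @param keep_going After a failure, keep building rules that do not
#'   depend on the failed one?
#' @param dry_run Print the plan without running anything?
#' @param quiet Suppress progress messages?
#' @return Invisibly, the `lir_build_report`.
#' @export
lir_make <- function(source, keep_going = FALSE, dry_run = FALSE,
                     quiet = TRUE) {
  t <- lir_tangle(source)
  a <- t$analysis
  fs <- snapshot_filesystem(a$dataflow, a$project_dir)
  plan <- plan_build(a$dataflow, fs)
  if (dry_run && !quiet) print(plan)
  report <- execute_plan(
    plan, a$dataflow, t$scripts, dir = a$project_dir,
    keep_going = keep_going, dry_run = dry_run,
    source_path = a$src$path, quiet = quiet
  )
  if (!dry_run) {
    dir.create(file.path(a$project_dir, ".lir"), showWarnings = FALSE)
    jsonlite::write_json(
      list(success = attr(report, "success"),
           rules = report[, c("rule", "transformation", "status", "reason",
                              "exit_code", "log", "seconds")]),
      file.path(a$project_dir, ".lir", "report.json"),
      auto_unbox = TRUE, pretty = TRUE, na = "null"
    )
  }
  invisible(report)
}

#' Weave: compile the final HTML document
#'
#' Renders the literate source plus the built results into one cross-linked
#' HTML document. Weaving does not require a prior build: placeholders
#' whose files are missing render as visible error boxes with diagnostics,
#' which supports drafting the document before the data exist.
#'
#' @param source Path to the literate source file.
#' @param output Path of the HTML file to write; default is the source
#'   path with its extension replaced by `.html`.
#' @param style Optional CSS file replacing the built-in stylesheet.
#' @param embed Inline figures as base64 data URIs, making the HTML fully
#'   self-contained?
#' @return Invisibly, the `lir_woven` object (with `output` attribute).
#' @export
lir_weave <- function(source, output = NULL, style = NULL, embed = FALSE) {
  a <- analyse_source(source)
  idx <- assign_numbers(a$src, a$graph)
  woven <- weave_document(
    a$src, a$graph, a$dataflow, idx, style = style,
    project_dir = a$project_dir, embed = embed
  )
  if (is.null(output)) {
    output <- file.path(dirname(source),
                        paste0(sub("\\.[^.]*$", "", basename(source)),
                               ".html"))
  }
  write_if_changed(output, woven$html)
  attr(woven, "output") <- output
  invisible(woven)
}

#' Run the full pipeline: tangle, make, weave
#'
#' The three stages in succession. The run stops at the first failing
#' stage; on success the woven HTML and every sink exist and the build
#' report is at `.lir/report.json`.
#'
#' @inheritParams lir_make
#' @inheritParams lir_weave
#' @return Invisibly, a list `(report, woven)`; `woven` is `NULL` when the
#'   build failed or `dry_run` was set.
#' @export
lir_run <- function(source, keep_going = FALSE, dry_run = FALSE,
                    output = NULL, style = NULL, embed = FALSE,
                    quiet = TRUE) {
  report <- lir_make(source, keep_going = keep_going, dry_run = dry_run,
                     quiet = quiet)
  if (dry_run) return(invisible(list(report = report, woven = NULL)))
  if (!isTRUE(attr(report, "success"))) {
    warning("build failed; weave not attempted", call. = FALSE)
    return(invisible(list(report = report, woven = NULL)))
  }
  woven <- lir_weave(source, output = output, style = style, embed = embed)
  invisible(list(report = report, woven = woven))
}
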