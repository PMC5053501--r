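#' Snapshot file modification times for a dataflow
#'
#' Captures, in one pass before planning, the modification time of every
#' data object in the dataflow. Absent files are recorded as `NA`, which is
#' distinct from any timestamp.
#'
#' @param dataflow A `lir_dataflow`.
#' @param dir Project directory the object paths are relative to.
#' @return An object of class `lir_fs_state`: a named numeric vector of
#'   mtimes (seconds), `NA` for absent files.
#' @export
snapshot_filesystem <- function(dataflow, dir = ".") {
  stopifnot(inherits(dataflow, "lir_dataflow"))
  paths <- dataflow$objects$path
  full <- file.path(dir, paths)
  mt <- file.mtime(full)
  mt <- as.numeric(mt)
  names(mt) <- paths
  structure(mt, class = "lir_fs_state")
}

#' Directly stale rules
#'
#' A rule is directly stale iff any of its targets is absent, any of its
#' prerequisites is absent, or the newest prerequisite is strictly newer
#' than the oldest target. Equal timestamps count as up-to-date (so a chain
#' built within one clock tick does not rebuild forever).
#'
#' A declared source that is absent is a fatal error: no rule can create it.
#'
#' @param dataflow A `lir_dataflow`.
#' @param fs A `lir_fs_state` from [snapshot_filesystem()].
#' @return Integer vector of stale rule indices (into `dataflow$rules`).
#' @export
compute_stale <- function(dataflow, fs) {
  stopifnot(inherits(dataflow, "lir_dataflow"), inherits(fs, "lir_fs_state"))
  srcs <- dataflow$objects$path[dataflow$objects$role == "source"]
  missing_src <- srcs[is.na(fs[srcs])]
  if (length(missing_src) > 0L) {
    stop(sprintf("missing source file(s): %s",
                 paste(sprintf("'%s'", missing_src), collapse = ", ")),
         call. = FALSE)
  }
  stale <- integer()
  for (i in seq_along(dataflow$rules)) {
    r <- dataflow$rules[[i]]
    tmt <- fs[r$targets]
    pmt <- fs[r$prerequisites]
    if (anyNA(tmt) || anyNA(pmt) ||
        (length(pmt) > 0L && length(tmt) > 0L && max(pmt) > min(tmt))) {
      stale <- c(stale, i)
    }
  }
  stale
}

#' Plan an incremental build
#'
#' The plan contains every directly stale rule plus every rule downstream
#' of a planned rule (any rule with a prerequisite produced by a planned
#' rule, transitively), in topological order of the rule dependency graph.
#' Ties are broken by rule declaration order, so the plan is deterministic.
#' Rules not in the plan are untouched by [execute_plan()].
#'
#' @param dataflow A `lir_dataflow`.
#' @param fs A `lir_fs_state`.
#' @return An object of class `lir_build_plan`: a data frame with columns
#'   `rule` (index into `dataflow$rules`), `reason` (one of
#'   `"target-missing"`, `"prerequisite-newer"`, `"upstream-scheduled"`),
#'   and `transformation`.
#' @export
plan_build <- function(dataflow, fs) {
  stale <- compute_stale(dataflow, fs)
  n <- length(dataflow$rules)
  deps <- rule_dependencies(dataflow)     # deps[[i]]: rules rule i depends on
  order <- topological_rule_order(deps, n)

  planned <- logical(n)
  planned[stale] <- TRUE
  reason <- rep(NA_character_, n)
  for (i in stale) {
    r <- dataflow$rules[[i]]
    reason[i] <- if (anyNA(fs[r$targets])) "target-missing"
                 else "prerequisite-newer"
  }
  # propagate downstream in topological order
  for (i in order) {
    if (!planned[i] && any(planned[deps[[i]]])) {
      planned[i] <- TRUE
      reason[i] <- "upstream-scheduled"
    }
  }
  idx <- order[planned[order]]
  plan <- data.frame(
    rule = idx,
    reason = reason[idx],
    transformation = vapply(dataflow$rules[idx], `[[`, "", "transformation"),
    stringsAsFactors = FALSE
  )
  class(plan) <- c("lir_build_plan", class(plan))
  plan
}

# deps[[i]] = indices of rules producing a prerequisite of rule i
rule_dependencies <- function(dataflow) {
  lapply(seq_along(dataflow$rules), function(i) {
    pre <- dataflow$rules[[i]]$prerequisites
    unname(dataflow$producer[intersect(pre, names(dataflow$producer))])
  })
}

# Kahn's algorithm; ties broken by declaration order (smallest index first).
topological_rule_order <- function(deps, n) {
  if (n == 0L) return(integer())
  indeg <- vapply(deps, length, 0L)
  out <- integer()
  remaining <- rep(TRUE, n)
  while (any(remaining)) {
    ready <- which(remaining & indeg == 0L)
    if (length(ready) == 0L) {
      stop("rule dependency graph contains a cycle", call. = FALSE)
    }
    i <- ready[1]
    out <- c(out, i)
    remaining[i] <- FALSE
    for (j in which(remaining)) {
      indeg[j] <- indeg[j] - sum(deps[[j]] == i)
    }
  }
  out
}

#' Execute a build plan
#'
#' Runs the planned rules sequentially, in plan order, from the project
#' directory. Each rule executes its transformation's tangled script as a
#' child process (directly when the script has a shebang, otherwise through
#' `sh`), with stdout and stderr captured to
#' `.lir/log/<rule>-<script>.log` and the environment variable `LIR_SOURCE`
#' set to the source file path. A rule whose process exits nonzero, or that
#' exits zero without creating every declared target, is marked `failed`.
#'
#' On failure, rules that depend (transitively) on the failed rule are
#' `skipped`; with `keep_going = TRUE` independent rules still run,
#' otherwise all remaining rules are skipped. With `dry_run = TRUE` nothing
#' executes and every planned rule reports `ok`.
#'
#' @param plan A `lir_build_plan`.
#' @param dataflow The `lir_dataflow` the plan was computed from.
#' @param scripts The `lir_tangled_scripts` data frame.
#' @param dir Project directory (working directory for the child
#'   processes).
#' @param keep_going Continue with independent rules after a failure?
#' @param dry_run Print what would run without running it?
#' @param source_path Value for the `LIR_SOURCE` child environment
#'   variable.
#' @param quiet Suppress per-rule progress messages?
#' @return An object of class `lir_build_report`: a data frame with one row
#'   per planned rule (`rule`, `transformation`, `status`, `reason`,
#'   `exit_code`, `log`, `seconds`) and attribute `success`.
#' @export
execute_plan <- function(plan, dataflow, scripts, dir = ".",
                         keep_going = FALSE, dry_run = FALSE,
                         source_path = "", quiet = TRUE) {
  stopifnot(inherits(plan, "lir_build_plan"), inherits(dataflow, "lir_dataflow"))
  dir <- normalizePath(dir, mustWork = TRUE)
  deps <- rule_dependencies(dataflow)
  n <- nrow(plan)
  status <- character(n)
  why <- character(n)
  exit_code <- rep(NA_integer_, n)
  log_file <- rep(NA_character_, n)
  secs <- rep(NA_real_, n)
  failed_rules <- integer()
  aborted <- FALSE

  log_dir <- file.path(dir, ".lir", "log")
  if (!dry_run && n > 0L) {
    dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
  }

  for (k in seq_len(n)) {
    i <- plan$rule[k]
    r <- dataflow$rules[[i]]
    s <- scripts[scripts$chunk_name == r$transformation, , drop = FALSE]

    depends_on_failure <- depends_transitively(i, failed_rules, deps)
    if (depends_on_failure || (aborted && !keep_going)) {
      status[k] <- "skipped"
      why[k] <- if (depends_on_failure) "upstream-failed" else "aborted"
      next
    }
    if (dry_run) {
      status[k] <- "ok"
      why[k] <- plan$reason[k]
      next
    }
    if (nrow(s) == 0L || !file.exists(file.path(dir, s$file_path[1]))) {
      status[k] <- "failed"
      why[k] <- "script-missing"
      failed_rules <- c(failed_rules, i)
      aborted <- TRUE
      next
    }
    cmd <- script_command(s$file_path[1], s$interpreter[1])
    log_file[k] <- file.path(".lir", "log",
                             paste0(i, "-", basename(s$file_path[1]), ".log"))
    if (!quiet) message(sprintf("[%d/%d] %s", k, n, r$transformation))
    t0 <- Sys.time()
    code <- run_in_dir(cmd, dir, file.path(dir, log_file[k]), source_path)
    secs[k] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    exit_code[k] <- code
    missing_targets <- r$targets[!file.exists(file.path(dir, r$targets))]
    if (code != 0L) {
      status[k] <- "failed"
      why[k] <- "nonzero-exit"
    } else if (length(missing_targets) > 0L) {
      status[k] <- "failed"
      why[k] <- paste0("target-not-created:",
                       paste(missing_targets, collapse = ","))
    } else {
      status[k] <- "ok"
      why[k] <- plan$reason[k]
    }
    if (status[k] == "failed") {
      failed_rules <- c(failed_rules, i)
      aborted <- TRUE
    }
  }

  report <- data.frame(
    rule = plan$rule, transformation = plan$transformation,
    status = status, reason = why, exit_code = exit_code,
    log = log_file, seconds = secs, stringsAsFactors = FALSE
  )
  attr(report, "success") <- !any(status == "failed")
  class(report) <- c("lir_build_report", class(report))
  report
}

# TRUE iff rule i depends, through prerequisite -> producer links, on any
# rule in `bad`.
depends_transitively <- function(i, bad, deps) {
  if (length(bad) == 0L) return(FALSE)
  seen <- logical(length(deps))
  stack <- deps[[i]]
  while (length(stack) > 0L) {
    j <- stack[[1]]
    stack <- stack[-1]
    if (j %in% bad) return(TRUE)
    if (!seen[j]) {
      seen[j] <- TRUE
      stack <- c(stack, deps[[j]])
    }
  }
  FALSE
}

# Runs `cmd` (a shell command line) in `dir`, stdout+stderr to `log_path`;
# returns the child's exit code. The child inherits the environment plus
# LIR_SOURCE.
run_in_dir <- function(cmd, dir, log_path, source_path) {
  owd <- setwd(dir)
  on.exit(setwd(owd))
  old <- Sys.getenv("LIR_SOURCE", unset = NA)
  Sys.setenv(LIR_SOURCE = source_path)
  on.exit({
    if (is.na(old)) Sys.unsetenv("LIR_SOURCE") else Sys.setenv(LIR_SOURCE = old)
  }, add = TRUE, after = FALSE)
  code <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = log_path, stderr = log_path)
  )
  as.integer(code)
}

#' @export
print.lir_build_plan <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<lir_build_plan> nothing to do\n")
    return(invisible(x))
  }
  cat(sprintf("<lir_build_plan> %d rule(s):\n", nrow(x)))
  for (k in seq_len(nrow(x))) {
    cat(sprintf("  %d. %s  (%s)\n", x$rule[k], x$transformation[k],
                x$reason[k]))
  }
  invisible(x)
}

#' @export
print.lir_build_report <- function(x, ...) {
  ok <- attr(x, "success")
  cat(sprintf("<lir_build_report> %d rule(s) planned; %s\n", nrow(x),
              if (isTRUE(ok)) "success" else "FAILED"))
  for (k in seq_len(nrow(x))) {
    cat(sprintf("  %-8s %s (%s)\n", x$status[k], x$transformation[k],
                x$reason[k]))
  }
  invisible(x)
}
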