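# Independent oracles for property tests. These deliberately avoid the
# package's parsing/graph machinery: they operate directly on the data the
# random generators produce, so implementation and oracle can only agree by
# computing the same answer.

# --- chunk expansion -------------------------------------------------------

# Naive recursive substitution on a plain named list of body lines.
oracle_expand <- function(bodies, name) {
  rec <- function(nm) {
    out <- character()
    for (line in bodies[[nm]]) {
      m <- regmatches(line, regexec("^([ \t]*)<<(.+)>>$", line))[[1]]
      if (length(m) == 3L && m[3] %in% names(bodies)) {
        sub_lines <- rec(m[3])
        out <- c(out, paste0(m[2], sub_lines))
      } else {
        line <- gsub("@<<", "<<", line, fixed = TRUE)
        line <- gsub("@>>", ">>", line, fixed = TRUE)
        out <- c(out, line)
      }
    }
    out
  }
  lines <- rec(name)
  if (length(lines) == 0L) "" else paste0(paste(lines, collapse = "\n"), "\n")
}

# Random acyclic chunk definitions: chunk i may reference only chunks j > i,
# which makes cycles impossible by construction.
random_acyclic_chunks <- function(n_chunks = sample(1:8, 1)) {
  names <- paste0("c", seq_len(n_chunks))
  bodies <- list()
  for (i in seq_len(n_chunks)) {
    n_lines <- sample(0:4, 1)
    lines <- character(n_lines)
    for (k in seq_len(n_lines)) {
      roll <- runif(1)
      if (roll < 0.35 && i < n_chunks) {
        pool <- (i + 1):n_chunks   # sample() treats a scalar as 1:n
        target <- names[pool[sample.int(length(pool), 1)]]
        indent <- paste(rep(" ", sample(0:4, 1)), collapse = "")
        lines[k] <- paste0(indent, "<<", target, ">>")
      } else if (roll < 0.45) {
        lines[k] <- paste0("x @<<", sample(letters, 1), "@>> y")
      } else {
        lines[k] <- paste(sample(letters, sample(1:3, 1)), collapse = " ")
      }
    }
    bodies[[names[i]]] <- lines
  }
  bodies
}

# Renders chunk definitions to literate source text (doc prose between
# definitions), so the implementation path exercises parse + graph + expand.
chunks_to_source <- function(bodies) {
  lines <- c("Preamble text.", "")
  for (nm in names(bodies)) {
    lines <- c(lines, paste0("<<", nm, ">>="), bodies[[nm]], "@ prose",
               "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# --- build planning --------------------------------------------------------

# Brute-force staleness + downstream reachability on plain rule lists.
# rules: list of list(targets, prerequisites); mtimes: named numeric with NA
# for absent files. Returns the sorted set of rule indices that must run.
oracle_plan_set <- function(rules, mtimes) {
  n <- length(rules)
  stale <- vapply(seq_len(n), function(i) {
    r <- rules[[i]]
    tmt <- mtimes[r$targets]
    pmt <- mtimes[r$prerequisites]
    anyNA(tmt) || anyNA(pmt) ||
      (length(pmt) > 0L && max(pmt) > min(tmt))
  }, TRUE)
  planned <- stale
  repeat {
    grew <- FALSE
    for (i in seq_len(n)) {
      if (planned[i]) next
      upstream_files <- unlist(lapply(which(planned),
                                      function(j) rules[[j]]$targets))
      if (any(rules[[i]]$prerequisites %in% upstream_files)) {
        planned[i] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  sort(which(planned))
}

# Random layered rule DAG with its filesystem state. Rule i produces file
# "t<i>" from a random subset of source files and earlier targets.
random_rule_dag <- function(n_rules = sample(1:10, 1), n_sources = 3) {
  sources <- paste0("s", seq_len(n_sources))
  rules <- list()
  for (i in seq_len(n_rules)) {
    pool <- c(sources, if (i > 1) paste0("t", seq_len(i - 1)))
    k <- sample(0:min(3, length(pool)), 1)
    rules[[i]] <- list(
      targets = paste0("t", i),
      prerequisites = if (k > 0) sample(pool, k) else character(),
      transformation = paste0("step ", i),
      declaration_line = i
    )
  }
  all_paths <- c(sources, paste0("t", seq_len(n_rules)))
  mtimes <- stats::setNames(as.numeric(sample(1:50, length(all_paths),
                                              replace = TRUE)), all_paths)
  # some targets absent; sources always present
  absent <- paste0("t", which(runif(n_rules) < 0.3))
  mtimes[absent] <- NA_real_
  list(rules = rules, mtimes = mtimes, sources = sources)
}

# Wraps a random DAG in the package's dataflow / filesystem-state classes.
as_dataflow <- function(dag) {
  targets <- vapply(dag$rules, function(r) r$targets[1], "")
  producer <- stats::setNames(seq_along(dag$rules), targets)
  objects <- data.frame(
    path = names(dag$mtimes),
    role = ifelse(names(dag$mtimes) %in% dag$sources, "source",
                  ifelse(names(dag$mtimes) %in% targets[
                    !targets %in% unlist(lapply(dag$rules, `[[`,
                                                "prerequisites"))],
                    "sink", "intermediate")),
    displayed = FALSE, stringsAsFactors = FALSE
  )
  structure(list(objects = objects, rules = dag$rules, producer = producer),
            class = "lir_dataflow")
}

as_fs_state <- function(mtimes) {
  structure(mtimes, class = "lir_fs_state")
}

# --- LCG -------------------------------------------------------------------

# Independent evaluation of the recurrence, exact in double precision via a
# 20/11-bit split of the state (every intermediate product stays below
# 2^53, and (u * 2^20) mod m may reduce u mod m first).
oracle_lcg_states <- function(seed, n) {
  m <- 2^31
  a <- 1103515245
  x <- seed
  out <- numeric(n)
  for (i in seq_len(n)) {
    x_hi <- x %/% 2^20
    x_lo <- x %% 2^20
    p1 <- (((a * x_hi) %% m) * 2^20) %% m
    x <- (p1 + a * x_lo + 12345) %% m
    out[i] <- x
  }
  out
}

# --- misc ------------------------------------------------------------------

# A fresh throwaway project directory path (parent removed by withr when
# the calling test finishes). The directory itself is not created.
local_project_dir <- function(env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), "proj")
}

has_fatal_diag <- function(d) nrow(d) > 0L && any(d$severity == "fatal")

# Matches of a perl regex in a single string.
match_count <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}
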