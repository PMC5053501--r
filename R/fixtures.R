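#' Deterministic pseudo-random stream
#'
#' A small linear congruential generator used to synthesize example data:
#' the state recurrence is `x <- (1103515245 * x + 12345) mod 2^31`, and
#' each state maps to the value `2 * x / 2^31 - 1` in `[-1, 1)`. The
#' generator is self-contained and platform-independent (the modular
#' arithmetic is carried out in exact double-precision pieces), so the same
#' seed always yields bit-identical example projects, independent of R's
#' own RNG state.
#'
#' @param seed Integer in `[0, 2^31)`.
#' @param n Number of values (the states after 1..n iterations).
#' @return Numeric vector of `n` values in `[-1, 1)`.
#' @examples
#' lcg_stream(42, 3)
#' @export
lcg_stream <- function(seed, n) {
  stopifnot(n >= 0)
  if (seed < 0 || seed >= 2^31 || seed != floor(seed)) {
    stop("seed must be an integer in [0, 2^31)", call. = FALSE)
  }
  x <- as.double(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- lcg_next(x)
    out[i] <- 2 * x / 2^31 - 1
  }
  out
}

# (1103515245 * x + 12345) mod 2^31 without loss of double precision:
# split x into 16-bit halves so every intermediate product stays < 2^53.
lcg_next <- function(x) {
  a <- 1103515245
  hi <- floor(x / 65536)          # upper 15 bits
  lo <- x - hi * 65536            # lower 16 bits
  t <- (a * hi) %% 32768          # (a*hi*2^16) mod 2^31 = ((a*hi) mod 2^15)*2^16
  (t * 65536 + a * lo + 12345) %% 2^31
}

#' Generate a self-contained example project
#'
#' Writes a complete toy analysis into `dir`: a synthetic input table
#' (`data/input.csv`, columns `id,value`, values from [lcg_stream()]
#' rendered with six decimal digits) and a literate source file
#' (`analysis.lir`) that documents and defines a four-step pipeline across
#' two interpreters:
#'
#' 1. a shell step filtering rows with positive values into
#'    `results/pos.csv`;
#' 2. a Python step computing the count and mean of the positive values
#'    into `results/stats.tsv`;
#' 3. a shell step rendering the count as a small SVG bar chart,
#'    `results/plot.svg`;
#' 4. a shell step copying the first five data lines to
#'    `results/head.txt`.
#'
#' The source declares the input in `lir:sources`, wires the steps in
#' `lir:rules`, marks `results/pos.csv` as an extra (non-displayed) sink in
#' `lir:sinks`, and displays the other three results through a table, a
#' figure, and a listing placeholder. Regenerating with the same seed
#' reproduces every file byte-for-byte.
#'
#' @param dir Target directory; must be empty or absent.
#' @param seed LCG seed for the synthetic values.
#' @param n_rows Number of data rows.
#' @return An object of class `lir_fixture_manifest`: `project_dir`,
#'   `source_file`, `input_files` (data frame `path`, `md5`),
#'   `expected_sinks`, `seed`, `n_rows`.
#' @export
generate_example_project <- function(dir, seed = 42L, n_rows = 100L) {
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE,
                                           no.. = TRUE)) > 0L) {
    stop(sprintf("directory '%s' exists and is not empty", dir),
         call. = FALSE)
  }
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)

  values <- sprintf("%.6f", lcg_stream(seed, n_rows))
  csv <- c("id,value", paste0(seq_len(n_rows), ",", values))
  write_lines_lf(csv, file.path(dir, "data", "input.csv"))

  src_path <- file.path(dir, "analysis.lir")
  write_lines_lf(example_source_lines(seed, n_rows), src_path)

  input_csv <- file.path(dir, "data", "input.csv")
  manifest <- structure(
    list(
      project_dir = dir,
      source_file = src_path,
      input_files = data.frame(
        path = c("data/input.csv", "analysis.lir"),
        md5 = unname(tools::md5sum(c(input_csv, src_path))),
        stringsAsFactors = FALSE
      ),
      expected_sinks = c("results/stats.tsv", "results/plot.svg",
                         "results/head.txt", "results/pos.csv"),
      seed = seed, n_rows = n_rows
    ),
    class = "lir_fixture_manifest"
  )
  manifest
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  close(con)
}

# The literate source of the example project. Kept as code (not a stored
# fixture) so the project regenerates identically everywhere.
example_source_lines <- function(seed, n_rows) {
  c(
    "# A toy analysis",
    "",
    sprintf("This project analyses `data/input.csv`: %d synthetic values in", n_rows),
    sprintf("`[-1, 1)` drawn from a linear congruential generator (seed %d).", seed),
    "The pipeline filters the positive values, summarizes them, and draws",
    "the count as a bar.",
    "",
    "## Filtering",
    "",
    "Rows with a positive `value` are kept. The output has no header row,",
    "so its line count is the number of positive values.",
    "",
    "<<filter positive rows>>=",
    "#!/bin/sh",
    "<<ensure results directory>>",
    "awk -F, 'NR > 1 && $2 + 0 > 0' data/input.csv > results/pos.csv",
    "@",
    "",
    "Creating the output directory is shared by several steps:",
    "",
    "<<ensure results directory>>=",
    "mkdir -p results",
    "@",
    "",
    "## Summary statistics",
    "",
    "The count and mean of the positive values:",
    "",
    "<<summarize positives>>=",
    "#!/usr/bin/env python3",
    "import csv",
    "",
    "with open(\"results/pos.csv\", newline=\"\") as fh:",
    "    vals = [float(row[1]) for row in csv.reader(fh) if row]",
    "n = len(vals)",
    "mean = sum(vals) / n if n else 0.0",
    "with open(\"results/stats.tsv\", \"w\") as out:",
    "    out.write(\"count\\tmean\\n\")",
    "    out.write(\"%d\\t%.6f\\n\" % (n, mean))",
    "@",
    "",
    "%%table results/stats.tsv :: Count and mean of the positive values.",
    "",
    "## A picture",
    "",
    "One horizontal bar whose length is the count of positive values,",
    "written as a minimal SVG by shell templating (no plotting library):",
    "",
    "<<draw count bar>>=",
    "<<ensure results directory>>",
    "count=$(awk -F'\\t' 'NR == 2 { print $1 }' results/stats.tsv)",
    "width=$((count * 3))",
    "{",
    "  printf '<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"340\" height=\"60\" viewBox=\"0 0 340 60\">\\n'",
    "  printf '  <rect x=\"10\" y=\"20\" width=\"%s\" height=\"20\" fill=\"#4477aa\"/>\\n' \"$width\"",
    "  printf '  <text x=\"10\" y=\"15\" font-size=\"12\">positive values: %s</text>\\n' \"$count\"",
    "  printf '</svg>\\n'",
    "} > results/plot.svg",
    "@",
    "",
    "%%figure results/plot.svg :: Count of positive values, as a bar.",
    "",
    "## A peek at the input",
    "",
    "The first five data lines of the input, for the record:",
    "",
    "<<preview input>>=",
    "#!/bin/sh",
    "<<ensure results directory>>",
    "sed -n '2,6p' data/input.csv > results/head.txt",
    "@",
    "",
    "%%listing results/head.txt :: First five rows of the input table.",
    "",
    "## Analysis definition",
    "",
    "The declared input:",
    "",
    "<<lir:sources>>=",
    "data/input.csv",
    "@",
    "",
    "The filtered table is kept even though it is not displayed:",
    "",
    "<<lir:sinks>>=",
    "results/pos.csv",
    "@",
    "",
    "The rules wiring files to transformations:",
    "",
    "<<lir:rules>>=",
    "results/pos.csv : data/input.csv",
    "\tfilter positive rows",
    "results/stats.tsv : results/pos.csv",
    "\tsummarize positives",
    "results/plot.svg : results/stats.tsv",
    "\tdraw count bar",
    "results/head.txt : data/input.csv",
    "\tpreview input",
    "@"
  )
}

#' @export
print.lir_fixture_manifest <- function(x, ...) {
  cat(sprintf(
    "<lir_fixture_manifest> %s (seed %d, %d rows)\n  source: %s\n  expected sinks: %s\n",
    x$project_dir, x$seed, x$n_rows, x$source_file,
    paste(x$expected_sinks, collapse = ", ")
  ))
  invisible(x)
}
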