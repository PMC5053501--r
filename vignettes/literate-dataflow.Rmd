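---
title: "Literate dataflow documents: the model behind litweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literate dataflow documents: the model behind litweave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litweave)
```

## The model

A `litweave` source file is a sequence of documentation chunks and named
code chunks in the noweb tradition. Code chunks may splice other chunks by
name, so programs can be presented in the order of the exposition rather
than the order a compiler needs; chunks never referenced by another chunk
are *roots*, and roots are the unit of execution: each one defines a data
transformation.

On top of the chunk model sits an explicit dataflow. Three specially named
chunks declare it:

* `lir:sources` — the input files, whitespace-separated, `#` comments
  allowed. Declaring inputs explicitly is what lets the build refuse to
  run when an input is missing rather than silently producing nothing.
* `lir:sinks` — result files that must be generated even though they are
  not displayed in the report.
* `lir:rules` — one rule per transformation application, in a strict
  make-compatible subset: a line `targets : prerequisites` followed by
  exactly one tab-indented recipe line holding the root chunk's name
  verbatim.

Files are vertices, rules are edges, and the whole must be a DAG. Every
display placeholder in the prose (`%%figure PATH :: CAPTION`, likewise
`%%table` and `%%listing`) makes its file a sink as well. Validation
rejects cycles, targets produced twice, rules naming unknown or non-root
chunks, sinks nothing produces, and files that are both declared sources
and rule targets; it warns about roots no rule uses and sources no rule
reads. A sink may feed a later rule: displayed intermediates that are
reused downstream are normal practice, not an error.

## The dialect, precisely

The chunk syntax deliberately pins down details that folklore leaves
loose, because the parser must be lossless (serializing the parse
reproduces the file byte-for-byte, which the test suite checks on
hundreds of randomly generated sources):

* `<<name>>=` alone at column 0 opens a code chunk; a line that is `@` or
  starts with `@ ` returns to documentation, with the text after `@ `
  belonging to the prose.
* A chunk reference must stand alone on its line (whitespace indentation
  allowed); `<<...>>` elsewhere in a code line is literal text, and
  `@<<` / `@>>` escape literal delimiters. Inline (mid-line) splices are
  not supported — they add grammar ambiguity and no expressive power for
  whole-program transformations.
* Re-defining a chunk name continues it: bodies concatenate in file
  order. Reference expansion is depth-first, and a reference indented by
  some prefix prepends that exact prefix to every line it produces, so
  tangled Python keeps valid indentation.
* Placeholders are only recognized in documentation chunks; an identical
  line inside a code chunk is code.
* Encoding is UTF-8 and CRLF is normalized to LF on input, so parses are
  identical across platforms.

The placeholder spelling (`%%kind PATH :: CAPTION`) is this package's own
choice: it cannot collide with markdown, and it greps trivially.

## Tangling and the exported makefile

Each rule-referenced root chunk is expanded and written to
`.lir/scripts/<sanitized-name>` (characters outside `[A-Za-z0-9._-]`
become `_`; two names that collide are an error, not a silent overwrite).
A leading `#!` line makes the script run directly; otherwise it runs
through POSIX `sh`, the least common denominator on the supported
platforms. Tangling is write-if-changed: unchanged scripts keep their
bytes *and* mtimes, so re-tangling an unchanged source never cascades
into a rebuild.

Only rule-referenced roots are tangled; a root no rule names is flagged
as a warning instead, since nothing defines where its outputs would go.

The same dataflow is also exported to `.lir/Makefile` (`all` depends on
every sink; multi-target rules use GNU make's grouped-target `&:`
separator so the recipe runs once for the group). The makefile plus the
tangled scripts are self-sufficient: a machine with only the analysis
tools and `make` can rebuild everything without this package installed.
The internal scheduler remains the primary builder — it removes the
external dependency and reports per-rule results — and the test suite
checks that the two routes produce byte-identical sinks on the example
project when a `make` program is present.

## Incremental builds

Staleness is judged from file modification times, captured in a single
snapshot before planning: a rule is directly stale iff a target is
absent, a prerequisite is absent, or the newest prerequisite is strictly
newer than the oldest target. Equal timestamps count as up to date —
on filesystems with coarse clocks, a chain built within one tick must not
rebuild forever. An absent *declared source* is a fatal error instead:
no rule can create it, so building would only push the failure
downstream.

The plan is the directly stale rules plus everything reachable from them
through prerequisite–producer links, in topological order with ties
broken by declaration order, which makes plans and logs deterministic.
Execution is sequential in v1 (parallelism would be purely additive);
each transformation runs as a child process from the project directory,
inheriting the environment plus `LIR_SOURCE=<source path>`, with
stdout/stderr captured to `.lir/log/` and a machine-readable report
written to `.lir/report.json`. A rule that exits zero without creating
all of its declared targets is marked failed — the declaration is a
contract, and auditing it catches the classic silently-truncated-output
bug. After a failure the default is to stop (dependent rules are
reported skipped); `keep_going = TRUE` still runs independent rules.
`dry_run = TRUE` prints the plan with reasons and runs nothing. These
failure semantics are a design choice of this package; stop-by-default
matches what interactive users expect from build tools.

Correctness of the planner is established against independent oracles in
the test suite: naive recursive substitution for chunk expansion, and
brute-force stale-marking plus reachability for plan sets, each on a few
hundred randomly generated cases per run, alongside the convergence
property (build; build again; the second plan is empty) and the
minimality property (touch one file; exactly the downstream rules
re-run).

## Weaving

The woven HTML document contains the full text of the source. Prose is
rendered as CommonMark — one pinned dialect keeps output deterministic —
with a table of contents built from headings of levels 1–3
(anchor ids are slugified, duplicates disambiguated). Each physical code
chunk definition gets the next number in file order and renders under a
`⟨name⟩ n ≡` header (`+≡` with a backlink when it continues an earlier
definition — continuations get distinct numbers so "used in chunk 7" is
unambiguous). References are hyperlinked to the referee's first
definition, and each chunk lists the chunks that use it. Display items
are numbered per kind with the labels "Figure", "Table", and "Listing":
figures by reference to the image file (base64-inlined with
`embed = TRUE`), tables parsed from the file (tab-delimited if the first
line contains a tab, else comma; double-quote wrapping honored) with the
first row as header, listings verbatim. Sinks that are not displayed are
linked in a closing "Generated files" section. A missing display file
renders as a visible error box plus a diagnostic rather than aborting:
one can weave a draft document before any data exist. The built-in CSS
can be replaced wholesale with a user stylesheet; PDF output is out of
scope for v1.

## The example project and what it does (not) show

`generate_example_project()` writes a deterministic toy analysis used
throughout the tests: `data/input.csv` holds `n_rows = 100` values drawn
from a bespoke linear congruential generator
(`x <- (1103515245 x + 12345) mod 2^31`, mapped to `[-1, 1)`, rendered
with six decimals; default seed 42). A bespoke LCG rather than R's RNG
keeps the fixture bit-identical across platforms and independent of any
runtime's sampler; the arithmetic is split into 16-bit halves so every
intermediate stays exact in double precision. The pipeline has the shape
of a real multi-tool analysis at toy scale — a shell/awk filter, a Python
summary, a templated SVG chart, a POSIX text extraction, chained through
an intermediate file and displayed via all three placeholder kinds — and
its defaults (100 rows, seed 42) are small enough to build in seconds
yet visibly nontrivial (45 of 100 values are positive).

What passing on this fixture shows: the chunk grammar, expansion,
dataflow extraction, planning, execution, and weaving compose correctly
end-to-end, deterministically, across two interpreters. What it cannot
show: behavior on large inputs, long-running or flaky transformations,
exotic encodings in data files, or concurrent edits to the project while
a build runs — none of which the scheduler attempts to handle in v1.
Property tests use problem sizes of up to 8 chunks and 10 rules with a
few hundred replicates per run, chosen to exhaust the structural variety
of small DAGs while keeping the default test run fast.

## Numerical and degenerate-input choices

* Timestamps compare strictly (`>`); equality is up to date.
* An empty chunk expands to the empty string; expansion output otherwise
  ends with exactly one trailing newline.
* An empty dataflow (no `lir:rules`) is a warning, not an error: the
  document-only workflow is legitimate, and weaving works without rules.
* Cycle errors name the full cycle path (`<<a>> -> <<b>> -> <<a>>`);
  undefined-chunk diagnostics carry the referencing line number.
* Paths are project-relative with `/` separators; whitespace in paths is
  unrepresentable in the declaration syntax, by design.
* Exit codes of the command-line wrapper: 0 success, 1 fatal
  diagnostics or failed build, 2 usage error.
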