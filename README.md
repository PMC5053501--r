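# litweave

Literate, reproducible data-analysis documents with incremental builds.

## The problem

A typical data analysis is scattered across scripts in several languages,
ad-hoc shell commands, intermediate files nobody remembers how to
regenerate, and a report that was pasted together by hand. When one input
changes, it is unclear what must be re-run; when the report is read, it is
unclear which code produced which figure.

`litweave` keeps the entire analysis in **one plain-text source file**
containing three kinds of material:

* **documentation chunks** — markdown prose explaining the analysis;
* **code chunks** — named, reusable blocks of executable code in any
  language (noweb conventions: `<<name>>=` opens a chunk, `@` returns to
  prose, `<<name>>` on its own line splices one chunk into another);
* **an analysis definition** — three specially named chunks declaring the
  input files (`lir:sources`), extra results to keep (`lir:sinks`), and
  make-style rules (`lir:rules`) binding each transformation (a *root*
  code chunk, one not referenced by any other chunk) to the files it reads
  and writes.

Together the declarations form a **dataflow DAG**: data files are the
vertices, transformation applications the edges, declared inputs the
sources, and displayed or declared results the sinks. From this single
file the package

1. **tangles** every transformation into an executable script (and exports
   an equivalent makefile, so results can be rebuilt on a machine that has
   only the analysis tools and `make`);
2. **builds** all results incrementally — a rule re-runs only when a
   target is missing or a prerequisite is strictly newer (file mtimes),
   plus everything downstream, in topological order;
3. **weaves** a cross-linked HTML report: numbered code chunks with
   hyperlinked references and "used in" backlinks, a table of contents,
   and the pipeline's figures, tables, and listings embedded at their
   `%%figure` / `%%table` / `%%listing` placeholders, numbered per kind.

## Worked example

The package generates a complete toy project — 100 synthetic values in
`[-1, 1)` from a built-in linear congruential generator, analysed by a
four-step shell + Python pipeline:

```r
library(litweave)
m <- generate_example_project("demo", seed = 42, n_rows = 100)
res <- lir_run("demo/analysis.lir")
res$report
#> <lir_build_report> 4 rule(s) planned; success
#>   ok       filter positive rows (target-missing)
#>   ok       summarize positives (target-missing)
#>   ok       draw count bar (target-missing)
#>   ok       preview input (target-missing)
cat(readLines("demo/results/stats.tsv"), sep = "\n")
#> count	mean
#> 45	0.488169
```

Of the 100 values drawn with seed 42, 45 are positive and their mean is
0.488169; `results/pos.csv` holds those 45 rows, `results/plot.svg` draws
the count as a bar, and `demo/analysis.html` is the woven report. A second
`lir_make("demo/analysis.lir")` plans zero rules — everything is up to
date — and after editing only `data/input.csv`, exactly the four rules
downstream of it re-run.

The same pipeline is scriptable from a shell:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "litweave", package = "litweave"))')
"$cli" example demo --seed 42 --rows 100
"$cli" run demo/analysis.lir
```

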