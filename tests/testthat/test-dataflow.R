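# Builds a parsed source + chunk graph from declaration pieces.
dataflow_fixture <- function(rules_body,
                             sources = "data/in.csv",
                             sinks = NULL,
                             extra = "",
                             transformations = c("clean data")) {
  txt <- paste0(
    extra,
    "<<lir:sources>>=\n", paste(sources, collapse = "\n"), "\n@\n",
    if (!is.null(sinks))
      paste0("<<lir:sinks>>=\n", paste(sinks, collapse = "\n"), "\n@\n"),
    paste0("<<", transformations, ">>=\n#!/bin/sh\necho run\n@\n",
           collapse = ""),
    "<<lir:rules>>=\n", rules_body
  )
  src <- parse_source(txt)
  graph <- build_chunk_graph(src)
  c(list(src = src, graph = graph), extract_dataflow(src, graph))
}

test_that("roles are assigned from declarations, placeholders, and rules", {
  f <- dataflow_fixture("out.csv : data/in.csv\n\tclean data\n")
  o <- f$dataflow$objects
  expect_equal(o$role[o$path == "data/in.csv"], "source")
  expect_equal(o$role[o$path == "out.csv"], "intermediate")
  expect_length(f$dataflow$rules, 1)
  expect_equal(f$dataflow$rules[[1]]$transformation, "clean data")
  expect_equal(unname(f$dataflow$producer["out.csv"]), 1L)

  # a displayed placeholder turns the target into a displayed sink
  f <- dataflow_fixture("out.csv : data/in.csv\n\tclean data\n",
                        extra = "%%table out.csv :: caption\n")
  o <- f$dataflow$objects
  expect_equal(o$role[o$path == "out.csv"], "sink")
  expect_true(o$displayed[o$path == "out.csv"])

  # an lir:sinks entry is a non-displayed sink
  f <- dataflow_fixture("log.txt : data/in.csv\n\tclean data\n",
                        sinks = "log.txt")
  o <- f$dataflow$objects
  expect_equal(o$role[o$path == "log.txt"], "sink")
  expect_false(o$displayed[o$path == "log.txt"])
})

test_that("comments and whitespace in declarations are tolerated", {
  f <- dataflow_fixture(
    "out.csv : data/in.csv\n\tclean data\n",
    sources = c("data/in.csv  # the input", "# nothing else")
  )
  o <- f$dataflow$objects
  expect_equal(sum(o$role == "source"), 1)
})

test_that("rule syntax violations carry line numbers", {
  f <- dataflow_fixture("out.csv : data/in.csv\n")        # no recipe
  expect_true(any(f$diagnostics$code == "rule-syntax"))
  expect_false(anyNA(f$diagnostics$line[f$diagnostics$code == "rule-syntax"]))

  f <- dataflow_fixture(": data/in.csv\n\tclean data\n")  # zero targets
  expect_true(any(grepl("zero targets", f$diagnostics$message)))

  f <- dataflow_fixture("out.csv : data/in.csv\n\tclean data\n\textra\n")
  expect_true(any(grepl("more than one recipe", f$diagnostics$message)))

  # a source with no lir:rules chunk gives an empty dataflow plus warning
  src <- parse_source("prose only\n")
  g <- build_chunk_graph(src)
  ext <- extract_dataflow(src, g)
  expect_length(ext$dataflow$rules, 0)
  expect_true(any(ext$diagnostics$code == "no-rules"))
})

test_that("validation finds the fatal DAG violations", {
  # dependency cycle
  f <- dataflow_fixture(
    "b : a\n\tt1\na : b\n\tt2\n",
    sources = "s", transformations = c("t1", "t2")
  )
  d <- validate_dataflow(f$dataflow, f$graph)
  expect_true(any(d$code == "dependency-cycle" & d$severity == "fatal"))
  expect_match(d$message[d$code == "dependency-cycle"], "->")

  # declared source that is also a rule target
  f <- dataflow_fixture("x : y\n\tclean data\n", sources = "x")
  d <- validate_dataflow(f$dataflow, f$graph)
  expect_true(any(d$code == "source-is-target"))

  # two rules producing the same target
  f <- dataflow_fixture(
    "o : data/in.csv\n\tt1\no : data/in.csv\n\tt2\n",
    transformations = c("t1", "t2")
  )
  d <- validate_dataflow(f$dataflow, f$graph)
  expect_true(any(d$code == "duplicate-producer"))

  # recipe naming an unknown chunk
  f <- dataflow_fixture("o : data/in.csv\n\tno such chunk\n")
  d <- validate_dataflow(f$dataflow, f$graph)
  expect_true(any(d$code == "unknown-transformation"))

  # recipe naming a chunk that is referenced elsewhere (not a root)
  f <- dataflow_fixture(
    "o : data/in.csv\n\thelper\n",
    extra = "<<wrapper>>=\n<<helper>>\n@\n<<helper>>=\nx\n@\n",
    transformations = character()
  )
  d <- validate_dataflow(f$dataflow, f$graph)
  expect_true(any(d$code == "transformation-not-root"))

  # sink that nothing produces
  f <- dataflow_fixture("o : data/in.csv\n\tclean data\n",
                        sinks = "phantom.txt")
  d <- validate_dataflow(f$dataflow, f$graph)
  expect_true(any(d$code == "unproduced-sink"))
})

test_that("validation warns about unused roots and unused sources", {
  f <- dataflow_fixture(
    "o : data/in.csv\n\tclean data\n",
    sources = c("data/in.csv", "spare.csv"),
    extra = "<<orphan step>>=\necho never\n@\n"
  )
  d <- validate_dataflow(f$dataflow, f$graph)
  expect_true(any(d$code == "unused-transformation" &
                  d$severity == "warning"))
  expect_true(any(d$code == "unused-source" & d$severity == "warning"))
  # a sink reused as a prerequisite downstream is not a violation
  f <- dataflow_fixture(
    "mid.csv : data/in.csv\n\tt1\nfinal.csv : mid.csv\n\tt2\n",
    sinks = c("mid.csv", "final.csv"), transformations = c("t1", "t2")
  )
  d <- validate_dataflow(f$dataflow, f$graph)
  expect_false(has_fatal_diag(d))
})

test_that("the exported makefile is deterministic and complete", {
  f <- dataflow_fixture(
    "out.csv : data/in.csv\n\tclean data\n",
    extra = "%%table out.csv :: t\n"
  )
  dir <- withr::local_tempdir()
  scripts <- tangle_scripts(f$graph, "clean data",
                            file.path(dir, ".lir", "scripts"))
  # use project-relative script paths as the interface layer does
  scripts$file_path <- file.path(".lir", "scripts",
                                 basename(scripts$file_path))
  mk <- export_makefile(f$dataflow, scripts)
  expect_match(mk, "all: out.csv\n", fixed = TRUE)
  expect_match(mk, "out.csv : data/in.csv\n\t./.lir/scripts/clean_data",
               fixed = TRUE)
  expect_identical(mk, export_makefile(f$dataflow, scripts))

  # grouped multi-target syntax
  f2 <- dataflow_fixture("a b : data/in.csv\n\tclean data\n")
  mk2 <- export_makefile(f2$dataflow, scripts)
  expect_match(mk2, "a b &: data/in.csv", fixed = TRUE)

  # empty dataflow still yields a valid makefile with only `all:`
  src <- parse_source("prose\n")
  g <- build_chunk_graph(src)
  ext <- extract_dataflow(src, g)
  mk3 <- export_makefile(ext$dataflow, scripts[0, ])
  expect_match(mk3, "\nall:\n", fixed = TRUE)
  expect_equal(match_count(mk3, "\n\t"), 0)

  # export refuses when validation has fatals
  bad <- dataflow_fixture("x : y\n\tclean data\n", sources = "x")
  expect_error(export_makefile(bad$dataflow, scripts, bad$graph),
               "fatal")
})
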