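# A concrete two-rule chain project written to disk:
#   data/in.txt -> mid.txt -> out.txt, plus an independent side.txt.
write_chain_project <- function(dir) {
  dir.create(file.path(dir, "data"), recursive = TRUE)
  writeLines("1", file.path(dir, "data", "in.txt"))
  src <- paste0(
    "<<lir:sources>>=\ndata/in.txt\n@\n",
    "<<make mid>>=\n#!/bin/sh\ncat data/in.txt > mid.txt\n@\n",
    "<<make out>>=\n#!/bin/sh\ncat mid.txt mid.txt > out.txt\n@\n",
    "<<make side>>=\n#!/bin/sh\necho side > side.txt\n@\n",
    "<<lir:sinks>>=\nout.txt side.txt\n@\n",
    "<<lir:rules>>=\n",
    "mid.txt : data/in.txt\n\tmake mid\n",
    "out.txt : mid.txt\n\tmake out\n",
    "side.txt : data/in.txt\n\tmake side\n"
  )
  path <- file.path(dir, "analysis.lir")
  writeLines(src, path, sep = "")
  path
}

analyse <- function(path) {
  src <- parse_source(path = path)
  graph <- build_chunk_graph(src)
  ext <- extract_dataflow(src, graph)
  list(src = src, graph = graph, dataflow = ext$dataflow)
}

test_that("staleness follows missing files and strict mtime comparison", {
  dag <- random_rule_dag(3)
  # deterministic small case instead: one rule, t1 <- s1
  rules <- list(list(targets = "t1", prerequisites = "s1",
                     transformation = "step 1", declaration_line = 1L))
  dag <- list(rules = rules,
              mtimes = c(s1 = 10, t1 = 20), sources = "s1")
  df <- as_dataflow(dag)
  expect_equal(compute_stale(df, as_fs_state(c(s1 = 10, t1 = 20))),
               integer())
  # equal timestamps are up-to-date
  expect_equal(compute_stale(df, as_fs_state(c(s1 = 20, t1 = 20))),
               integer())
  # strictly newer prerequisite is stale
  expect_equal(compute_stale(df, as_fs_state(c(s1 = 21, t1 = 20))), 1L)
  # missing target is stale
  expect_equal(compute_stale(df, as_fs_state(c(s1 = 10, t1 = NA))), 1L)
  # absent declared source is fatal
  expect_error(compute_stale(df, as_fs_state(c(s1 = NA, t1 = 20))),
               "missing source.*'s1'")
})

test_that("plans cascade downstream with the right reasons", {
  rules <- list(
    list(targets = "b", prerequisites = "a", transformation = "r1",
         declaration_line = 1L),
    list(targets = "c", prerequisites = "b", transformation = "r2",
         declaration_line = 2L)
  )
  dag <- list(rules = rules, mtimes = c(a = 30, b = 20, c = 25),
              sources = "a")
  df <- as_dataflow(dag)
  plan <- plan_build(df, as_fs_state(dag$mtimes))
  expect_equal(plan$rule, c(1L, 2L))
  expect_equal(plan$reason, c("prerequisite-newer", "upstream-scheduled"))

  # nothing stale -> empty plan
  plan <- plan_build(df, as_fs_state(c(a = 10, b = 20, c = 25)))
  expect_equal(nrow(plan), 0)

  # a missing intermediate makes its producer target-missing stale and its
  # consumer directly stale through the absent prerequisite
  plan <- plan_build(df, as_fs_state(c(a = 10, b = NA, c = 25)))
  expect_equal(plan$reason, c("target-missing", "prerequisite-newer"))
})

test_that("planned sets equal the stale-plus-reachability oracle", {
  set.seed(60601)
  for (i in 1:220) {
    dag <- random_rule_dag()
    df <- as_dataflow(dag)
    plan <- plan_build(df, as_fs_state(dag$mtimes))
    expect_equal(sort(plan$rule),
                 oracle_plan_set(dag$rules, dag$mtimes))
    # order is topological: every dependency of a planned rule that is
    # itself planned appears earlier
    pos <- match(seq_along(dag$rules), plan$rule)
    for (k in seq_len(nrow(plan))) {
      i_rule <- plan$rule[k]
      for (p in dag$rules[[i_rule]]$prerequisites) {
        j <- which(vapply(dag$rules,
                          function(r) p %in% r$targets, TRUE))
        if (length(j) == 1 && j %in% plan$rule) {
          expect_lt(pos[j], k + 1)
          expect_lt(pos[j], pos[i_rule])
        }
      }
    }
  }
})

test_that("executing a plan builds the chain and converges", {
  dir <- withr::local_tempdir()
  path <- write_chain_project(dir)
  a <- analyse(path)
  scripts <- withr::with_dir(dir, tangle_scripts(
    a$graph, unique(vapply(a$dataflow$rules, `[[`, "", "transformation")),
    file.path(".lir", "scripts")
  ))
  fs <- snapshot_filesystem(a$dataflow, dir)
  plan <- plan_build(a$dataflow, fs)
  expect_equal(nrow(plan), 3)
  report <- execute_plan(plan, a$dataflow, scripts, dir = dir)
  expect_true(attr(report, "success"))
  expect_true(all(file.exists(file.path(dir, c("mid.txt", "out.txt",
                                               "side.txt")))))
  # convergence: a fresh snapshot finds nothing stale
  fs2 <- snapshot_filesystem(a$dataflow, dir)
  expect_equal(compute_stale(a$dataflow, fs2), integer())
  # empty plan executes successfully and runs nothing
  report2 <- execute_plan(plan_build(a$dataflow, fs2), a$dataflow, scripts,
                          dir = dir)
  expect_equal(nrow(report2), 0)
  expect_true(attr(report2, "success"))
  # logs were captured per rule
  expect_true(dir.exists(file.path(dir, ".lir", "log")))
})

test_that("a failing rule fails the build and skips its dependents", {
  dir <- withr::local_tempdir()
  path <- write_chain_project(dir)
  a <- analyse(path)
  scripts <- withr::with_dir(dir, tangle_scripts(
    a$graph, unique(vapply(a$dataflow$rules, `[[`, "", "transformation")),
    file.path(".lir", "scripts")
  ))
  # sabotage the first script after tangling
  writeLines(c("#!/bin/sh", "exit 3"),
             file.path(dir, ".lir", "scripts", "make_mid"))
  plan <- plan_build(a$dataflow, snapshot_filesystem(a$dataflow, dir))

  # default: stop after the failure
  report <- execute_plan(plan, a$dataflow, scripts, dir = dir)
  expect_false(attr(report, "success"))
  expect_equal(report$status[report$transformation == "make mid"], "failed")
  expect_equal(report$exit_code[report$transformation == "make mid"], 3L)
  expect_equal(report$status[report$transformation == "make out"], "skipped")

  # keep_going: the independent branch still completes
  report <- execute_plan(plan, a$dataflow, scripts, dir = dir,
                         keep_going = TRUE)
  expect_equal(report$status[report$transformation == "make side"], "ok")
  expect_equal(report$reason[report$transformation == "make out"],
               "upstream-failed")
  expect_true(file.exists(file.path(dir, "side.txt")))
})

test_that("a rule that exits 0 without creating its target is failed", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "data"), recursive = TRUE)
  writeLines("1", file.path(dir, "data", "in.txt"))
  src <- paste0(
    "<<lir:sources>>=\ndata/in.txt\n@\n",
    "<<liar>>=\n#!/bin/sh\ntrue\n@\n",
    "<<lir:sinks>>=\nout.txt\n@\n",
    "<<lir:rules>>=\nout.txt : data/in.txt\n\tliar\n"
  )
  writeLines(src, file.path(dir, "analysis.lir"), sep = "")
  a <- analyse(file.path(dir, "analysis.lir"))
  scripts <- withr::with_dir(dir, tangle_scripts(a$graph, "liar",
                                                 file.path(".lir", "scripts")))
  plan <- plan_build(a$dataflow, snapshot_filesystem(a$dataflow, dir))
  report <- execute_plan(plan, a$dataflow, scripts, dir = dir)
  expect_false(attr(report, "success"))
  expect_match(report$reason[1], "target-not-created")
})

test_that("dry runs execute nothing and report every planned rule ok", {
  dir <- withr::local_tempdir()
  path <- write_chain_project(dir)
  a <- analyse(path)
  scripts <- withr::with_dir(dir, tangle_scripts(
    a$graph, unique(vapply(a$dataflow$rules, `[[`, "", "transformation")),
    file.path(".lir", "scripts")
  ))
  plan <- plan_build(a$dataflow, snapshot_filesystem(a$dataflow, dir))
  report <- execute_plan(plan, a$dataflow, scripts, dir = dir,
                         dry_run = TRUE)
  expect_true(attr(report, "success"))
  expect_true(all(report$status == "ok"))
  expect_false(any(file.exists(file.path(dir, c("mid.txt", "out.txt",
                                                "side.txt")))))
})
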