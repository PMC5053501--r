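Package: litweave
Title: Literate, Reproducible Data-Analysis Documents with Incremental Builds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A literate-programming system for reproducible data analysis.
    A single plain-text source file holds the documentation (markdown), the
    executable code of every data transformation (noweb-style named chunks),
    and the dataflow graph connecting input data, intermediate files, and
    final results. The package tangles the code chunks into executable
    scripts, exports an equivalent makefile, rebuilds stale results
    incrementally from file modification times, and weaves a cross-linked
    HTML report in which figures, tables, and listings produced by the
    pipeline are numbered, captioned, and embedded at their placeholders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    commonmark,
    jsonlite,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
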