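# Random well-formed literate source texts for round-trip testing. The
# generator emits the raw text directly (never via the package's
# serializer), mixing documentation, markers, placeholders, chunk
# definitions, references, and escapes.

random_word_line <- function() {
  paste(sample(c(letters, "alpha", "beta", "-", "*", "1."),
               sample(1:5, 1), replace = TRUE), collapse = " ")
}

random_doc_lines <- function(n = sample(0:4, 1)) {
  vapply(seq_len(n), function(i) {
    roll <- runif(1)
    if (roll < 0.1) {
      ""
    } else if (roll < 0.2) {
      paste0("%%", sample(c("figure", "table", "listing"), 1),
             " results/f", sample(1:5, 1), ".txt",
             if (runif(1) < 0.5) " :: a caption" else "")
    } else if (roll < 0.3) {
      paste("#", random_word_line())
    } else {
      random_word_line()
    }
  }, "")
}

random_code_lines <- function(chunk_names, n = sample(0:4, 1)) {
  vapply(seq_len(n), function(i) {
    roll <- runif(1)
    if (roll < 0.2 && length(chunk_names) > 0) {
      paste0(strrep(" ", sample(0:3, 1)),
             "<<", sample(chunk_names, 1), ">>")
    } else if (roll < 0.3) {
      paste0("echo @<<literal@>> ", sample(letters, 1))
    } else if (roll < 0.4) {
      ""
    } else {
      paste0(sample(c("cmd ", "  cmd ", "\tcmd "), 1), random_word_line())
    }
  }, "")
}

random_source_text <- function() {
  chunk_names <- paste0("chunk ", sample(LETTERS, sample(1:5, 1)))
  lines <- random_doc_lines()
  n_blocks <- sample(1:6, 1)
  for (b in seq_len(n_blocks)) {
    if (runif(1) < 0.6) {
      nm <- sample(chunk_names, 1)
      lines <- c(lines, paste0("<<", nm, ">>="),
                 random_code_lines(chunk_names))
    }
    marker <- sample(c("@", "@ back to prose", "@ "), 1)
    lines <- c(lines, marker, random_doc_lines())
  }
  paste0(paste(lines, collapse = "\n"),
         if (runif(1) < 0.9) "\n" else "")
}
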