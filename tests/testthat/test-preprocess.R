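test_that("split_sentences handles prose, empty text, and exact offsets", {
  expect_identical(nrow(split_sentences("")), 0L)

  one <- split_sentences(zydelig_sentence())
  expect_identical(one$text, zydelig_sentence())
  expect_identical(one$start, 0L)

  s1 <- "Severe rash occurred."
  s2 <- "Therapy was stopped."
  two <- split_sentences(paste(s1, s2))
  expect_identical(two$text, c(s1, s2))
  expect_identical(diff(two$start), nchar(s1) + 1L)

  ## sentences are exact substrings at their offsets
  fx <- make_synth_corpus(3L, seed = 41L)
  for (lbl in fx$labels) for (sec in lbl$sections) {
    sp <- split_sentences(sec$text)
    for (i in seq_len(nrow(sp)))
      expect_identical(substr(sec$text, sp$start[i] + 1L,
                              sp$start[i] + nchar(sp$text[i])), sp$text[i])
  }
})

test_that("split_sentences never loses non-whitespace characters", {
  fx <- make_synth_corpus(3L, seed = 43L)
  for (lbl in fx$labels) for (sec in lbl$sections) {
    sp <- split_sentences(sec$text)
    covered <- logical(nchar(sec$text))
    for (i in seq_len(nrow(sp)))
      covered[(sp$start[i] + 1L):(sp$start[i] + nchar(sp$text[i]))] <- TRUE
    gaps <- strsplit(sec$text, "")[[1L]][!covered]
    expect_true(all(grepl("^\\s$", gaps)))
  }
})

test_that("table-like lines are emitted one sentence per line", {
  txt <- paste("Adverse reactions were frequent.",
               "Reaction      Rate      Grade",
               "rash          12%       2",
               "Therapy continued.", sep = "\n")
  sp <- split_sentences(txt)
  expect_identical(sp$text[2L], "Reaction      Rate      Grade")
  expect_identical(sp$text[3L], "rash          12%       2")
  expect_true(is_table_row("a  b  c"))
  expect_true(is_table_row("x | y | z"))
  expect_false(is_table_row("plain prose line"))
})

test_that("tokenizer reproduces the printed offsets and handles punctuation", {
  tok <- tokenize_with_offsets(zydelig_sentence(), 2763L)
  exp <- zydelig_expected()
  expect_identical(tok$text, exp$text)
  expect_identical(as.integer(tok$start), exp$start)
  expect_identical(as.integer(tok$length), exp$length)

  expect_identical(nrow(tokenize_with_offsets("", 0L)), 0L)

  tok2 <- tokenize_with_offsets("cancer.", 100L)
  expect_identical(tok2$text, c("cancer", "."))
  expect_identical(as.integer(tok2$start), c(100L, 106L))
})

test_that("token offsets are faithful to the section text", {
  fx <- make_synth_corpus(3L, seed = 47L)
  for (lbl in fx$labels) for (sec in lbl$sections) {
    sp <- split_sentences(sec$text)
    for (i in seq_len(nrow(sp))) {
      tok <- tokenize_with_offsets(sp$text[i], sp$start[i])
      for (k in seq_len(nrow(tok)))
        expect_identical(substr(sec$text, tok$start[k] + 1L,
                                tok$start[k] + tok$length[k]), tok$text[k])
    }
  }
})

test_that("encode_bio2 matches the printed tag column and conventions", {
  tok <- tokenize_with_offsets(zydelig_sentence(), 2763L)
  expect_identical(encode_bio2(tok, zydelig_mentions()),
                   zydelig_expected()$tag)
  expect_identical(encode_bio2(tok, list()), rep("O", 10L))

  tok2 <- tokenize_with_offsets("hypersensitivity reactions", 0L)
  m <- adr_mention("H1", "S1", "AdverseReaction", 0L, 26L,
                   "hypersensitivity reactions")
  expect_identical(encode_bio2(tok2, list(m)), c("B-ADR", "I-ADR"))
})

test_that("non-aligned mention spans expand to covering tokens with a warning", {
  tok <- tokenize_with_offsets("severe headaches occurred", 0L)
  m <- adr_mention("X1", "S1", "AdverseReaction", 7L, 8L, "headache")
  expect_warning(tags <- encode_bio2(tok, list(m)), "aligned")
  expect_identical(tags, c("O", "B-ADR", "O"))
})

test_that("decode_bio2 inverts encode_bio2 and repairs invalid I tags", {
  tok2 <- tokenize_with_offsets("hypersensitivity reactions", 0L)
  ms <- decode_bio2(tok2, c("B-ADR", "I-ADR"), "S1",
                    "hypersensitivity reactions")
  expect_length(ms, 1L)
  expect_identical(ms[[1L]]$text, "hypersensitivity reactions")
  expect_identical(ms[[1L]]$type, "AdverseReaction")

  expect_identical(decode_bio2(tok2, c("O", "O")), list())

  ## lenient repair: I-X after O becomes B-X
  ms2 <- decode_bio2(tok2, c("O", "I-ADR"), "S1")
  expect_length(ms2, 1L)
  expect_identical(as.integer(ms2[[1L]]$starts), 17L)
  expect_identical(repair_bio2(c("I-SEV", "O", "I-ADR")),
                   c("B-SEV", "O", "B-ADR"))
})

test_that("encode/decode are mutually inverse on synthetic sentences", {
  fx <- make_synth_corpus(5L, seed = 53L)
  for (s in fx$sentences) {
    ms <- decode_bio2(s$tokens, s$tags, s$section_id)
    expect_identical(encode_bio2(s$tokens, ms), s$tags)
  }
})

test_that("flatten_irregular handles the shared-fragment pattern", {
  ## "<head> of the a , b , and c": one contiguous + two discontinuous
  txt <- "Angioedema of the face , lips , and tongue was seen ."
  h <- 0L; hl <- 17L                         # "Angioedema of the"
  face <- c(18L, 4L); lips <- c(25L, 4L); tongue <- c(36L, 6L)
  ms <- list(
    adr_mention("A1", "S1", "AdverseReaction", 0L, 22L, "Angioedema of the face"),
    adr_mention("A2", "S1", "AdverseReaction", c(h, lips[1L]), c(hl, lips[2L]),
                "Angioedema of the lips"),
    adr_mention("A3", "S1", "AdverseReaction", c(h, tongue[1L]), c(hl, tongue[2L]),
                "Angioedema of the tongue"))
  fl <- flatten_irregular(ms, txt, "S1")
  expect_identical(vapply(fl, `[[`, "", "text"),
                   c("Angioedema of the", "face", "lips", "tongue"))
  ## all contiguous single-span and non-overlapping
  st <- vapply(fl, function(m) m$starts[1L], 0L)
  en <- st + vapply(fl, function(m) m$lengths[1L], 0L)
  expect_true(all(st[-1L] >= en[-length(en)]))
})

test_that("flatten_irregular is identity on regular input and applies priority", {
  txt <- "severe rash and fever occurred"
  ms <- list(adr_mention("R1", "S1", "AdverseReaction", 7L, 4L, "rash"),
             adr_mention("R2", "S1", "AdverseReaction", 16L, 5L, "fever"))
  fl <- flatten_irregular(ms, txt, "S1")
  expect_identical(lapply(fl, function(m) c(m$starts, m$lengths)),
                   lapply(ms, function(m) c(m$starts, m$lengths)))

  ## identical spans of different types: higher-priority type wins
  both <- list(adr_mention("P1", "S1", "Severity", 0L, 6L, "severe"),
               adr_mention("P2", "S1", "AdverseReaction", 0L, 6L, "severe"))
  fl2 <- flatten_irregular(both, txt, "S1")
  expect_length(fl2, 1L)
  expect_identical(fl2[[1L]]$type, "AdverseReaction")
})

test_that("flattened irregular corpora are contiguous and non-overlapping", {
  fx <- make_synth_corpus(4L, seed = 59L, irregular_fraction = 1)
  n_irr <- 0L
  for (lbl in fx$labels) for (sec in lbl$sections) {
    ms <- Filter(function(m) m$section_id == sec$id, lbl$mentions)
    n_irr <- n_irr + sum(vapply(ms, function(m) length(m$starts) > 1L, TRUE))
    fl <- flatten_irregular(ms, sec$text, sec$id)
    if (length(fl) > 1L) {
      st <- vapply(fl, function(m) m$starts[1L], 0L)
      en <- st + vapply(fl, function(m) m$lengths[1L], 0L)
      o <- order(st)
      expect_true(all(st[o][-1L] >= en[o][-length(en)]))
    }
    for (m in fl) expect_length(m$starts, 1L)
  }
  expect_gt(n_irr, 0L)   # the generator did plant discontinuous mentions
})
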