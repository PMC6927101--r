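test_that("case_feature assigns the documented classes", {
  cases <- c("2015" = 0L,            # numeric
             "123mg" = 1L,           # mainly numeric (3/5 digits)
             "patients" = 2L,        # all lower
             "FDA" = 3L,             # all upper
             "Fatal" = 4L,           # initial upper
             "11C-choline" = 5L,     # contains digit (2/11 digits)
             "anti-TNF" = 6L)        # other (mixed case, no digits)
  for (tok in names(cases))
    expect_identical(case_feature(tok), unname(cases[tok]))
  expect_identical(case_feature(NA_character_), 7L)   # padding
  expect_error(case_feature(""), "empty")
})

test_that("word lookup follows the fallback chain", {
  tab <- embedding_table(c("cancer", "x0mg"), dim = 4L, seed = 5L)
  exact <- word_lookup("cancer", tab)
  expect_length(exact, 4L)
  ## lowercase fallback
  expect_identical(word_lookup("Cancer", tab), exact)
  ## digit-normalization fallback: "x27mg" -> "x0mg"
  expect_identical(word_lookup("x27mg", tab), word_lookup("x0mg", tab))
  ## OOV
  oov <- tab$vectors[tab$index[["<OOV>"]], ]
  expect_identical(word_lookup("zzzznotaword", tab), oov)
  expect_identical(normalize_word("Ab12cd345"), "ab0cd0")
})

test_that("word-vector files round-trip", {
  tab <- embedding_table(c("alpha", "beta"), dim = 3L, seed = 9L)
  f <- tempfile(fileext = ".vec")
  write_word_vectors(tab, f)
  back <- read_word_vectors(f)
  expect_equal(word_lookup("alpha", back), word_lookup("alpha", tab),
               tolerance = 1e-6)
  expect_equal(back$dim, 3L)
})

test_that("char representation has the contracted shape and max-pool semantics", {
  tok <- data.frame(text = c("abcd", "ge"), start = c(0L, 5L),
                    length = c(4L, 2L))
  sent <- tagged_sentence("S1", tok, c("O", "O"))
  cfg <- tagger_config(char_emb_dim = 2L, char_filters = 1L,
                       variational_dropout = 0, word_emb_dim = 4L,
                       lstm_units = c(3L, 2L), seed = 2L)
  model <- init_tagger(list(sent), config = cfg)

  out <- char_representation("abcd", model)
  expect_length(out, 1L)
  expect_true(all(is.finite(out)))

  ## hand computation: 1 filter, width 3; enumerate windows explicitly
  p <- model$params
  idx <- adrex:::char_indices("abcd", model$char_index, model$pad_len)
  emb <- p$char_emb[idx, ]
  wins <- vapply(seq_len(length(idx) - 2L), function(w) {
    sum(p$conv_W[1L, ] * as.vector(t(emb[w:(w + 2L), ]))) + p$conv_b[1L]
  }, 0)
  expect_equal(out, max(wins), tolerance = 1e-12)

  ## zero embeddings + zero bias -> zero output
  m0 <- model
  m0$params$char_emb[] <- 0
  m0$params$conv_b[] <- 0
  expect_equal(char_representation("abcd", m0), 0)

  ## default geometry gives length 30
  m30 <- init_tagger(list(sent), config = tagger_config(seed = 2L))
  expect_length(char_representation("abcd", m30), 30L)
})

test_that("build_input concatenates char, word and case parts (238 dims)", {
  tok <- data.frame(text = c("Fatal", "rash", "rash"),
                    start = c(0L, 6L, 11L), length = c(5L, 4L, 4L))
  sent <- tagged_sentence("S1", tok, c("O", "O", "O"))
  model <- init_tagger(list(sent), config = tagger_config(seed = 3L))
  X <- build_input(model, tok)
  expect_identical(dim(X), c(30L + 200L + 8L, 3L))
  ## case one-hot slot: "Fatal" is initial-upper (class index 4)
  expect_equal(X[230L + case_feature("Fatal") + 1L, 1L], 1)
  expect_equal(sum(X[231:238, 1L]), 1)
  ## identical tokens give identical combined vectors
  expect_identical(X[, 2L], X[, 3L])
})

test_that("network gradients match finite differences on a tiny model", {
  set.seed(7)
  tok <- data.frame(text = c("Abc", "de-9", "x"), start = c(0L, 4L, 9L),
                    length = c(3L, 4L, 1L))
  sent <- tagged_sentence("S1", tok, c("B-ADR", "I-ADR", "O"))
  cfg <- tagger_config(char_emb_dim = 4L, char_filters = 3L, word_emb_dim = 5L,
                       lstm_units = c(4L, 3L), variational_dropout = 0,
                       seed = 3L)
  model <- init_tagger(list(sent), config = cfg)
  gold <- adrex:::tags_to_idx(sent$tags, model$tags)
  loss_fn <- function(m) {
    fwd <- adrex:::sentence_forward(m, tok)
    adrex:::crf_nll_grad(fwd$emissions, m$params$trans, gold)$loss
  }
  g <- adrex:::zero_grads(model$params)
  fwd <- adrex:::sentence_forward(model, tok)
  crf <- adrex:::crf_nll_grad(fwd$emissions, model$params$trans, gold)
  g$trans <- g$trans + crf$d_transitions
  adrex:::sentence_backward(model, fwd, crf$d_emissions, g)
  eps <- 1e-6
  frozen_char_pad <- function(nm, k) {
    ## the <PAD> char-embedding row is frozen by design
    nm == "char_emb" &&
      ((k - 1L) %% nrow(model$params$char_emb)) + 1L == adrex:::PAD_CHAR_IDX
  }
  for (nm in names(model$params)) {
    P <- model$params[[nm]]
    ks <- sample(length(P), min(5L, length(P)))
    for (k in ks) {
      if (frozen_char_pad(nm, k)) next
      m2 <- model
      m2$params[[nm]][k] <- m2$params[[nm]][k] + eps
      num <- (loss_fn(m2) - crf$loss) / eps
      expect_equal(num, g[[nm]][k], tolerance = 1e-3,
                   label = paste("grad", nm, k))
    }
  }
})
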