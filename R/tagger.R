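## The neural sequence tagger: char-CNN + word + case embeddings feeding
## two stacked bidirectional LSTMs and a linear-chain CRF, trained with
## NADAM under global gradient-norm clipping and variational dropout.

#' Tagger hyper-parameter configuration
#'
#' Defaults follow the published recipe for this architecture: 30-filter
#' width-3 stride-1 character CNN over 30-dimensional character
#' embeddings, 200-dimensional word embeddings, 8 one-hot case features,
#' stacked Bi-LSTMs with 100 and 75 recurrent units, variational dropout
#' 0.25, global gradient-norm clipping at 1.0, NADAM optimization.
#' `max_epochs`, `batch_size` and `learning_rate` are not pinned by the
#' recipe; the defaults here (50 with early stopping, 32, 2e-3) are the
#' common choices for NADAM at this scale.
#'
#' @param char_emb_dim,char_filters,char_filter_width,char_stride
#'   Character-CNN geometry.
#' @param word_emb_dim Word-embedding dimension.
#' @param case_emb_dim One-hot case-feature width.
#' @param lstm_units Integer vector of the two stacked Bi-LSTM sizes.
#' @param variational_dropout Dropout rate in `[0, 1)`, same mask across
#'   time steps.
#' @param grad_norm_clip Global gradient-norm cap (> 0).
#' @param optimizer Only `"nadam"` is implemented.
#' @param max_epochs,batch_size,learning_rate Training-loop parameters.
#' @param patience Early-stopping patience on held-out mention F1.
#' @param dev_fraction Fraction of the corpus held out for early stopping.
#' @param seed RNG seed controlling initialization, batching and dropout.
#' @return A `tagger_config` list.
#' @export
tagger_config <- function(char_emb_dim = 30L, char_filters = 30L,
                          char_filter_width = 3L, char_stride = 1L,
                          word_emb_dim = 200L, case_emb_dim = 8L,
                          lstm_units = c(100L, 75L),
                          variational_dropout = 0.25,
                          grad_norm_clip = 1.0, optimizer = "nadam",
                          max_epochs = 50L, batch_size = 32L,
                          learning_rate = 2e-3, patience = 5L,
                          dev_fraction = 0.1, seed = 1L) {
  stopifnot(char_emb_dim > 0, char_filters > 0, char_filter_width > 0,
            word_emb_dim > 0, case_emb_dim == 8L, all(lstm_units > 0),
            variational_dropout >= 0, variational_dropout < 1,
            grad_norm_clip > 0, identical(tolower(optimizer), "nadam"))
  structure(list(char_emb_dim = as.integer(char_emb_dim),
                 char_filters = as.integer(char_filters),
                 char_filter_width = as.integer(char_filter_width),
                 char_stride = as.integer(char_stride),
                 word_emb_dim = as.integer(word_emb_dim),
                 case_emb_dim = 8L,
                 lstm_units = as.integer(lstm_units),
                 variational_dropout = variational_dropout,
                 grad_norm_clip = grad_norm_clip,
                 optimizer = "nadam",
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 dev_fraction = dev_fraction,
                 seed = as.integer(seed)),
            class = "tagger_config")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

init_lstm <- function(p, prefix, H, D) {
  p[[paste0(prefix, "W")]] <- glorot(4L * H, D)
  p[[paste0(prefix, "U")]] <- glorot(4L * H, H)
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1                        # forget-gate bias
  p[[paste0(prefix, "b")]] <- b
  p
}

#' Initialize an untrained tagger model
#'
#' Builds vocabularies from the corpus, seeds all weights, and returns a
#' model usable with [predict_tags] (untrained) or [train_tagger].
#' Word embeddings come from `table` when supplied (missing words and the
#' OOV entry are seeded uniform(-0.25, 0.25)); otherwise the whole table is
#' randomly initialized, so the package trains with no downloads.
#'
#' @param corpus List of [tagged_sentence] objects.
#' @param table Optional pre-trained [embedding_table].
#' @param config A [tagger_config].
#' @return An object of class `tagger_model`.
#' @export
init_tagger <- function(corpus, table = NULL, config = tagger_config()) {
  if (!length(corpus)) stop("empty corpus")
  set.seed(config$seed)
  words <- unique(unlist(lapply(corpus, function(s) s$tokens$text)))
  vocab <- unique(c(words, tolower(words), normalize_word(words)))
  all_words <- c(PAD_TOKEN, OOV_TOKEN, vocab)
  V <- length(all_words)
  d <- config$word_emb_dim
  word_emb <- matrix(stats::runif(V * d, -0.25, 0.25), V, d)
  word_emb[1L, ] <- 0
  word_index <- stats::setNames(seq_len(V), all_words)
  if (!is.null(table)) {
    if (table$dim != d) stop("embedding table dim ", table$dim,
                             " != word_emb_dim ", d)
    hit <- intersect(all_words, names(table$index))
    word_emb[word_index[hit], ] <- table$vectors[table$index[hit], ]
  }
  char_index <- build_char_index(words)
  pad_len <- max(nchar(words), config$char_filter_width)
  tags <- tag_set()
  K <- length(tags)

  p <- list()
  p$char_emb <- matrix(stats::runif((length(char_index) + 2L) * config$char_emb_dim,
                                    -0.25, 0.25),
                       length(char_index) + 2L, config$char_emb_dim)
  p$char_emb[PAD_CHAR_IDX, ] <- 0
  p$conv_W <- glorot(config$char_filters,
                     config$char_filter_width * config$char_emb_dim)
  p$conv_b <- numeric(config$char_filters)
  p$word_emb <- word_emb
  input_dim <- config$char_filters + d + 8L
  p <- init_lstm(p, "l1f_", config$lstm_units[1L], input_dim)
  p <- init_lstm(p, "l1b_", config$lstm_units[1L], input_dim)
  p <- init_lstm(p, "l2f_", config$lstm_units[2L], 2L * config$lstm_units[1L])
  p <- init_lstm(p, "l2b_", config$lstm_units[2L], 2L * config$lstm_units[1L])
  p$emit_W <- glorot(K, 2L * config$lstm_units[2L])
  p$emit_b <- numeric(K)
  p$trans <- matrix(0, K + 2L, K + 2L)

  structure(list(config = config, params = p, word_index = word_index,
                 char_index = char_index, pad_len = pad_len, tags = tags),
            class = "tagger_model")
}

#' Combined input vectors for a sentence
#'
#' Concatenates, per token, the char-CNN representation
#' (`char_filters`), the word embedding (`word_emb_dim`) and the one-hot
#' case feature (8), giving vectors of length 238 under the defaults.
#'
#' @param model A `tagger_model`.
#' @param tokens Token data frame (`text`, `start`, `length`).
#' @return Numeric matrix, one column per token.
#' @export
build_input <- function(model, tokens) {
  sentence_forward(model, tokens)$X
}

## ---- NADAM ---------------------------------------------------------------

nadam_state <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

## One NADAM step (Adam with Nesterov momentum) over the flat parameter
## list.  grads must carry the same names/shapes.
nadam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    m_hat <- state$m[[nm]] / bc1
    v_hat <- state$v[[nm]] / bc2
    upd <- (beta1 * m_hat + (1 - beta1) * gmat / bc1) / (sqrt(v_hat) + eps)
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

zero_grads <- function(params) {
  g <- new.env(parent = emptyenv())
  for (nm in names(params)) g[[nm]] <- params[[nm]] * 0
  g
}

clip_global_norm <- function(g, max_norm) {
  ss <- 0
  for (nm in ls(g)) ss <- ss + sum(g[[nm]]^2)
  nrm <- sqrt(ss)
  if (nrm > max_norm) {
    sc <- max_norm / nrm
    for (nm in ls(g)) g[[nm]] <- g[[nm]] * sc
  }
  nrm
}

tags_to_idx <- function(tags, tagset) {
  idx <- match(tags, tagset)
  if (anyNA(idx)) stop("unknown tag(s): ",
                       paste(unique(tags[is.na(idx)]), collapse = ", "))
  idx
}

## Loss and gradient accumulation for one sentence (training path).
sentence_loss_grad <- function(model, sent, g, masks) {
  fwd <- sentence_forward(model, sent$tokens, masks = masks)
  gold <- tags_to_idx(sent$tags, model$tags)
  crf <- crf_nll_grad(fwd$emissions, model$params$trans, gold)
  g$trans <- g$trans + crf$d_transitions
  sentence_backward(model, fwd, crf$d_emissions, g)
  crf$loss
}

#' Train the neural tagger
#'
#' Minimizes the mean CRF negative log-likelihood over the corpus with
#' NADAM, clipping the global gradient norm at `config$grad_norm_clip` and
#' applying variational dropout (the same mask at every time step, sampled
#' independently per Bi-LSTM layer and direction) during training only.
#' A seeded fraction of the corpus is held out and mention-level F1 on it
#' drives early stopping; the best-scoring weights are restored.
#'
#' @param corpus Non-empty list of [tagged_sentence] objects.
#' @param table Optional pre-trained [embedding_table].
#' @param config A [tagger_config].
#' @param quiet Suppress per-epoch progress messages?
#' @return A trained `tagger_model` (with a `history` element).
#' @export
train_tagger <- function(corpus, table = NULL, config = tagger_config(),
                         quiet = TRUE) {
  if (!length(corpus)) stop("empty corpus")
  model <- init_tagger(corpus, table, config)
  set.seed(config$seed + 1L)
  n <- length(corpus)
  n_dev <- floor(config$dev_fraction * n)
  dev_idx <- if (n_dev >= 1L && n - n_dev >= 1L) sample(n, n_dev) else integer(0)
  train_set <- if (length(dev_idx)) corpus[-dev_idx] else corpus
  dev_set <- corpus[dev_idx]

  input_dim <- config$char_filters + config$word_emb_dim + 8L
  state <- nadam_state(model$params)
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0), dev_f1 = numeric(0))
  stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(train_set))
    total_loss <- 0
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      g <- zero_grads(model$params)
      for (si in bidx) {
        sent <- train_set[[si]]
        if (!nrow(sent$tokens)) next
        masks <- sample_dropout_masks(config, input_dim, config$lstm_units[1L])
        total_loss <- total_loss +
          sentence_loss_grad(model, sent, g, masks)
      }
      for (nm in ls(g)) g[[nm]] <- g[[nm]] / length(bidx)
      g$char_emb[PAD_CHAR_IDX, ] <- 0
      g$word_emb[1L, ] <- 0
      clip_global_norm(g, config$grad_norm_clip)
      upd <- nadam_step(model$params, as.list(g)[names(model$params)], state,
                        config$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    dev_f1 <- if (length(dev_set)) dev_mention_f1(model, dev_set) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = total_loss / length(train_set),
                                         dev_f1 = dev_f1))
    if (!quiet)
      message(sprintf("epoch %d: loss %.4f dev F1 %s", epoch,
                      total_loss / length(train_set),
                      ifelse(is.na(dev_f1), "-", sprintf("%.3f", dev_f1))))
    if (length(dev_set)) {
      if (dev_f1 > best$f1 + 1e-9) {
        best <- list(f1 = dev_f1, params = model$params, epoch = epoch)
        stale <- 0L
      } else {
        ## on a dev-score tie keep the later (further-trained) weights:
        ## the dev set is small and saturates early, while the loss is
        ## still improving
        if (dev_f1 >= best$f1 - 1e-9)
          best <- list(f1 = best$f1, params = model$params, epoch = epoch)
        stale <- stale + 1L
      }
      if (stale >= config$patience) break
    }
  }
  if (length(dev_set) && is.finite(best$f1)) model$params <- best$params
  model$history <- history
  model$trained <- TRUE
  model
}

## Held-out mention-level F1 used for early stopping.
dev_mention_f1 <- function(model, sentences) {
  pred <- predict_tags(model, sentences)
  gold_m <- list(); pred_m <- list()
  for (i in seq_along(sentences)) {
    s <- sentences[[i]]
    sid <- paste0(s$section_id, "#", i)   # sentence-scoped matching
    gold_m <- c(gold_m, decode_bio2(s$tokens, s$tags, section_id = sid))
    pred_m <- c(pred_m, decode_bio2(pred[[i]]$tokens, pred[[i]]$tags,
                                    section_id = sid))
  }
  score_mentions(gold_m, pred_m)[["f1"]]
}

#' Predict BIO2 tags for sentences
#'
#' Runs the forward pass with dropout disabled and decodes each sentence
#' with Viterbi; output tags are made BIO2-valid by lenient repair.
#'
#' @param model A `tagger_model`.
#' @param sentences List of [tagged_sentence] objects (tags ignored).
#' @return List of [tagged_sentence] objects with predicted tags.
#' @export
predict_tags <- function(model, sentences) {
  lapply(sentences, function(s) {
    if (!nrow(s$tokens))
      return(tagged_sentence(s$section_id, s$tokens, character(0)))
    fwd <- sentence_forward(model, s$tokens, masks = NULL)
    vit <- crf_viterbi(fwd$emissions, model$params$trans)
    tags <- repair_bio2(model$tags[vit$tags])
    tagged_sentence(s$section_id, s$tokens, tags)
  })
}

#' Save / load a tagger model
#'
#' Serializes the configuration, vocabularies and weights as a single
#' archive; a reloaded model yields identical predictions.
#'
#' @param model A `tagger_model`.
#' @param path File path.
#' @return `save_tagger` returns `path` invisibly; `load_tagger` the model.
#' @export
save_tagger <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tagger_model")) stop("not a tagger model: ", path)
  model
}
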