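## Hand-rolled LSTM machinery for the sequence tagger: forward pass,
## backpropagation through time, and the full sentence-level forward and
## backward passes that wire char-CNN + word + case inputs through two
## stacked bidirectional LSTM layers into CRF emissions.

sigmoid <- function(x) 1 / (1 + exp(-x))

## One directional LSTM pass over the columns of X (D x T).
## lp is list(W (4H x D), U (4H x H), b (4H)).  Gate order: i, f, o, g.
lstm_forward <- function(lp, X, reverse = FALSE) {
  H <- ncol(lp$U)
  Tn <- ncol(X)
  Hm <- matrix(0, H, Tn)
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  WX <- lp$W %*% X + lp$b
  ii <- 1:H; fi <- (H + 1L):(2L * H); oi <- (2L * H + 1L):(3L * H)
  gi <- (3L * H + 1L):(4L * H)
  h <- numeric(H); cc <- numeric(H)
  cache <- vector("list", Tn)
  for (t in ord) {
    z <- WX[, t] + lp$U %*% h
    i <- sigmoid(z[ii]); f <- sigmoid(z[fi]); o <- sigmoid(z[oi])
    g <- tanh(z[gi])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = cc, tc = tc,
                       h_prev = h)
    h <- h_new; cc <- c_new
    Hm[, t] <- h
  }
  list(H = Hm, cache = cache, ord = ord)
}

## BPTT for one directional LSTM.  dH is the gradient w.r.t. the layer's
## hidden outputs (H x T).  Returns dX (D x T) and accumulates dW, dU, db
## into the gradient environment g under names paste0(prefix, c("W","U","b")).
lstm_backward <- function(lp, fwd, X, dH, g, prefix) {
  H <- ncol(lp$U); Tn <- ncol(X)
  ii <- 1:H; fi <- (H + 1L):(2L * H); oi <- (2L * H + 1L):(3L * H)
  gi <- (3L * H + 1L):(4L * H)
  DZ <- matrix(0, 4L * H, Tn)
  Hprev <- matrix(0, H, Tn)
  dh_next <- numeric(H); dc_next <- numeric(H)
  tU <- t(lp$U)
  for (t in rev(fwd$ord)) {
    cc <- fwd$cache[[t]]
    dh <- dH[, t] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- numeric(4L * H)
    dz[ii] <- di * cc$i * (1 - cc$i)
    dz[fi] <- df * cc$f * (1 - cc$f)
    dz[oi] <- do_ * cc$o * (1 - cc$o)
    dz[gi] <- dg * (1 - cc$g^2)
    DZ[, t] <- dz
    Hprev[, t] <- cc$h_prev
    dh_next <- as.vector(tU %*% dz)
    dc_next <- dc * cc$f
  }
  wn <- paste0(prefix, "W"); un <- paste0(prefix, "U"); bn <- paste0(prefix, "b")
  g[[wn]] <- g[[wn]] + DZ %*% t(X)
  g[[un]] <- g[[un]] + DZ %*% t(Hprev)
  g[[bn]] <- g[[bn]] + rowSums(DZ)
  crossprod(lp$W, DZ)                              # dX
}

lstm_params <- function(p, prefix) {
  list(W = p[[paste0(prefix, "W")]], U = p[[paste0(prefix, "U")]],
       b = p[[paste0(prefix, "b")]])
}

## Sample variational dropout masks (one mask per layer input, shared
## across time steps), already scaled for inverted dropout.
sample_dropout_masks <- function(config, input_dim, h1_dim) {
  p <- config$variational_dropout
  if (p <= 0) return(NULL)
  mk <- function(d) (stats::runif(d) >= p) / (1 - p)
  list(l1f = mk(input_dim), l1b = mk(input_dim),
       l2f = mk(2L * h1_dim), l2b = mk(2L * h1_dim))
}

## Full forward pass for one sentence.  Returns emissions (T x K) and the
## caches needed for the backward pass.  masks = NULL disables dropout.
sentence_forward <- function(model, tokens, masks = NULL) {
  p <- model$params
  cfg <- model$config
  Tn <- nrow(tokens)
  d_char <- cfg$char_filters
  d_word <- cfg$word_emb_dim
  lookup <- list(index = model$word_index)
  X <- matrix(0, d_char + d_word + 8L, Tn)
  char_caches <- vector("list", Tn)
  word_rows <- integer(Tn)
  for (t in seq_len(Tn)) {
    idx <- char_indices(tokens$text[t], model$char_index, model$pad_len)
    cc <- char_cnn_forward(p, idx, cfg$char_filter_width)
    char_caches[[t]] <- cc
    wr <- word_row(tokens$text[t], lookup)
    word_rows[t] <- wr
    case_idx <- case_feature(tokens$text[t]) + 1L
    X[1:d_char, t] <- cc$out
    X[(d_char + 1L):(d_char + d_word), t] <- p$word_emb[wr, ]
    X[d_char + d_word + case_idx, t] <- 1
  }
  m1f <- if (is.null(masks)) 1 else masks$l1f
  m1b <- if (is.null(masks)) 1 else masks$l1b
  m2f <- if (is.null(masks)) 1 else masks$l2f
  m2b <- if (is.null(masks)) 1 else masks$l2b
  X1f <- X * m1f; X1b <- X * m1b
  f1f <- lstm_forward(lstm_params(p, "l1f_"), X1f)
  f1b <- lstm_forward(lstm_params(p, "l1b_"), X1b, reverse = TRUE)
  H1 <- rbind(f1f$H, f1b$H)
  X2f <- H1 * m2f; X2b <- H1 * m2b
  f2f <- lstm_forward(lstm_params(p, "l2f_"), X2f)
  f2b <- lstm_forward(lstm_params(p, "l2b_"), X2b, reverse = TRUE)
  H2 <- rbind(f2f$H, f2b$H)
  E <- t(p$emit_W %*% H2 + p$emit_b)               # T x K
  list(emissions = E, X = X, X1f = X1f, X1b = X1b, X2f = X2f, X2b = X2b,
       f1f = f1f, f1b = f1b, f2f = f2f, f2b = f2b, H1 = H1, H2 = H2,
       char_caches = char_caches, word_rows = word_rows, masks = masks)
}

## Backward pass: dE is the gradient w.r.t. emissions (T x K); gradients
## accumulate into environment g (same names/shapes as model$params plus
## word_emb for the embedding table).
sentence_backward <- function(model, fwd, dE, g) {
  p <- model$params
  cfg <- model$config
  d_char <- cfg$char_filters
  d_word <- cfg$word_emb_dim
  Tn <- nrow(fwd$emissions)
  h1 <- cfg$lstm_units[1L]; h2 <- cfg$lstm_units[2L]
  dEm <- t(dE)                                     # K x T
  g$emit_W <- g$emit_W + dEm %*% t(fwd$H2)
  g$emit_b <- g$emit_b + rowSums(dEm)
  dH2 <- crossprod(p$emit_W, dEm)                  # 150 x T
  dX2f <- lstm_backward(lstm_params(p, "l2f_"), fwd$f2f, fwd$X2f,
                        dH2[seq_len(h2), , drop = FALSE], g, "l2f_")
  dX2b <- lstm_backward(lstm_params(p, "l2b_"), fwd$f2b, fwd$X2b,
                        dH2[(h2 + 1L):(2L * h2), , drop = FALSE], g, "l2b_")
  m <- fwd$masks
  m2f <- if (is.null(m)) 1 else m$l2f
  m2b <- if (is.null(m)) 1 else m$l2b
  dH1 <- dX2f * m2f + dX2b * m2b
  dX1f <- lstm_backward(lstm_params(p, "l1f_"), fwd$f1f, fwd$X1f,
                        dH1[seq_len(h1), , drop = FALSE], g, "l1f_")
  dX1b <- lstm_backward(lstm_params(p, "l1b_"), fwd$f1b, fwd$X1b,
                        dH1[(h1 + 1L):(2L * h1), , drop = FALSE], g, "l1b_")
  m1f <- if (is.null(m)) 1 else m$l1f
  m1b <- if (is.null(m)) 1 else m$l1b
  dX <- dX1f * m1f + dX1b * m1b                    # 238 x T
  for (t in seq_len(Tn)) {
    char_cnn_backward(p, fwd$char_caches[[t]], dX[seq_len(d_char), t], g,
                      cfg$char_filter_width)
    wr <- fwd$word_rows[t]
    if (wr != 1L)                                  # <PAD> row frozen
      g$word_emb[wr, ] <- g$word_emb[wr, ] +
        dX[(d_char + 1L):(d_char + d_word), t]
  }
  invisible(NULL)
}
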