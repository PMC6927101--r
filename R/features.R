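## Token-level input features for the neural tagger: orthographic case
## classes, word-embedding lookup with normalization fallbacks, and the
## character-level CNN representation.

## The eight orthographic case classes (0-based indices).  Exactly one
## class applies to any token; "padding" is reserved for padding tokens.
CASE_CLASSES <- c("numeric", "mainly_numeric", "all_lower", "all_upper",
                  "initial_upper", "contains_digit", "other", "padding")

#' Orthographic case class of a token
#'
#' Classifies a token into exactly one of eight classes: `numeric` (all
#' digits), `mainly_numeric` (more than half digits), `all_lower`,
#' `all_upper`, `initial_upper`, `contains_digit`, `other`, or `padding`.
#'
#' @param token_text Non-empty token string, or `NA` for the padding class.
#' @return 0-based class index in `[0, 8)`; see `CASE_CLASSES` for order.
#' @export
case_feature <- function(token_text) {
  if (length(token_text) != 1L) stop("one token at a time")
  if (is.na(token_text)) return(7L)                 # padding
  if (!nzchar(token_text)) stop("empty token has no case class")
  chars <- strsplit(token_text, "")[[1L]]
  n_digit <- sum(grepl("[0-9]", chars))
  n <- length(chars)
  if (n_digit == n) return(0L)                      # numeric
  if (n_digit / n > 0.5) return(1L)                 # mainly numeric
  has_alpha <- grepl("[[:alpha:]]", token_text)
  if (n_digit == 0L && has_alpha && token_text == tolower(token_text))
    return(2L)                                      # all lower
  if (n_digit == 0L && has_alpha && token_text == toupper(token_text))
    return(3L)                                      # all upper
  first <- substr(token_text, 1L, 1L)
  if (n_digit == 0L && grepl("[[:upper:]]", first) &&
      substring(token_text, 2L) == tolower(substring(token_text, 2L)))
    return(4L)                                      # initial upper
  if (n_digit > 0L) return(5L)                      # contains digit
  6L                                                # other
}

#' Normalize a word for embedding lookup
#'
#' Lowercases and replaces every maximal digit run with `"0"`.
#'
#' @param word Character vector.
#' @return Normalized character vector.
#' @export
normalize_word <- function(word) {
  gsub("[0-9]+", "0", tolower(word))
}

OOV_TOKEN <- "<OOV>"
PAD_TOKEN <- "<PAD>"

#' Build a word-embedding table
#'
#' Creates a table mapping words to dense vectors.  The special `<OOV>`
#' and `<PAD>` entries are always present; `<PAD>` is the zero vector and
#' all other vectors are seeded uniform(-0.25, 0.25) draws unless supplied.
#'
#' @param words Character vector of vocabulary words.
#' @param dim Embedding dimension.
#' @param vectors Optional numeric matrix (`length(words) x dim`) of
#'   pre-trained vectors, rows aligned with `words`.
#' @param seed Seed for random initialization.
#' @return An object of class `embedding_table` with elements `vectors`
#'   (matrix, rows = words) and `index` (named integer row lookup).
#' @export
embedding_table <- function(words, dim = 200L, vectors = NULL, seed = 1L) {
  words <- setdiff(unique(words), c(OOV_TOKEN, PAD_TOKEN))
  all_words <- c(PAD_TOKEN, OOV_TOKEN, words)
  V <- length(all_words)
  if (is.null(vectors)) {
    set.seed(seed)
    mat <- matrix(stats::runif(V * dim, -0.25, 0.25), V, dim)
  } else {
    stopifnot(nrow(vectors) == length(words), ncol(vectors) == dim)
    set.seed(seed)
    mat <- rbind(matrix(stats::runif(2L * dim, -0.25, 0.25), 2L, dim), vectors)
  }
  mat[1L, ] <- 0                                   # <PAD> is zero
  structure(list(vectors = mat,
                 index = stats::setNames(seq_len(V), all_words),
                 dim = dim),
            class = "embedding_table")
}

#' Row index of a token in an embedding table
#'
#' Fallback chain: exact form, lowercase, lowercase with digit runs
#' replaced by `"0"`, then the `<OOV>` entry.
#'
#' @param token_text Token string.
#' @param table An [embedding_table].
#' @return Integer row index into `table$vectors`.
#' @export
word_row <- function(token_text, table) {
  idx <- table$index
  r <- idx[token_text]
  if (!is.na(r)) return(unname(r))
  r <- idx[tolower(token_text)]
  if (!is.na(r)) return(unname(r))
  r <- idx[normalize_word(token_text)]
  if (!is.na(r)) return(unname(r))
  unname(idx[[OOV_TOKEN]])
}

#' Look up a token's word vector
#'
#' @inheritParams word_row
#' @return Numeric vector of length `table$dim`.
#' @export
word_lookup <- function(token_text, table) {
  table$vectors[word_row(token_text, table), ]
}

#' Read word vectors in the standard text format
#'
#' One token plus space-separated floats per line, with an optional
#' `"<count> <dim>"` header line.
#'
#' @param path Path to the vector file.
#' @return An [embedding_table] (plus `<OOV>`/`<PAD>` entries).
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty word-vector file: ", path)
  first <- strsplit(lines[1L], "[ \t]+")[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))))
    lines <- lines[-1L]                            # count/dim header
  parts <- strsplit(lines, "[ \t]+")
  words <- vapply(parts, `[[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(parts[[1L]]) - 1L)))
  embedding_table(words, dim = ncol(vecs), vectors = vecs)
}

#' Write an embedding table in the standard text format
#'
#' @param table An [embedding_table].
#' @param path Output path.
#' @param header Write the `"<count> <dim>"` header line?
#' @return Invisibly `path`.
#' @export
write_word_vectors <- function(table, path, header = TRUE) {
  words <- names(table$index)
  keep <- !words %in% c(OOV_TOKEN, PAD_TOKEN)
  mat <- table$vectors[keep, , drop = FALSE]
  lines <- paste(words[keep],
                 apply(mat, 1L, function(v) paste(format(v, scientific = FALSE),
                                                  collapse = " ")))
  if (header) lines <- c(paste(sum(keep), table$dim), lines)
  writeLines(lines, path)
  invisible(path)
}

## ---- character CNN -------------------------------------------------------

PAD_CHAR_IDX <- 1L   # row 1 of the character-embedding matrix; frozen at 0
OOV_CHAR_IDX <- 2L

#' Build a character index from a corpus vocabulary
#' @param words Character vector of token texts.
#' @return Named integer vector mapping characters to embedding rows
#'   (rows 1 and 2 are reserved for padding and unknown characters).
#' @keywords internal
build_char_index <- function(words) {
  chars <- sort(unique(unlist(strsplit(words, ""))))
  stats::setNames(seq_along(chars) + 2L, chars)
}

char_indices <- function(token_text, char_index, pad_len) {
  ch <- strsplit(token_text, "")[[1L]]
  idx <- unname(char_index[ch])
  idx[is.na(idx)] <- OOV_CHAR_IDX
  if (length(idx) > pad_len) idx <- idx[seq_len(pad_len)]
  c(idx, rep(PAD_CHAR_IDX, pad_len - length(idx)))
}

## forward pass of the character CNN for one (padded) token.
## p needs char_emb (rows x d), conv_W (nf x width*d), conv_b (nf).
char_cnn_forward <- function(p, idx, width = 3L) {
  d <- ncol(p$char_emb)
  L <- length(idx)
  nw <- L - width + 1L
  if (nw < 1L) stop("padded length shorter than filter width")
  Cm <- p$char_emb[idx, , drop = FALSE]            # L x d
  X <- matrix(0, width * d, nw)
  for (w in seq_len(width))
    X[((w - 1L) * d + 1L):(w * d), ] <- t(Cm[w:(w + nw - 1L), , drop = FALSE])
  Z <- p$conv_W %*% X + p$conv_b                   # nf x nw
  amax <- max.col(Z, ties.method = "first")
  out <- Z[cbind(seq_len(nrow(Z)), amax)]
  list(out = out, X = X, amax = amax, idx = idx, nw = nw)
}

## backward: route gradients through the max-pooled windows.  Accumulates
## into the gradient environment g (conv_W, conv_b, char_emb).
char_cnn_backward <- function(p, cache, dout, g, width = 3L) {
  d <- ncol(p$char_emb)
  nf <- length(dout)
  dX <- matrix(0, nrow(cache$X), cache$nw)
  for (f in seq_len(nf)) {
    w <- cache$amax[f]
    g$conv_W[f, ] <- g$conv_W[f, ] + dout[f] * cache$X[, w]
    dX[, w] <- dX[, w] + dout[f] * p$conv_W[f, ]
  }
  g$conv_b <- g$conv_b + dout
  ## scatter window-input gradients back to character embedding rows
  for (w in seq_len(cache$nw)) {
    col <- dX[, w]
    if (!any(col != 0)) next
    for (k in seq_len(width)) {
      row <- cache$idx[w + k - 1L]
      if (row == PAD_CHAR_IDX) next                # padding embedding frozen
      g$char_emb[row, ] <- g$char_emb[row, ] +
        col[((k - 1L) * d + 1L):(k * d)]
    }
  }
  invisible(NULL)
}

#' Character-CNN representation of a token
#'
#' Convolves learned character embeddings with `char_filters` filters of
#' width `char_filter_width` (stride 1) and max-pools over the windows,
#' yielding one feature per filter.
#'
#' @param token_text Token string.
#' @param model A trained or freshly initialized `tagger_model`.
#' @return Numeric vector of length `char_filters` (default 30).
#' @export
char_representation <- function(token_text, model) {
  idx <- char_indices(token_text, model$char_index, model$pad_len)
  char_cnn_forward(model$params, idx, model$config$char_filter_width)$out
}
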