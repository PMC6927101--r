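## Offset-preserving preprocessing: sentence splitting with table-row
## detection, tokenization, and BIO2 encoding/decoding.  Offsets are
## 0-based character counts from the start of the section's raw text.

## Punctuation peeled off token edges by the tokenizer.  Internal hyphens
## and slashes are kept so "Zydelig-treated" remains one token.
DEFAULT_EDGE_PUNCT <- c(".", ",", ";", ":", "!", "?", "(", ")", "[", "]",
                        "{", "}", "\"", "'", "%")

#' Detect whether a line looks like a table row
#'
#' A line is treated as a table row when it contains at least two runs of
#' two or more consecutive whitespace characters, or at least two `|` cell
#' delimiters.  Table rows are emitted one "sentence" per line instead of
#' being merged into prose sentences.
#'
#' @param line A character scalar (one line, no newline).
#' @param min_gap_runs,min_pipes Heuristic thresholds.
#' @return Logical scalar.
#' @export
is_table_row <- function(line, min_gap_runs = 2L, min_pipes = 2L) {
  gaps <- gregexpr("[ \t]{2,}", line)[[1L]]
  n_gaps <- if (gaps[1L] == -1L) 0L else length(gaps)
  n_pipes <- lengths(regmatches(line, gregexpr("|", line, fixed = TRUE)))
  n_gaps >= min_gap_runs || n_pipes >= min_pipes
}

#' Split section text into sentences with exact offsets
#'
#' Lines classified as table rows become one sentence each; runs of prose
#' lines are merged and split at sentence-final punctuation followed by
#' whitespace.  Every returned sentence is an exact substring of the
#' section at its reported offset, so the sentence spans tile the section
#' up to whitespace-only gaps.
#'
#' @param section_text Raw section text.
#' @return A data frame with columns `text` and `start` (0-based offset of
#'   the sentence's first character in the section).
#' @export
split_sentences <- function(section_text) {
  empty <- data.frame(text = character(0), start = integer(0))
  if (!nzchar(section_text)) return(empty)

  ## carve the section into lines, keeping each line's absolute offset
  nl <- c(0L, gregexpr("\n", section_text, fixed = TRUE)[[1L]])
  if (length(nl) > 1L && nl[2L] == -1L) nl <- nl[1L]
  line_starts <- nl + 1L                       # 1-based substring positions
  line_ends <- c(line_starts[-1L] - 2L, nchar(section_text))
  out_text <- character(0); out_start <- integer(0)
  emit <- function(txt, start0) {
    ## trim edges, adjusting the offset; drop whitespace-only pieces
    lead <- regmatches(txt, regexpr("^\\s*", txt))
    core <- trimws(txt)
    if (nzchar(core)) {
      out_text <<- c(out_text, core)
      out_start <<- c(out_start, start0 + nchar(lead))
    }
  }
  split_prose <- function(txt, start0) {
    ## sentence boundary: [.!?]+ followed by whitespace (or end of block)
    m <- gregexpr("[.!?]+(?=\\s|$)", txt, perl = TRUE)[[1L]]
    if (m[1L] == -1L) { emit(txt, start0); return(invisible()) }
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    prev <- 1L
    for (e in ends) {
      emit(substr(txt, prev, e), start0 + prev - 1L)
      prev <- e + 1L
    }
    if (prev <= nchar(txt)) emit(substr(txt, prev, nchar(txt)), start0 + prev - 1L)
    invisible()
  }

  i <- 1L
  n_lines <- length(line_starts)
  while (i <= n_lines) {
    ln <- substr(section_text, line_starts[i], line_ends[i])
    if (!nzchar(trimws(ln))) { i <- i + 1L; next }
    if (is_table_row(ln)) {
      emit(ln, line_starts[i] - 1L)
      i <- i + 1L
    } else {
      ## accumulate a run of prose lines into one block
      j <- i
      while (j + 1L <= n_lines) {
        nxt <- substr(section_text, line_starts[j + 1L], line_ends[j + 1L])
        if (!nzchar(trimws(nxt)) || is_table_row(nxt)) break
        j <- j + 1L
      }
      block <- substr(section_text, line_starts[i], line_ends[j])
      split_prose(block, line_starts[i] - 1L)
      i <- j + 1L
    }
  }
  data.frame(text = out_text, start = out_start)
}

#' Tokenize a sentence, preserving section offsets
#'
#' Whitespace split, then leading/trailing punctuation is peeled into
#' separate tokens.  Internal hyphens and slashes are preserved, so
#' hyphenated compounds stay intact; trailing sentence punctuation becomes
#' its own token.
#'
#' @param sentence_text Sentence string.
#' @param sentence_start 0-based section offset of `sentence_text`'s first
#'   character.
#' @param edge_punct Characters peeled off token edges.
#' @return Data frame of tokens with columns `text`, `start`, `length`.
#' @export
tokenize_with_offsets <- function(sentence_text, sentence_start = 0L,
                                  edge_punct = DEFAULT_EDGE_PUNCT) {
  empty <- data.frame(text = character(0), start = integer(0), length = integer(0))
  if (!nzchar(sentence_text)) return(empty)
  m <- gregexpr("\\S+", sentence_text)[[1L]]
  if (m[1L] == -1L) return(empty)
  words <- regmatches(sentence_text, list(m))[[1L]]
  starts0 <- sentence_start + as.integer(m) - 1L

  texts <- character(0); starts <- integer(0)
  push <- function(txt, st) {
    texts <<- c(texts, txt); starts <<- c(starts, st)
  }
  for (k in seq_along(words)) {
    w <- words[k]; st <- starts0[k]
    ## peel leading punctuation
    lead <- character(0)
    while (nchar(w) > 1L && substr(w, 1L, 1L) %in% edge_punct) {
      lead <- c(lead, substr(w, 1L, 1L))
      w <- substring(w, 2L)
    }
    ## peel trailing punctuation (collected in reverse)
    trail <- character(0)
    while (nchar(w) > 1L && substr(w, nchar(w), nchar(w)) %in% edge_punct) {
      trail <- c(substr(w, nchar(w), nchar(w)), trail)
      w <- substr(w, 1L, nchar(w) - 1L)
    }
    for (p in lead) { push(p, st); st <- st + 1L }
    push(w, st); st <- st + nchar(w)
    for (p in trail) { push(p, st); st <- st + 1L }
  }
  data.frame(text = texts, start = starts, length = nchar(texts))
}

mention_tag_code <- function(type) {
  if (type %in% names(MENTION_TYPES)) MENTION_TYPES[[type]] else toupper(type)
}

tag_code_type <- function(code) {
  hit <- names(MENTION_TYPES)[MENTION_TYPES == code]
  if (length(hit)) hit else code
}

#' Encode mentions as BIO2 tags over a token sequence
#'
#' The first token of each contiguous mention fragment is tagged
#' `B-<TYPE>`, subsequent tokens `I-<TYPE>`, everything else `O`.  Mention
#' spans not aligned to token boundaries are expanded outward to the full
#' covering tokens with a warning.  When overlaps force a choice, the
#' priority order AdverseReaction > Severity > Factor > DrugClass >
#' Negation > Animal decides.
#'
#' @param tokens Token data frame (`text`, `start`, `length`).
#' @param mentions List of single- or multi-span [adr_mention] objects
#'   restricted to this sentence's token span.
#' @return Character vector of BIO2 tags, one per token.
#' @export
encode_bio2 <- function(tokens, mentions) {
  n <- nrow(tokens)
  tags <- rep("O", n)
  if (!n || !length(mentions)) return(tags)
  prio <- match(vapply(mentions, `[[`, "", "type"), names(MENTION_TYPES))
  prio[is.na(prio)] <- length(MENTION_TYPES) + 1L
  ord <- order(prio, vapply(mentions, function(m) m$starts[1L], 0L))
  tok_start <- tokens$start
  tok_end <- tokens$start + tokens$length          # exclusive
  for (m in mentions[ord]) {
    code <- mention_tag_code(m$type)
    for (si in seq_along(m$starts)) {
      s <- m$starts[si]; e <- s + m$lengths[si]
      idx <- which(tok_end > s & tok_start < e)    # covering tokens
      if (!length(idx)) next
      if (tok_start[idx[1L]] < s || tok_end[idx[length(idx)]] > e)
        warning("mention '", m$id, "' span not aligned to token boundaries; ",
                "expanded to covering tokens")
      idx <- idx[tags[idx] == "O"]                 # higher priority wins
      if (!length(idx)) next
      ## tag each contiguous run of still-free tokens as its own fragment
      runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
      for (r in runs) {
        tags[r[1L]] <- paste0("B-", code)
        if (length(r) > 1L) tags[r[-1L]] <- paste0("I-", code)
      }
    }
  }
  check_bio2(tags)
  tags
}

#' Repair a tag sequence to BIO2 validity
#'
#' Lenient decoding repair: `I-X` after `O`, start of sentence, or a tag of
#' a different type becomes `B-X`.
#'
#' @param tags Character vector of tags.
#' @return Repaired tag vector.
#' @export
repair_bio2 <- function(tags) {
  prev <- "O"
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "I-")) {
      ty <- substring(t, 3L)
      if (!(prev %in% paste0(c("B-", "I-"), ty))) tags[i] <- paste0("B-", ty)
    }
    prev <- tags[i]
  }
  tags
}

#' Decode BIO2 tags into contiguous mentions
#'
#' One single-span mention per maximal `B-X (I-X)*` run; mention text is
#' reconstructed from the token offsets (via `section_text` when given,
#' else from the token texts joined by single spaces).
#'
#' @param tokens Token data frame.
#' @param tags BIO2 tags (invalid `I-X` is repaired to `B-X` first).
#' @param section_id Section id attached to the mentions.
#' @param section_text Optional raw section text for exact surface strings.
#' @param id_prefix Prefix for generated mention ids.
#' @return List of [adr_mention] objects.
#' @export
decode_bio2 <- function(tokens, tags, section_id = "S1", section_text = NULL,
                        id_prefix = "M") {
  tags <- repair_bio2(tags)
  mentions <- list()
  i <- 1L; n <- length(tags)
  while (i <= n) {
    if (startsWith(tags[i], "B-")) {
      ty <- substring(tags[i], 3L)
      j <- i
      while (j + 1L <= n && tags[j + 1L] == paste0("I-", ty)) j <- j + 1L
      s <- tokens$start[i]
      e <- tokens$start[j] + tokens$length[j]
      txt <- if (!is.null(section_text)) span_text(section_text, s, e - s) else
        paste(tokens$text[i:j], collapse = " ")
      mentions[[length(mentions) + 1L]] <- adr_mention(
        id = paste0(id_prefix, length(mentions) + 1L),
        section_id = section_id, type = tag_code_type(ty),
        starts = s, lengths = e - s, text = txt)
      i <- j + 1L
    } else i <- i + 1L
  }
  mentions
}

#' Flatten irregular (discontinuous/overlapping) mentions
#'
#' Produces a set of contiguous, non-overlapping single-span mentions
#' suitable for BIO2 encoding.  Every span of every mention contributes; a
#' fragment shared by several same-type mentions is emitted once, and span
#' boundaries cut longer spans into their constituent pieces (so a
#' contiguous "X of the a" overlapping a shared fragment "X of the" yields
#' the pieces "X of the" and "a").  Overlaps between types are resolved by
#' the priority order AdverseReaction > Severity > Factor > DrugClass >
#' Negation > Animal; lower-priority pieces are trimmed to the unclaimed
#' region.  Contiguous non-overlapping input is returned unchanged (up to
#' mention ids).
#'
#' @param mentions List of [adr_mention] objects (one section).
#' @param section_text Raw text of the section the mentions index into.
#' @param section_id Section id for the output mentions.
#' @return List of contiguous, non-overlapping [adr_mention] objects.
#' @export
flatten_irregular <- function(mentions, section_text, section_id = NULL) {
  if (!length(mentions)) return(list())
  if (is.null(section_id)) section_id <- mentions[[1L]]$section_id
  types <- unique(vapply(mentions, `[[`, "", "type"))
  prio <- match(types, names(MENTION_TYPES))
  prio[is.na(prio)] <- length(MENTION_TYPES) + 1L
  types <- types[order(prio)]

  claimed <- logical(nchar(section_text))   # per-character ownership mask
  out <- list()
  for (ty in types) {
    spans <- do.call(rbind, lapply(mentions, function(m) {
      if (m$type != ty) return(NULL)
      cbind(start = m$starts, end = m$starts + m$lengths)
    }))
    spans <- unique(spans)
    ## atomic segmentation: cut the union of spans at every span boundary
    cuts <- sort(unique(c(spans[, "start"], spans[, "end"])))
    pieces <- list()
    for (k in seq_len(length(cuts) - 1L)) {
      a <- cuts[k]; b <- cuts[k + 1L]
      if (any(spans[, "start"] <= a & spans[, "end"] >= b))
        pieces[[length(pieces) + 1L]] <- c(a, b)
    }
    for (p in pieces) {
      ## trim to unclaimed characters (may split into several sub-pieces)
      chars <- seq.int(p[1L] + 1L, p[2L])          # 1-based char indices
      free <- chars[!claimed[chars]]
      if (!length(free)) next
      runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
      for (r in runs) {
        s <- r[1L] - 1L; e <- r[length(r)]
        txt <- span_text(section_text, s, e - s)
        ## trim whitespace at the edges
        lead <- nchar(regmatches(txt, regexpr("^\\s*", txt)))
        core <- trimws(txt)
        if (!nzchar(core)) next
        s2 <- s + lead
        claimed[seq.int(s2 + 1L, s2 + nchar(core))] <- TRUE
        out[[length(out) + 1L]] <- adr_mention(
          id = paste0("F", length(out) + 1L), section_id = section_id,
          type = ty, starts = s2, lengths = nchar(core), text = core)
      }
    }
  }
  out[order(vapply(out, function(m) m$starts[1L], 0L))]
}
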