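## Seeded generators for a mini MedDRA-like dictionary and annotated
## synthetic drug labels.  The vocabulary is synthetic pseudo-medical word
## stock (no real terminology strings), built so that every other module
## is testable with no downloads: gold offsets are exact by construction,
## ADR surfaces come from the generating dictionary, and tags are a
## deterministic function of dictionary membership.

SYN_STEMS <- c("cardi", "derm", "neur", "hepat", "nephr", "gastr", "pulm",
               "oste", "myel", "angi", "arthr", "cephal", "vascul", "cutan",
               "ren", "thromb", "glyc", "lipid", "hemat", "pancre")
SYN_SUFFIXES <- c("opathy", "itis", "osis", "algia", "emia", "oma",
                  "edema", "orrhea", "oplegia", "ospasm")
SYN_ORGANS <- c("stomus", "cranex", "dermax", "renix", "hepatax", "cardox",
                "neurom", "gastrix")
SYN_MODIFIERS <- c("acute", "chronic", "severe", "transient", "focal",
                   "diffuse", "recurrent", "persistent")

SYN_FILLERS <- c("patients", "treatment", "study", "reported", "observed",
                 "during", "following", "cases", "therapy", "dose", "daily",
                 "clinical", "trials", "received", "events", "common",
                 "discontinued", "treated", "occurred", "with", "in", "of",
                 "the", "and", "was", "were", "a", "for")
SYN_DISTRACTORS <- c("zorvax", "quilent", "bramide", "texilol", "darvone",
                     "milbex", "corzide", "fexatin")
SYN_SEVERITY <- c("severe", "mild", "serious", "fatal", "moderate")
SYN_FACTOR <- c("risk", "possible", "potential", "likelihood")
SYN_DRUGCLASS <- c("statins", "diuretics", "antibiotics", "anticoagulants")
SYN_NEGATION <- c("no", "not", "without")
SYN_ANIMAL <- c("rats", "mice", "rabbits", "dogs")
SYN_DRUGS <- c("Zorvalin", "Quilentra", "Bramivex", "Texilor", "Darvonex",
               "Milbexa", "Corzidan", "Fexatinib", "Valproxen", "Nubratol")

#' Generate a mini MedDRA-like dictionary
#'
#' Builds `n_pt` Preferred Terms from pseudo-medical word stock, each with
#' `llt_per_pt` Lowest Level Terms: the PT name's regular plural, one
#' multi-word synonym of the form "<term> of the <organ>", and
#' modifier variants.  Deterministic under `seed`; when `dir` is given the
#' flat files `pt.tsv` and `llt.tsv` are written there (byte-identical
#' across runs with the same arguments).
#'
#' @param n_pt Number of Preferred Terms (>= 1).
#' @param llt_per_pt Number of LLTs per PT (>= 0).
#' @param seed RNG seed.
#' @param dir Optional output directory for `pt.tsv` / `llt.tsv`.
#' @return List with `pt` and `llt` data frames, the loaded
#'   `meddra_dictionary` object (`dictionary`), and the file paths when
#'   `dir` was given.
#' @export
generate_dictionary <- function(n_pt, llt_per_pt = 3L, seed = 1L, dir = NULL) {
  stopifnot(n_pt >= 1L, llt_per_pt >= 0L)
  combos <- as.vector(outer(SYN_STEMS, SYN_SUFFIXES, paste0))
  if (n_pt > length(combos))
    stop("at most ", length(combos), " synthetic PTs available")
  set.seed(seed)
  base <- sample(combos, n_pt)
  cap <- function(x) paste0(toupper(substr(x, 1L, 1L)), substring(x, 2L))
  pt <- data.frame(pt_id = sprintf("2%07d", seq_len(n_pt)),
                   pt_name = cap(base))
  llt_rows <- list()
  for (i in seq_len(n_pt)) {
    variants <- character(0)
    if (llt_per_pt >= 1L) variants <- pluralize_term(base[i])
    if (llt_per_pt >= 2L)
      variants <- c(variants, paste(base[i], "of the", sample(SYN_ORGANS, 1L)))
    if (llt_per_pt > 2L) {
      mods <- sample(SYN_MODIFIERS, llt_per_pt - 2L)
      variants <- c(variants, paste(mods, base[i]))
    }
    for (v in variants)
      llt_rows[[length(llt_rows) + 1L]] <-
        data.frame(llt_id = sprintf("3%07d", length(llt_rows) + 1L),
                   llt_name = v, pt_id = pt$pt_id[i])
  }
  llt <- if (length(llt_rows)) do.call(rbind, llt_rows) else
    data.frame(llt_id = character(0), llt_name = character(0),
               pt_id = character(0))
  out <- list(pt = pt, llt = llt)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$pt_file <- file.path(dir, "pt.tsv")
    out$llt_file <- file.path(dir, "llt.tsv")
    writeLines(c("pt_id\tpt_name", paste(pt$pt_id, pt$pt_name, sep = "\t")),
               out$pt_file)
    writeLines(c("llt_id\tllt_name\tpt_id",
                 if (nrow(llt)) paste(llt$llt_id, llt$llt_name, llt$pt_id,
                                      sep = "\t")),
               out$llt_file)
    out$dictionary <- load_dictionary(out$pt_file, out$llt_file)
  } else {
    tmp_pt <- tempfile(fileext = ".tsv"); tmp_llt <- tempfile(fileext = ".tsv")
    writeLines(c("pt_id\tpt_name", paste(pt$pt_id, pt$pt_name, sep = "\t")), tmp_pt)
    writeLines(c("llt_id\tllt_name\tpt_id",
                 if (nrow(llt)) paste(llt$llt_id, llt$llt_name, llt$pt_id,
                                      sep = "\t")), tmp_llt)
    out$dictionary <- load_dictionary(tmp_pt, tmp_llt)
    unlink(c(tmp_pt, tmp_llt))
  }
  out
}

## Surface forms of one PT entry (name + its LLT names) with their ids.
pt_surfaces <- function(dict, pt_id) {
  llt <- dict$llt[dict$llt$pt_id == pt_id, , drop = FALSE]
  rbind(data.frame(surface = unname(dict$pt[pt_id]), level = "PT",
                   id = pt_id),
        if (nrow(llt)) data.frame(surface = llt$llt_name, level = "LLT",
                                  id = llt$llt_id))
}

## A sentence under construction: text pieces plus mention bookkeeping.
new_sentence_builder <- function(offset) {
  env <- new.env(parent = emptyenv())
  env$text <- ""
  env$offset <- offset
  env$mentions <- list()     # list(type, start, length, text) fragments
  env
}

sb_add <- function(sb, piece, type = NULL) {
  if (nzchar(sb$text)) sb$text <- paste0(sb$text, " ")
  start <- sb$offset + nchar(sb$text)
  sb$text <- paste0(sb$text, piece)
  if (!is.null(type))
    sb$mentions[[length(sb$mentions) + 1L]] <-
      list(type = type, start = start, length = nchar(piece), text = piece)
  invisible(start)
}

#' Generate synthetic annotated drug labels
#'
#' Each label has 2-4 sections of template prose with planted mentions of
#' all six types at exact gold offsets.  ADR surfaces are drawn from the
#' generating dictionary (so a dictionary matcher recovers every
#' contiguous planted ADR), gold Reactions carry the true PT per planted
#' ADR, and `irregular_fraction` of ADR plantings use the overlapping/
#' discontinuous pattern "<term> of the <a>, <b>, and <c>" (one contiguous
#' mention plus discontinuous mentions sharing the head fragment).
#'
#' @param n_labels Number of labels.
#' @param dictionary Either the list returned by [generate_dictionary] or
#'   a `meddra_dictionary`.
#' @param mention_rate Probability that a sentence carries planted
#'   mentions, in `[0, 1]`.
#' @param irregular_fraction Fraction of ADR plantings made
#'   discontinuous/overlapping, in `[0, 1]`.
#' @param seed RNG seed.
#' @param distractor_rate Probability that a filler sentence contains an
#'   out-of-dictionary distractor term.
#' @return List of [drug_label] objects.
#' @export
generate_labels <- function(n_labels, dictionary, mention_rate = 0.3,
                            irregular_fraction = 0, seed = 1L,
                            distractor_rate = 0.1) {
  dict <- if (inherits(dictionary, "meddra_dictionary")) dictionary
  else dictionary$dictionary
  stopifnot(mention_rate >= 0, mention_rate <= 1,
            irregular_fraction >= 0, irregular_fraction <= 1,
            length(dict$pt) >= 1L)
  set.seed(seed)
  pt_ids <- names(dict$pt)

  make_sentence <- function(sb) {
    ## returns list of reactions (pt_id, pt_name, llt_id, llt_name) planted
    reactions <- list()
    if (stats::runif(1) < mention_rate) {
      pt_id <- sample(pt_ids, 1L)
      surf <- pt_surfaces(dict, pt_id)
      irregular <- stats::runif(1) < irregular_fraction
      if (irregular) {
        ## "<term> of the a , b , and c": contiguous mention on the first
        ## organ, discontinuous mentions (head fragment + organ) on the rest
        head_word <- tolower(unname(dict$pt[pt_id]))
        organs <- sample(SYN_ORGANS, 3L)
        h_start <- sb_add(sb, head_word)
        sb_add(sb, "of"); sb_add(sb, "the")
        the_end <- sb$offset + nchar(sb$text)
        o1 <- sb_add(sb, organs[1L]); o1e <- o1 + nchar(organs[1L])
        sb_add(sb, ",")
        o2 <- sb_add(sb, organs[2L]); o2e <- o2 + nchar(organs[2L])
        sb_add(sb, ",")
        sb_add(sb, "and")
        o3 <- sb_add(sb, organs[3L]); o3e <- o3 + nchar(organs[3L])
        sb_add(sb, "has been reported")
        head_len <- the_end - h_start
        sb$mentions[[length(sb$mentions) + 1L]] <-
          list(type = "AdverseReaction", start = h_start, length = o1e - h_start,
               text = NA)                           # contiguous, text filled later
        for (o in list(c(o2, o2e), c(o3, o3e)))
          sb$mentions[[length(sb$mentions) + 1L]] <-
            list(type = "AdverseReaction",
                 start = c(h_start, o[1L]), length = c(head_len, o[2L] - o[1L]),
                 text = NA)
        reactions[[1L]] <- list(pt_id = pt_id,
                                pt_name = unname(dict$pt[pt_id]))
      } else {
        row <- surf[sample(nrow(surf), 1L), ]
        surface <- tolower(row$surface)
        tmpl <- sample(4L, 1L)
        if (tmpl == 1L) {
          sb_add(sb, sample(SYN_SEVERITY, 1L), "Severity")
          sb_add(sb, surface, "AdverseReaction")
          sb_add(sb, "occurred in patients")
        } else if (tmpl == 2L) {
          sb_add(sb, sample(SYN_ANIMAL, 1L), "Animal")
          sb_add(sb, "treated showed")
          sb_add(sb, surface, "AdverseReaction")
        } else if (tmpl == 3L) {
          sb_add(sb, sample(SYN_NEGATION, 1L), "Negation")
          sb_add(sb, surface, "AdverseReaction")
          sb_add(sb, "was observed with")
          sb_add(sb, sample(SYN_DRUGCLASS, 1L), "DrugClass")
        } else {
          sb_add(sb, "there was a")
          sb_add(sb, sample(SYN_FACTOR, 1L), "Factor")
          sb_add(sb, "for")
          sb_add(sb, surface, "AdverseReaction")
          sb_add(sb, "in patients")
        }
        rx <- list(pt_id = if (row$level == "PT") row$id else
          dict$llt$pt_id[dict$llt$llt_id == row$id],
          pt_name = NA)
        rx$pt_name <- unname(dict$pt[rx$pt_id])
        if (row$level == "LLT") {
          rx$llt_id <- row$id; rx$llt_name <- row$surface
        }
        reactions[[1L]] <- rx
      }
    } else {
      n_w <- sample(4:8, 1L)
      words <- sample(SYN_FILLERS, n_w, replace = TRUE)
      if (stats::runif(1) < distractor_rate)
        words[sample(n_w, 1L)] <- sample(SYN_DISTRACTORS, 1L)
      for (w in words) sb_add(sb, w)
    }
    sb_add(sb, ".")
    reactions
  }

  labels <- vector("list", n_labels)
  for (li in seq_len(n_labels)) {
    drug <- sample(SYN_DRUGS, 1L)
    n_sec <- sample(2:4, 1L)
    sections <- list(); mentions <- list(); reactions <- list()
    seen_pt <- character(0)
    m_count <- 0L
    for (si in seq_len(n_sec)) {
      sec_id <- paste0("S", si)
      n_sent <- sample(3:8, 1L)
      sec_text <- ""
      for (k in seq_len(n_sent)) {
        if (nzchar(sec_text)) sec_text <- paste0(sec_text, " ")
        sb <- new_sentence_builder(nchar(sec_text))
        rx <- make_sentence(sb)
        sec_text <- paste0(sec_text, sb$text)
        for (m in sb$mentions) {
          m_count <- m_count + 1L
          frags <- mapply(span_text, start = m$start, length = m$length,
                          MoreArgs = list(text = sec_text))
          mentions[[length(mentions) + 1L]] <- adr_mention(
            id = paste0("M", m_count), section_id = sec_id,
            type = m$type, starts = m$start, lengths = m$length,
            text = paste(frags, collapse = " "))
        }
        for (r in rx) {
          if (r$pt_id %in% seen_pt) next
          seen_pt <- c(seen_pt, r$pt_id)
          reactions[[length(reactions) + 1L]] <- adr_reaction(
            text = tolower(r$pt_name), normalizations = list(r))
        }
      }
      sections[[si]] <- adr_section(sec_id, sec_text)
    }
    labels[[li]] <- drug_label(drug, sections, mentions, reactions)
  }
  labels
}

#' Convert a drug label to tagged sentences
#'
#' The standard preprocessing path: sentence splitting with table
#' detection, offset-preserving tokenization, irregular-mention
#' flattening, and BIO2 encoding of the label's gold mentions.
#'
#' @param label A [drug_label].
#' @return List of [tagged_sentence] objects.
#' @export
label_to_sentences <- function(label) {
  out <- list()
  for (sec in label$sections) {
    ms <- Filter(function(m) m$section_id == sec$id, label$mentions)
    flat <- flatten_irregular(ms, sec$text, sec$id)
    sents <- split_sentences(sec$text)
    for (si in seq_len(nrow(sents))) {
      tok <- tokenize_with_offsets(sents$text[si], sents$start[si])
      if (!nrow(tok)) next
      lo <- min(tok$start); hi <- max(tok$start + tok$length)
      in_sent <- Filter(function(m) m$starts[1L] >= lo &&
                          m$starts[1L] + m$lengths[1L] <= hi, flat)
      tags <- encode_bio2(tok, in_sent)
      out[[length(out) + 1L]] <- tagged_sentence(sec$id, tok, tags)
    }
  }
  out
}
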