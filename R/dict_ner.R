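## Dictionary- and rule-based recognition of ADR mentions: a two-level
## MedDRA-like dictionary (PT / LLT), plural/singular term expansion, and
## case-insensitive longest-match scanning at token boundaries.

#' Normalize a surface form for dictionary matching
#'
#' Case-folds, treats hyphens as spaces, and collapses internal
#' whitespace, so "Injection-Site  Reaction" matches "injection site
#' reaction".
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_surface <- function(x) {
  x <- tolower(x)
  x <- gsub("-", " ", x, fixed = TRUE)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Pluralize / singularize a term
#'
#' Regular English inflection applied to the last word of the form:
#' consonant-`y` becomes `-ies`; `-s/-x/-z/-ch/-sh` take `-es`; everything
#' else takes `-s`.  `singularize_term` applies the inverse rules and
#' returns the input unchanged when it is not a regular plural.
#'
#' @param x Character scalar (already surface-normalized or not).
#' @return The inflected form.
#' @export
pluralize_term <- function(x) {
  words <- strsplit(x, " ", fixed = TRUE)[[1L]]
  w <- words[length(words)]
  w <- if (grepl("[^aeiou]y$", w)) sub("y$", "ies", w)
  else if (grepl("(s|x|z|ch|sh)$", w)) paste0(w, "es")
  else paste0(w, "s")
  paste(c(words[-length(words)], w), collapse = " ")
}

#' @rdname pluralize_term
#' @export
singularize_term <- function(x) {
  words <- strsplit(x, " ", fixed = TRUE)[[1L]]
  w <- words[length(words)]
  w2 <- if (grepl("ies$", w)) sub("ies$", "y", w)
  else if (grepl("(s|x|z|ch|sh)es$", w)) sub("es$", "", w)
  else if (grepl("[^s]s$", w)) sub("s$", "", w)
  else w
  paste(c(words[-length(words)], w2), collapse = " ")
}

new_meddra_dictionary <- function(pt, llt, pt_surface, llt_surface,
                                  expanded = FALSE) {
  d <- structure(list(pt = pt, llt = llt, pt_surface = pt_surface,
                      llt_surface = llt_surface, expanded = expanded),
                 class = "meddra_dictionary")
  forms <- c(names(pt_surface), names(llt_surface))
  d$max_words <- if (length(forms))
    max(lengths(strsplit(forms, " ", fixed = TRUE))) else 0L
  d
}

#' Load a two-level MedDRA-like dictionary
#'
#' Reads tab-separated `pt` (pt_id, pt_name) and `llt` (llt_id, llt_name,
#' pt_id) flat files (a header line naming the columns is tolerated) and
#' builds the case-folded surface index.  Duplicate surface forms at the
#' same level keep the first mapping with a warning; an LLT referencing a
#' missing PT is an error.
#'
#' @param pt_file,llt_file Paths to the flat files.
#' @return An object of class `meddra_dictionary`.
#' @export
load_dictionary <- function(pt_file, llt_file) {
  read_tsv0 <- function(path, n_col) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) && grepl("^(pt_id|llt_id)\t", lines[1L]))
      lines <- lines[-1L]
    if (!length(lines))
      return(as.data.frame(matrix(character(0), 0L, n_col)))
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) != n_col)
    if (length(bad)) stop(path, " line ", bad[1L], ": expected ", n_col,
                          " tab-separated columns")
    as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  }
  ptd <- read_tsv0(pt_file, 2L); names(ptd) <- c("pt_id", "pt_name")
  lltd <- read_tsv0(llt_file, 3L); names(lltd) <- c("llt_id", "llt_name", "pt_id")
  if (anyDuplicated(ptd$pt_id)) stop("duplicate pt_id in ", pt_file)
  if (anyDuplicated(lltd$llt_id)) stop("duplicate llt_id in ", llt_file)
  missing_pt <- setdiff(lltd$pt_id, ptd$pt_id)
  if (length(missing_pt))
    stop("LLT(s) reference missing PT id(s): ", paste(missing_pt, collapse = ", "))
  pt <- stats::setNames(ptd$pt_name, ptd$pt_id)
  add_surfaces <- function(forms, ids, level) {
    idx <- character(0)
    for (k in seq_along(forms)) {
      f <- forms[k]
      if (f %in% names(idx)) {
        if (idx[[f]] != ids[k])
          warning("duplicate ", level, " surface form '", f,
                  "': keeping first mapping (", idx[[f]], ")")
        next
      }
      idx[f] <- ids[k]
    }
    idx
  }
  pt_surface <- add_surfaces(normalize_surface(ptd$pt_name), ptd$pt_id, "PT")
  llt_surface <- add_surfaces(normalize_surface(lltd$llt_name), lltd$llt_id, "LLT")
  new_meddra_dictionary(pt, lltd, pt_surface, llt_surface)
}

#' Expand dictionary surface forms with plural/singular variants
#'
#' For every indexed surface form, adds its regular plural — and, when the
#' form itself is a regular plural, its singular — pointing at the same
#' entry, unless that form is already present (idempotent; existing
#' mappings are never overwritten).
#'
#' Expanding an already-expanded dictionary is a no-op, so derived plural
#' forms never pick up a second inflection.
#'
#' @param dictionary A `meddra_dictionary`.
#' @return The expanded dictionary.
#' @export
expand_terms <- function(dictionary) {
  if (isTRUE(dictionary$expanded)) return(dictionary)
  expand_one <- function(idx) {
    base <- names(idx)
    for (f in base) {
      for (v in unique(c(pluralize_term(f), singularize_term(f)))) {
        if (!identical(v, f) && !v %in% names(idx)) idx[v] <- idx[[f]]
      }
    }
    idx
  }
  new_meddra_dictionary(dictionary$pt, dictionary$llt,
                        expand_one(dictionary$pt_surface),
                        expand_one(dictionary$llt_surface),
                        expanded = TRUE)
}

## look up a normalized surface form; PT level takes priority.
surface_hit <- function(form, dictionary) {
  id <- dictionary$pt_surface[form]
  if (!is.na(id)) return(list(level = "PT", id = unname(id)))
  id <- dictionary$llt_surface[form]
  if (!is.na(id)) return(list(level = "LLT", id = unname(id)))
  NULL
}

#' Dictionary match of ADR mentions in a section
#'
#' Tokenizes the section (same tokenizer as the neural pipeline) and scans
#' each sentence left to right with case-insensitive longest-match-first
#' lookup at token boundaries: at each position the widest token window
#' whose normalized surface is in the dictionary (and not excluded) is
#' reported and the scan resumes after it, so matches inside longer
#' matches are suppressed.
#'
#' @param section An [adr_section].
#' @param dictionary An expanded `meddra_dictionary`.
#' @param exclusions Character vector of surface forms never to report
#'   (normalized internally).
#' @return List of single-span AdverseReaction [adr_mention] objects with
#'   exact offsets.
#' @export
match_mentions <- function(section, dictionary, exclusions = character(0)) {
  if (!dictionary$max_words) return(list())
  excl <- normalize_surface(exclusions)
  sents <- split_sentences(section$text)
  out <- list()
  for (si in seq_len(nrow(sents))) {
    tok <- tokenize_with_offsets(sents$text[si], sents$start[si])
    n <- nrow(tok)
    i <- 1L
    while (i <= n) {
      hit_w <- 0L
      ## widest window first; a hyphenated token can cover two dictionary
      ## words, so the window cap in text tokens is the form word count
      for (w in seq(min(dictionary$max_words, n - i + 1L), 1L)) {
        j <- i + w - 1L
        s <- tok$start[i]
        e <- tok$start[j] + tok$length[j]
        form <- normalize_surface(span_text(section$text, s, e - s))
        if (form %in% excl) next
        if (!is.null(surface_hit(form, dictionary))) { hit_w <- w; break }
      }
      if (hit_w) {
        j <- i + hit_w - 1L
        s <- tok$start[i]
        e <- tok$start[j] + tok$length[j]
        out[[length(out) + 1L]] <- adr_mention(
          id = paste0("D", length(out) + 1L), section_id = section$id,
          type = "AdverseReaction", starts = s, lengths = e - s,
          text = span_text(section$text, s, e - s))
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  out
}
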