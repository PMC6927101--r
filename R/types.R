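#' @keywords internal
"_PACKAGE"

## Mention types recognised by the pipeline, and the short codes used in
## BIO2 tags (B-ADR, I-SEV, ...).  Order doubles as the conflict-priority
## order when overlapping mentions force a choice: the ADR class is the
## task's target and wins ties.
MENTION_TYPES <- c(
  AdverseReaction = "ADR",
  Severity        = "SEV",
  Factor          = "FAC",
  DrugClass       = "DRU",
  Negation        = "NEG",
  Animal          = "ANI"
)

#' Ordered BIO2 tag set
#'
#' The 13 BIO2 labels over the six mention types plus `O`.  `O` is first so
#' that score ties in CRF decoding resolve to the non-entity label.
#'
#' @return Character vector of 13 tags.
#' @export
tag_set <- function() {
  c("O", as.vector(rbind(paste0("B-", MENTION_TYPES), paste0("I-", MENTION_TYPES))))
}

#' Construct a drug-label section
#'
#' @param id Non-empty section identifier (e.g. `"S2"`).
#' @param text Raw section text (may be empty).
#' @return An object of class `adr_section`.
#' @export
adr_section <- function(id, text = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(text), length(text) == 1L)
  structure(list(id = id, text = text), class = "adr_section")
}

#' Construct an entity mention
#'
#' A mention covers one or more character spans of a section.  Offsets are
#' 0-based: `start` is the number of characters before the first character
#' of the span.  Discontinuous mentions carry multiple spans; their surface
#' `text` is the spans' substrings joined by a single space.
#'
#' @param id Mention identifier.
#' @param section_id Identifier of the section the spans index into.
#' @param type Mention type (`"AdverseReaction"`, `"Severity"`, ...).
#'   Unknown types are kept but trigger a warning.
#' @param starts Integer vector of 0-based span starts, sorted.
#' @param lengths Integer vector of span lengths (>= 1), same length.
#' @param text Surface string of the mention.
#' @return An object of class `adr_mention`.
#' @export
adr_mention <- function(id, section_id, type, starts, lengths, text) {
  starts <- as.integer(starts); lengths <- as.integer(lengths)
  if (length(starts) == 0L || length(starts) != length(lengths))
    stop("mention '", id, "': spans must be non-empty and starts/lengths equal length")
  if (any(lengths < 1L)) stop("mention '", id, "': span lengths must be >= 1")
  if (is.unsorted(starts, strictly = TRUE) && length(starts) > 1L)
    stop("mention '", id, "': spans must be sorted by start")
  ends <- starts + lengths
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))
    stop("mention '", id, "': spans must be non-overlapping")
  if (!type %in% names(MENTION_TYPES))
    warning("mention '", id, "': unknown mention type '", type, "' kept verbatim")
  structure(list(id = id, section_id = section_id, type = type,
                 starts = starts, lengths = lengths, text = text),
            class = "adr_mention")
}

#' Construct a normalized reaction
#'
#' @param text Reaction surface string.
#' @param normalizations List of normalizations, each a list with elements
#'   `pt_id`, `pt_name` and optionally `llt_id`, `llt_name`.  Each
#'   normalization must carry at least a `pt_id` or the `llt_id`/`llt_name`
#'   pair.
#' @return An object of class `adr_reaction`.
#' @export
adr_reaction <- function(text, normalizations = list()) {
  for (nm in normalizations) {
    has_pt <- !is.null(nm$pt_id) && nzchar(nm$pt_id)
    has_llt <- !is.null(nm$llt_id) && nzchar(nm$llt_id) &&
      !is.null(nm$llt_name) && nzchar(nm$llt_name)
    if (!has_pt && !has_llt)
      stop("reaction '", text, "': normalization needs pt_id or (llt_id, llt_name)")
  }
  structure(list(text = text, normalizations = normalizations),
            class = "adr_reaction")
}

#' Construct a drug label
#'
#' @param drug_name Free-text drug name.
#' @param sections List of [adr_section] objects (ordered).
#' @param mentions List of [adr_mention] objects.
#' @param reactions List of [adr_reaction] objects.
#' @param validate Check invariants (unique section ids, spans within
#'   bounds, surface text agreement)?  Default `TRUE`.
#' @return An object of class `drug_label`.
#' @export
drug_label <- function(drug_name, sections = list(), mentions = list(),
                       reactions = list(), validate = TRUE) {
  lbl <- structure(list(drug_name = drug_name, sections = sections,
                        mentions = mentions, reactions = reactions),
                   class = "drug_label")
  if (validate) validate_label(lbl)
  lbl
}

#' Extract a 0-based span from text
#'
#' @param text Character scalar.
#' @param start 0-based character offset.
#' @param length Number of characters.
#' @return The substring.
#' @keywords internal
span_text <- function(text, start, length) {
  substr(text, start + 1L, start + length)
}

#' Validate drug-label invariants
#'
#' Checks that section ids are unique, every mention points at an existing
#' section, spans lie within section bounds, and the mention surface text
#' matches the section substrings at its spans (either the space-joined
#' concatenation or fragment-wise).
#'
#' @param label A [drug_label].
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_label <- function(label) {
  sec_ids <- vapply(label$sections, `[[`, "", "id")
  if (anyDuplicated(sec_ids))
    stop("duplicate section ids: ", paste(sec_ids[duplicated(sec_ids)], collapse = ", "))
  sec_text <- stats::setNames(vapply(label$sections, `[[`, "", "text"), sec_ids)
  for (m in label$mentions) {
    if (!m$section_id %in% sec_ids)
      stop("mention '", m$id, "': unknown section '", m$section_id, "'")
    txt <- sec_text[[m$section_id]]
    if (any(m$starts + m$lengths > nchar(txt)))
      stop("mention '", m$id, "': span outside section bounds")
    frags <- mapply(span_text, start = m$starts, length = m$lengths,
                    MoreArgs = list(text = txt))
    joined <- paste(frags, collapse = " ")
    ## tolerate either the space-joined convention or a fragment-wise match
    ok <- identical(joined, m$text) ||
      (length(frags) > 1L && identical(paste(frags, collapse = ""), m$text))
    if (!ok)
      stop("mention '", m$id, "': surface text '", m$text,
           "' does not match section substring '", joined, "'")
  }
  invisible(TRUE)
}

#' @export
print.drug_label <- function(x, ...) {
  cat("<drug_label> ", x$drug_name, ": ", length(x$sections), " section(s), ",
      length(x$mentions), " mention(s), ", length(x$reactions), " reaction(s)\n",
      sep = "")
  invisible(x)
}

#' Construct a tagged sentence
#'
#' @param section_id Section the token offsets index into.
#' @param tokens Data frame with columns `text`, `start` (0-based section
#'   offset) and `length`.
#' @param tags Character vector of BIO2 tags, same length as `tokens` rows.
#' @return An object of class `tagged_sentence`.
#' @export
tagged_sentence <- function(section_id, tokens, tags = NULL) {
  tokens <- as.data.frame(tokens)
  if (is.null(tags)) tags <- rep("O", nrow(tokens))
  if (length(tags) != nrow(tokens))
    stop("tags length (", length(tags), ") != token count (", nrow(tokens), ")")
  check_bio2(tags)
  structure(list(section_id = section_id, tokens = tokens, tags = tags),
            class = "tagged_sentence")
}

#' Check BIO2 validity of a tag sequence
#'
#' Valid BIO2: every tag is `O` or `B-X`/`I-X`, and `I-X` only follows
#' `B-X` or `I-X`.
#'
#' @param tags Character vector of tags.
#' @param strict Stop on violation (default) or return `FALSE`.
#' @return `TRUE`/`FALSE` (invisibly when strict).
#' @export
check_bio2 <- function(tags, strict = TRUE) {
  ok_form <- grepl("^(O|[BI]-[A-Za-z]+)$", tags)
  bad <- NULL
  if (!all(ok_form)) bad <- paste0("malformed tag '", tags[!ok_form][1L], "'")
  if (is.null(bad) && length(tags)) {
    prev <- "O"
    for (i in seq_along(tags)) {
      t <- tags[i]
      if (startsWith(t, "I-")) {
        ty <- substring(t, 3L)
        if (!(prev %in% paste0(c("B-", "I-"), ty))) {
          bad <- paste0("I-", ty, " at position ", i, " follows '", prev, "'")
          break
        }
      }
      prev <- t
    }
  }
  if (!is.null(bad)) {
    if (strict) stop("invalid BIO2 sequence: ", bad)
    return(FALSE)
  }
  if (strict) invisible(TRUE) else TRUE
}
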