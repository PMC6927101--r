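## LLT-to-PT normalization of recognized ADR mention strings, and
## per-label aggregation into distinct PT sets.

#' Normalize an ADR mention string to a MedDRA Preferred Term
#'
#' Lookup order: exact PT surface, exact LLT surface, then the expanded
#' (plural/singular, hyphen-normalized) variants at each level.  An LLT
#' hit resolves to its parent PT.  A PT surface match takes priority over
#' an LLT match so provenance is deterministic.
#'
#' @param mention_text Mention surface string.
#' @param dictionary An expanded `meddra_dictionary`.
#' @return A list with `pt_id`, `pt_name`, `level` (`"PT"` or `"LLT"`) and,
#'   for LLT hits, `llt_id`/`llt_name`; or `NULL` when unmappable.
#' @export
normalize_mention <- function(mention_text, dictionary) {
  base <- normalize_surface(mention_text)
  forms <- unique(c(base, singularize_term(base), pluralize_term(base)))
  for (form in forms) {
    id <- dictionary$pt_surface[form]
    if (!is.na(id))
      return(list(pt_id = unname(id), pt_name = unname(dictionary$pt[id]),
                  level = "PT"))
  }
  for (form in forms) {
    id <- dictionary$llt_surface[form]
    if (!is.na(id)) {
      row <- dictionary$llt[dictionary$llt$llt_id == id, ][1L, ]
      return(list(pt_id = row$pt_id,
                  pt_name = unname(dictionary$pt[row$pt_id]),
                  level = "LLT", llt_id = row$llt_id, llt_name = row$llt_name))
    }
  }
  NULL
}

#' Normalize a label's ADR mentions to a distinct PT set
#'
#' Only AdverseReaction mentions are normalized; other types pass through
#' untouched.  Duplicate PTs collapse; unmappable mentions are counted and
#' reported, not silently dropped.
#'
#' @param mentions List of [adr_mention] objects.
#' @param dictionary An expanded `meddra_dictionary`.
#' @return A list with `pt` (data frame `pt_id`, `pt_name`, one row per
#'   distinct PT), `unmapped` (count) and `unmapped_texts`.
#' @export
normalize_label <- function(mentions, dictionary) {
  pt_id <- character(0); pt_name <- character(0)
  unmapped <- character(0)
  for (m in mentions) {
    if (!identical(m$type, "AdverseReaction")) next
    hit <- normalize_mention(m$text, dictionary)
    if (is.null(hit)) {
      unmapped <- c(unmapped, m$text)
    } else if (!hit$pt_id %in% pt_id) {
      pt_id <- c(pt_id, hit$pt_id)
      pt_name <- c(pt_name, hit$pt_name)
    }
  }
  list(pt = data.frame(pt_id = pt_id, pt_name = pt_name),
       unmapped = length(unmapped), unmapped_texts = unmapped)
}

#' Write per-label normalized PTs as TSV
#'
#' @param norms Named list (by drug/label id) of [normalize_label] results.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_normalizations_tsv <- function(norms, path) {
  rows <- c("drug_id\tpt_id\tpt_name")
  for (id in names(norms)) {
    pt <- norms[[id]]$pt
    if (nrow(pt))
      rows <- c(rows, paste(id, pt$pt_id, pt$pt_name, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
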