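## I/O for the TAC-style drug-label XML dialect and the 6-column CoNLL
## interchange format used between pipeline stages.

#' Read a drug label from TAC-style XML
#'
#' Parses the drug-label XML dialect: a `Label` root with `Text/Section`
#' elements carrying the raw text, `Mentions/Mention` elements with 0-based
#' `start`/`len` character offsets (comma-joined for discontinuous
#' mentions), and `Reactions/Reaction/Normalization` elements with MedDRA
#' PT/LLT ids.  All mention spans are validated against the section text.
#'
#' @param path_or_text Path to an XML file, or a character scalar holding
#'   the XML itself.
#' @return A [drug_label].
#' @export
read_label_xml <- function(path_or_text) {
  doc <- xml2::read_xml(path_or_text)
  root <- xml2::xml_find_first(doc, "/Label")
  if (inherits(root, "xml_missing")) stop("not a drug-label document: no <Label> root")
  drug <- xml2::xml_attr(root, "drug")
  if (is.na(drug)) drug <- ""

  sections <- lapply(xml2::xml_find_all(doc, "/Label/Text/Section"), function(s) {
    adr_section(id = xml2::xml_attr(s, "id"), text = xml2::xml_text(s))
  })

  mentions <- lapply(xml2::xml_find_all(doc, "/Label/Mentions/Mention"), function(m) {
    starts <- as.integer(strsplit(xml2::xml_attr(m, "start"), ",", fixed = TRUE)[[1L]])
    lens <- as.integer(strsplit(xml2::xml_attr(m, "len"), ",", fixed = TRUE)[[1L]])
    adr_mention(id = xml2::xml_attr(m, "id"),
                section_id = xml2::xml_attr(m, "section"),
                type = xml2::xml_attr(m, "type"),
                starts = starts, lengths = lens,
                text = xml2::xml_attr(m, "str"))
  })

  reactions <- lapply(xml2::xml_find_all(doc, "/Label/Reactions/Reaction"), function(r) {
    norms <- lapply(xml2::xml_find_all(r, "./Normalization"), function(n) {
      attr_or_null <- function(a) {
        v <- xml2::xml_attr(n, a)
        if (is.na(v)) NULL else v
      }
      list(pt_id = attr_or_null("meddra_pt_id"),
           pt_name = attr_or_null("meddra_pt"),
           llt_id = attr_or_null("meddra_llt_id"),
           llt_name = attr_or_null("meddra_llt"))
    })
    adr_reaction(text = xml2::xml_attr(r, "str"), normalizations = norms)
  })

  drug_label(drug_name = drug, sections = sections, mentions = mentions,
             reactions = reactions, validate = TRUE)
}

#' Write a drug label as TAC-style XML
#'
#' Inverse of [read_label_xml]: `read_label_xml(write_label_xml(x))` is
#' field-equal to `x`.  Multi-span mentions emit comma-joined `start`/`len`
#' attributes.
#'
#' @param label A [drug_label].
#' @param path Optional file path; when `NULL` the XML text is returned.
#' @return XML text (invisibly when `path` is given).
#' @export
write_label_xml <- function(label, path = NULL) {
  validate_label(label)
  doc <- xml2::xml_new_root("Label", drug = label$drug_name)
  text_node <- xml2::xml_add_child(doc, "Text")
  for (s in label$sections) {
    n <- xml2::xml_add_child(text_node, "Section", id = s$id)
    xml2::xml_text(n) <- s$text
  }
  mnode <- xml2::xml_add_child(doc, "Mentions")
  for (m in label$mentions) {
    xml2::xml_add_child(mnode, "Mention", id = m$id, section = m$section_id,
                        type = m$type,
                        start = paste(m$starts, collapse = ","),
                        len = paste(m$lengths, collapse = ","),
                        str = m$text)
  }
  rnode <- xml2::xml_add_child(doc, "Reactions")
  for (i in seq_along(label$reactions)) {
    r <- label$reactions[[i]]
    rn <- xml2::xml_add_child(rnode, "Reaction", id = paste0("R", i), str = r$text)
    for (j in seq_along(r$normalizations)) {
      nm <- r$normalizations[[j]]
      attrs <- c(id = paste0("R", i, ".N", j))
      if (!is.null(nm$pt_name)) attrs <- c(attrs, meddra_pt = nm$pt_name)
      if (!is.null(nm$pt_id)) attrs <- c(attrs, meddra_pt_id = nm$pt_id)
      if (!is.null(nm$llt_name)) attrs <- c(attrs, meddra_llt = nm$llt_name)
      if (!is.null(nm$llt_id)) attrs <- c(attrs, meddra_llt_id = nm$llt_id)
      do.call(xml2::xml_add_child, c(list(rn, "Normalization"), as.list(attrs)))
    }
  }
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

CONLL_RESERVED <- "-"

#' Write tagged sentences in 6-column CoNLL format
#'
#' One token per line with tab-separated columns: token text, BIO2 tag,
#' section id, 0-based start offset, length, and a reserved sixth column
#' (`"-"`).  Sentences are separated by a blank line.  Token offsets are
#' checked against the label's section text when `label` is supplied.
#'
#' @param label A [drug_label] used to verify offsets, or `NULL` to skip
#'   verification.
#' @param sentences List of [tagged_sentence] objects.
#' @param path Optional output file.
#' @return The CoNLL text (invisibly when `path` is given).
#' @export
write_conll <- function(label, sentences, path = NULL) {
  sec_text <- NULL
  if (!is.null(label)) {
    sec_text <- stats::setNames(vapply(label$sections, `[[`, "", "text"),
                                vapply(label$sections, `[[`, "", "id"))
  }
  blocks <- vapply(sentences, function(s) {
    tok <- s$tokens
    if (!is.null(sec_text) && s$section_id %in% names(sec_text)) {
      got <- mapply(span_text, start = tok$start, length = tok$length,
                    MoreArgs = list(text = sec_text[[s$section_id]]))
      if (nrow(tok) && !all(got == tok$text))
        stop("token offset inconsistent with section text in section ",
             s$section_id, ": '", tok$text[got != tok$text][1L], "'")
    }
    paste(tok$text, s$tags, s$section_id, tok$start, tok$length,
          CONLL_RESERVED, sep = "\t", collapse = "\n")
  }, "")
  txt <- if (length(blocks)) paste0(paste(blocks, collapse = "\n\n"), "\n") else ""
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Read 6-column CoNLL text into tagged sentences
#'
#' @param text CoNLL text, or a length-one path to a file when `is_path`.
#' @param is_path Treat `text` as a file path?
#' @return List of [tagged_sentence] objects (sentence boundaries restored
#'   at blank lines; BIO2 validity checked).
#' @export
read_conll <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text, warn = FALSE) else
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  ## trim trailing blank lines
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (!length(lines)) return(list())
  sentences <- list()
  buf <- list()
  flush <- function(buf) {
    if (!length(buf)) return(NULL)
    df <- do.call(rbind, buf)
    tags <- df$tag
    check_bio2(tags)
    sec <- unique(df$section)
    if (length(sec) != 1L) stop("sentence spans multiple sections: ",
                                paste(sec, collapse = ", "))
    tagged_sentence(sec, data.frame(text = df$text, start = df$start,
                                    length = df$length), tags)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) {
      s <- flush(buf)
      if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
      buf <- list()
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 6L)
      stop("line ", i, ": expected 6 tab-separated columns, got ", length(f))
    buf[[length(buf) + 1L]] <- data.frame(
      text = f[1L], tag = f[2L], section = f[3L],
      start = as.integer(f[4L]), length = as.integer(f[5L]))
  }
  s <- flush(buf)
  if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
  sentences
}
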