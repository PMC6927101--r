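## Pipeline wiring: the two recognition arms (neural "ml" and dictionary
## "dict"), shared normalization, scoring against gold labels, and the
## reproducibility manifest.

#' Predict mentions for a label with the dictionary arm
#'
#' @param label A [drug_label].
#' @param dictionary An expanded `meddra_dictionary`.
#' @param exclusions Character vector of excluded surface forms.
#' @return List of predicted [adr_mention] objects.
#' @export
dict_label_mentions <- function(label, dictionary, exclusions = character(0)) {
  out <- list()
  for (sec in label$sections)
    out <- c(out, match_mentions(sec, dictionary, exclusions))
  for (i in seq_along(out)) out[[i]]$id <- paste0("D", i)
  out
}

#' Predict mentions for a label with the neural arm
#'
#' Splits and tokenizes each section, tags with the trained model, and
#' decodes the BIO2 output into contiguous mentions.
#'
#' @param label A [drug_label].
#' @param model A trained `tagger_model`.
#' @return List of predicted [adr_mention] objects.
#' @export
ml_label_mentions <- function(label, model) {
  out <- list()
  for (sec in label$sections) {
    sents <- split_sentences(sec$text)
    if (!nrow(sents)) next
    sent_objs <- lapply(seq_len(nrow(sents)), function(si) {
      tagged_sentence(sec$id,
                      tokenize_with_offsets(sents$text[si], sents$start[si]))
    })
    sent_objs <- Filter(function(s) nrow(s$tokens) > 0, sent_objs)
    pred <- predict_tags(model, sent_objs)
    for (ps in pred)
      out <- c(out, decode_bio2(ps$tokens, ps$tags, section_id = sec$id,
                                section_text = sec$text))
  }
  for (i in seq_along(out)) out[[i]]$id <- paste0("P", i)
  out
}

#' Gold PT set of a label
#'
#' Collects the distinct PT ids carried by the label's Reaction
#' normalizations; normalizations carrying only an LLT are resolved
#' through the dictionary when supplied.
#'
#' @param label A [drug_label].
#' @param dictionary Optional `meddra_dictionary` for LLT resolution.
#' @return Character vector of PT ids.
#' @export
gold_pt_set <- function(label, dictionary = NULL) {
  ids <- character(0)
  for (r in label$reactions) for (nm in r$normalizations) {
    id <- nm$pt_id
    if (is.null(id) && !is.null(dictionary) && !is.null(nm$llt_id)) {
      hit <- dictionary$llt$pt_id[dictionary$llt$llt_id == nm$llt_id]
      if (length(hit)) id <- hit[1L]
    }
    if (!is.null(id)) ids <- c(ids, id)
  }
  unique(ids)
}

#' Run the extraction + normalization pipeline
#'
#' `config` selects the recognition arm: `"ml"` runs preprocessing, the
#' neural tagger and the normalizer; `"dict"` runs the dictionary
#' recognizer and the normalizer directly on the raw section text (no
#' CoNLL preprocessing).  Both arms share the normalizer, and both end in
#' evaluation when the input labels carry gold annotations.
#'
#' @param config A named list (or path to a YAML file) with at least:
#'   `arm` (`"ml"` or `"dict"`), `labels` (directory of label XML files or
#'   a list of [drug_label] objects), `dictionary` (list with `pt` and
#'   `llt` file paths, or a `meddra_dictionary`), and `output_dir`.
#'   Optional: `seed`, `exclusions` (path), `train_labels` (directory or
#'   label list for the ml arm), `model` (path to a saved tagger),
#'   `tagger` (list of [tagger_config] overrides), `evaluate` (default
#'   `TRUE` when gold annotations are present).
#' @return Invisibly, a list with `predictions` (per-label mentions),
#'   `normalizations`, `report` (an [eval_report] or `NULL`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$arm) || !config$arm %in% c("ml", "dict"))
    stop("config error: arm must be 'ml' or 'dict'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config error: output_dir missing")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  input_files <- character(0)
  labels <- config$labels
  if (is.character(labels)) {
    input_files <- sort(list.files(labels, pattern = "\\.xml$",
                                   full.names = TRUE))
    if (!length(input_files)) stop("no label XML files found in ", labels)
    labels <- lapply(input_files, read_label_xml)
  }
  if (!length(labels)) stop("config error: no input labels")
  label_ids <- vapply(seq_along(labels), function(i) {
    nm <- labels[[i]]$drug_name
    if (nzchar(nm)) paste0(nm, "_", i) else paste0("label_", i)
  }, "")

  dict <- config$dictionary
  if (!inherits(dict, "meddra_dictionary")) {
    if (is.null(dict$pt) || is.null(dict$llt))
      stop("config error: dictionary needs pt and llt file paths")
    input_files <- c(input_files, dict$pt, dict$llt)
    dict <- load_dictionary(dict$pt, dict$llt)
  }
  dict <- expand_terms(dict)
  exclusions <- character(0)
  if (!is.null(config$exclusions)) {
    exclusions <- readLines(config$exclusions, warn = FALSE)
    exclusions <- exclusions[nzchar(exclusions)]
  }

  model <- NULL
  if (config$arm == "ml") {
    if (!is.null(config$model)) {
      model <- load_tagger(config$model)
    } else {
      train_labels <- config$train_labels
      if (is.null(train_labels))
        stop("config error: ml arm needs 'model' or 'train_labels'")
      if (is.character(train_labels))
        train_labels <- lapply(sort(list.files(train_labels,
                                               pattern = "\\.xml$",
                                               full.names = TRUE)),
                               read_label_xml)
      corpus <- unlist(lapply(train_labels, label_to_sentences),
                       recursive = FALSE)
      tc_args <- config$tagger
      if (is.null(tc_args)) tc_args <- list()
      tc_args$seed <- seed
      tcfg <- do.call(tagger_config, tc_args)
      table <- if (!is.null(config$embeddings))
        read_word_vectors(config$embeddings) else NULL
      model <- train_tagger(corpus, table, tcfg)
      save_tagger(model, file.path(out_dir, "tagger.rds"))
    }
  }

  predictions <- vector("list", length(labels))
  normalizations <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    pred <- if (config$arm == "dict")
      dict_label_mentions(labels[[i]], dict, exclusions)
    else ml_label_mentions(labels[[i]], model)
    predictions[[i]] <- pred
    normalizations[[i]] <- normalize_label(pred, dict)
    ## emit predictions in the gold XML dialect
    pred_label <- drug_label(labels[[i]]$drug_name, labels[[i]]$sections,
                             pred, lapply(seq_len(nrow(normalizations[[i]]$pt)),
                                          function(k) {
                                            row <- normalizations[[i]]$pt[k, ]
                                            adr_reaction(tolower(row$pt_name),
                                                         list(list(pt_id = row$pt_id,
                                                                   pt_name = row$pt_name)))
                                          }),
                             validate = FALSE)
    write_label_xml(pred_label,
                    file.path(out_dir, paste0(label_ids[i], ".pred.xml")))
  }
  names(predictions) <- names(normalizations) <- label_ids
  write_normalizations_tsv(normalizations,
                           file.path(out_dir, "normalizations.tsv"))

  report <- NULL
  has_gold <- any(vapply(labels, function(l)
    length(l$mentions) + length(l$reactions) > 0, TRUE))
  do_eval <- if (is.null(config$evaluate)) has_gold else isTRUE(config$evaluate)
  if (do_eval) {
    gold_m <- list(); pred_m <- list()
    gold_pt <- list(); pred_pt <- list()
    for (i in seq_along(labels)) {
      ## scope mention matching to the label
      scope <- function(ms) lapply(ms, function(m) {
        m$section_id <- paste0(label_ids[i], "/", m$section_id); m
      })
      gold_m <- c(gold_m, scope(labels[[i]]$mentions))
      pred_m <- c(pred_m, scope(predictions[[i]]))
      gold_pt[[label_ids[i]]] <- gold_pt_set(labels[[i]], dict)
      pred_pt[[label_ids[i]]] <- normalizations[[i]]$pt$pt_id
    }
    report <- eval_report(gold_m, pred_m, gold_pt, pred_pt)
    jsonlite::write_json(report_as_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    arm = config$arm, seed = seed,
    config_hash = digest::digest(config[setdiff(names(config), "output_dir")]),
    n_labels = length(labels),
    n_predicted_mentions = sum(lengths(predictions)),
    input_checksums = if (length(input_files))
      stats::setNames(vapply(unique(input_files), digest::digest, "",
                             file = TRUE), basename(unique(input_files)))
    else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(predictions = predictions, normalizations = normalizations,
                 report = report, manifest = manifest))
}

report_as_list <- function(report) {
  list(identification = list(precision = report$mention_precision,
                             recall = report$mention_recall,
                             f1 = report$mention_f1),
       normalization = list(
         micro = list(precision = report$norm_micro_p,
                      recall = report$norm_micro_r, f1 = report$norm_micro_f1),
         macro = list(precision = report$norm_macro_p,
                      recall = report$norm_macro_r, f1 = report$norm_macro_f1)))
}
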