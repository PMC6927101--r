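## TAC-style scoring: mention-level precision/recall/F1 with exact-span
## one-to-one matching, and micro-/macro-averaged PT-level normalization
## scores per drug label.

f1_of <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

mention_key <- function(m) {
  paste(m$section_id, m$type,
        paste(m$starts, collapse = ","), paste(m$lengths, collapse = ","),
        sep = "|")
}

#' Mention-level precision, recall and F1
#'
#' A prediction is a true positive iff its section, exact span set and
#' type all match a distinct gold mention (one-to-one matching; no partial
#' credit).  Conventions: precision 0 when there are no predictions,
#' recall 0 when there is no gold, F1 0 when `p + r = 0`.
#'
#' @param gold,pred Lists of [adr_mention] objects.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
score_mentions <- function(gold, pred) {
  gk <- vapply(gold, mention_key, "")
  pk <- vapply(pred, mention_key, "")
  avail <- table(gk)
  tp <- 0L
  for (k in pk) {
    if (!is.na(avail[k]) && avail[k] > 0L) {
      tp <- tp + 1L
      avail[k] <- avail[k] - 1L
    }
  }
  p <- if (length(pk)) tp / length(pk) else 0
  r <- if (length(gk)) tp / length(gk) else 0
  c(precision = p, recall = r, f1 = f1_of(p, r))
}

#' Micro- and macro-averaged PT-level normalization scores
#'
#' Gold and predicted PT sets are compared per drug label.  Micro scores
#' pool true/false positives and false negatives over all (label, pt_id)
#' pairs; macro scores average the per-label precision, recall and F1
#' arithmetically over labels.  A label with empty gold and empty
#' prediction scores (1, 1, 1).
#'
#' @param gold_pt_sets,pred_pt_sets Named lists (same label keys) of
#'   character vectors of PT ids.
#' @return List with `micro`, `macro` (each `c(precision, recall, f1)`)
#'   and `per_label` (data frame).
#' @export
score_normalization <- function(gold_pt_sets, pred_pt_sets) {
  if (!setequal(names(gold_pt_sets), names(pred_pt_sets)))
    stop("gold and prediction label keys differ")
  keys <- names(gold_pt_sets)
  tp <- fp <- fn <- 0L
  per <- data.frame(label = keys, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_)
  for (i in seq_along(keys)) {
    g <- unique(gold_pt_sets[[keys[i]]])
    p <- unique(pred_pt_sets[[keys[i]]])
    tpi <- length(intersect(g, p))
    fpi <- length(setdiff(p, g))
    fni <- length(setdiff(g, p))
    tp <- tp + tpi; fp <- fp + fpi; fn <- fn + fni
    if (!length(g) && !length(p)) {
      per[i, 2:4] <- c(1, 1, 1)
    } else {
      pp <- if (length(p)) tpi / length(p) else 0
      rr <- if (length(g)) tpi / length(g) else 0
      per[i, 2:4] <- c(pp, rr, f1_of(pp, rr))
    }
  }
  if (tp + fp + fn == 0L) {
    micro <- c(precision = 1, recall = 1, f1 = 1)
  } else {
    mp <- if (tp + fp > 0L) tp / (tp + fp) else 0
    mr <- if (tp + fn > 0L) tp / (tp + fn) else 0
    micro <- c(precision = mp, recall = mr, f1 = f1_of(mp, mr))
  }
  macro <- c(precision = mean(per$precision), recall = mean(per$recall),
             f1 = mean(per$f1))
  list(micro = micro, macro = macro, per_label = per)
}

#' Full evaluation report
#'
#' Combines mention-level scores with micro/macro PT-level normalization
#' scores into the report layout used for the shared-task tables
#' (identification + normalization blocks, values as proportions).
#'
#' @param gold_mentions,pred_mentions Lists of [adr_mention] objects.
#' @param gold_pt_sets,pred_pt_sets Named lists of PT-id vectors per label.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(gold_mentions, pred_mentions, gold_pt_sets,
                        pred_pt_sets) {
  m <- score_mentions(gold_mentions, pred_mentions)
  n <- score_normalization(gold_pt_sets, pred_pt_sets)
  structure(list(mention_precision = m[["precision"]],
                 mention_recall = m[["recall"]],
                 mention_f1 = m[["f1"]],
                 norm_micro_p = n$micro[["precision"]],
                 norm_micro_r = n$micro[["recall"]],
                 norm_micro_f1 = n$micro[["f1"]],
                 norm_macro_p = n$macro[["precision"]],
                 norm_macro_r = n$macro[["recall"]],
                 norm_macro_f1 = n$macro[["f1"]],
                 per_label = n$per_label),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) sprintf("%.1f", 100 * v)
  cat("Identification  P ", pct(x$mention_precision),
      "  R ", pct(x$mention_recall), "  F1 ", pct(x$mention_f1), "\n",
      "Normalization (micro)  P ", pct(x$norm_micro_p),
      "  R ", pct(x$norm_micro_r), "  F1 ", pct(x$norm_micro_f1), "\n",
      "Normalization (macro)  P ", pct(x$norm_macro_p),
      "  R ", pct(x$norm_macro_r), "  F1 ", pct(x$norm_macro_f1), "\n",
      sep = "")
  invisible(x)
}
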