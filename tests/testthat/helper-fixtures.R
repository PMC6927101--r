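## Shared fixtures and independent oracles, all built in code.

## The printed worked-example sentence with "risk" at section offset 2309
## and "cancer" at 2318 (the three id/name pairs are in-paper data).
choline_sentence <- function() {
  "Long-term cumulative radiation exposure is associated with an increased risk for cancer."
}

choline_section_text <- function() {
  sent <- choline_sentence()
  pad <- 2309L - (regexpr("risk", sent, fixed = TRUE) - 1L)
  paste0(strrep(" ", pad), sent)
}

choline_label_xml <- function() {
  paste0(
    '<Label drug="choline"><Text><Section id="S2">',
    choline_section_text(),
    '</Section></Text><Mentions>',
    '<Mention id="M10" section="S2" type="Factor" start="2309" len="4" str="risk" />',
    '<Mention id="M11" section="S2" type="AdverseReaction" start="2318" len="6" str="cancer" />',
    '</Mentions><Reactions><Reaction id="R4" str="cancer">',
    '<Normalization id="R4.N1" meddra_pt="Neoplasm malignant" meddra_pt_id="10028997" ',
    'meddra_llt="Cancer" meddra_llt_id="10007050" /></Reaction></Reactions></Label>')
}

## mini PT/LLT dictionary files using the printed id/name pairs
mini_dict_files <- function(dir = tempfile("dict")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- file.path(dir, "pt.tsv")
  llt <- file.path(dir, "llt.tsv")
  writeLines(c("pt_id\tpt_name",
               "10028997\tNeoplasm malignant",
               "10022095\tInjection site reaction",
               "10019211\tHeadache"), pt)
  writeLines(c("llt_id\tllt_name\tpt_id",
               "10007050\tCancer\t10028997",
               "10022097\tInjection-site reaction\t10022095"), llt)
  list(pt = pt, llt = llt)
}

## Table 2 worked example: tokens, offsets, lengths and tags
zydelig_sentence <- function() {
  "Fatal and serious intestinal perforation occurred in Zydelig-treated patients."
}

zydelig_expected <- function() {
  data.frame(
    text = c("Fatal", "and", "serious", "intestinal", "perforation",
             "occurred", "in", "Zydelig-treated", "patients", "."),
    tag = c("B-ADR", "O", "B-SEV", "B-ADR", "I-ADR", "O", "O", "O", "O", "O"),
    start = c(2763L, 2769L, 2773L, 2781L, 2792L, 2804L, 2813L, 2816L, 2832L, 2840L),
    length = c(5L, 3L, 7L, 10L, 11L, 8L, 2L, 15L, 8L, 1L))
}

zydelig_mentions <- function() {
  list(adr_mention("Z1", "S3", "AdverseReaction", 2763L, 5L, "Fatal"),
       adr_mention("Z2", "S3", "Severity", 2773L, 7L, "serious"),
       adr_mention("Z3", "S3", "AdverseReaction", 2781L, 22L,
                   "intestinal perforation"))
}

## synthetic corpus shared across tests
make_synth_corpus <- function(n_labels = 12L, seed = 11L, mention_rate = 0.5,
                              irregular_fraction = 0) {
  gen <- generate_dictionary(8L, 3L, seed = seed)
  labels <- generate_labels(n_labels, gen, mention_rate = mention_rate,
                            irregular_fraction = irregular_fraction,
                            seed = seed)
  list(gen = gen, labels = labels,
       sentences = unlist(lapply(labels, label_to_sentences),
                          recursive = FALSE))
}

## ---- independent oracles -------------------------------------------------

## brute-force CRF: enumerate all K^T sequences
crf_brute <- function(emissions, transitions) {
  Tn <- nrow(emissions); K <- ncol(emissions)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  scores <- apply(seqs, 1L, function(y) crf_score(emissions, transitions, y))
  best <- which.max(scores)
  ## lexicographically-earliest argmax among ties
  ties <- which(abs(scores - scores[best]) < 1e-12)
  if (length(ties) > 1L) {
    ord <- do.call(order, as.data.frame(seqs[ties, , drop = FALSE]))
    best <- ties[ord[1L]]
  }
  m <- max(scores)
  list(best_seq = unname(seqs[best, ]), best_score = scores[best],
       logZ = m + log(sum(exp(scores - m))))
}

## brute-force mention scorer: naive one-to-one matching by field equality
score_mentions_brute <- function(gold, pred) {
  used <- logical(length(gold))
  tp <- 0L
  for (p in pred) {
    for (gi in seq_along(gold)) {
      g <- gold[[gi]]
      if (!used[gi] && identical(g$section_id, p$section_id) &&
          identical(g$type, p$type) &&
          identical(as.integer(g$starts), as.integer(p$starts)) &&
          identical(as.integer(g$lengths), as.integer(p$lengths))) {
        used[gi] <- TRUE; tp <- tp + 1L; break
      }
    }
  }
  p_ <- if (length(pred)) tp / length(pred) else 0
  r_ <- if (length(gold)) tp / length(gold) else 0
  c(precision = p_, recall = r_,
    f1 = if (p_ + r_ == 0) 0 else 2 * p_ * r_ / (p_ + r_))
}

## brute-force normalization scorer: count over explicit pair lists
score_normalization_brute <- function(gold_sets, pred_sets) {
  keys <- names(gold_sets)
  pairs <- function(sets) {
    out <- character(0)
    for (k in names(sets)) for (id in unique(sets[[k]]))
      out <- c(out, paste(k, id, sep = "\r"))
    out
  }
  gp <- pairs(gold_sets); pp <- pairs(pred_sets)
  tp <- sum(pp %in% gp)
  micro_p <- if (length(pp)) tp / length(pp) else NA
  micro_r <- if (length(gp)) tp / length(gp) else NA
  if (!length(pp) && !length(gp)) { micro_p <- 1; micro_r <- 1 }
  if (is.na(micro_p)) micro_p <- 0
  if (is.na(micro_r)) micro_r <- 0
  micro_f <- if (micro_p + micro_r == 0) 0 else
    2 * micro_p * micro_r / (micro_p + micro_r)
  per <- t(vapply(keys, function(k) {
    g <- unique(gold_sets[[k]]); p <- unique(pred_sets[[k]])
    if (!length(g) && !length(p)) return(c(1, 1, 1))
    tpi <- sum(p %in% g)
    pp_ <- if (length(p)) tpi / length(p) else 0
    rr_ <- if (length(g)) tpi / length(g) else 0
    c(pp_, rr_, if (pp_ + rr_ == 0) 0 else 2 * pp_ * rr_ / (pp_ + rr_))
  }, numeric(3)))
  list(micro = c(precision = micro_p, recall = micro_r, f1 = micro_f),
       macro = c(precision = mean(per[, 1]), recall = mean(per[, 2]),
                 f1 = mean(per[, 3])))
}

## random gold/pred PT-set pairs for the metric oracle
random_pt_sets <- function(n_labels, universe = sprintf("PT%02d", 1:8)) {
  g <- list(); p <- list()
  for (i in seq_len(n_labels)) {
    k <- paste0("L", i)
    g[[k]] <- sample(universe, sample(0:5, 1L))
    p[[k]] <- sample(universe, sample(0:5, 1L))
  }
  list(gold = g, pred = p)
}
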