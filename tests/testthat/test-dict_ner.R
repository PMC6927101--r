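test_that("load_dictionary builds the surface index from the mini dictionary", {
  f <- mini_dict_files()
  d <- load_dictionary(f$pt, f$llt)
  expect_identical(unname(d$llt_surface["cancer"]), "10007050")
  expect_identical(unname(d$pt_surface["neoplasm malignant"]), "10028997")
  ## hyphen normalization at load: "Injection-site reaction"
  expect_identical(unname(d$llt_surface["injection site reaction"]),
                   "10022097")
})

test_that("empty dictionary files load and match nothing", {
  dir <- tempfile(); dir.create(dir)
  writeLines("pt_id\tpt_name", file.path(dir, "pt.tsv"))
  writeLines("llt_id\tllt_name\tpt_id", file.path(dir, "llt.tsv"))
  d <- load_dictionary(file.path(dir, "pt.tsv"), file.path(dir, "llt.tsv"))
  expect_length(d$pt, 0L)
  expect_identical(match_mentions(adr_section("S1", "some headache text."),
                                  expand_terms(d)), list())
})

test_that("an LLT referencing a missing PT is a load error naming the id", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("pt_id\tpt_name", "100\tRash"), file.path(dir, "pt.tsv"))
  writeLines(c("llt_id\tllt_name\tpt_id", "200\tSkin rash\t999"),
             file.path(dir, "llt.tsv"))
  expect_error(load_dictionary(file.path(dir, "pt.tsv"),
                               file.path(dir, "llt.tsv")), "999")
})

test_that("duplicate surface forms keep the first mapping with a warning", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("pt_id\tpt_name", "100\tRash", "101\trash"),
             file.path(dir, "pt.tsv"))
  writeLines("llt_id\tllt_name\tpt_id", file.path(dir, "llt.tsv"))
  expect_warning(d <- load_dictionary(file.path(dir, "pt.tsv"),
                                      file.path(dir, "llt.tsv")), "duplicate")
  expect_identical(unname(d$pt_surface["rash"]), "100")
})

test_that("pluralization rules and expansion", {
  expect_identical(pluralize_term("headache"), "headaches")
  expect_identical(pluralize_term("allergy"), "allergies")
  expect_identical(pluralize_term("rash"), "rashes")
  expect_identical(pluralize_term("reflex"), "reflexes")
  expect_identical(singularize_term("allergies"), "allergy")
  expect_identical(singularize_term("rashes"), "rash")
  expect_identical(singularize_term("reflexes"), "reflex")
  expect_identical(singularize_term("reactions"), "reaction")
  ## last word only on multi-word terms
  expect_identical(pluralize_term("injection site reaction"),
                   "injection site reactions")

  f <- mini_dict_files()
  d <- expand_terms(load_dictionary(f$pt, f$llt))
  expect_identical(unname(d$pt_surface["headaches"]), "10019211")
  expect_identical(unname(d$llt_surface["cancers"]), "10007050")
  ## idempotent; original mappings preserved
  d2 <- expand_terms(d)
  expect_identical(d2$pt_surface, d$pt_surface)
  expect_identical(d2$llt_surface, d$llt_surface)
})

test_that("match_mentions finds the printed example with exact offsets", {
  f <- mini_dict_files()
  d <- expand_terms(load_dictionary(f$pt, f$llt))
  sec <- adr_section("S2", choline_section_text())
  ms <- match_mentions(sec, d)
  expect_length(ms, 1L)
  expect_identical(ms[[1L]]$text, "cancer")
  expect_identical(as.integer(ms[[1L]]$starts), 2318L)
  expect_identical(as.integer(ms[[1L]]$lengths), 6L)
  expect_identical(ms[[1L]]$type, "AdverseReaction")

  expect_identical(match_mentions(adr_section("S1", "no known terms here x"),
                                  d), list())
})

test_that("longest match suppresses embedded shorter matches", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("pt_id\tpt_name", "100\tInjection site reaction",
               "101\tReaction"), file.path(dir, "pt.tsv"))
  writeLines("llt_id\tllt_name\tpt_id", file.path(dir, "llt.tsv"))
  d <- expand_terms(load_dictionary(file.path(dir, "pt.tsv"),
                                    file.path(dir, "llt.tsv")))
  sec <- adr_section("S1", "A mild injection site reaction was seen.")
  ms <- match_mentions(sec, d)
  expect_length(ms, 1L)
  expect_identical(ms[[1L]]$text, "injection site reaction")
  ## and matching is at token boundaries: "scan" must not hit "cancer" etc.
  sec2 <- adr_section("S1", "The scanner reactionary text.")
  expect_identical(match_mentions(sec2, d), list())
  ## hyphenated text matches the space-separated form
  sec3 <- adr_section("S1", "An injection-site reaction occurred.")
  ms3 <- match_mentions(sec3, d)
  expect_length(ms3, 1L)
  expect_identical(ms3[[1L]]$text, "injection-site reaction")
})

test_that("exclusions suppress matches", {
  f <- mini_dict_files()
  d <- expand_terms(load_dictionary(f$pt, f$llt))
  sec <- adr_section("S1", "Severe cancer and headache were reported.")
  with_excl <- match_mentions(sec, d, exclusions = "cancer")
  expect_identical(vapply(with_excl, `[[`, "", "text"), "headache")
})

test_that("matching is insensitive to input casing (property)", {
  f <- mini_dict_files()
  d <- expand_terms(load_dictionary(f$pt, f$llt))
  base <- "Severe cancer and headaches were reported after injection site reaction."
  set.seed(71)
  ref <- match_mentions(adr_section("S1", base), d)
  ref_spans <- lapply(ref, function(m) c(m$starts, m$lengths))
  for (r in 1:20) {
    chars <- strsplit(base, "")[[1L]]
    flip <- stats::runif(length(chars)) < 0.3
    chars[flip] <- ifelse(stats::runif(sum(flip)) < 0.5,
                          toupper(chars[flip]), tolower(chars[flip]))
    pert <- paste(chars, collapse = "")
    ms <- match_mentions(adr_section("S1", pert), d)
    expect_identical(lapply(ms, function(m) c(m$starts, m$lengths)), ref_spans)
  }
})

test_that("every reported mention's surface is in the expanded index", {
  fx <- make_synth_corpus(4L, seed = 61L)
  d <- expand_terms(fx$gen$dictionary)
  for (lbl in fx$labels) for (sec in lbl$sections) {
    for (m in match_mentions(sec, d)) {
      form <- normalize_surface(m$text)
      expect_true(form %in% names(d$pt_surface) ||
                    form %in% names(d$llt_surface))
    }
  }
})
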