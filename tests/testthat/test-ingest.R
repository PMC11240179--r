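test_that("clean_abstract flattens sections and strips artifacts", {
  expect_equal(
    clean_abstract(setNames("Text body. (ABSTRACT TRUNCATED AT 250 WORDS)",
                            "")),
    "Text body."
  )
  expect_equal(
    clean_abstract(c(METHODS = "We did X.", RESULTS = "We found Y.")),
    "We did X. We found Y."
  )
  expect_equal(clean_abstract("One paragraph."), "One paragraph.")
  expect_equal(clean_abstract(list(c("BACKGROUND", "A  spaced   text."))),
               "A spaced text.")
  expect_equal(clean_abstract(c("", "   ")), "")
})

test_that("filter fixture yields the expected kept and rejected counts", {
  recs <- filter_fixture()
  res <- filter_records(recs)
  expect_equal(nrow(res$kept), 14)
  tab <- table(res$rejections$reason)
  expect_equal(tab[["too_short"]], 1)
  expect_equal(tab[["too_long"]], 1)
  expect_equal(tab[["unfinished"]], 2)
  expect_equal(tab[["non_english"]], 1)
  expect_equal(tab[["duplicate_pmid"]], 1)
  # the truncation-phrase record is kept with the phrase removed
  kept14 <- res$kept$abstract[res$kept$pmid == "14"]
  expect_false(grepl("ABSTRACT TRUNCATED", kept14))
  expect_true(grepl("[.?!]$", kept14))
})

test_that("length bounds are inclusive and reasons account for all drops", {
  ab250 <- paste0(strrep("y", 249), ".")
  recs <- data.frame(pmid = "1", title = "t", abstract = ab250,
                     journal = "j", year = 2000L, language = "eng",
                     stringsAsFactors = FALSE)
  res <- filter_records(recs)
  expect_equal(nrow(res$kept), 1)

  recs <- filter_fixture()
  res <- filter_records(recs)
  expect_equal(nrow(res$rejections), nrow(recs) - nrow(res$kept))
})

test_that("filtering is idempotent", {
  res <- filter_records(filter_fixture())
  res2 <- filter_records(res$kept)
  expect_equal(nrow(res2$rejections), 0)
  expect_equal(res2$kept$abstract, res$kept$abstract)
})

test_that("journal labels match case-insensitive substrings", {
  labs <- assign_journal_labels(c("Annals of Surgery", "Nature",
                                  "JOURNAL OF VIROLOGY"))
  expect_equal(labs, c("surgery", NA, "virology"))

  multi <- "Neuroscience and Pharmacology Reports"
  l1 <- assign_journal_labels(multi, seed = 7)
  expect_true(l1 %in% c("neuroscience", "pharmacology"))
  expect_identical(l1, assign_journal_labels(multi, seed = 7))

  expect_error(assign_journal_labels("x", keywords = character(0)),
               "nonempty")
})

test_that("sub-corpus selectors implement the documented term rules", {
  recs <- data.frame(
    pmid = as.character(1:6),
    abstract = c(
      "We study SARS-CoV-2 spike proteins.",
      "Transmission of hiv among cohorts.",
      "Seasonal Influenza burden.",
      "A meta-analysis of trials.",
      "This Retraction notice replaces the abstract.",
      "Deep machine learning models for imaging."
    ),
    retracted = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    label = c("virology", NA, NA, NA, NA, "radiology"),
    stringsAsFactors = FALSE
  )
  expect_equal(which(select_subcorpus(recs, "covid")), 1L)
  expect_equal(which(select_subcorpus(recs, "hiv_aids")), 2L)
  expect_equal(which(select_subcorpus(recs, "influenza")), 3L)
  expect_equal(which(select_subcorpus(recs, "meta_analysis")), 4L)
  expect_equal(which(select_subcorpus(recs, "ml_mention")), 6L)
  expect_equal(which(select_subcorpus(recs, "journal_label",
                                      terms = "virology")), 1L)
  # record 5 is retracted but its abstract mentions the retraction;
  # record 6 is retracted with an intact abstract
  expect_equal(which(select_subcorpus(recs, "retracted_intact")), 6L)
  expect_equal(sum(select_subcorpus(recs, "custom", terms = character(0))),
               0)
  expect_error(select_subcorpus(recs, "nope"), "unknown selector")

  # masks are pure functions of the text: permuting rows permutes masks
  perm <- c(3, 1, 6, 2, 5, 4)
  m <- select_subcorpus(recs, "hiv_aids")
  mp <- select_subcorpus(recs[perm, ], "hiv_aids")
  expect_equal(as.logical(mp), as.logical(m)[perm])
})

test_that("covid title topics are assigned with seeded tie-breaks", {
  t1 <- assign_covid_topics("COVID-19 mortality trends")
  expect_equal(t1, "mortality")
  t2 <- assign_covid_topics("Vaccine hesitancy during the outbreak",
                            seed = 3)
  expect_true(t2 %in% c("vaccine", "outbreak"))
  expect_identical(t2, assign_covid_topics(
    "Vaccine hesitancy during the outbreak", seed = 3))
  expect_true(is.na(assign_covid_topics("Aetiology of gout")))
})

test_that("forename extraction follows the first-word rule", {
  expect_equal(extract_forename(c("Eva-Maria", "Jose Maria", "Maria", "J",
                                  "")),
               c("Eva", "Jose", "Maria", NA, NA))
})

test_that("gender inference clamps years and applies the threshold", {
  tab <- builtin_name_table()
  g2015 <- infer_gender("Leslie", 2015, tab)
  g2012 <- infer_gender("Leslie", 2012, tab)
  expect_identical(g2015, g2012)
  expect_equal(infer_gender("Leslie", 1910, tab)$gender, "male")
  expect_equal(infer_gender("Leslie", 2000, tab)$gender, "female")
  expect_equal(infer_gender("Zaphod", 2000, tab)$gender, "unknown")

  custom <- name_gender_table(data.frame(
    name = c("Alex", "Sam", "Kim"), year = 2000,
    prop_female = c(0.7, 0.5, 0.3)
  ))
  g <- infer_gender(c("Alex", "Sam", "Kim"), 2000, custom)
  expect_equal(g$gender, c("female", "male", "male"))  # tie goes to male
  expect_equal(g$prop_female, c(0.7, 0.5, 0.3))
})

test_that("MEDLINE-style XML round-trips through writer and reader", {
  recs <- generate_records(synthetic_config(20, seed = 5))
  path <- withr::local_tempfile(fileext = ".xml")
  write_medline_xml(recs, path)
  back <- read_medline_xml(path)
  expect_equal(back$pmid, recs$pmid)
  expect_equal(back$journal, recs$journal)
  expect_equal(back$year, recs$year)
  expect_equal(back$first_forename, recs$first_forename)
  expect_equal(vapply(back$abstract_sections, clean_abstract,
                      character(1)),
               recs$abstract)
})

test_that("labelled XML sections keep their labels on read", {
  xml <- c(
    '<?xml version="1.0"?>',
    "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
    "<PMID>99</PMID><Article>",
    "<Journal><Title>Test Journal</Title>",
    "<JournalIssue><PubDate><Year>1999</Year></PubDate></JournalIssue>",
    "</Journal>",
    "<ArticleTitle>A structured abstract</ArticleTitle>",
    "<Abstract>",
    '<AbstractText Label="METHODS">We did X.</AbstractText>',
    '<AbstractText Label="RESULTS">We found Y.</AbstractText>',
    "</Abstract><Language>eng</Language>",
    "<AuthorList><Author><ForeName>Eva-Maria</ForeName>",
    "<LastName>Smith</LastName></Author></AuthorList>",
    "</Article></MedlineCitation></PubmedArticle></PubmedArticleSet>"
  )
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  recs <- read_medline_xml(path)
  expect_equal(recs$abstract_sections[[1]]$label, c("METHODS", "RESULTS"))
  expect_equal(clean_abstract(recs$abstract_sections[[1]]),
               "We did X. We found Y.")
  expect_equal(extract_forename(recs$first_forename), "Eva")
})
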