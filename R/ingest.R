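#' Flatten a sectioned abstract into a single paragraph
#'
#' Structured abstracts arrive as an ordered list of (section label, text)
#' pairs. Section labels (e.g. "METHODS", "RESULTS") are dropped, texts are
#' joined with single spaces, any legacy "(ABSTRACT TRUNCATED AT <number>
#' WORDS)" phrase is removed, and surrounding/internal whitespace is
#' normalized. All-empty input yields an empty string, which the filter
#' stage rejects as an empty abstract.
#'
#' @param sections a character vector of section texts (names, if present,
#'   are treated as labels and ignored), a list of two-element
#'   `c(label, text)` pairs, or a data.frame with `label` and `text`
#'   columns as produced by [read_medline_xml()].
#' @return single character string.
#' @examples
#' clean_abstract(c(METHODS = "We did X.", RESULTS = "We found Y."))
#' @export
clean_abstract <- function(sections) {
  if (is.data.frame(sections)) {
    texts <- as.character(sections$text)
  } else if (is.list(sections)) {
    texts <- vapply(sections, function(s) {
      if (length(s) >= 2) as.character(s[[2]]) else as.character(s[[1]])
    }, character(1))
  } else {
    texts <- as.character(sections)
  }
  texts <- texts[!is.na(texts) & nzchar(trimws(texts))]
  if (length(texts) == 0) return("")
  txt <- paste(texts, collapse = " ")
  txt <- gsub("\\s*\\(ABSTRACT TRUNCATED AT \\d+ WORDS\\)", "", txt)
  txt <- gsub("\\s+", " ", txt)
  trimws(txt)
}

#' Filter a corpus of paper records
#'
#' Applies the cleaning and exclusion rules used for large abstract corpora:
#' non-English records, empty abstracts, abstracts shorter than `min_chars`
#' or longer than `max_chars` characters (inclusive bounds are kept),
#' unfinished abstracts (not ending with ".", "?" or "!", checked after
#' removing the truncation phrase), and duplicated pmids (first occurrence
#' kept). Rejections are data, not errors: the return value carries a
#' per-reason log. Character counts are taken on the cleaned
#' single-paragraph text, and filtering is idempotent.
#'
#' @param records a data.frame with at least `pmid` and `abstract` (or an
#'   `abstract_sections` list column from [read_medline_xml()]); `language`
#'   is checked when present.
#' @param min_chars,max_chars inclusive abstract length bounds.
#' @param english_codes language codes accepted as English.
#' @param dedupe drop repeated pmids (first occurrence kept).
#' @return list with `kept` (a `clean_records` data.frame with the cleaned
#'   `abstract`) and `rejections` (data.frame with `pmid` and `reason`, one
#'   of `non_english`, `empty_abstract`, `too_short`, `too_long`,
#'   `unfinished`, `duplicate_pmid`).
#' @export
filter_records <- function(records, min_chars = 250, max_chars = 4000,
                           english_codes = c("eng", "en"),
                           dedupe = TRUE) {
  stopifnot(is.data.frame(records), "pmid" %in% names(records))
  n <- nrow(records)
  if ("abstract_sections" %in% names(records)) {
    abstract <- vapply(records$abstract_sections, clean_abstract,
                       character(1))
  } else if ("abstract" %in% names(records)) {
    abstract <- vapply(records$abstract, clean_abstract, character(1),
                       USE.NAMES = FALSE)
  } else {
    stop("records need an `abstract` or `abstract_sections` column",
         call. = FALSE)
  }

  reason <- rep(NA_character_, n)
  if ("language" %in% names(records)) {
    bad <- !(tolower(records$language) %in% english_codes)
    reason[is.na(reason) & bad] <- "non_english"
  }
  reason[is.na(reason) & !nzchar(abstract)] <- "empty_abstract"
  len <- nchar(abstract)
  reason[is.na(reason) & len < min_chars] <- "too_short"
  reason[is.na(reason) & len > max_chars] <- "too_long"
  finished <- grepl("[.?!]$", abstract)
  reason[is.na(reason) & !finished] <- "unfinished"
  if (dedupe) {
    dup <- duplicated(records$pmid)
    reason[is.na(reason) & dup] <- "duplicate_pmid"
  }

  keep <- is.na(reason)
  kept <- records[keep, setdiff(names(records), "abstract_sections"),
                  drop = FALSE]
  kept$abstract <- abstract[keep]
  rownames(kept) <- NULL
  class(kept) <- c("clean_records", "data.frame")
  rejections <- data.frame(pmid = records$pmid[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  list(kept = kept, rejections = rejections)
}

#' Assign discipline labels from journal titles
#'
#' A record gets a keyword label iff its journal title contains that keyword
#' as a substring, matched case-insensitively. When several keywords match,
#' one is drawn uniformly at random under the given seed; titles matching no
#' keyword stay unlabeled (`NA`).
#'
#' @param records data.frame with a `journal` column, or a character vector
#'   of journal titles.
#' @param keywords candidate labels; defaults to the built-in 38 terms.
#' @param seed integer seed for tie-breaking draws.
#' @param word_boundary if `TRUE`, keywords must match as whole words rather
#'   than raw substrings.
#' @return character vector of labels (`NA` where unlabeled).
#' @export
assign_journal_labels <- function(records,
                                  keywords = journal_label_keywords(),
                                  seed = 1, word_boundary = FALSE) {
  if (length(keywords) == 0) stop("`keywords` must be nonempty",
                                  call. = FALSE)
  journals <- if (is.data.frame(records)) records$journal else
    as.character(records)
  pat <- if (word_boundary) paste0("\\b", keywords, "\\b") else keywords
  hits <- vapply(pat, function(p) grepl(p, journals, ignore.case = TRUE),
                 logical(length(journals)))
  hits <- matrix(hits, nrow = length(journals))
  pick_with_ties(hits, keywords, seed)
}

# Shared resolver: one keyword per row, seeded uniform draw on multi-match.
pick_with_ties <- function(hits, keywords, seed) {
  n <- nrow(hits)
  out <- rep(NA_character_, n)
  counts <- rowSums(hits)
  single <- which(counts == 1)
  if (length(single)) {
    out[single] <- keywords[apply(hits[single, , drop = FALSE], 1,
                                  which.max)]
  }
  multi <- which(counts > 1)
  if (length(multi)) {
    with_seed(seed, {
      for (i in multi) {
        cand <- keywords[hits[i, ]]
        out[i] <- cand[sample.int(length(cand), 1)]
      }
    })
  }
  out
}

#' Select a sub-corpus by abstract or label rules
#'
#' Builds a boolean membership mask over the records. Built-in selectors:
#' \describe{
#'   \item{`covid`}{abstract contains one of the eight exact-case COVID
#'     spellings from [covid_terms()].}
#'   \item{`hiv_aids`}{abstract contains "HIV" or "AIDS" in any case.}
#'   \item{`influenza`}{abstract contains "influenza", capitalized or not.}
#'   \item{`meta_analysis`}{abstract contains "meta-analysis".}
#'   \item{`journal_label`}{record's `label` equals `terms` (one keyword).}
#'   \item{`retracted_intact`}{retraction flag set and the abstract lacks
#'     the four retraction words ([retraction_words()]), i.e. the original
#'     abstract is intact.}
#'   \item{`ml_mention`}{abstract contains "machine learning".}
#'   \item{`custom`}{abstract contains any of `terms` (case-insensitive
#'     unless `ignore_case = FALSE`).}
#' }
#'
#' @param records a `clean_records` data.frame (needs `abstract`; `label`
#'   for `journal_label`; `retracted` for `retracted_intact`).
#' @param selector selector name, see above.
#' @param terms term list for `custom`, or the keyword for `journal_label`.
#' @param ignore_case case folding for `custom` term matching.
#' @return object of class `subcorpus_mask`: logical membership vector with
#'   attributes `selector` and `terms`.
#' @export
select_subcorpus <- function(records, selector, terms = NULL,
                             ignore_case = TRUE) {
  stopifnot(is.data.frame(records))
  abstract <- records$abstract
  mask <- switch(
    selector,
    covid = {
      terms <- covid_terms()
      Reduce(`|`, lapply(terms, function(tm) grepl(tm, abstract,
                                                   fixed = TRUE)))
    },
    hiv_aids = {
      terms <- c("HIV", "AIDS")
      grepl("HIV", abstract, ignore.case = TRUE) |
        grepl("AIDS", abstract, ignore.case = TRUE)
    },
    influenza = {
      terms <- "influenza"
      grepl("influenza", abstract, ignore.case = TRUE)
    },
    meta_analysis = {
      terms <- "meta-analysis"
      grepl("meta-analysis", abstract, ignore.case = TRUE)
    },
    journal_label = {
      if (is.null(terms) || length(terms) != 1) {
        stop("`journal_label` needs a single keyword in `terms`",
             call. = FALSE)
      }
      if (!"label" %in% names(records)) {
        stop("records need a `label` column for `journal_label`",
             call. = FALSE)
      }
      !is.na(records$label) & records$label == terms
    },
    retracted_intact = {
      if (!"retracted" %in% names(records)) {
        stop("records need a `retracted` column", call. = FALSE)
      }
      terms <- retraction_words()
      edited <- Reduce(`|`, lapply(terms, function(tm)
        grepl(tm, abstract, ignore.case = TRUE)))
      records$retracted & !edited
    },
    ml_mention = {
      terms <- "machine learning"
      grepl("machine learning", abstract, ignore.case = TRUE)
    },
    custom = {
      if (is.null(terms)) stop("`custom` needs `terms`", call. = FALSE)
      if (length(terms) == 0) rep(FALSE, length(abstract)) else
        Reduce(`|`, lapply(terms, function(tm)
          grepl(tm, abstract, ignore.case = ignore_case)))
    },
    stop(sprintf("unknown selector '%s'", selector), call. = FALSE)
  )
  structure(as.logical(mask), selector = selector, terms = terms,
            class = c("subcorpus_mask", "logical"))
}

#' Assign COVID subtopic keywords from titles
#'
#' A title gets a subtopic keyword iff it contains that term, capitalized or
#' not; titles matching several terms are assigned one uniformly at random
#' under the seed; others get `NA`.
#'
#' @param titles character vector of paper titles.
#' @param seed integer seed for tie-breaking.
#' @param topics candidate terms; defaults to the 27 built-in subtopics.
#' @return character vector of subtopic keywords or `NA`.
#' @export
assign_covid_topics <- function(titles, seed = 1,
                                topics = covid_title_topics()) {
  hits <- vapply(topics, function(p) grepl(p, titles, ignore.case = TRUE),
                 logical(length(titles)))
  hits <- matrix(hits, nrow = length(titles))
  pick_with_ties(hits, topics, seed)
}

#' Extract an author's first name from a ForeName field
#'
#' MEDLINE's ForeName tag sometimes carries full or hyphenated names.
#' Hyphens are replaced with spaces and the first whitespace-delimited word
#' is taken ("Eva-Maria" -> "Eva"); single-character results (initials) are
#' discarded because no gender can be inferred from them.
#'
#' @param forename_field character vector of ForeName contents.
#' @return character vector of first names, `NA` where none usable.
#' @export
extract_forename <- function(forename_field) {
  x <- trimws(gsub("-", " ", as.character(forename_field)))
  first <- sub("\\s.*$", "", x)
  first[is.na(first) | nchar(first) <= 1] <- NA_character_
  first
}

#' Infer an author's gender from a forename and publication year
#'
#' Looks the (name, year) pair up in a [name_gender_table()], clamping the
#' year to the table's covered range (1930-2012 for the packaged table).
#' The inferred gender is the majority gender: female when the proportion
#' female exceeds `threshold`, male otherwise; exact ties go to male.
#' Names absent from the table give `"unknown"`.
#'
#' @param name,year vectors (recycled to common length).
#' @param table a [name_gender_table()].
#' @param threshold majority cutoff, default 0.5.
#' @return data.frame with columns `gender` (`"female"`, `"male"`,
#'   `"unknown"`) and `prop_female`.
#' @export
infer_gender <- function(name, year, table = builtin_name_table(),
                         threshold = 0.5) {
  k <- max(length(name), length(year))
  name <- rep_len(as.character(name), k)
  year <- rep_len(year, k)
  p <- vapply(seq_len(k), function(i) {
    if (is.na(name[i])) return(NA_real_)
    name_gender_lookup(table, name[i], year[i])
  }, numeric(1))
  gender <- ifelse(is.na(p), "unknown",
                   ifelse(p > threshold, "female", "male"))
  data.frame(gender = gender, prop_female = p, stringsAsFactors = FALSE)
}
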