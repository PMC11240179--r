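#' Read a MEDLINE-style XML subset
#'
#' Parses the dialect used by PubMed bulk exports: `PubmedArticle` elements
#' carrying `PMID`, `ArticleTitle`, one or more `AbstractText` nodes (with
#' an optional `Label` attribute for structured abstracts), `Journal/Title`,
#' `PubDate/Year`, `Language`, and `AuthorList/Author` nodes with `ForeName`
#' and `LastName`. Only this subset of the full schema is read.
#'
#' @param path XML file path.
#' @return a `paper_records` data.frame with an `abstract_sections` list
#'   column (data.frame of `label`, `text` per record), an `authors` list
#'   column, and convenience `first_forename` / `last_forename` columns.
#' @export
read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  get1 <- function(node, xp) {
    v <- xml2::xml_find_first(node, xp)
    if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
  }
  rows <- lapply(arts, function(a) {
    secs <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    sections <- data.frame(
      label = vapply(secs, function(s)
        xml2::xml_attr(s, "Label") %||% NA_character_, character(1)),
      text = vapply(secs, xml2::xml_text, character(1)),
      stringsAsFactors = FALSE
    )
    auth <- xml2::xml_find_all(a, ".//AuthorList/Author")
    authors <- data.frame(
      forename = vapply(auth, function(x) get1(x, "./ForeName"),
                        character(1)),
      lastname = vapply(auth, function(x) get1(x, "./LastName"),
                        character(1)),
      stringsAsFactors = FALSE
    )
    year <- suppressWarnings(as.integer(get1(a, ".//PubDate/Year")))
    list(
      pmid = get1(a, ".//PMID"),
      title = get1(a, ".//ArticleTitle"),
      sections = sections,
      journal = get1(a, ".//Journal/Title"),
      year = year,
      language = get1(a, ".//Language"),
      authors = authors
    )
  })
  first_or_na <- function(x) if (length(x)) x[1] else NA_character_
  last_or_na <- function(x) if (length(x)) x[length(x)] else NA_character_
  out <- data.frame(
    pmid = vapply(rows, `[[`, character(1), "pmid"),
    title = vapply(rows, `[[`, character(1), "title"),
    journal = vapply(rows, `[[`, character(1), "journal"),
    year = vapply(rows, `[[`, integer(1), "year"),
    language = vapply(rows, `[[`, character(1), "language"),
    stringsAsFactors = FALSE
  )
  out$abstract_sections <- lapply(rows, `[[`, "sections")
  out$authors <- lapply(rows, `[[`, "authors")
  out$first_forename <- vapply(rows, function(r)
    first_or_na(r$authors$forename), character(1))
  out$last_forename <- vapply(rows, function(r)
    last_or_na(r$authors$forename), character(1))
  class(out) <- c("paper_records", "data.frame")
  out
}

#' Write records in the MEDLINE-style XML dialect
#'
#' The inverse of [read_medline_xml()] for flat records: each abstract is
#' written as a single unlabeled `AbstractText`, and the first/last author
#' forenames become a two-author `AuthorList` (one author if they match).
#'
#' @param records data.frame with `pmid`, `title`, `abstract`, `journal`,
#'   `year`, `language` and optionally `first_forename`, `last_forename`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(records, path) {
  stopifnot(is.data.frame(records))
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(records))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", records$pmid[i])
    article <- xml2::xml_add_child(cit, "Article")
    journal <- xml2::xml_add_child(article, "Journal")
    xml2::xml_add_child(journal, "Title", records$journal[i])
    issue <- xml2::xml_add_child(journal, "JournalIssue")
    pd <- xml2::xml_add_child(issue, "PubDate")
    xml2::xml_add_child(pd, "Year", as.character(records$year[i]))
    xml2::xml_add_child(article, "ArticleTitle", records$title[i])
    abs_node <- xml2::xml_add_child(article, "Abstract")
    xml2::xml_add_child(abs_node, "AbstractText", records$abstract[i])
    xml2::xml_add_child(article, "Language", records$language[i] %||% "eng")
    al <- xml2::xml_add_child(article, "AuthorList")
    add_author <- function(fore) {
      if (is.null(fore) || is.na(fore)) return(invisible(NULL))
      au <- xml2::xml_add_child(al, "Author")
      xml2::xml_add_child(au, "ForeName", fore)
      xml2::xml_add_child(au, "LastName", "Author")
    }
    add_author(records$first_forename[i])
    if (!identical(records$first_forename[i], records$last_forename[i])) {
      add_author(records$last_forename[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
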