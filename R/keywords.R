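#' Built-in term lists for labelling and sub-corpus selection
#'
#' `journal_label_keywords()` returns the 38 discipline keywords matched
#' against journal titles (e.g. a paper in *Annals of Surgery* gets the
#' label "surgery"). `covid_terms()` returns the exact-case spellings whose
#' presence in an abstract marks a paper as COVID-related.
#' `covid_title_topics()` returns the 27 frequent title terms used to split
#' the COVID literature into subtopics. `retraction_words()` returns the
#' words whose presence in a retracted paper's abstract indicates the
#' abstract was edited after retraction (such papers are excluded from the
#' "intact" retracted set).
#'
#' @return character vector of terms.
#' @export
journal_label_keywords <- function() {
  c("anesthesiology", "biochemistry", "bioinformatics", "cancer",
    "cardiology", "chemistry", "computation", "dermatology", "ecology",
    "education", "engineering", "environment", "ethics", "genetics",
    "gynecology", "healthcare", "immunology", "infectious", "material",
    "microbiology", "neurology", "neuroscience", "nursing", "nutrition",
    "ophthalmology", "optics", "pathology", "pediatric", "pharmacology",
    "physics", "physiology", "psychiatry", "psychology", "radiology",
    "rehabilitation", "surgery", "veterinary", "virology")
}

#' @rdname journal_label_keywords
#' @export
covid_terms <- function() {
  c("covid-19", "COVID-19", "Covid-19", "CoViD-19", "2019-nCoV",
    "SARS-CoV-2", "coronavirus disease 2019", "Coronavirus disease 2019")
}

#' @rdname journal_label_keywords
#' @export
covid_title_topics <- function() {
  c("antibody", "anxiety", "cancer", "children", "clinical", "epidemic",
    "healthcare", "immune", "implications", "mental", "mortality",
    "outbreak", "pediatric", "pneumonia", "population", "psychological",
    "respiratory", "social", "strategies", "students", "surgery",
    "symptoms", "therapy", "transmission", "treatment", "vaccine",
    "workers")
}

#' @rdname journal_label_keywords
#' @export
retraction_words <- function() {
  c("retracted", "retraction", "withdrawn", "withdrawal")
}
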