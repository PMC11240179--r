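# Crafted 20-record corpus with known filter violations:
#   13 valid records, 1 record whose truncation phrase is removed (kept),
#   1 too-short (exactly 249 characters), 1 too-long (> 4000), 2 unfinished,
#   1 non-English, 1 duplicate pmid.
# Expected outcome: 14 kept; rejections: too_short 1, too_long 1,
# unfinished 2, non_english 1, duplicate_pmid 1.
filter_fixture <- function() {
  valid_abs <- function(word) {
    reps <- ceiling(260 / (nchar(word) + 1))
    out <- paste0(strrep(paste0(word, " "), reps),
                  "This abstract is complete.")
    stopifnot(nchar(out) >= 250, nchar(out) <= 4000)
    out
  }
  ab249 <- paste0(strrep("x", 248), ".")
  stopifnot(nchar(ab249) == 249)
  ab_long <- paste0(strrep("abcd ", 810), "It ends properly.")
  stopifnot(nchar(ab_long) > 4000)
  ab_unfinished <- paste0(strrep("results ", 35), "expression increased")
  ab_trunc <- paste0(valid_abs("trimmed"),
                     " (ABSTRACT TRUNCATED AT 250 WORDS)")
  recs <- data.frame(
    pmid = c(sprintf("%02d", 1:13),      # valid
             "14",                       # truncation phrase, kept
             "15",                       # too short
             "16",                       # too long
             "17", "18",                 # unfinished
             "19",                       # non-English
             "01"),                      # duplicate pmid
    title = paste("Title", 1:20),
    abstract = c(vapply(paste0("word", 1:13), valid_abs, character(1)),
                 ab_trunc, ab249, ab_long, ab_unfinished, ab_unfinished,
                 valid_abs("mot"), valid_abs("again")),
    journal = rep("Journal of Testing", 20),
    year = rep(2010L, 20),
    language = c(rep("eng", 18), "fre", "eng"),
    stringsAsFactors = FALSE
  )
  recs
}
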