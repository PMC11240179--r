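#' Forename-gender lookup tables
#'
#' A name-gender table maps (forename, year) pairs to the proportion of
#' people with that forename born around that year who are female. Real
#' studies use historical registry data (e.g. US Social Security records
#' covering 1930-2012) because naming practices drift: Leslie, for example,
#' was mostly a male name early in the twentieth century and is mostly
#' female today. The packaged table is *synthetic*: a small, hand-built set
#' of common forenames with plausible trajectories, sufficient to exercise
#' gender inference end to end. It is not registry data.
#'
#' Lookups clamp the year to the table's covered range (1930-2012 for the
#' packaged table) and then use the nearest covered year.
#'
#' @param entries data.frame with columns `name`, `year`, `prop_female`.
#' @return an object of class `name_gender_table`.
#' @examples
#' tab <- builtin_name_table()
#' name_gender_lookup(tab, "Leslie", 1910)  # majority male
#' name_gender_lookup(tab, "Leslie", 2000)  # majority female
#' @export
name_gender_table <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("name", "year", "prop_female") %in% names(entries)))
  if (any(entries$prop_female < 0 | entries$prop_female > 1)) {
    stop("`prop_female` must lie in [0, 1]", call. = FALSE)
  }
  entries <- entries[order(entries$name, entries$year), , drop = FALSE]
  structure(
    list(entries = entries,
         year_range = range(entries$year)),
    class = "name_gender_table"
  )
}

#' @rdname name_gender_table
#' @export
builtin_name_table <- function() {
  path <- system.file("extdata", "forename_gender_synthetic.tsv",
                      package = "litmap", mustWork = TRUE)
  name_gender_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname name_gender_table
#' @param table a `name_gender_table`.
#' @param name forename to look up (exact match).
#' @param year calendar year; clamped to the covered range.
#' @return `name_gender_lookup()`: the proportion female in `[0, 1]`, or
#'   `NA` if the name is absent from the table.
#' @export
name_gender_lookup <- function(table, name, year) {
  stopifnot(inherits(table, "name_gender_table"))
  year <- max(table$year_range[1], min(table$year_range[2], year))
  sub <- table$entries[table$entries$name == name, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  sub$prop_female[which.min(abs(sub$year - year))]
}

#' @export
print.name_gender_table <- function(x, ...) {
  cat(sprintf("<name_gender_table> %d names, years %d-%d\n",
              length(unique(x$entries$name)),
              x$year_range[1], x$year_range[2]))
  invisible(x)
}
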