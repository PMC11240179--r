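#' Wilson score interval for a binomial proportion
#'
#' @param x successes, `n` trials (vectorized).
#' @param n trials.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with `lower` and `upper`.
#' @export
wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Yearly fraction series for a record predicate
#'
#' Counts, per publication year, how many records satisfy a predicate and
#' how many are eligible, and attaches Wilson 95% intervals. The terminal
#' (most recent) year can be dropped when it is known to be incompletely
#' indexed. For gender trends, pass `denominator` to restrict the eligible
#' set (e.g. records with a resolved gender).
#'
#' @param records data.frame with a `year` column.
#' @param predicate a function of the records returning a logical vector,
#'   or a logical vector directly.
#' @param year_range optional `c(from, to)` filter.
#' @param exclude_terminal drop the last observed year.
#' @param denominator optional logical vector marking eligible records
#'   (default: all).
#' @param conf_level confidence level for the Wilson interval.
#' @return data.frame of class `trend_series` with `year`, `numerator`,
#'   `denominator`, `fraction`, `lower`, `upper`.
#' @export
yearly_fraction <- function(records, predicate, year_range = NULL,
                            exclude_terminal = FALSE, denominator = NULL,
                            conf_level = 0.95) {
  stopifnot(is.data.frame(records), "year" %in% names(records))
  hit <- if (is.function(predicate)) predicate(records) else
    as.logical(predicate)
  stopifnot(length(hit) == nrow(records))
  elig <- if (is.null(denominator)) rep(TRUE, nrow(records)) else
    as.logical(denominator)
  years <- records$year
  keep <- elig & !is.na(years)
  if (!is.null(year_range)) {
    if (year_range[1] > year_range[2]) stop("empty year range",
                                            call. = FALSE)
    keep <- keep & years >= year_range[1] & years <= year_range[2]
  }
  if (!any(keep)) stop("no records in the requested year range",
                       call. = FALSE)
  yrs <- sort(unique(years[keep]))
  if (exclude_terminal) yrs <- yrs[-length(yrs)]
  num <- vapply(yrs, function(y) sum(hit & keep & years == y), numeric(1))
  den <- vapply(yrs, function(y) sum(keep & years == y), numeric(1))
  ci <- wilson_interval(num, den, conf_level)
  out <- data.frame(year = yrs, numerator = num, denominator = den,
                    fraction = num / den, lower = ci$lower,
                    upper = ci$upper)
  class(out) <- c("trend_series", "data.frame")
  out
}

#' Penalized-spline trend fit over publication year
#'
#' Fits a generalized additive model with year as the sole predictor, using
#' cubic regression splines: Gaussian-identity with 6 basis functions for
#' continuous responses, binomial-logit with 12 for binary responses (the
#' defaults). The smoothing penalty is chosen by generalized
#' cross-validation (`smoothing = "cv-grid"`) or fixed via `lambda`.
#' Predictions and pointwise 95% intervals are returned on the integer year
#' grid of the observed range (intervals are computed on the link scale and
#' back-transformed, so binomial curves stay inside (0, 1)).
#'
#' @param years numeric predictor (calendar year per observation).
#' @param response numeric response; 0/1 for the binomial family.
#' @param family `"gaussian"` or `"binomial"`.
#' @param n_splines number of spline basis functions; defaults to 6 for
#'   gaussian and 12 for binomial.
#' @param smoothing `"cv-grid"` (penalty by cross-validated grid search) or
#'   `"fixed"`.
#' @param lambda smoothing parameter when `smoothing = "fixed"`.
#' @param grid prediction grid; defaults to the integer years of the
#'   observed range.
#' @param conf_level confidence level of the pointwise interval.
#' @return object of class `trend_fit`: list with `curve` (data.frame
#'   `year`, `fit`, `lower`, `upper`), the fitted `model`, `family` and
#'   `n_splines`.
#' @export
fit_trend <- function(years, response,
                      family = c("gaussian", "binomial"),
                      n_splines = NULL,
                      smoothing = c("cv-grid", "fixed"),
                      lambda = NULL, grid = NULL, conf_level = 0.95) {
  family <- match.arg(family)
  smoothing <- match.arg(smoothing)
  n_splines <- n_splines %||% if (family == "gaussian") 6L else 12L
  if (length(unique(years)) < n_splines) {
    stop("need at least `n_splines` distinct years", call. = FALSE)
  }
  fam <- if (family == "gaussian") stats::gaussian() else
    stats::binomial(link = "logit")
  dat <- data.frame(year = years, y = response)
  if (smoothing == "fixed") {
    if (is.null(lambda)) stop("`lambda` required for fixed smoothing",
                              call. = FALSE)
    model <- mgcv::gam(y ~ s(year, k = n_splines, bs = "cr"), family = fam,
                       data = dat, sp = lambda)
  } else {
    model <- mgcv::gam(y ~ s(year, k = n_splines, bs = "cr"), family = fam,
                       data = dat, method = "GCV.Cp")
  }
  grid <- grid %||% seq(floor(min(years)), ceiling(max(years)))
  pr <- predict(model, newdata = data.frame(year = grid), se.fit = TRUE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  inv <- fam$linkinv
  structure(
    list(curve = data.frame(year = grid,
                            fit = inv(pr$fit),
                            lower = inv(pr$fit - z * pr$se.fit),
                            upper = inv(pr$fit + z * pr$se.fit)),
         model = model, family = family, n_splines = n_splines),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s GAM, %d basis functions, grid %d-%d\n",
              x$family, x$n_splines, min(x$curve$year), max(x$curve$year)))
  invisible(x)
}
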