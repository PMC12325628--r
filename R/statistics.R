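#' Normalize firmness-recovery values to [0, 1]
#'
#' Min-max normalization across the cohort: the least firm sample maps to 0,
#' the firmest to 1.
#'
#' @param x numeric vector of raw firmness (elastic recovery) values.
#' @return numeric vector in [0, 1].
#' @export
normalizeFirmness <- function(x) {
  if (length(x) < 2) stop("need at least two samples to normalize")
  rng <- range(x)
  if (diff(rng) == 0) stop("all firmness values are identical")
  (x - rng[1]) / diff(rng)
}

#' Pearson correlation with significance test
#'
#' @param x,y numeric vectors of equal length.
#' @return list with \code{r}, \code{pValue}, \code{n} and the underlying
#'   \code{htest} object.
#' @export
pearsonCorrelation <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pValue = ct$p.value, n = length(x), test = ct)
}

#' Welch two-sample t-test between groups
#'
#' @param a,b numeric vectors (unequal variances assumed).
#' @return list with \code{t}, \code{df}, \code{pValue}, group means
#'   \code{meanA}, \code{meanB} and the \code{htest} object.
#' @export
welchTTest <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value, meanA = mean(a), meanB = mean(b), test = tt)
}

#' Simple linear regression of y on x
#'
#' @param x,y numeric vectors of equal length.
#' @return list with \code{slope}, \code{intercept}, \code{r2},
#'   \code{pValueSlope} and the fitted \code{lm} object.
#' @export
simpleLinearRegression <- function(x, y) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       pValueSlope = sm$coefficients[2, 4],
       fit = fit)
}

#' Load the bundled nine-donor cohort table
#'
#' Per-donor skin architecture metrics and normalized firmness used throughout
#' the examples: age (years), mean fiber diameter (um), fiber count, elastin
#' volume fraction (%), cluster count, largest cluster size, vertical fiber
#' proportion (%) and firmness normalized to [0, 1].
#'
#' @return data.frame with one row per donor.
#' @export
cohortTable <- function() {
  path <- system.file("extdata", "cohort_metrics.csv", package = "dermafiber",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Split a cohort into younger and older groups
#'
#' @param ages numeric vector of donor ages.
#' @param cutoff group boundary; ages strictly below it are "younger".
#' @return logical vector, TRUE for the younger group.
#' @export
youngerGroup <- function(ages, cutoff = 50) ages < cutoff

#' Group summary statistics for a metric
#'
#' Mean, standard deviation and five-number boxplot statistics (Tukey
#' whiskers at 1.5 IQR) per group.
#'
#' @param values numeric metric values.
#' @param younger logical vector from \code{\link{youngerGroup}}.
#' @return list with \code{younger} and \code{older}, each holding
#'   \code{mean}, \code{sd}, \code{n} and \code{boxStats} (lower whisker,
#'   lower hinge, median, upper hinge, upper whisker).
#' @export
groupSummary <- function(values, younger) {
  one <- function(v) {
    bs <- grDevices::boxplot.stats(v, coef = 1.5)
    list(mean = mean(v), sd = stats::sd(v), n = length(v), boxStats = bs$stats)
  }
  list(younger = one(values[younger]), older = one(values[!younger]))
}

#' Age-group comparison of every architecture metric
#'
#' Runs a Welch t-test between the younger and older groups for each metric
#' column and reports group means with p-values.
#'
#' @param cohort data.frame with an \code{age} column and numeric metric
#'   columns.
#' @param metrics character vector of metric column names (default: all
#'   numeric columns except age).
#' @param cutoff age boundary of the younger group.
#' @return data.frame with columns \code{metric}, \code{mean_younger},
#'   \code{sd_younger}, \code{mean_older}, \code{sd_older}, \code{t},
#'   \code{p_value}.
#' @export
compareAgeGroups <- function(cohort, metrics = NULL, cutoff = 50) {
  yg <- youngerGroup(cohort$age, cutoff)
  if (is.null(metrics)) {
    metrics <- setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)], "age")
  }
  rows <- lapply(metrics, function(m) {
    a <- cohort[[m]][yg]; b <- cohort[[m]][!yg]
    tt <- welchTTest(a, b)
    data.frame(metric = m, mean_younger = mean(a), sd_younger = stats::sd(a),
               mean_older = mean(b), sd_older = stats::sd(b),
               t = tt$t, p_value = tt$pValue)
  })
  do.call(rbind, rows)
}

#' Correlate architecture metrics with firmness
#'
#' Pearson correlation of each metric column against normalized firmness,
#' plus the linear fit.
#'
#' @param cohort data.frame with a \code{firmness} column and numeric metric
#'   columns.
#' @param metrics metric column names (default: all numeric columns except
#'   firmness).
#' @return data.frame with columns \code{metric}, \code{r}, \code{p_value},
#'   \code{slope}, \code{r2}.
#' @export
correlateWithFirmness <- function(cohort, metrics = NULL) {
  if (is.null(cohort$firmness)) stop("cohort must contain a 'firmness' column")
  if (is.null(metrics)) {
    metrics <- setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)],
                       "firmness")
  }
  rows <- lapply(metrics, function(m) {
    pc <- pearsonCorrelation(cohort[[m]], cohort$firmness)
    lr <- simpleLinearRegression(cohort[[m]], cohort$firmness)
    data.frame(metric = m, r = pc$r, p_value = pc$pValue,
               slope = lr$slope, r2 = lr$r2)
  })
  do.call(rbind, rows)
}
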