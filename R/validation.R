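# Method-agreement statistics: relative error with one-sample t inference
# and Bland-Altman bias / limits of agreement, plus the published 5-km
# course validation dataset embedded as a fixture.

#' Paired method-vs-reference measurements
#'
#' @param reference reference (criterion) VO2 values, e.g. from a portable
#'   breath-by-breath metabolic system; cumulative ml/kg.
#' @param method the estimation method's values, same length and units.
#' @param ids optional labels, one per pair.
#' @return An object of class `paired_measurements` (a data.frame with
#'   columns `id`, `reference`, `method`).
#' @export
paired_measurements <- function(reference, method, ids = NULL) {
  if (!is.numeric(reference) || !is.numeric(method))
    stop("`reference` and `method` must be numeric")
  if (length(reference) != length(method))
    stop("`reference` and `method` must have equal length")
  if (length(reference) < 2L)
    stop("need at least 2 pairs")
  if (anyNA(reference) || anyNA(method)) stop("missing values in pairs")
  if (is.null(ids)) ids <- as.character(seq_along(reference))
  structure(data.frame(id = as.character(ids), reference = reference,
                       method = method, stringsAsFactors = FALSE),
            class = c("paired_measurements", "data.frame"))
}

as_pairs <- function(pairs, method) {
  if (inherits(pairs, "paired_measurements")) return(pairs)
  paired_measurements(pairs, method)
}

#' Relative error of a method against a reference
#'
#' Per-pair relative error `(method - reference) / reference`, its mean and
#' sample SD, and a one-sample t-test against 0: t = mean / (sd / sqrt(n)),
#' two-sided p with n - 1 degrees of freedom, and the 95% t confidence
#' interval `mean ± t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param pairs a [paired_measurements()], or a numeric reference vector
#'   (then supply `method`).
#' @param method numeric method values when `pairs` is a plain vector.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An object of class `relative_error_result`: `per_subject`, `n`,
#'   `mean`, `sd`, `abs_mean` (= |mean|), `ci_low`, `ci_high`, `t_stat`,
#'   `p_two_sided`. With zero error variance the interval collapses to the
#'   mean and t/p are `NA`, with a warning.
#' @details Relative error is scale-free: rescaling both columns by any
#'   positive factor leaves every output unchanged.
#' @examples
#' d <- fivek_validation()
#' relative_errors(paired_measurements(d$k5, d$mets, d$id))
#' @export
relative_errors <- function(pairs, method = NULL, conf_level = 0.95) {
  pairs <- as_pairs(pairs, method)
  if (any(pairs$reference <= 0))
    stop("reference values must be strictly positive for relative error")
  err <- (pairs$method - pairs$reference) / pairs$reference
  n <- length(err)
  m <- mean(err)
  s <- stats::sd(err)
  if (s == 0) {
    warning("zero error variance: confidence interval collapses to the mean")
    ci <- c(m, m); t_stat <- NA_real_; p <- NA_real_
  } else {
    tt <- stats::t.test(err, mu = 0, conf.level = conf_level)
    ci <- as.numeric(tt$conf.int)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(per_subject = stats::setNames(err, pairs$id), n = n,
                 mean = m, sd = s, abs_mean = abs(m),
                 ci_low = ci[1L], ci_high = ci[2L],
                 t_stat = t_stat, p_two_sided = p,
                 conf_level = conf_level),
            class = "relative_error_result")
}

#' @export
print.relative_error_result <- function(x, ...) {
  cat(sprintf("<relative_error> n = %d: mean %.4f (sd %.4f), %d%% CI (%.4f, %.4f)\n",
              x$n, x$mean, x$sd, round(100 * x$conf_level), x$ci_low, x$ci_high))
  if (!is.na(x$t_stat))
    cat(sprintf("  one-sample t vs 0: t = %.3f, p = %.4f\n", x$t_stat, x$p_two_sided))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences `method - reference` (the direction is fixed and
#' stated in the output), bias = mean difference, and limits of agreement
#' bias ± 1.96 x sample SD of the differences.
#'
#' @inheritParams relative_errors
#' @param loa_mult limit-of-agreement multiplier (default 1.96).
#' @return An object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `means` (per-pair averages, the plot abscissa),
#'   `diffs`, `n`, `direction`, `within_loa` (TRUE iff every difference
#'   lies inside the limits).
#' @examples
#' d <- fivek_validation()
#' ba <- bland_altman(paired_measurements(d$k5, d$mets, d$id))
#' ba$bias
#' @export
bland_altman <- function(pairs, method = NULL, loa_mult = 1.96) {
  pairs <- as_pairs(pairs, method)
  diffs <- pairs$method - pairs$reference
  means <- (pairs$method + pairs$reference) / 2
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  loa <- bias + c(-1, 1) * loa_mult * s
  structure(list(bias = bias, sd_diff = s, loa_low = loa[1L],
                 loa_high = loa[2L],
                 means = stats::setNames(means, pairs$id),
                 diffs = stats::setNames(diffs, pairs$id),
                 n = length(diffs), direction = "method - reference",
                 loa_mult = loa_mult,
                 within_loa = all(diffs >= loa[1L] & diffs <= loa[2L])),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d (%s)\n", x$n, x$direction))
  cat(sprintf("  bias %.3f, LoA (%.3f, %.3f)%s\n", x$bias, x$loa_low, x$loa_high,
              if (x$within_loa) ", all pairs within LoA" else ""))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Per-pair differences against per-pair means, with the bias (solid) and
#' limits of agreement (dashed).
#'
#' @param x a `bland_altman_result`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman_result <- function(x, ...) {
  ylim <- range(c(x$diffs, x$loa_low, x$loa_high))
  plot(x$means, x$diffs, xlab = "Mean of methods", ylab = x$direction,
       ylim = ylim + c(-0.1, 0.1) * diff(ylim), pch = 19, ...)
  abline(h = x$bias, lty = 1)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' 5-km course validation dataset
#'
#' Published cumulative oxygen consumption (ml/kg) for ten participants who
#' completed a 5-km mixed-terrain course: the reference value measured by a
#' portable breath-by-breath metabolic system (`k5`), the slope-adjusted
#' METs model estimate (`mets`), the ACSM running equation applied at all
#' speeds (`acsm_run`), the speed-switched ACSM walk/run estimate
#' (`acsm_rw`), and each participant's mean speed. Participants A-E ran the
#' whole course (`group = "running"`); F-J alternated running and walking
#' (`group = "running_walking"`).
#'
#' @return A data.frame with columns `id`, `group`, `k5`, `mets`,
#'   `acsm_run`, `acsm_rw`, `mean_speed_kmh`.
#' @examples
#' colMeans(fivek_validation()[, c("k5", "mets", "acsm_run", "acsm_rw")])
#' @export
fivek_validation <- function() {
  data.frame(
    id = LETTERS[1:10],
    group = rep(c("running", "running_walking"), each = 5L),
    k5       = c(1214.9, 1173.4, 1102.0,  975.0,  842.9,
                 1280.8, 1275.4,  893.2, 1067.5, 1285.2),
    mets     = c(1099.6, 1026.5, 1058.8, 1052.1, 1071.6,
                 1047.3, 1020.7,  990.4, 1152.1, 1079.4),
    acsm_run = c(1143.3, 1106.6, 1123.8, 1155.8, 1024.1,
                 1189.9, 1172.1, 1044.6, 1267.7, 1161.4),
    acsm_rw  = c(1135.7, 1099.0, 1123.2, 1152.8, 1021.5,
                  914.4,  780.6,  939.8, 1106.7,  877.7),
    mean_speed_kmh = c(11.4, 11.2, 10.9, 14.6, 17.4,
                        7.2,  5.8,  9.0,  7.7,  6.3),
    stringsAsFactors = FALSE
  )
}
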