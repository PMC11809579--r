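# Diagnostic plots, in the style of the standard coverage/RUV panels:
# true-vs-posterior-mean scatter with HPD whiskers coloured by coverage,
# rank histogram with its binomial band, rank ECDF with its simultaneous band.

#' Coverage scatter plot with HPD whiskers
#'
#' True values against posterior means; vertical whiskers are the HPD
#' intervals, coloured by whether they cover the truth.
#'
#' @param rs the [replicateSet()] that was calibrated.
#' @param cr the matching [CoverageReport-class].
#' @return a ggplot object.
#' @export
plotCoverage <- function(rs, cr) {
  df <- data.frame(truth = rs@truths,
                   postMean = rowMeans(rs@draws),
                   lower = cr@intervals[, 1L], upper = cr@intervals[, 2L],
                   covered = ifelse(cr@covered, "covered", "missed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$postMean,
                                   colour = .data$covered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower,
                                         ymax = .data$upper)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(covered = "#2c7fb8",
                                            missed = "#d7301f")) +
    ggplot2::labs(x = "true value", y = "posterior mean",
                  title = sprintf("%s: %d/%d in %d%%-HPD (band [%d, %d])",
                                  rs@parameter, coveredCount(cr),
                                  length(cr@covered), round(100 * cr@alpha),
                                  cr@lower, cr@upper)) +
    ggplot2::theme_minimal()
}

#' Rank histogram with binomial band
#'
#' @param rv a [RuvReport-class].
#' @return a ggplot object.
#' @export
plotRankHistogram <- function(rv) {
  bins <- rv@bins
  df <- data.frame(mid = (seq_len(bins) - 0.5) / bins, count = rv@counts)
  n <- length(rv@ranks)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 1, ymin = rv@bandLower,
                      ymax = rv@bandUpper, fill = "#a6cee3", alpha = 0.5) +
    ggplot2::geom_col(width = 1 / bins, fill = "grey35") +
    ggplot2::geom_hline(yintercept = n / bins) +
    ggplot2::labs(x = "normalised rank", y = "count",
                  title = sprintf("rank histogram (pattern: %s)", rv@pattern)) +
    ggplot2::theme_minimal()
}

#' Rank ECDF with simultaneous band
#'
#' @param rv a [RuvReport-class].
#' @param reps Monte-Carlo replicates for the band.
#' @return a ggplot object.
#' @export
plotRankEcdf <- function(rv, reps = 2000L) {
  eb <- ecdfBand(rv@ranks, rv@L, reps = reps)
  df <- data.frame(x = eb$grid, ecdf = eb$ecdf,
                   lo = eb$bandLower, hi = eb$bandUpper)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "#a6cee3", alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_step(ggplot2::aes(y = .data$ecdf)) +
    ggplot2::labs(x = "normalised rank", y = "ECDF",
                  title = sprintf("rank ECDF (band %s)",
                                  if (eb$pass) "ok" else "violated")) +
    ggplot2::theme_minimal()
}
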