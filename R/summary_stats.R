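#' Across-year summary of a nugget series
#'
#' Mean, sample standard deviation (divisor n - 1), minimum and maximum of
#' the non-missing yearly nuggets. With a single value the sd is reported
#' missing; an all-missing series is an error.
#'
#' @param yearly numeric vector of yearly nuggets; NA marks years where no
#'   valid fit was obtained.
#' @return list with \code{mean}, \code{sd}, \code{min}, \code{max},
#'   \code{n}.
#' @export
across_year_stats <- function(yearly) {
  v <- yearly[!is.na(yearly)]
  if (length(v) == 0L) stop("all yearly values missing")
  list(mean = mean(v),
       sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
       min = min(v),
       max = max(v),
       n = length(v))
}

#' 95% confidence interval for a mean nugget
#'
#' Student-t interval: mean +/- t(0.975, n - 1) * sd / sqrt(n) over the
#' non-missing yearly values.
#'
#' @inheritParams across_year_stats
#' @return list with \code{mean}, \code{halfwidth}, \code{lower},
#'   \code{upper}, \code{n}.
#' @export
ci95 <- function(yearly) {
  v <- yearly[!is.na(yearly)]
  n <- length(v)
  if (n < 2L) stop("need >= 2 non-missing values for a confidence interval")
  m <- mean(v)
  hw <- stats::qt(0.975, n - 1L) * stats::sd(v) / sqrt(n)
  list(mean = m, halfwidth = hw, lower = m - hw, upper = m + hw, n = n)
}

#' Per-region descriptive richness and abundance summaries
#'
#' Per plot: species richness (number of species present) and total
#' relative abundance (summed max counts). Per region and year: median and
#' quartiles of both.
#'
#' @param per_year named list (by year) of abundance
#'   \code{\link{community_matrix}} objects.
#' @param meta plot metadata assigning plots to regions.
#' @return list with \code{per_plot} (plot/year richness and abundance)
#'   and \code{per_region} (region/year medians and quartiles).
#' @export
richness_abundance_summary <- function(per_year, meta) {
  stopifnot(length(per_year) >= 1L)
  rows <- lapply(names(per_year), function(yr) {
    cm <- per_year[[yr]]
    inc <- if (cm$type == "incidence") cm else to_presence(cm)
    data.frame(plot_id = cm$plots,
               year = yr,
               richness = rowSums(inc$values),
               abundance = rowSums(cm$values),
               region = meta$region[match(cm$plots, meta$plot_id)],
               stringsAsFactors = FALSE)
  })
  per_plot <- do.call(rbind, rows)
  agg <- function(v) c(q1 = unname(stats::quantile(v, 0.25)),
                       median = stats::median(v),
                       q3 = unname(stats::quantile(v, 0.75)))
  per_region <- do.call(rbind, lapply(
    split(per_plot, list(per_plot$region, per_plot$year), drop = TRUE),
    function(g) {
      r <- agg(g$richness); a <- agg(g$abundance)
      data.frame(region = g$region[1L], year = g$year[1L],
                 rich_q1 = r[[1L]], rich_median = r[[2L]], rich_q3 = r[[3L]],
                 abund_q1 = a[[1L]], abund_median = a[[2L]], abund_q3 = a[[3L]],
                 stringsAsFactors = FALSE)
    }))
  rownames(per_region) <- NULL
  list(per_plot = per_plot, per_region = per_region)
}

#' Descriptive association between nuggets and species richness
#'
#' Ordinary least-squares regression of nuggets on richness (or any paired
#' predictor), reported descriptively: slope, F statistic, p value and
#' (adjusted) R-squared. No decision logic is attached.
#'
#' @param nuggets numeric response.
#' @param richness numeric predictor of the same length.
#' @return list with \code{slope}, \code{F}, \code{p}, \code{r2},
#'   \code{adj_r2}, \code{n}.
#' @export
nugget_richness_association <- function(nuggets, richness) {
  keep <- is.finite(nuggets) & is.finite(richness)
  x <- richness[keep]; y <- nuggets[keep]
  if (length(x) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2L]),
       F = unname(fstat[1L]),
       p = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                            lower.tail = FALSE)),
       r2 = sm$r.squared,
       adj_r2 = sm$adj.r.squared,
       n = length(x))
}

#' Format a fitted quantity for report output
#'
#' Fixed 4-decimal formatting for nuggets and other fitted quantities,
#' with missing values rendered as "n/a".
#'
#' @param x numeric vector.
#' @param digits decimals (default 4).
#' @return character vector.
#' @export
format_fitted <- function(x, digits = 4L) {
  out <- ifelse(is.na(x), "n/a", formatC(x, format = "f", digits = digits))
  unname(out)
}
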