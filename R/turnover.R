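#' Species persistently present at a plot
#'
#' Species observed at the plot in at least \code{threshold} of the
#' surveyed years (default 4, i.e. "seen in four or five years" of a
#' five-year study).
#'
#' @param per_year list of per-year incidence \code{\link{community_matrix}}
#'   objects sharing the same plot set.
#' @param plot plot identifier.
#' @param threshold minimum number of years of presence; when NULL it
#'   defaults to 4 for >= 5 years of data and \code{ceiling(0.8 * years)}
#'   otherwise.
#' @return character vector of persistent species.
#' @export
persistent_species <- function(per_year, plot, threshold = NULL) {
  stopifnot(length(per_year) >= 1L)
  if (is.null(threshold)) threshold <- .default_persistence(length(per_year))
  if (threshold > length(per_year)) {
    stop("persistence threshold exceeds the number of years")
  }
  counts <- .presence_years(per_year, plot)
  names(counts)[counts >= threshold]
}

.default_persistence <- function(n_years) {
  if (n_years >= 5L) 4L else as.integer(ceiling(0.8 * n_years))
}

## years of presence per species at one plot
.presence_years <- function(per_year, plot) {
  species <- sort(unique(unlist(lapply(per_year, `[[`, "species"))))
  counts <- stats::setNames(integer(length(species)), species)
  for (cm in per_year) {
    if (!(plot %in% cm$plots)) stop("unknown plot: ", plot)
    pres <- cm$values[plot, ]
    counts[cm$species] <- counts[cm$species] + as.integer(pres > 0)
  }
  counts
}

#' Inter-annual species turnover of a plot
#'
#' Turnover is the transient fraction of the plot's cumulative species
#' list: (cumulative - persistent) / cumulative, where persistent species
#' are those seen in at least \code{threshold} years. A plot with an empty
#' cumulative list has undefined turnover (NA, with a warning).
#'
#' @inheritParams persistent_species
#' @return a one-row \code{data.frame}: \code{plot_id},
#'   \code{n_cumulative}, \code{n_persistent}, \code{turnover}.
#' @export
plot_turnover <- function(per_year, plot, threshold = NULL) {
  if (is.null(threshold)) threshold <- .default_persistence(length(per_year))
  counts <- .presence_years(per_year, plot)
  n_cum <- sum(counts >= 1L)
  n_per <- sum(counts >= threshold)
  if (n_cum == 0L) {
    warning("plot ", plot, " has an empty cumulative species list; ",
            "turnover undefined")
    turn <- NA_real_
  } else {
    turn <- (n_cum - n_per) / n_cum
  }
  data.frame(plot_id = plot, n_cumulative = n_cum, n_persistent = n_per,
             turnover = turn, stringsAsFactors = FALSE)
}

#' Turnover table for every plot
#'
#' @inheritParams persistent_species
#' @return a \code{data.frame} with one [plot_turnover()] row per plot.
#' @export
turnover_table <- function(per_year, threshold = NULL) {
  plots <- per_year[[1L]]$plots
  do.call(rbind, lapply(plots, function(p) {
    plot_turnover(per_year, p, threshold = threshold)
  }))
}

#' Exclude plots with high inter-annual turnover
#'
#' Plots whose turnover exceeds the cut-off (strictly) are removed; a plot
#' exactly at the cut-off is retained. Used to check whether high nuggets
#' are driven by incomplete sampling.
#'
#' @param plots character vector of candidate plots.
#' @param records turnover table from [turnover_table()] covering all
#'   \code{plots}.
#' @param cutoff turnover cut-off in (0, 1], e.g. 0.6, 0.7 or 0.8.
#' @return the surviving plots (character vector).
#' @export
filter_by_turnover <- function(plots, records, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1) {
    stop("turnover cutoff must be a single value in (0, 1]")
  }
  idx <- match(plots, records$plot_id)
  if (anyNA(idx)) {
    stop("no turnover record for plot(s): ",
         paste(plots[is.na(idx)], collapse = ", "))
  }
  turn <- records$turnover[idx]
  plots[!is.na(turn) & turn <= cutoff]
}
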