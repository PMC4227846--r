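#' Run the full randomness analysis on a survey dataset
#'
#' Orchestrates the end-to-end pipeline: per-year and cumulative incidence
#' matrices per region, pairwise distance/dissimilarity tables, dissimogram
#' fits per stratum (all plots, high/low management intensity, turnover
#' cut-offs) and family, and the across-year summary tables (mean, sd,
#' min/max, 95% CI, pseudo-R2 matrix). Cells where a fit fails, is invalid
#' (nugget outside [0, 1]) or has fewer than 2 plots are reported as NA
#' ("n/a" in the CSV output) and the run continues.
#'
#' @param surveys survey table (see [read_surveys()]).
#' @param plots plot metadata (see [read_plots()]).
#' @param families curve families to fit.
#' @param cutoffs turnover cut-offs for the filtered strata.
#' @param persistence persistence threshold in years (NULL = default rule).
#' @param excluded species to drop before analysis (e.g. aerial species).
#' @param strata which strata to compute.
#' @param out_dir optional directory; when given, CSV tables (4-decimal
#'   fixed formatting for fitted quantities) are written there.
#' @return list with \code{fits} (one row per region x scope x stratum x
#'   family), \code{turnover}, \code{summary} (across-year stats per
#'   region/stratum/family), \code{ci} (95% CIs for the all-plots
#'   stratum), \code{log} (excluded pairs/plots and failure reasons).
#' @export
run_analysis <- function(surveys, plots,
                         families = c("gompertz", "negexp"),
                         cutoffs = c(0.6, 0.7, 0.8),
                         persistence = NULL,
                         excluded = character(),
                         strata = c("all", "intensity", "turnover"),
                         out_dir = NULL) {
  stopifnot(length(families) >= 1L)
  families <- match.arg(families, c("gompertz", "negexp"), several.ok = TRUE)
  if (any(cutoffs <= 0 | cutoffs > 1)) stop("cutoffs must lie in (0, 1]")
  strata <- match.arg(strata, c("all", "intensity", "turnover"),
                      several.ok = TRUE)
  surveys <- exclude_species(surveys, excluded)
  regions <- sort(unique(plots$region))
  years <- sort(unique(surveys$year))

  fits <- list()
  turn_all <- list()
  logs <- list()
  note <- function(...) logs[[length(logs) + 1L]] <<- paste0(...)

  for (reg in regions) {
    meta_r <- plots[plots$region == reg, , drop = FALSE]
    sur_r <- surveys[surveys$plot_id %in% meta_r$plot_id, , drop = FALSE]
    if (nrow(sur_r) == 0L) {
      note("region ", reg, ": no survey records, skipped")
      next
    }
    per_year <- lapply(years, function(yr) {
      to_presence(max_abundance(sur_r, yr, plots = meta_r$plot_id))
    })
    names(per_year) <- years
    cum <- cumulative_composition(per_year)
    scopes <- c(as.list(stats::setNames(per_year, years)),
                list(cumulative = cum))

    turn <- turnover_table(per_year, threshold = persistence)
    turn$region <- reg
    turn_all[[reg]] <- turn

    strata_sets <- list(all = meta_r$plot_id)
    if ("intensity" %in% strata) {
      split_try <- tryCatch(median_split(plots, reg), error = function(e) {
        note("region ", reg, ": intensity split failed: ",
             conditionMessage(e))
        NULL
      })
      if (!is.null(split_try)) {
        strata_sets$high_intensity <- split_try$high
        strata_sets$low_intensity <- split_try$low
      }
    }
    if ("turnover" %in% strata) {
      for (co in cutoffs) {
        nm <- sprintf("cutoff_%d", round(100 * co))
        strata_sets[[nm]] <- filter_by_turnover(meta_r$plot_id, turn, co)
      }
    }

    for (scope in names(scopes)) {
      cm <- scopes[[scope]]
      for (st in names(strata_sets)) {
        keep <- intersect(cm$plots, strata_sets[[st]])
        for (fam in families) {
          row <- data.frame(region = reg, scope = scope, stratum = st,
                            family = fam, a = NA_real_, b = NA_real_,
                            c = NA_real_, nugget = NA_real_,
                            asymptote = NA_real_, pseudo_r2 = NA_real_,
                            converged = FALSE, valid = FALSE,
                            n_pairs = NA_integer_, stringsAsFactors = FALSE)
          if (length(keep) < 2L) {
            note("region ", reg, " scope ", scope, " stratum ", st,
                 ": fewer than 2 plots, reported n/a")
          } else {
            fit <- tryCatch({
              pt <- suppressWarnings(build_pair_table(subset_plots(cm, keep),
                                                      meta_r))
              nx <- attr(pt, "n_excluded")
              if (nx > 0L) {
                note("region ", reg, " scope ", scope, " stratum ", st,
                     ": ", nx, " undefined pair(s) excluded")
              }
              fit_dissimogram(pt, family = fam)
            }, error = function(e) {
              note("region ", reg, " scope ", scope, " stratum ", st,
                   " family ", fam, ": fit failed: ", conditionMessage(e))
              NULL
            })
            if (!is.null(fit)) {
              co <- fit$coefficients
              row$a <- co[["a"]]; row$b <- co[["b"]]; row$c <- co[["c"]]
              row$nugget <- if (fit$valid) fit$nugget else NA_real_
              row$asymptote <- fit$asymptote
              row$pseudo_r2 <- fit$pseudo_r2
              row$converged <- fit$converged
              row$valid <- fit$valid
              row$n_pairs <- fit$n_pairs
              if (!fit$valid) {
                note("region ", reg, " scope ", scope, " stratum ", st,
                     " family ", fam, ": invalid fit (nugget ",
                     format(fit$nugget), "), reported n/a")
              }
            }
          }
          fits[[length(fits) + 1L]] <- row
        }
      }
    }
  }
  fits <- do.call(rbind, fits)
  turnover <- do.call(rbind, turn_all)
  rownames(turnover) <- NULL

  ## Table-1-style across-year summaries of valid yearly nuggets
  yearly <- fits[fits$scope != "cumulative", , drop = FALSE]
  summ <- do.call(rbind, lapply(
    split(yearly, list(yearly$region, yearly$stratum, yearly$family),
          drop = TRUE),
    function(g) {
      v <- g$nugget
      if (all(is.na(v))) {
        data.frame(region = g$region[1L], stratum = g$stratum[1L],
                   family = g$family[1L], mean = NA_real_, sd = NA_real_,
                   min = NA_real_, max = NA_real_, n = 0L,
                   stringsAsFactors = FALSE)
      } else {
        s <- across_year_stats(v)
        data.frame(region = g$region[1L], stratum = g$stratum[1L],
                   family = g$family[1L], mean = s$mean, sd = s$sd,
                   min = s$min, max = s$max, n = s$n,
                   stringsAsFactors = FALSE)
      }
    }))
  rownames(summ) <- NULL

  ## Table-2-style CI over the all-plots yearly nuggets
  ci <- do.call(rbind, lapply(
    split(yearly[yearly$stratum == "all", , drop = FALSE],
          list(yearly$region[yearly$stratum == "all"],
               yearly$family[yearly$stratum == "all"]), drop = TRUE),
    function(g) {
      v <- g$nugget[!is.na(g$nugget)]
      if (length(v) < 2L) return(NULL)
      x <- ci95(g$nugget)
      data.frame(region = g$region[1L], family = g$family[1L],
                 mean = x$mean, ci = x$halfwidth, lower = x$lower,
                 upper = x$upper, n = x$n, stringsAsFactors = FALSE)
    }))
  if (!is.null(ci)) rownames(ci) <- NULL

  out <- list(fits = fits, turnover = turnover, summary = summ, ci = ci,
              log = unlist(logs))
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' Write analysis result tables as CSV
#'
#' Fitted quantities are written with fixed 4-decimal formatting (CI table
#' with 3 decimals) and missing cells as "n/a".
#'
#' @param result a [run_analysis()] result bundle.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_analysis <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df, cols, digits = 4L) {
    for (cl in intersect(cols, names(df))) {
      df[[cl]] <- format_fitted(df[[cl]], digits)
    }
    df
  }
  paths <- character()
  p <- file.path(out_dir, "fits.csv")
  utils::write.csv(fmt(result$fits, c("a", "b", "nugget", "asymptote",
                                      "pseudo_r2")),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "turnover.csv")
  utils::write.csv(fmt(result$turnover, "turnover"), p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "summary_table1.csv")
  utils::write.csv(fmt(result$summary, c("mean", "sd", "min", "max")), p,
                   row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(result$ci)) {
    p <- file.path(out_dir, "summary_table2.csv")
    utils::write.csv(fmt(result$ci, c("mean", "ci", "lower", "upper"), 3L),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "run_log.txt")
  writeLines(if (is.null(result$log)) character() else result$log, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Run the simulation-based recovery study
#'
#' Thin wrapper combining [simulate_metacommunity()]-based replication
#' with the analysis pipeline via [nugget_recovery_study()], optionally
#' writing the summary table as CSV.
#'
#' @param rho randomness fractions to simulate.
#' @param n_reps replicates per rho.
#' @param seed base seed.
#' @param out_dir optional output directory.
#' @param ... overrides passed to [sim_config()].
#' @return the [nugget_recovery_study()] table.
#' @export
run_simulation <- function(rho = c(0, 0.5, 1), n_reps = 20L, seed = 1L,
                           out_dir = NULL, ...) {
  res <- nugget_recovery_study(rho = rho, n_reps = n_reps, seed = seed, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "recovery_study.csv"),
                     row.names = FALSE)
  }
  res
}
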