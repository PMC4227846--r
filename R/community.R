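#' Read long-format point-count survey records
#'
#' Reads a CSV of repeated point-count survey records (one row per plot,
#' year, survey round and species) and validates it. Column names in the
#' file are mapped onto the canonical names \code{plot_id}, \code{region},
#' \code{year}, \code{round}, \code{species}, \code{count} via
#' \code{columns}.
#'
#' @param path path to a CSV file with a header row.
#' @param columns named character vector mapping canonical column names to
#'   the names used in the file. Defaults to the identity mapping.
#' @param n_rounds number of survey rounds per year (default 5). Rounds
#'   outside \code{1..n_rounds} are a validation error.
#' @param meta optional plot metadata (see [read_plots()]). Records whose
#'   plot is absent from \code{meta} trigger a warning listing the unknown
#'   plots.
#' @return a \code{data.frame} of validated survey records with canonical
#'   column names.
#' @export
read_surveys <- function(path, columns = NULL, n_rounds = 5, meta = NULL) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c("plot_id", "region", "year", "round", "species", "count")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(columns)) map[names(columns)] <- columns
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab <- data.frame(
    plot_id = as.character(raw[[map[["plot_id"]]]]),
    region  = as.character(raw[[map[["region"]]]]),
    year    = as.integer(raw[[map[["year"]]]]),
    round   = as.integer(raw[[map[["round"]]]]),
    species = as.character(raw[[map[["species"]]]]),
    count   = as.integer(raw[[map[["count"]]]]),
    stringsAsFactors = FALSE
  )
  validate_surveys(tab, n_rounds = n_rounds, meta = meta)
}

#' @keywords internal
validate_surveys <- function(tab, n_rounds = 5, meta = NULL) {
  bad <- which(is.na(tab$count) | tab$count < 0)
  if (length(bad) > 0L) {
    stop("negative or missing count at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  bad_round <- which(is.na(tab$round) | tab$round < 1L | tab$round > n_rounds)
  if (length(bad_round) > 0L) {
    stop("survey round outside 1..", n_rounds, " at row(s): ",
         paste(utils::head(bad_round, 10L), collapse = ", "))
  }
  key <- paste(tab$plot_id, tab$year, tab$round, tab$species, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    shown <- unique(paste(tab$plot_id[dup], tab$year[dup], tab$round[dup],
                          tab$species[dup], sep = "/"))
    stop("duplicate (plot, year, round, species) record(s): ",
         paste(utils::head(shown, 5L), collapse = "; "))
  }
  if (!is.null(meta)) {
    unknown <- setdiff(unique(tab$plot_id), meta$plot_id)
    if (length(unknown) > 0L) {
      warning("survey records for plot(s) absent from metadata: ",
              paste(unknown, collapse = ", "))
    }
  }
  tab
}

#' Read plot metadata
#'
#' Reads the plot table: identifier, region, projected coordinates in
#' meters and a real-valued management-intensity score.
#'
#' @inheritParams read_surveys
#' @return a \code{data.frame} with columns \code{plot_id}, \code{region},
#'   \code{x}, \code{y}, \code{intensity}.
#' @export
read_plots <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("plot file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- c("plot_id", "region", "x", "y", "intensity")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(columns)) map[names(columns)] <- columns
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta <- data.frame(
    plot_id   = as.character(raw[[map[["plot_id"]]]]),
    region    = as.character(raw[[map[["region"]]]]),
    x         = as.numeric(raw[[map[["x"]]]]),
    y         = as.numeric(raw[[map[["y"]]]]),
    intensity = as.numeric(raw[[map[["intensity"]]]]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(meta$plot_id)) {
    stop("duplicate plot_id in plot metadata: ",
         paste(unique(meta$plot_id[duplicated(meta$plot_id)]), collapse = ", "))
  }
  if (any(!is.finite(meta$x)) || any(!is.finite(meta$y))) {
    bad <- meta$plot_id[!is.finite(meta$x) | !is.finite(meta$y)]
    stop("non-finite coordinates for plot(s): ", paste(bad, collapse = ", "))
  }
  meta
}

#' Remove species from a survey table
#'
#' Drops all records of the listed species (e.g. aerial foragers surveyed
#' irregularly). Excluding a species that never occurs is a no-op.
#'
#' @param tab survey table as returned by [read_surveys()].
#' @param excluded character vector of species identifiers to drop.
#' @return the filtered survey table.
#' @export
exclude_species <- function(tab, excluded = character()) {
  if (length(excluded) == 0L) return(tab)
  out <- tab[!(tab$species %in% excluded), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a community matrix
#'
#' A community matrix holds plots x species values (abundance counts or
#' 0/1 incidence) for a single year or cumulatively across years.
#'
#' @param values numeric matrix with plot rownames and species colnames.
#' @param scope scope label, e.g. a year or \code{"cumulative"}.
#' @param type \code{"abundance"} or \code{"incidence"}.
#' @return an object of class \code{community_matrix}.
#' @export
community_matrix <- function(values, scope, type = c("abundance", "incidence")) {
  type <- match.arg(type)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0)) stop("community matrix values must be non-negative")
  if (type == "incidence" && !all(values %in% c(0, 1))) {
    stop("incidence matrix may contain only 0 and 1")
  }
  structure(list(values = values, plots = rownames(values),
                 species = colnames(values), scope = scope, type = type),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("Community matrix (", x$type, "), scope: ", as.character(x$scope), "\n",
      length(x$plots), " plots x ", length(x$species), " species\n", sep = "")
  invisible(x)
}

#' Per-year maximum abundance per plot and species
#'
#' The maximum count over the survey rounds of one year is used as the
#' relative abundance of a species at a plot; species never recorded at a
#' plot get 0.
#'
#' @param tab survey table.
#' @param year the year to aggregate.
#' @param plots,species optional plot/species universes for the matrix
#'   dimensions; default to all plots/species present in \code{tab}.
#' @return an abundance \code{\link{community_matrix}}.
#' @export
max_abundance <- function(tab, year, plots = NULL, species = NULL) {
  sel <- tab[tab$year == year, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no survey records for year ", year)
  if (is.null(plots)) plots <- sort(unique(tab$plot_id))
  if (is.null(species)) species <- sort(unique(tab$species))
  m <- matrix(0L, nrow = length(plots), ncol = length(species),
              dimnames = list(plots, species))
  sel <- sel[sel$plot_id %in% plots & sel$species %in% species, , drop = FALSE]
  if (nrow(sel) > 0L) {
    agg <- stats::aggregate(count ~ plot_id + species, data = sel, FUN = max)
    m[cbind(agg$plot_id, agg$species)] <- agg$count
  }
  community_matrix(m, scope = year, type = "abundance")
}

#' Convert an abundance matrix to presence/absence
#'
#' @param cm an abundance (or incidence) \code{\link{community_matrix}}.
#' @return an incidence \code{\link{community_matrix}}; idempotent.
#' @export
to_presence <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  v <- ifelse(cm$values > 0, 1L, 0L)
  dimnames(v) <- dimnames(cm$values)
  community_matrix(v, scope = cm$scope, type = "incidence")
}

#' Cumulative species composition across years
#'
#' Element-wise union of per-year incidence matrices: a species is present
#' cumulatively if it was present at the plot in at least one year.
#'
#' @param per_year list of incidence \code{\link{community_matrix}} objects
#'   sharing the same plot set (species lists are unioned).
#' @return an incidence \code{\link{community_matrix}} with scope
#'   \code{"cumulative"}.
#' @export
cumulative_composition <- function(per_year) {
  stopifnot(length(per_year) >= 1L)
  plots <- per_year[[1L]]$plots
  for (cm in per_year) {
    if (cm$type != "incidence") stop("all matrices must be incidence matrices")
    if (!setequal(cm$plots, plots)) {
      stop("plot sets differ between per-year matrices")
    }
  }
  species <- sort(unique(unlist(lapply(per_year, `[[`, "species"))))
  acc <- matrix(0L, nrow = length(plots), ncol = length(species),
                dimnames = list(plots, species))
  for (cm in per_year) {
    acc[cm$plots, cm$species] <- acc[cm$plots, cm$species] | cm$values
  }
  mode(acc) <- "integer"
  community_matrix(acc, scope = "cumulative", type = "incidence")
}

#' Split a region's plots at the median management intensity
#'
#' Plots with intensity strictly above the regional median form the
#' high-intensity group; ties at the median go to the low-intensity group,
#' so that the rule is deterministic (with 50 distinct intensities this
#' yields the familiar 25/25 split).
#'
#' @param meta plot metadata (see [read_plots()]).
#' @param region region identifier to split.
#' @return list with character vectors \code{high} and \code{low}.
#' @export
median_split <- function(meta, region) {
  sub <- meta[meta$region == region, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no plots in region ", region)
  known <- !is.na(sub$intensity)
  if (!any(known)) stop("all intensities missing in region ", region)
  if (sum(known) < 2L) stop("need >= 2 plots with known intensity in region ", region)
  if (any(!known)) {
    warning("dropping ", sum(!known), " plot(s) with missing intensity in region ",
            region)
    sub <- sub[known, , drop = FALSE]
  }
  med <- stats::median(sub$intensity)
  high <- sub$plot_id[sub$intensity > med]
  low <- sub$plot_id[sub$intensity <= med]
  list(high = high, low = low)
}

#' Subset a community matrix to a set of plots
#'
#' @param cm a \code{\link{community_matrix}}.
#' @param plots character vector of plot identifiers to keep.
#' @return the subset \code{\link{community_matrix}}.
#' @export
subset_plots <- function(cm, plots) {
  stopifnot(inherits(cm, "community_matrix"))
  missing_p <- setdiff(plots, cm$plots)
  if (length(missing_p) > 0L) {
    stop("plot(s) not in matrix: ", paste(missing_p, collapse = ", "))
  }
  community_matrix(cm$values[plots, , drop = FALSE], scope = cm$scope,
                   type = cm$type)
}
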