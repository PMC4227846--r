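#' Jaccard dissimilarity between two species sets
#'
#' Classic incidence-based Jaccard: the index D' is the number of shared
#' species divided by the number of species in the union; the returned
#' dissimilarity is 1 - D'. Undefined (NA) when both sets are empty.
#'
#' @param a,b character vectors of species identifiers (treated as sets).
#' @return dissimilarity in [0, 1], or NA if both sets are empty.
#' @export
jaccard_dissimilarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  n_union <- length(union(a, b))
  if (n_union == 0L) return(NA_real_)
  1 - length(intersect(a, b)) / n_union
}

#' Euclidean distance between two plots
#'
#' Straight-line distance in meters between projected plot coordinates.
#'
#' @param p,q rows of a plot metadata table (lists or one-row data frames
#'   with \code{x}, \code{y} and optionally \code{plot_id}).
#' @return distance in meters.
#' @export
euclidean_distance <- function(p, q) {
  for (pt in list(p, q)) {
    if (!is.finite(pt$x[1L]) || !is.finite(pt$y[1L])) {
      id <- if (!is.null(pt$plot_id)) pt$plot_id[1L] else "<unnamed>"
      stop("missing coordinates for plot ", id)
    }
  }
  sqrt((p$x[1L] - q$x[1L])^2 + (p$y[1L] - q$y[1L])^2)
}

#' Build the pairwise distance-dissimilarity table
#'
#' Computes, for every unordered pair of plots in an incidence matrix, the
#' Euclidean distance between the plots and the Jaccard dissimilarity of
#' their species sets. Pairs where both communities are empty (undefined
#' dissimilarity) are excluded with a warning; the number excluded is kept
#' in the \code{"n_excluded"} attribute.
#'
#' @param cm an incidence \code{\link{community_matrix}} (n >= 2 plots).
#' @param meta plot metadata covering every plot in \code{cm}.
#' @return a \code{data.frame} of class \code{pair_table} with columns
#'   \code{plot_i}, \code{plot_j}, \code{distance_m}, \code{dissimilarity};
#'   n(n-1)/2 rows before exclusion.
#' @export
build_pair_table <- function(cm, meta) {
  stopifnot(inherits(cm, "community_matrix"))
  if (cm$type != "incidence") stop("pair table requires an incidence matrix")
  n <- length(cm$plots)
  if (n < 2L) stop("need at least 2 plots to build a pair table")
  idx <- match(cm$plots, meta$plot_id)
  if (anyNA(idx)) {
    stop("no coordinates for plot(s): ",
         paste(cm$plots[is.na(idx)], collapse = ", "))
  }
  xy <- cbind(meta$x[idx], meta$y[idx])
  if (any(!is.finite(xy))) {
    stop("non-finite coordinates for plot(s): ",
         paste(cm$plots[rowSums(!is.finite(xy)) > 0], collapse = ", "))
  }
  m <- cm$values
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  un <- outer(sizes, sizes, "+") - inter
  dis <- ifelse(un > 0, 1 - inter / un, NA_real_)
  dmat <- as.matrix(stats::dist(xy))

  ij <- which(upper.tri(dis), arr.ind = TRUE)
  out <- data.frame(
    plot_i = cm$plots[ij[, 1L]],
    plot_j = cm$plots[ij[, 2L]],
    distance_m = dmat[ij],
    dissimilarity = dis[ij],
    stringsAsFactors = FALSE
  )
  n_excluded <- sum(is.na(out$dissimilarity))
  if (n_excluded > 0L) {
    warning(n_excluded,
            " pair(s) with two empty communities excluded (undefined Jaccard)")
    out <- out[!is.na(out$dissimilarity), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("pair_table", "data.frame")
  out
}
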