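#' Correlation distance between cell activity traces
#'
#' \code{d_ij = 1 - r_ij} with \code{r} the Pearson correlation of the two
#' cells' traces over the analyzed episode, so identical traces are at
#' distance 0 and perfectly anticorrelated ones at 2. Zero-variance traces
#' are excluded with a warning.
#'
#' @param ts a \code{trace_set} or a frames x cells numeric matrix with
#'   column names.
#' @return a symmetric distance matrix with zero diagonal; excluded cell ids
#'   in attribute \code{"excluded"}.
#' @export
correlation_distance <- function(ts) {
  vals <- if (inherits(ts, "trace_set")) ts$values else as.matrix(ts)
  if (ncol(vals) < 2) stop_input("need at least 2 cells")
  v <- apply(vals, 2, stats::var)
  excluded <- colnames(vals)[v == 0 | !is.finite(v)]
  if (length(excluded)) {
    warning("excluding zero-variance traces: ",
            paste(excluded, collapse = ", "))
    vals <- vals[, !(colnames(vals) %in% excluded), drop = FALSE]
  }
  if (ncol(vals) < 2) stop_input("fewer than 2 cells with variance")
  d <- 1 - stats::cor(vals)
  diag(d) <- 0
  attr(d, "excluded") <- excluded
  d
}

#' Cluster cells by cutting a correlation-distance dendrogram
#'
#' Average-linkage hierarchical clustering on the correlation distance,
#' cut at a fixed height; cells landing in clusters smaller than
#' \code{min_cluster_size} are flagged excluded (not clustered-out, but
#' ignored by the dorsoventrality statistics).
#'
#' @param distance matrix from \code{\link{correlation_distance}}.
#' @param linkage_method \code{stats::hclust} method (default "average").
#' @param cut_height dendrogram cut height on the distance scale (default 0.7).
#' @param min_cluster_size clusters below this size are excluded (default 3).
#' @return A \code{cluster_assignment}: list with \code{labels} (named
#'   integer vector), \code{included} (named logical), \code{sizes},
#'   parameters.
#' @export
cut_dendrogram <- function(distance, linkage_method = "average",
                           cut_height = 0.7, min_cluster_size = 3L) {
  if (nrow(distance) < 2) stop_input("need at least 2 cells to cluster")
  hc <- stats::hclust(stats::as.dist(distance), method = linkage_method)
  labels <- stats::cutree(hc, h = cut_height)
  sizes <- table(labels)
  included <- sizes[as.character(labels)] >= min_cluster_size
  names(included) <- names(labels)
  structure(list(labels = labels, included = included,
                 sizes = as.integer(sizes),
                 linkage_method = linkage_method, cut_height = cut_height,
                 min_cluster_size = min_cluster_size, hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells in %d clusters (%s linkage, cut %.2f); %d excluded (< %d members)\n",
              length(x$labels), length(x$sizes), x$linkage_method,
              x$cut_height, sum(!x$included), x$min_cluster_size))
  invisible(x)
}

#' Dorsoventrality index per cell
#'
#' The DVI of a cell is the fraction of dorsally located cells in that cell's
#' cluster, so all members of one cluster share the same DVI. Cells excluded
#' for small cluster size carry \code{NA}.
#'
#' @param assignment a \code{cluster_assignment}.
#' @param surfaces named character vector ("ventral"/"dorsal") covering every
#'   clustered cell.
#' @return named numeric vector of DVIs in [0, 1] (NA for excluded cells).
#' @export
dorsoventrality <- function(assignment, surfaces) {
  ids <- names(assignment$labels)
  if (!all(ids %in% names(surfaces))) {
    stop_input("missing surface label for: ",
               paste(setdiff(ids, names(surfaces))[1:3], collapse = ", "))
  }
  surf <- surfaces[ids]
  if (!all(surf %in% c("ventral", "dorsal"))) {
    stop_input("surfaces must be 'ventral' or 'dorsal'")
  }
  frac <- tapply(surf == "dorsal", assignment$labels, mean)
  dvi <- as.numeric(frac[as.character(assignment$labels)])
  dvi[!assignment$included] <- NA_real_
  stats::setNames(dvi, ids)
}

#' Integration coefficient
#'
#' \code{CI = <1 - 2 |DVI - 1/2|>}, averaged across all included cells (each
#' cell is one entry, not each cluster): 0 if every cluster lies wholly on
#' one surface, 1 if every cluster is spread 50:50.
#'
#' @param dvi numeric DVI vector; \code{NA}s (excluded cells) are dropped.
#' @return CI in [0, 1].
#' @export
integration_coefficient <- function(dvi) {
  dvi <- dvi[!is.na(dvi)]
  if (length(dvi) == 0) stop_input("no included cells: CI undefined")
  mean(1 - 2 * abs(dvi - 0.5))
}

#' Per-behavior cluster/DVI/CI summary
#'
#' Convenience wrapper: correlation distance, dendrogram cut, DVI and CI for
#' one behavior's traces.
#'
#' @param ts a \code{trace_set} or matrix.
#' @param surfaces named surface vector (see \code{\link{dorsoventrality}}).
#' @param ... passed to \code{\link{cut_dendrogram}}.
#' @return list: \code{assignment}, \code{dvi}, \code{ci}, \code{table}
#'   (cell_id, cluster, surface, DVI, included).
#' @export
cluster_integration <- function(ts, surfaces, ...) {
  d <- correlation_distance(ts)
  ca <- cut_dendrogram(d, ...)
  dvi <- dorsoventrality(ca, surfaces)
  ids <- names(ca$labels)
  tab <- data.frame(cell_id = ids, cluster = as.integer(ca$labels),
                    surface = surfaces[ids], dvi = dvi,
                    included = as.logical(ca$included),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(assignment = ca, dvi = dvi, ci = integration_coefficient(dvi),
       table = tab)
}

#' DVI histogram (per-cell entries)
#'
#' Tabulates DVIs of included cells into equal-width bins; each cell is one
#' entry, so large clusters weigh more, preventing overrepresentation of
#' small clusters.
#'
#' @param dvi DVI vector.
#' @param breaks number of bins (default 10).
#' @return a \code{hist}-like list from \code{graphics::hist} (not plotted).
#' @export
dvi_histogram <- function(dvi, breaks = 10) {
  dvi <- dvi[!is.na(dvi)]
  graphics::hist(dvi, breaks = seq(0, 1, length.out = breaks + 1),
                 plot = FALSE)
}
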