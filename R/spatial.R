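EARTH_RADIUS_M <- 6371000

#' Project geographic coordinates to a local plane in meters
#'
#' Local equirectangular projection about an origin (default: the centroid):
#' `x = R cos(lat0) dlon`, `y = R dlat` (radians), with `R` the mean Earth
#' radius; altitude passes through as `z`. At the extent of a regional lake
#' survey the distortion relative to exact geodesy is negligible.
#'
#' @param lat,lon decimal degrees.
#' @param alt altitude in meters (default 0).
#' @param origin optional `c(lat, lon)` reference point.
#' @return Data frame with columns `x`, `y`, `z` (meters).
#' @export
geo_to_meters <- function(lat, lon, alt = 0, origin = NULL) {
  stopifnot(all(abs(lat) <= 90), all(abs(lon) <= 360))
  if (is.null(origin)) origin <- c(mean(lat), mean(lon))
  rad <- pi / 180
  data.frame(
    x = EARTH_RADIUS_M * cos(origin[1] * rad) * (lon - origin[2]) * rad,
    y = EARTH_RADIUS_M * (lat - origin[1]) * rad,
    z = rep_len(alt, length(lat)))
}

## longest edge of the minimum spanning tree of a distance matrix
mst_threshold <- function(d) {
  max(vegan::spantree(d)$dist)
}

#' Distance-based Moran's eigenvector maps
#'
#' Builds an orthogonal spatial basis from the Euclidean distance matrix of
#' site coordinates: distances beyond the truncation threshold (the longest
#' minimum-spanning-tree edge, so the truncated graph stays connected) are
#' replaced by 4x the threshold, the squared distances are Gower
#' double-centered, and the eigenvectors with positive eigenvalues are
#' retained as spatial covariates.
#'
#' @param coords data frame or matrix of site coordinates (e.g.
#'   [geo_to_meters()] output); >= 3 rows.
#' @param truncation optional threshold in meters (default: longest MST edge).
#' @param eig_tol relative eigenvalue tolerance; axes with eigenvalue
#'   `> eig_tol * max(eigenvalue)` are retained (default 1e-9).
#' @return A list of class `stockload_mem`: `vectors` (sites x axes,
#'   orthonormal, centered, ordered by decreasing eigenvalue), `values`
#'   (retained eigenvalues), `truncation` (meters) and `values_all`.
#' @export
build_dbmem <- function(coords, truncation = NULL, eig_tol = 1e-9) {
  xyz <- as.matrix(coords)
  n <- nrow(xyz)
  if (n < 3) stop("need at least 3 sites")
  d <- as.matrix(stats::dist(xyz))
  if (is.null(truncation)) {
    truncation <- mst_threshold(stats::as.dist(d))
    if (truncation == 0) warning("coincident sites give a zero MST edge; ",
                                 "consider jittering coordinates")
  }
  dtr <- d
  dtr[dtr > truncation] <- 4 * truncation
  a <- -0.5 * dtr^2
  cent <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(cent %*% a %*% cent, symmetric = TRUE)
  keep <- e$values > eig_tol * max(e$values)
  vec <- e$vectors[, keep, drop = FALSE]
  rownames(vec) <- rownames(xyz)
  colnames(vec) <- paste0("MEM", seq_len(ncol(vec)))
  structure(list(vectors = vec, values = e$values[keep],
                 truncation = truncation, values_all = e$values),
            class = "stockload_mem")
}

#' @export
print.stockload_mem <- function(x, ...) {
  cat(sprintf("<stockload_mem> %d sites, %d retained axes, truncation %.1f m\n",
              nrow(x$vectors), ncol(x$vectors), x$truncation))
  invisible(x)
}
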