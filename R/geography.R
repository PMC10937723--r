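#' Tropical classification of latitudes
#'
#' A polygon is tropical when its centroid lies within `threshold` degrees
#' of the equator (boundary inclusive).
#'
#' @param lat latitude(s) in degrees, in \[-90, 90\].
#' @param threshold tropical belt half-width in degrees (default 23).
#' @return logical vector.
#' @export
classify_tropical <- function(lat, threshold = 23) {
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("latitude out of [-90, 90]")
  abs(lat) <= threshold
}

#' Great-circle distance matrix between polygon centroids
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param meta a `polygon_metadata` data.frame (or any data.frame with
#'   columns `polygon_id`, `lon`, `lat`).
#' @param radius sphere radius in km.
#' @return symmetric numeric matrix (km) with polygon ids as dimnames.
#' @export
great_circle_matrix <- function(meta, radius = 6371) {
  if (any(is.na(meta$lon)) || any(is.na(meta$lat))) {
    stop("missing centroid coordinates")
  }
  lat <- meta$lat * pi / 180
  lon <- meta$lon * pi / 180
  n <- length(lat)
  dlat <- outer(lat, lat, "-") / 2
  dlon <- outer(lon, lon, "-") / 2
  h <- sin(dlat)^2 + outer(cos(lat), cos(lat)) * sin(dlon)^2
  h <- pmin(pmax(h, 0), 1)
  d <- 2 * radius * asin(sqrt(h))
  diag(d) <- 0
  dimnames(d) <- list(meta$polygon_id, meta$polygon_id)
  d
}

#' Write / read a labelled square matrix as CSV
#'
#' Shared serialization for distance, dissimilarity and homogenization
#' matrices: first column and header row carry the polygon labels.
#'
#' @param m square matrix with dimnames.
#' @param path CSV path.
#' @export
write_square_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_square_csv
#' @export
read_square_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}
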