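#' Species-by-polygon incidence table with occurrence status
#'
#' An `incidence_table` stores binary species occurrences across spatial
#' polygons, each occurrence flagged `"native"` or `"nonnative"`. The
#' native-only occurrences define the assemblages *before* human-mediated
#' dispersal; all occurrences together define the assemblages *after*.
#'
#' @param species_id character vector of species identifiers, one per
#'   occurrence record.
#' @param polygon_id character vector of polygon identifiers, same length.
#' @param status character vector, each `"native"` or `"nonnative"`.
#' @return An object of class `incidence_table`: a list with `occurrences`
#'   (a data.frame with columns `species_id`, `polygon_id`, `status`),
#'   `species_ids` and `polygon_ids` (sorted unique identifiers).
#' @details Duplicate (species, polygon, status) records are dropped. A pair
#'   recorded both native and nonnative is resolved to native, with a
#'   warning: a species cannot be introduced where it is native.
#' @export
incidence_table <- function(species_id, polygon_id, status) {
  stopifnot(length(species_id) == length(polygon_id),
            length(species_id) == length(status))
  species_id <- as.character(species_id)
  polygon_id <- as.character(polygon_id)
  status <- as.character(status)
  bad <- !status %in% c("native", "nonnative")
  if (any(bad)) {
    stop("invalid status value(s): ", paste(unique(status[bad]), collapse = ", "))
  }
  occ <- data.frame(species_id = species_id, polygon_id = polygon_id,
                    status = status, stringsAsFactors = FALSE)
  occ <- unique(occ)
  # conflicting status for the same pair -> native wins
  key <- paste(occ$species_id, occ$polygon_id, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    warning(length(unique(dup)),
            " (species, polygon) pair(s) recorded both native and nonnative;",
            " resolved to native")
    conflicted <- key %in% dup
    occ <- occ[!(conflicted & occ$status == "nonnative"), , drop = FALSE]
  }
  occ <- occ[order(occ$species_id, occ$polygon_id), , drop = FALSE]
  rownames(occ) <- NULL
  structure(list(occurrences = occ,
                 species_ids = sort(unique(occ$species_id)),
                 polygon_ids = sort(unique(occ$polygon_id))),
            class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat("incidence_table:", length(x$species_ids), "species x",
      length(x$polygon_ids), "polygons,", nrow(x$occurrences),
      "occurrences (", sum(x$occurrences$status == "nonnative"),
      "nonnative )\n")
  invisible(x)
}

#' Read an incidence table from CSV
#'
#' Two dialects are supported. `"long"`: columns `species_id`, `polygon_id`,
#' `status`. `"wide"`: a 0/1 matrix whose first column holds species ids and
#' whose header row holds polygon ids, plus a separate long-format status
#' table (`status_path`); cells equal to 1 are occurrences, and any
#' occurrence absent from the status table defaults to `"native"`.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @param status_path for the wide dialect, path of a CSV with columns
#'   `species_id`, `polygon_id`, `status` listing the nonnative occurrences.
#' @return An [incidence_table()].
#' @export
read_incidence <- function(path, dialect = c("long", "wide"),
                           status_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("species_id", "polygon_id", "status")
    if (!all(need %in% names(df))) {
      stop("long incidence CSV must have columns ",
           paste(need, collapse = ", "))
    }
    return(incidence_table(df$species_id, df$polygon_id, df$status))
  }
  m <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  mat <- as.matrix(m)
  if (!all(mat %in% c(0, 1))) stop("wide incidence CSV must contain only 0/1")
  idx <- which(mat == 1, arr.ind = TRUE)
  sp <- rownames(mat)[idx[, 1]]
  pg <- colnames(mat)[idx[, 2]]
  status <- rep("native", nrow(idx))
  if (!is.null(status_path)) {
    st <- utils::read.csv(status_path, stringsAsFactors = FALSE,
                          colClasses = "character")
    nn <- st$status == "nonnative"
    key <- paste(sp, pg, sep = "\r")
    status[key %in% paste(st$species_id[nn], st$polygon_id[nn], sep = "\r")] <-
      "nonnative"
  }
  incidence_table(sp, pg, status)
}

#' Write an incidence table to CSV
#'
#' @param table an [incidence_table()].
#' @param path output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @param status_path for the wide dialect, where to write the status table.
#' @export
write_incidence <- function(table, path, dialect = c("long", "wide"),
                            status_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    utils::write.csv(table$occurrences, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  mat <- incidence_matrix(table, phase = "after")
  df <- data.frame(species_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(status_path)) {
    nn <- table$occurrences[table$occurrences$status == "nonnative", ,
                            drop = FALSE]
    utils::write.csv(nn, status_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Extract the before- or after-dispersal view of an incidence table
#'
#' The "before" view keeps native occurrences only (species ranges before
#' human-mediated dispersal); the "after" view keeps all occurrences.
#' Species with no occurrence left in a view are dropped from its species
#' index.
#'
#' @param table an [incidence_table()].
#' @param phase `"before"` or `"after"`.
#' @return An [incidence_table()].
#' @export
incidence_view <- function(table, phase = c("before", "after")) {
  phase <- match.arg(phase)
  occ <- table$occurrences
  if (phase == "before") occ <- occ[occ$status == "native", , drop = FALSE]
  incidence_table(occ$species_id, occ$polygon_id, occ$status)
}

#' Binary incidence matrix for a phase
#'
#' @param table an [incidence_table()].
#' @param phase `"before"` or `"after"`.
#' @return integer matrix, species in rows, polygons in columns; polygons
#'   with zero occurrences in the phase are absent.
#' @export
incidence_matrix <- function(table, phase = c("before", "after")) {
  phase <- match.arg(phase)
  occ <- table$occurrences
  if (phase == "before") occ <- occ[occ$status == "native", , drop = FALSE]
  sp <- sort(unique(occ$species_id))
  pg <- sort(unique(occ$polygon_id))
  mat <- matrix(0L, length(sp), length(pg), dimnames = list(sp, pg))
  mat[cbind(match(occ$species_id, sp), match(occ$polygon_id, pg))] <- 1L
  mat
}

#' Species that have at least one nonnative occurrence
#'
#' @param table an [incidence_table()].
#' @return character vector of species ids.
#' @export
nonnative_species <- function(table) {
  occ <- table$occurrences
  sort(unique(occ$species_id[occ$status == "nonnative"]))
}

#' Per-polygon richness and donor/recipient summaries
#'
#' For each polygon: native richness, nonnative (received) richness, the
#' number of non-native-capable species whose native range includes the
#' polygon (donated), and the ratio of nonnative to native richness
#' (`NA` where native richness is zero).
#'
#' @param table an [incidence_table()].
#' @param nonnative_sp character vector of non-native-capable species ids;
#'   defaults to species with >= 1 nonnative occurrence in `table`.
#' @return data.frame with columns `polygon_id`, `native_richness`,
#'   `nonnative_richness`, `donated`, `ratio`.
#' @export
polygon_summaries <- function(table, nonnative_sp = nonnative_species(table)) {
  unknown <- setdiff(nonnative_sp, table$species_ids)
  if (length(unknown)) {
    stop("unknown species id(s) in nonnative_sp: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  occ <- table$occurrences
  pg <- table$polygon_ids
  nat <- occ[occ$status == "native", , drop = FALSE]
  non <- occ[occ$status == "nonnative", , drop = FALSE]
  tab <- function(x) {
    out <- integer(length(pg)); names(out) <- pg
    t <- table(factor(x, levels = pg)); out[names(t)] <- as.integer(t); out
  }
  native_richness <- tab(nat$polygon_id)
  nonnative_richness <- tab(non$polygon_id)
  donated <- tab(nat$polygon_id[nat$species_id %in% nonnative_sp])
  ratio <- ifelse(native_richness > 0, nonnative_richness / native_richness, NA_real_)
  data.frame(polygon_id = pg,
             native_richness = unname(native_richness),
             nonnative_richness = unname(nonnative_richness),
             donated = unname(donated),
             ratio = unname(ratio),
             stringsAsFactors = FALSE)
}

#' Polygon metadata table
#'
#' Validates a per-polygon metadata table: centroid coordinates, the
#' island/mainland flag, a subcontinental region label (used downstream as
#' the mixed-model random effect), and a derived tropical flag based on the
#' centroid latitude.
#'
#' @param polygon_id character vector of unique polygon ids.
#' @param lon,lat centroid coordinates in decimal degrees.
#' @param is_island logical.
#' @param region character region labels.
#' @param tropic_lat latitude (degrees) of the tropical belt boundary;
#'   centroids with `abs(lat) <= tropic_lat` are tropical.
#' @return data.frame of class `polygon_metadata` with an added
#'   `is_tropical` column.
#' @export
polygon_metadata <- function(polygon_id, lon, lat, is_island, region,
                             tropic_lat = 23) {
  polygon_id <- as.character(polygon_id)
  if (anyDuplicated(polygon_id)) stop("duplicate polygon_id in metadata")
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("centroid coordinates out of range")
  }
  out <- data.frame(polygon_id = polygon_id, lon = as.numeric(lon),
                    lat = as.numeric(lat), is_island = as.logical(is_island),
                    region = as.character(region),
                    is_tropical = classify_tropical(lat, tropic_lat),
                    stringsAsFactors = FALSE)
  class(out) <- c("polygon_metadata", "data.frame")
  out
}

#' Read polygon metadata from CSV
#'
#' Expects columns `polygon_id`, `lon`, `lat`, `is_island`, `region`.
#'
#' @inheritParams read_incidence
#' @inheritParams polygon_metadata
#' @return a `polygon_metadata` data.frame.
#' @export
read_polygon_metadata <- function(path, tropic_lat = 23) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("polygon_id", "lon", "lat", "is_island", "region")
  if (!all(need %in% names(df))) {
    stop("metadata CSV must have columns ", paste(need, collapse = ", "))
  }
  polygon_metadata(df$polygon_id, df$lon, df$lat, df$is_island, df$region,
                   tropic_lat = tropic_lat)
}

#' Write polygon metadata to CSV (the derived tropical flag is dropped)
#'
#' @param meta a `polygon_metadata` data.frame.
#' @param path output CSV path.
#' @export
write_polygon_metadata <- function(meta, path) {
  utils::write.csv(meta[, c("polygon_id", "lon", "lat", "is_island", "region")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_metadata_covers <- function(meta, polygon_ids) {
  missing <- setdiff(polygon_ids, meta$polygon_id)
  if (length(missing)) {
    stop("metadata missing for polygon(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(TRUE)
}
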