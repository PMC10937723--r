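#' Configuration for the synthetic biogeographic world
#'
#' The generator plants `n_realms` compositionally distinct realms on a
#' lon/lat grid: each realm occupies its own longitude sector and latitude
#' band (bands recycle over a tropical/temperate template so the world
#' contains both tropical and non-tropical polygons), holds a mix of
#' mainland and island polygons, and hosts its own species pool with
#' log-uniform native range sizes. A bleed probability relocates single
#' occurrences into foreign realms, blurring boundaries. A biased
#' introduction process then emulates human-mediated dispersal: donor
#' species are drawn preferentially from tropical-mainland pools and
#' introductions land preferentially on tropical and island polygons.
#'
#' @param n_realms number of planted realms.
#' @param polygons_per_realm polygons per realm.
#' @param island_frac fraction of island polygons per realm.
#' @param species_per_realm species endemic to each realm pool.
#' @param range_min,range_max native range size bounds (polygons);
#'   sampled log-uniformly.
#' @param bleed probability that a single native occurrence falls outside
#'   the species' home realm.
#' @param nonnative_fraction fraction of species that become non-native.
#' @param lambda Poisson mean number of introductions per non-native
#'   species (truncated at 1).
#' @param recipient_tropical_weight,recipient_island_weight multiplicative
#'   sampling weights for introduction targets (a tropical island gets
#'   their product).
#' @param donor_tropical_mainland_weight sampling weight for
#'   tropical-mainland species when drawing the non-native pool.
#' @param seed integer seed; identical config and seed give a
#'   bit-identical world.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_realms = 5, polygons_per_realm = 100,
                         island_frac = 0.3, species_per_realm = 400,
                         range_min = 2, range_max = 50, bleed = 0.02,
                         nonnative_fraction = 0.02, lambda = 8,
                         recipient_tropical_weight = 2,
                         recipient_island_weight = 3,
                         donor_tropical_mainland_weight = 4,
                         seed = 1) {
  stopifnot(bleed >= 0, bleed < 1, n_realms >= 1, polygons_per_realm >= 2,
            species_per_realm >= 1, range_min >= 1,
            range_max <= polygons_per_realm,
            nonnative_fraction >= 0, nonnative_fraction <= 1,
            lambda > 0, recipient_tropical_weight > 0,
            recipient_island_weight > 0, donor_tropical_mainland_weight > 0)
  structure(as.list(environment()), class = "world_config")
}

#' Read a world configuration from a flat key-value file
#'
#' Lines of the form `key = value` (or `key: value`); keys match the
#' arguments of [world_config()]. Unknown keys are an error. Blank lines
#' and `#` comments are ignored.
#'
#' @param path file path.
#' @return a [world_config()].
#' @export
read_world_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  known <- names(formals(world_config))
  if (length(bad <- setdiff(keys, known))) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(world_config, stats::setNames(as.list(as.numeric(vals)), keys))
}

# latitude band template: tropical bands interleaved with north/south
# temperate ones, so even a 3-realm world has both tropical and
# non-tropical polygons
realm_lat_band <- function(r) {
  bands <- list(c(-20, 20), c(30, 55), c(-55, -30))
  template <- c(1, 2, 1, 3, 1)
  bands[[template[(r - 1) %% length(template) + 1]]]
}

#' Generate a synthetic world of planted realms
#'
#' @param config a [world_config()].
#' @return list with `table` (native-only [incidence_table()]), `meta`
#'   (`polygon_metadata`), and `realms` (named vector polygon -> planted
#'   realm id).
#' @export
generate_world <- function(config) {
  set.seed(config$seed)
  n_realms <- config$n_realms
  npr <- config$polygons_per_realm
  poly_realm <- rep(seq_len(n_realms), each = npr)
  n_poly <- length(poly_realm)
  pid <- sprintf("P%03d", seq_len(n_poly))
  lon <- lat <- numeric(n_poly)
  sector <- 360 / n_realms
  for (r in seq_len(n_realms)) {
    idx <- which(poly_realm == r)
    lon[idx] <- stats::runif(length(idx), -180 + (r - 1) * sector + 2,
                             -180 + r * sector - 2)
    band <- realm_lat_band(r)
    lat[idx] <- stats::runif(length(idx), band[1], band[2])
  }
  is_island <- unlist(lapply(seq_len(n_realms), function(r) {
    n_isl <- round(config$island_frac * npr)
    sample(c(rep(TRUE, n_isl), rep(FALSE, npr - n_isl)))
  }))
  region <- paste0("R", poly_realm, ifelse(is_island, "_isl", "_main"))
  meta <- polygon_metadata(pid, lon, lat, is_island, region)

  if (config$range_max > npr) stop("range_max exceeds polygons per realm")
  n_sp <- n_realms * config$species_per_realm
  sp_realm <- rep(seq_len(n_realms), each = config$species_per_realm)
  sizes <- pmax(1, round(exp(stats::runif(
    n_sp, log(config$range_min), log(config$range_max)))))
  occ_sp <- vector("list", n_sp)
  occ_pg <- vector("list", n_sp)
  for (s in seq_len(n_sp)) {
    home <- which(poly_realm == sp_realm[s])
    take <- sample(home, sizes[s])
    if (config$bleed > 0) {
      out <- stats::runif(sizes[s]) < config$bleed
      if (any(out)) {
        foreign <- which(poly_realm != sp_realm[s])
        take[out] <- sample(foreign, sum(out))
      }
    }
    occ_sp[[s]] <- rep(sprintf("S%05d", s), length(take))
    occ_pg[[s]] <- pid[take]
  }
  table <- incidence_table(unlist(occ_sp), unlist(occ_pg),
                           rep("native", length(unlist(occ_sp))))
  list(table = table, meta = meta,
       realms = stats::setNames(poly_realm, pid),
       species_realm = stats::setNames(sp_realm, sprintf("S%05d", seq_len(n_sp))))
}

#' Add biased non-native introductions to a synthetic world
#'
#' Samples the non-native-capable species pool with a donor bias toward
#' tropical-mainland species, then gives each a truncated-Poisson number
#' of introductions to polygons outside its native range, with recipient
#' weights favouring tropical and island polygons.
#'
#' @param world output of [generate_world()].
#' @param config the same [world_config()].
#' @return list like `world` but with `table` containing the nonnative
#'   occurrences and `nonnative_species` listing the introduced species.
#' @export
generate_introductions <- function(world, config) {
  set.seed(config$seed + 1L)
  table <- world$table
  meta <- world$meta
  occ <- table$occurrences
  sp <- table$species_ids
  n_nn <- round(config$nonnative_fraction * length(sp))
  if (n_nn == 0) {
    return(c(world, list(nonnative_species = character(0))))
  }
  # donor bias: species whose home realm band is tropical and whose native
  # range is mostly on mainlands
  tropical_poly <- stats::setNames(meta$is_tropical, meta$polygon_id)
  island_poly <- stats::setNames(meta$is_island, meta$polygon_id)
  frac_main <- vapply(split(occ$polygon_id, occ$species_id), function(p) {
    mean(!island_poly[p])
  }, numeric(1))[sp]
  frac_trop <- vapply(split(occ$polygon_id, occ$species_id), function(p) {
    mean(tropical_poly[p])
  }, numeric(1))[sp]
  w_donor <- ifelse(frac_trop > 0.5 & frac_main > 0.5,
                    config$donor_tropical_mainland_weight, 1)
  nn_sp <- sample(sp, n_nn, prob = w_donor)

  w_rec <- ifelse(meta$is_tropical, config$recipient_tropical_weight, 1) *
    ifelse(meta$is_island, config$recipient_island_weight, 1)
  new_sp <- new_pg <- list()
  ranges <- split(occ$polygon_id, occ$species_id)
  for (s in nn_sp) {
    candidates <- setdiff(meta$polygon_id, ranges[[s]])
    if (!length(candidates)) next
    k <- min(max(1, stats::rpois(1, config$lambda)), length(candidates))
    targets <- sample(candidates, k,
                      prob = w_rec[match(candidates, meta$polygon_id)])
    new_sp[[s]] <- rep(s, k)
    new_pg[[s]] <- targets
  }
  table2 <- incidence_table(
    c(occ$species_id, unlist(new_sp)),
    c(occ$polygon_id, unlist(new_pg)),
    c(occ$status, rep("nonnative", length(unlist(new_sp)))))
  out <- world
  out$table <- table2
  out$nonnative_species <- sort(nn_sp)
  out
}
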