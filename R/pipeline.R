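#' Restrict an incidence table to a set of polygons and/or species
#'
#' @param table an [incidence_table()].
#' @param polygons,species identifiers to keep (`NULL` = keep all).
#' @return an [incidence_table()].
#' @export
subset_incidence <- function(table, polygons = NULL, species = NULL) {
  occ <- table$occurrences
  if (!is.null(polygons)) occ <- occ[occ$polygon_id %in% polygons, , drop = FALSE]
  if (!is.null(species)) occ <- occ[occ$species_id %in% species, , drop = FALSE]
  if (!nrow(occ)) stop("empty table after subsetting")
  incidence_table(occ$species_id, occ$polygon_id, occ$status)
}

#' Run the full before/after biogeographic analysis
#'
#' Orchestrates the complete analysis for one geographic focus and one
#' species dataset: turnover matrices before and after human-mediated
#' dispersal, permutation-tested UPGMA realms for both phases, the
#' homogenization index with stratified summaries, the rank-based
#' two-way ANOVA of mean homogenization on island and tropical status,
#' pairwise Wilcoxon tests and count GLMMs for donated/received species,
#' and Mantel plus distance-decay analyses before and after.
#'
#' Turnover is recomputed within the focus subset (a mainland run uses
#' only mainland polygons), matching the separate mainland and island
#' analyses of the study design.
#'
#' @param table an [incidence_table()] with native/nonnative status.
#' @param meta a `polygon_metadata` covering the table's polygons.
#' @param focus `"global"`, `"mainland"` or `"island"`.
#' @param dataset `"all_species"` or `"nonnative_only"` (restricts the
#'   pool to species with at least one nonnative occurrence).
#' @param n_perm permutations for node significance and Mantel tests.
#' @param alpha significance level for the realm cut.
#' @param seed integer seed controlling every stochastic stage.
#' @param fit_glmms fit the count GLMMs (the slowest stage).
#' @param out_dir optional directory; when given, all result tables are
#'   written as CSV/JSON and the run manifest is recorded.
#' @return a list bundle with elements `beta_before`, `beta_after`,
#'   `realms_before`, `realms_after`, `homogenization`, `strata`, `srh`,
#'   `wilcoxon`, `glmm_received`, `glmm_donated`, `mantel_before`,
#'   `mantel_after`, `decay_before`, `decay_after`, `summaries`,
#'   `manifest`.
#' @export
run_full <- function(table, meta, focus = c("global", "mainland", "island"),
                     dataset = c("all_species", "nonnative_only"),
                     n_perm = 99, alpha = 0.05, seed = 1,
                     fit_glmms = TRUE, out_dir = NULL) {
  focus <- match.arg(focus)
  dataset <- match.arg(dataset)
  check_metadata_covers(meta, table$polygon_ids)
  nn_sp <- nonnative_species(table)
  keep_poly <- switch(focus,
    global = meta$polygon_id,
    mainland = meta$polygon_id[!meta$is_island],
    island = meta$polygon_id[meta$is_island])
  keep_sp <- if (dataset == "nonnative_only") nn_sp else NULL
  tab <- subset_incidence(table, polygons = keep_poly, species = keep_sp)

  tree_b <- node_significance(tab, "before", n_perm = n_perm, seed = seed)
  realms_b <- cut_significant(tree_b, alpha = alpha)
  tree_a <- node_significance(tab, "after", n_perm = n_perm, seed = seed + 1L)
  realms_a <- cut_significant(tree_a, alpha = alpha)

  beta_b <- beta_sim_matrix(tab, "before")
  beta_a <- beta_sim_matrix(tab, "after")
  hom <- suppressWarnings(homogenization_matrix(beta_b, beta_a))
  strat <- stratify_homogenization(hom, meta)
  poly <- strat$polygons
  srh <- scheirer_ray_hare(poly$h_bar, poly$is_island, poly$is_tropical)

  summ <- polygon_summaries(tab, nn_sp[nn_sp %in% tab$species_ids])
  summ <- merge(summ, meta[, c("polygon_id", "is_island", "is_tropical",
                               "region")], by = "polygon_id")
  stratum4 <- interaction(ifelse(summ$is_tropical, "tropical", "nontropical"),
                          ifelse(summ$is_island, "island", "mainland"),
                          drop = TRUE)
  wil <- list(
    received = pairwise_wilcoxon(summ$nonnative_richness, stratum4),
    donated = pairwise_wilcoxon(summ$donated, stratum4))

  glmm_rec <- glmm_don <- NULL
  if (fit_glmms && length(unique(summ$region)) >= 2) {
    glmm_rec <- tryCatch(
      select_count_glmm(summ$nonnative_richness, summ$is_tropical,
                        summ$is_island, summ$region),
      error = function(e) NULL)
    glmm_don <- tryCatch(
      select_count_glmm(summ$donated, summ$is_tropical, summ$is_island,
                        summ$region),
      error = function(e) NULL)
  }

  dist_m <- great_circle_matrix(meta[match(rownames(hom$h), meta$polygon_id), ])
  lbl <- rownames(hom$h)
  mant_b <- mantel_test(beta_b[lbl, lbl], dist_m, n_perm = n_perm,
                        seed = seed + 2L)
  mant_a <- mantel_test(beta_a[lbl, lbl], dist_m, n_perm = n_perm,
                        seed = seed + 3L)
  decay_b <- fit_distance_decay(similarity_matrix(beta_b[lbl, lbl]), dist_m)
  decay_a <- fit_distance_decay(similarity_matrix(beta_a[lbl, lbl]), dist_m)

  manifest <- list(focus = focus, dataset = dataset, n_perm = n_perm,
                   alpha = alpha, seed = seed,
                   n_polygons = length(tab$polygon_ids),
                   n_species = length(tab$species_ids),
                   version = as.character(utils::packageVersion("antbiogeo")))
  bundle <- list(beta_before = beta_b, beta_after = beta_a,
                 realms_before = realms_b, realms_after = realms_a,
                 homogenization = hom, strata = strat, srh = srh,
                 wilcoxon = wil, glmm_received = glmm_rec,
                 glmm_donated = glmm_don, mantel_before = mant_b,
                 mantel_after = mant_a, decay_before = decay_b,
                 decay_after = decay_a, summaries = summ,
                 manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_square_csv(bundle$beta_before, p("beta_before.csv"))
  write_square_csv(bundle$beta_after, p("beta_after.csv"))
  write_square_csv(bundle$homogenization$h, p("h_matrix.csv"))
  write_realms(bundle$realms_before, p("realms_before.csv"))
  write_realms(bundle$realms_after, p("realms_after.csv"))
  upgma_newick(bundle$realms_before$tree, p("tree_before.nwk"))
  upgma_newick(bundle$realms_after$tree, p("tree_after.nwk"))
  write_homogenization(bundle$strata, p("homogenization_polygons.csv"))
  utils::write.csv(bundle$strata$strata, p("homogenization_strata.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$srh), p("srh.csv"), row.names = FALSE)
  utils::write.csv(bundle$summaries, p("polygon_summaries.csv"),
                   row.names = FALSE)
  stats_json <- list(
    manifest = bundle$manifest,
    mantel_before = unclass(bundle$mantel_before),
    mantel_after = unclass(bundle$mantel_after),
    decay_before = unclass(bundle$decay_before),
    decay_after = unclass(bundle$decay_after),
    glmm_received = if (!is.null(bundle$glmm_received))
      bundle$glmm_received$table,
    glmm_donated = if (!is.null(bundle$glmm_donated))
      bundle$glmm_donated$table)
  jsonlite::write_json(stats_json, p("stats.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' Adjusted Rand index between two realm assignments
#'
#' Convenience wrapper around [adjusted_rand_index()] taking the
#' intersection of the polygon sets.
#'
#' @param a,b `realm_assignment`s or named label vectors.
#' @return numeric scalar.
#' @export
compare_assignments <- function(a, b) adjusted_rand_index(a, b)
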