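# Independent oracles and fixture builders used across the suite.

# brute-force Simpson turnover from explicit species sets
oracle_beta_pair <- function(A, B) {
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  c <- length(setdiff(B, A))
  1 - a / (min(b, c) + a)
}

oracle_beta_matrix <- function(sets) {
  n <- length(sets)
  out <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[i, j] <- oracle_beta_pair(sets[[i]], sets[[j]])
    }
  }
  out
}

# random incidence table; returns both the table and the per-polygon sets
random_incidence <- function(n_species, n_polygons, p = 0.35,
                             nonnative_frac = 0) {
  sp <- sprintf("s%02d", seq_len(n_species))
  pg <- sprintf("p%02d", seq_len(n_polygons))
  repeat {
    occ <- which(matrix(runif(n_species * n_polygons) < p,
                        n_species, n_polygons), arr.ind = TRUE)
    # every polygon and species non-empty so beta is defined everywhere
    if (length(unique(occ[, 2])) == n_polygons &&
        length(unique(occ[, 1])) == n_species) break
  }
  status <- rep("native", nrow(occ))
  if (nonnative_frac > 0) {
    status[runif(nrow(occ)) < nonnative_frac] <- "nonnative"
  }
  tab <- incidence_table(sp[occ[, 1]], pg[occ[, 2]], status)
  sets <- lapply(pg, function(g) {
    o <- tab$occurrences
    sort(unique(o$species_id[o$polygon_id == g]))
  })
  names(sets) <- pg
  list(table = tab, sets = sets)
}

# small planted-block incidence matrix: `k` blocks of `npg` polygons with
# `nsp` endemic species each, ranges sampled within the block
planted_blocks <- function(k, npg, nsp, range = c(2, npg)) {
  sp <- pg <- character(0)
  for (b in seq_len(k)) {
    for (s in seq_len(nsp)) {
      size <- sample(range[1]:range[2], 1)
      polys <- sample(npg, size)
      sp <- c(sp, rep(sprintf("b%d_s%03d", b, s), size))
      pg <- c(pg, sprintf("b%d_p%02d", b, polys))
    }
  }
  incidence_table(sp, pg, rep("native", length(sp)))
}

# structureless table: every species' range a uniform subset of all polygons
structureless_table <- function(n_species, n_polygons, range = c(2, 6)) {
  sp <- pg <- character(0)
  for (s in seq_len(n_species)) {
    size <- sample(range[1]:range[2], 1)
    sp <- c(sp, rep(sprintf("s%03d", s), size))
    pg <- c(pg, sprintf("p%02d", sample(n_polygons, size)))
  }
  incidence_table(sp, pg, rep("native", length(sp)))
}
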