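test_that("UPGMA on tiny hand-worked matrices", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.4)

  d3 <- matrix(c(0, 0.1, 0.5,
                 0.1, 0, 0.5,
                 0.5, 0.5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3$height, c(0.1, 0.5))
  expect_error(upgma(matrix(c(0, NaN, NaN, 0), 2, 2)), "NaN|symmetric")
})

test_that("UPGMA matches the reference agglomeration on random matrices", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 7
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    dimnames(m) <- list(letters[1:n], letters[1:n])
    got <- upgma(m)
    ref <- stats::hclust(stats::as.dist(m), method = "average")
    expect_equal(got$height, ref$height, tolerance = 1e-12)
    # same clusters at every k
    for (k in 2:(n - 1)) {
      expect_equal(adjusted_rand_index(
        stats::cutree(got, k), stats::cutree(ref, k)), 1)
    }
  }
})

test_that("UPGMA trees are ultrametric (three-point condition)", {
  set.seed(31)
  ri <- random_incidence(25, 9)
  tree <- upgma(beta_sim_matrix(ri$table, "before"))
  coph <- as.matrix(stats::cophenetic(tree))
  n <- nrow(coph)
  for (t in 1:100) {
    ijk <- sample(n, 3)
    d3 <- sort(c(coph[ijk[1], ijk[2]], coph[ijk[1], ijk[3]],
                 coph[ijk[2], ijk[3]]))
    expect_lte(d3[2], d3[3] + 1e-12)
    expect_equal(d3[2], d3[3], tolerance = 1e-9)  # two largest equal
  }
  # heights non-decreasing from leaves to root
  expect_true(all(diff(tree$height) >= -1e-12))
})

test_that("tie-break makes the tree invariant to input order", {
  set.seed(41)
  tab <- planted_blocks(2, 5, 12)
  b <- beta_sim_matrix(tab, "before")
  perm <- sample(nrow(b))
  t1 <- upgma(b)
  t2 <- upgma(b[perm, perm])
  expect_equal(t1$height, t2$height, tolerance = 1e-12)
  c1 <- stats::cutree(t1, 2)
  c2 <- stats::cutree(t2, 2)
  expect_equal(adjusted_rand_index(c1, c2[names(c1)]), 1)
})

test_that("permutation p-values: formula edge cases and planted separation", {
  set.seed(51)
  tab <- structureless_table(30, 10)
  tr <- node_significance(tab, "before", n_perm = 1, seed = 1)
  expect_true(all(tr$p_value %in% c(0.5, 1)))

  # two fully separated blocks: the root gap is maximal under the spec's
  # gap-above-taller-child statistic
  tab2 <- planted_blocks(2, 6, 15)
  tr2 <- node_significance(tab2, "before", n_perm = 99, seed = 2,
                           statistic = "max_child")
  root_p <- tr2$p_value[tr2$rank == 1]
  expect_equal(root_p, 1 / 100)
  # and the cohesion statistic flags both block roots
  tr3 <- node_significance(tab2, "before", n_perm = 99, seed = 3)
  asn <- cut_significant(tr3)
  expect_equal(asn$k, 2)
})

test_that("cut_significant falls back to one realm without significance", {
  set.seed(61)
  tab <- structureless_table(40, 12)
  tr <- node_significance(tab, "before", n_perm = 49, seed = 5)
  tr$p_value[] <- 1  # force: no node significant
  asn <- cut_significant(tr)
  expect_equal(asn$k, 1)
  expect_true(all(asn$realm == 1))
  expect_error(cut_significant(upgma(beta_sim_matrix(tab, "before"))),
               "no p-values")
})

test_that("planted realms are recovered and written correctly", {
  cfg <- world_config(n_realms = 4, polygons_per_realm = 15,
                      species_per_realm = 60, range_max = 12, bleed = 0,
                      seed = 9)
  w <- generate_world(cfg)
  tr <- node_significance(w$table, "before", n_perm = 99, seed = 10)
  asn <- cut_significant(tr)
  expect_equal(asn$k, 4)
  expect_equal(adjusted_rand_index(asn$realm, w$realms), 1)

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_realms(asn, tmp)
  df <- utils::read.csv(tmp)
  expect_equal(nrow(df), length(asn$realm))
  expect_equal(unique(df$k), 4)

  nwk <- upgma_newick(tr)
  expect_match(nwk, "^\\(.*\\);$")
  tree_ape <- ape::read.tree(text = nwk)
  expect_setequal(tree_ape$tip.label, names(asn$realm))
  # ultrametric serialization: every root-to-tip depth equals root height
  depths <- ape::node.depth.edgelength(tree_ape)[seq_along(tree_ape$tip.label)]
  expect_equal(unname(depths), rep(max(tr$height), length(depths)),
               tolerance = 1e-6)
})

test_that("cluster diagnostics recover planted k and degenerate bounds", {
  set.seed(71)
  tab <- planted_blocks(2, 8, 20)
  b <- beta_sim_matrix(tab, "before")
  tree <- upgma(b)
  diag2 <- cluster_diagnostics(b, tree, 2:6)
  expect_equal(diag2$best$silhouette, 2)
  # k = n-1: within-cluster spread collapses toward zero
  dn <- cluster_diagnostics(b, tree, nrow(b) - 1)
  expect_lt(dn$table$within, diag2$table$within[1])
  expect_error(cluster_diagnostics(b, tree, integer(0)), "empty k_range")
  expect_error(cluster_diagnostics(b, tree, c(1, 2)), "k_range outside")

  # homogeneous cloud: silhouette low for all k
  tab0 <- structureless_table(60, 14, range = c(4, 9))
  b0 <- beta_sim_matrix(tab0, "before")
  d0 <- cluster_diagnostics(b0, upgma(b0), 2:6)
  expect_true(all(d0$table$silhouette < 0.25))
})

test_that("adjusted Rand index agrees with the contingency formula", {
  expect_equal(adjusted_rand_index(c(a = 1, b = 1, c = 2),
                                   c(a = 5, b = 5, c = 9)), 1)
  # all-singletons vs one-cluster: expectation-adjusted value <= 0
  n <- 8
  x <- setNames(seq_len(n), letters[1:n])
  y <- setNames(rep(1, n), letters[1:n])
  expect_lte(adjusted_rand_index(x, y), 0)
  # independent random labelings average about zero
  set.seed(81)
  aris <- replicate(100, {
    adjusted_rand_index(setNames(sample(3, 30, TRUE), 1:30),
                        setNames(sample(3, 30, TRUE), 1:30))
  })
  expect_lt(abs(mean(aris)), 0.05)
  expect_error(adjusted_rand_index(c(a = 1), c(b = 1)), "no common")
})

test_that("subset sensitivity: full pool gives ARI 1, small pools vary", {
  cfg <- world_config(n_realms = 3, polygons_per_realm = 10,
                      species_per_realm = 50, range_max = 8, bleed = 0,
                      seed = 13)
  w <- generate_world(cfg)
  n_sp <- length(w$table$species_ids)
  res <- subset_sensitivity(w$table, sizes = c(15, n_sp), reps = 3,
                            n_perm = 49, seed = 14)
  full_row <- res$summary[res$summary$size == n_sp, ]
  expect_equal(full_row$mean_ari, 1)
  small_row <- res$summary[res$summary$size == 15, ]
  expect_lt(small_row$mean_ari, 1)
  expect_error(subset_sensitivity(w$table, sizes = n_sp + 1, reps = 1),
               "exceeds")
})
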