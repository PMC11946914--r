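test_that("simulate_tree is deterministic and matches the Yule depth oracle", {
  expect_error(simulate_tree(1L), "n_tips")
  t2 <- simulate_tree(2L, seed = 1L)
  expect_equal(length(t2$tip.label), 2L)  # single cherry

  expect_identical(write_newick(simulate_tree(40L, seed = 7L)),
                   write_newick(simulate_tree(40L, seed = 7L)))
  expect_false(identical(write_newick(simulate_tree(40L, seed = 7L)),
                         write_newick(simulate_tree(40L, seed = 8L))))

  # analytic Yule oracle: E[root-to-tip depth] = sum(1/k, k = 2..n) at birth 1
  n <- 200L
  expected <- sum(1 / (2:n))
  depths <- vapply(1:20, function(s) {
    tr <- simulate_tree(n, seed = 100L + s)
    mean(ape::node.depth.edgelength(tr)[seq_len(n)])
  }, numeric(1))
  # s.d. of one tree's depth is sqrt(sum(1/k^2)) ~ 0.8; 20 replicates
  expect_lt(abs(mean(depths) - expected), 4 * 0.8 / sqrt(20))
  # trees are ultrametric by construction
  tr <- simulate_tree(50L, seed = 12L)
  tipd <- ape::node.depth.edgelength(tr)[1:50]
  expect_lt(diff(range(tipd)), 1e-9)
})

test_that("simulate_traits honours degenerate and structured configurations", {
  tree <- simulate_tree(60L, seed = 4L)
  # arr_sd = 0: all slopes exactly arr_mean
  cfg0 <- sim_config(n_species = 60L, arr_sd = 0, seed = 3L)
  tr0 <- simulate_traits(tree, cfg0)
  expect_true(all(tr0$species$slope == cfg0$arr_mean))

  # lambda_true = 0: intercepts independent across the phylogeny
  # oracle: mean correlation between phylogenetically close pairs ~ 0
  cfgL0 <- sim_config(n_species = 60L, lambda_true = 0, seed = 3L)
  D <- ape::cophenetic.phylo(tree)
  close_pairs <- which(D < stats::quantile(D[D > 0], 0.1), arr.ind = TRUE)
  close_pairs <- close_pairs[close_pairs[, 1] < close_pairs[, 2], , drop = FALSE]
  diffs <- vapply(1:100, function(r) {
    cfg_r <- cfgL0; cfg_r$seed <- r
    x <- simulate_traits(tree, cfg_r)$species$intercept
    # with no phylogenetic signal close pairs are no more similar than random
    mean(abs(x[close_pairs[, 1]] - x[close_pairs[, 2]])) - mean(abs(outer(x, x, "-")))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.25)
})

test_that("trait tables have the stated missingness and recoverable slopes", {
  tree <- simulate_tree(300L, seed = 21L)
  cfg <- sim_config(n_species = 300L, seed = 21L)
  truth <- simulate_traits(tree, cfg)
  tab <- simulate_trait_table(truth, cfg)
  # species-level missingness within 1% of prop_missing
  sp_missing <- tapply(is.na(tab$ctmax), tab$species, all)
  expect_lt(abs(mean(sp_missing) - cfg$prop_missing), 0.01)
  # ctmax present implies se present
  expect_true(all(!is.na(tab$ctmax_se[!is.na(tab$ctmax)])))

  # prop_missing = 0: every species measured
  cfg0 <- sim_config(n_species = 50L, prop_missing = 0, seed = 5L)
  tab0 <- simulate_trait_table(simulate_traits(simulate_tree(50L, seed = 5L),
                                               cfg0), cfg0)
  expect_true(all(tapply(!is.na(tab0$ctmax), tab0$species, any)))

  # OLS oracle: within-species regression of CT_max on t_acc recovers the
  # acclimatization response ratio
  ok <- !is.na(tab$ctmax) & !is.na(tab$t_acc)
  d <- tab[ok, ]
  nrec <- table(d$species)
  d <- d[d$species %in% names(nrec)[nrec >= 5], ]
  slopes <- vapply(split(d, d$species), function(g)
    stats::coef(stats::lm(ctmax ~ t_acc, data = g))[2], numeric(1))
  expect_lt(abs(mean(slopes) - cfg$arr_mean), 0.05)

  # slope spread: truth s.d. within 20% of arr_sd at n >= 300
  expect_lt(abs(stats::sd(truth$species$slope) - cfg$arr_sd), 0.2 * cfg$arr_sd)
})

test_that("simulate_ranges stays on the grid and is reproducible", {
  grid <- list(lat = c(-10L, 10L), lon = c(0L, 3L))
  occ <- simulate_ranges(30L, grid, seed = 9L, k = 4L)
  expect_true(all(occ$lat >= -10 & occ$lat <= 10))
  expect_true(all(occ$lon >= 0 & occ$lon <= 3))
  expect_identical(occ, simulate_ranges(30L, grid, seed = 9L, k = 4L))
  # k = 1: every species in exactly one cell
  occ1 <- simulate_ranges(30L, grid, seed = 9L, k = 1L)
  expect_true(all(table(occ1$species) == 1L))
  # bands are contiguous in latitude within one longitude column
  by_sp <- split(occ, occ$species)
  expect_true(all(vapply(by_sp, function(d) {
    length(unique(d$lon)) == 1L &&
      all(diff(sort(d$lat)) == 1)
  }, logical(1))))
})

test_that("operative temperatures: additive offsets, variance ordering, determinism", {
  cells <- data.frame(cell_id = cell_id_of(c(0, 15, -20), c(0, 1, 2)),
                      lat = c(0.5, 15.5, -19.5), lon = c(0.5, 1.5, 2.5))
  yrs <- 2005:2008
  t0 <- simulate_operative_temps(cells, yrs, "terrestrial", 0, seed = 3L)
  t4 <- simulate_operative_temps(cells, yrs, "terrestrial", 4, seed = 3L)
  expect_equal(t4$daily_max - t0$daily_max, rep(4, nrow(t0)))

  expect_identical(t0, simulate_operative_temps(cells, yrs, "terrestrial", 0,
                                                seed = 3L))
  expect_error(simulate_operative_temps(cells, yrs, "burrow", 0), "unknown")

  arb <- simulate_operative_temps(cells, yrs, "arboreal", 0, seed = 3L)
  aqu <- simulate_operative_temps(cells, yrs, "aquatic", 0, seed = 3L)
  for (cid in cells$cell_id) {
    s_ter <- stats::sd(t0$daily_max[t0$cell_id == cid])
    s_arb <- stats::sd(arb$daily_max[arb$cell_id == cid])
    s_aqu <- stats::sd(aqu$daily_max[aqu$cell_id == cid])
    expect_lt(s_aqu, s_arb)
    expect_lt(s_arb, s_ter)
  }
  # per-cell streams: a subset of cells reproduces the same series
  sub <- simulate_operative_temps(cells[2, ], yrs, "terrestrial", 0, seed = 3L)
  expect_equal(sub$daily_max, t0$daily_max[t0$cell_id == cells$cell_id[2]])
})

test_that("simulate_inputs writes a complete deterministic bundle", {
  cfg <- sim_config(n_species = 8L, grid = list(lat = c(0L, 3L), lon = c(0L, 1L)),
                    years = 2005:2007, seed = 13L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_inputs(cfg, dir = d1, microhabitats = "terrestrial")
  simulate_inputs(cfg, dir = d2, microhabitats = "terrestrial")
  for (f in c("tree.nwk", "traits.csv", "occurrences.csv",
              "temps_terrestrial_current.csv", "sim_config.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
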