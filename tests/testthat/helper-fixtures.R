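# Shared fixtures. Heavy objects are built once per test run and cached so
# several test files can reuse the same model fits / pipeline output.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the spec's 3-tip hand-checkable tree
three_tip_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# fast MCMC settings for unit-scale fits
fast_mcmc <- function(n = 800L, burn = 300L)
  hm_mcmc_control(n, burn, 2L, lambda_grid_n = 41L)

# a small complete (no missing CT_max) synthetic world + one model fit
small_fit_world <- function() fixture("small_fit_world", function() {
  cfg <- sim_config(n_species = 80L, prop_missing = 0, seed = 42L)
  tree <- simulate_tree(cfg$n_species, seed = 5L)
  truth <- simulate_traits(tree, cfg)
  tab <- initialize_missing(simulate_trait_table(truth, cfg), seed = 2L)
  fit <- fit_phylo_mixed_model(tab, tree, mcmc = fast_mcmc(), seed = 9L)
  list(cfg = cfg, tree = tree, truth = truth, tab = tab, fit = fit)
})

# a moderate full pipeline run reused by assemblage / acceptance tests
small_pipeline <- function() fixture("small_pipeline", function() {
  cfg <- run_config(
    sim = sim_config(n_species = 40L,
                     grid = list(lat = c(-25L, 25L), lon = c(0L, 2L)),
                     seed = 11L),
    n_cycles = 2L,
    mcmc = fast_mcmc(700L, 250L),
    mcmc_cycle = fast_mcmc(400L, 150L),
    mcmc_sub = hm_mcmc_control(300L, 100L, 2L, lambda_grid_n = 21L))
  run_full_pipeline(cfg)
})
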