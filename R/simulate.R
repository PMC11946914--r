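#' Simulation configuration
#'
#' Bundles every knob of the synthetic world. Defaults mirror the published
#' amphibian compilation this generator emulates: 89.9% of species with no
#' heat-tolerance data, phylogenetic heritability (Pagel's lambda) 0.95,
#' species-level acclimatization response ratio 0.134 +/- 0.008 (degC/degC),
#' grand CT_max near 36.2 degC, daily operative temperature series for
#' 2005-2015 (first year a burn-in) under +0/+2/+4 degC uniform warming, and
#' microhabitat variance ordering aquatic < arboreal < terrestrial.
#'
#' @param n_species number of species (tree tips).
#' @param prop_missing proportion of species whose CT_max records are all
#'   masked (data-deficient species). Must be < 1.
#' @param lambda_true phylogenetic proportion of the species-level variance.
#' @param arr_mean,arr_sd mean and s.d. of species acclimatization response
#'   ratios (slope of CT_max on acclimatization temperature, degC/degC).
#' @param ctmax_mean grand mean CT_max (degC) at the reference acclimatization
#'   temperature `ref_t_acc`.
#' @param phylo_sd total species-level (non-residual) s.d. of CT_max (degC);
#'   split between phylogenetic and independent parts by `lambda_true`.
#' @param residual_sd within-species process s.d. (degC) beyond sampling error.
#' @param ref_t_acc acclimatization temperature (degC) at which species
#'   intercepts are defined.
#' @param grid list with integer-degree `lat` and `lon` extents (1-degree
#'   cells centred on the half-degree).
#' @param years calendar years simulated; the first is the burn-in.
#' @param warming_offsets uniform warming offsets (degC) defining scenarios.
#' @param seed master seed; fully determines every generated table.
#' @param ... overrides for the less commonly touched entries (record counts,
#'   sampling-error distribution, methodological effect sizes, climate
#'   parameters); see the package vignette.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_species = 500L, prop_missing = 0.899,
                       lambda_true = 0.95, arr_mean = 0.134, arr_sd = 0.008,
                       ctmax_mean = 36.2, phylo_sd = 2.4, residual_sd = 0.3,
                       ref_t_acc = 20,
                       grid = list(lat = c(-30L, 30L), lon = c(0L, 4L)),
                       years = 2005:2015, warming_offsets = c(0, 2, 4),
                       seed = 1L, ...) {
  cfg <- list(
    n_species = as.integer(n_species), prop_missing = prop_missing,
    lambda_true = lambda_true, arr_mean = arr_mean, arr_sd = arr_sd,
    ctmax_mean = ctmax_mean, phylo_sd = phylo_sd, residual_sd = residual_sd,
    ref_t_acc = ref_t_acc, grid = grid, years = as.integer(years),
    warming_offsets = warming_offsets, seed = as.integer(seed),
    records_range = c(1L, 10L),
    prop_covariate_missing = 0.10,
    se_meanlog = log(0.4), se_sdlog = 0.6, se_floor = 0.05,
    k_range_cells = 5L,
    slope_intercept_cor = 0,
    method_effects = list(
      endpoint = c(onset_of_spasms = 0, loss_of_righting = -0.8, other = 0.4),
      medium = c(water = 0, air = 0.6),
      life_stage = c(adult = 0, larva = -1.2),
      ecotype = c("ground-dwelling" = 0, fossorial = -0.3, aquatic = 0.5,
                  "semi-aquatic" = 0.3, "stream-dwelling" = -0.2,
                  arboreal = -0.4),
      duration_per_day = -0.02,  # centred at 10 d
      ramp_per_unit = 0.3,       # centred at 1 degC/min
      log_mass = 0.15            # centred at log(5 g)
    ),
    climate = list(base_t = 27, base_lat_slope = -0.22,
                   seas_amp0 = 3, seas_amp_slope = 0.20,
                   ar_phi = 0.7, noise_sd = 2.2, noise_df = 5,
                   arboreal_damp = 0.75, arboreal_offset = -0.8,
                   aquatic_damp = 0.65, aquatic_alpha = 0.25,
                   aquatic_offset = -1.5)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$prop_missing >= 1 || cfg$prop_missing < 0) stop("prop_missing must be in [0, 1)")
  if (cfg$lambda_true < 0 || cfg$lambda_true > 1) stop("lambda_true must be in [0, 1]")
  if (cfg$arr_mean < 0 || cfg$arr_mean > 1) stop("arr_mean outside plausible [0, 1]")
  if (length(cfg$years) < 2L) stop("need >= 2 years (the first is the burn-in)")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_species, "species,", round(100 * x$prop_missing, 1),
      "% data-deficient, lambda_true =", x$lambda_true,
      ", ARR =", x$arr_mean, "+/-", x$arr_sd, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Small polynomial hash (mod 2^31 - 2) so each cell/stage draws from its own
#' stream: generating a subset of cells reproduces each cell's series exactly.
#'
#' @param seed master integer seed
#' @param ... labels (coerced to character) identifying the stream
#' @return integer seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483646 + 1)
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Grow-to-n construction: while k lineages are extant the waiting time to the
#' next speciation is Exponential(k * birth) and a uniformly chosen lineage
#' splits, so the expected root-to-tip depth is `sum(1/(birth*k), k=2..n)`.
#' The tree is ultrametric with contemporaneous tips.
#'
#' @param n_tips number of tips (>= 2)
#' @param seed integer seed
#' @param birth speciation rate (per lineage per unit time)
#' @return a `phylo` object with tips labelled `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_tips, seed = 1L, birth = 1) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be an integer >= 2")
  set.seed(as.integer(seed))
  n_max <- 2L * n_tips - 1L
  kid1 <- integer(n_max); kid2 <- integer(n_max)
  btime <- numeric(n_max); stime <- rep(NA_real_, n_max)
  # node 1 is the root, splitting at time 0 into lineages 2 and 3
  stime[1] <- 0; kid1[1] <- 2L; kid2[1] <- 3L
  active <- c(2L, 3L); nxt <- 4L; k <- 2L; t <- 0
  while (k < n_tips) {
    t <- t + stats::rexp(1L, rate = birth * k)
    i <- active[sample.int(k, 1L)]
    stime[i] <- t; kid1[i] <- nxt; kid2[i] <- nxt + 1L
    btime[nxt] <- t; btime[nxt + 1L] <- t
    active <- c(active[active != i], nxt, nxt + 1L)
    nxt <- nxt + 2L
    k <- k + 1L
  }
  t_end <- t + stats::rexp(1L, rate = birth * k)
  wd <- max(3L, nchar(n_tips))
  tip_counter <- 0L
  nwk <- function(i) {
    if (kid1[i] == 0L) {
      tip_counter <<- tip_counter + 1L
      len <- t_end - btime[i]
      sprintf("sp%0*d:%.12g", wd, tip_counter, len)
    } else {
      len <- stime[i] - btime[i]
      sprintf("(%s,%s):%.12g", nwk(kid1[i]), nwk(kid2[i]), len)
    }
  }
  txt <- sprintf("(%s,%s);", nwk(2L), nwk(3L))
  read_newick(txt)
}

# lower Cholesky of lambda*C0 + (1-lambda)*I with a tiny jitter guard
.lambda_chol <- function(C0, lambda) {
  M <- lambda * C0
  diag(M) <- diag(M) + (1 - lambda) + 1e-10
  t(chol(M))
}

#' Simulate species-level ground truth on a phylogeny
#'
#' Species CT_max intercepts (at the reference acclimatization temperature)
#' are drawn with covariance `phylo_sd^2 * (lambda*C0 + (1-lambda)*I)` where
#' `C0` is the tree's correlation matrix, so `lambda_true` is exactly the
#' phylogenetic proportion of the non-residual variance. Acclimatization
#' slopes are drawn around `arr_mean` with the same lambda structure scaled
#' to `arr_sd`. Ecotype and body mass are species-level attributes.
#'
#' @param tree a `phylo` object
#' @param config a [sim_config()]
#' @return object of class `synthetic_truth`: list with `species`
#'   (data.frame: species, intercept, slope, ecotype, body_mass),
#'   `lambda_true`, and `config`.
#' @export
simulate_traits <- function(tree, config = sim_config()) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "traits"))
  sp <- tree$tip.label
  n <- length(sp)
  C0 <- stats::cov2cor(ape::vcv(tree))
  L <- .lambda_chol(C0, config$lambda_true)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- config$slope_intercept_cor
  z2 <- rho * z1 + sqrt(1 - rho^2) * z2
  intercept <- config$ctmax_mean + config$phylo_sd * as.numeric(L %*% z1)
  slope <- config$arr_mean + config$arr_sd * as.numeric(L %*% z2)
  ecolv <- names(config$method_effects$ecotype)
  truth <- data.frame(
    species = sp,
    intercept = intercept,
    slope = slope,
    ecotype = sample(ecolv, n, replace = TRUE),
    body_mass = pmax(0.05, stats::rlnorm(n, log(5), 1)),
    stringsAsFactors = FALSE
  )
  structure(list(species = truth, lambda_true = config$lambda_true,
                 config = config),
            class = "synthetic_truth")
}

#' Simulate a laboratory trait table from species-level truth
#'
#' Each species receives 1-10 records. Observed CT_max is
#' `intercept + slope*(t_acc - ref) + methodological effects + process noise
#' + sampling noise`, with per-record sampling SEs drawn from a right-skewed
#' lognormal. A `prop_missing` fraction of species then has all CT_max values
#' (and SEs) masked, emulating data-deficient species; covariates are masked
#' elementwise at rate `prop_covariate_missing` (ecotype is always known, as
#' in the compilation this emulates).
#'
#' @param truth a `synthetic_truth`
#' @param config a [sim_config()]; defaults to the one stored in `truth`
#' @return `data.frame` of trait records: species, ctmax, ctmax_se, t_acc,
#'   acc_duration, ramp_rate, endpoint, medium, life_stage, ecotype,
#'   body_mass, plus logical `masked_species`.
#' @export
simulate_trait_table <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(derive_seed(config$seed, "trait_table"))
  tt <- truth$species
  n_sp <- nrow(tt)
  nrec <- sample(seq(config$records_range[1], config$records_range[2]),
                 n_sp, replace = TRUE)
  idx <- rep(seq_len(n_sp), nrec)
  me <- config$method_effects
  n <- length(idx)
  df <- data.frame(
    species = tt$species[idx],
    t_acc = round(stats::runif(n, 12, 30), 1),
    acc_duration = sample(c(1:14, 21, 30), n, replace = TRUE),
    ramp_rate = sample(c(0.02, 0.1, 0.25, 0.5, 1, 1.5), n, replace = TRUE,
                       prob = c(0.05, 0.1, 0.15, 0.2, 0.4, 0.1)),
    endpoint = sample(names(me$endpoint), n, replace = TRUE,
                      prob = c(0.5, 0.35, 0.15)),
    medium = sample(names(me$medium), n, replace = TRUE, prob = c(0.7, 0.3)),
    life_stage = sample(names(me$life_stage), n, replace = TRUE,
                        prob = c(0.8, 0.2)),
    ecotype = tt$ecotype[idx],
    body_mass = tt$body_mass[idx],
    stringsAsFactors = FALSE
  )
  se <- pmax(config$se_floor,
             stats::rlnorm(n, config$se_meanlog, config$se_sdlog))
  mu <- tt$intercept[idx] + tt$slope[idx] * (df$t_acc - config$ref_t_acc) +
    me$endpoint[df$endpoint] + me$medium[df$medium] +
    me$life_stage[df$life_stage] + me$ecotype[df$ecotype] +
    me$duration_per_day * (df$acc_duration - 10) +
    me$ramp_per_unit * (df$ramp_rate - 1) +
    me$log_mass * (log(df$body_mass) - log(5))
  df$ctmax <- round(mu + stats::rnorm(n, 0, config$residual_sd) +
                      stats::rnorm(n, 0, se), 3)
  df$ctmax_se <- round(se, 4)
  n_mask <- round(config$prop_missing * n_sp)
  masked <- sample(tt$species, n_mask)
  df$masked_species <- df$species %in% masked
  df$ctmax[df$masked_species] <- NA_real_
  df$ctmax_se[df$masked_species] <- NA_real_
  pm <- config$prop_covariate_missing
  for (col in c("t_acc", "acc_duration", "ramp_rate", "endpoint", "medium",
                "life_stage", "body_mass")) {
    df[[col]][stats::runif(n) < pm] <- NA
  }
  rownames(df) <- NULL
  df
}

# canonical integer id of a 1-degree cell from its south-west corner
cell_id_of <- function(lat, lon) {
  (as.integer(floor(lat)) + 90L) * 360L + (as.integer(floor(lon)) + 180L)
}

#' Simulate species occurrences on a 1-degree grid
#'
#' Each species occupies a contiguous latitudinal band of 1 to `k` cells in a
#' single longitude column (a crude but sufficient emulation of narrow-ranged
#' amphibian distributions).
#'
#' @param species character vector of species labels (or an integer count,
#'   in which case `sp###` labels are generated)
#' @param grid list with `lat` and `lon` integer extents
#' @param seed integer seed
#' @param k maximum band length in cells
#' @return `data.frame`: species, cell_id, lat, lon (cell centres)
#' @export
simulate_ranges <- function(species, grid = sim_config()$grid, seed = 1L,
                            k = 5L) {
  if (is.numeric(species) && length(species) == 1L)
    species <- sprintf("sp%03d", seq_len(species))
  lats <- seq(grid$lat[1], grid$lat[2] - 1L)
  lons <- seq(grid$lon[1], grid$lon[2] - 1L)
  if (!length(lats) || !length(lons)) stop("empty grid")
  set.seed(derive_seed(seed, "ranges"))
  out <- lapply(species, function(s) {
    lon <- sample(lons, 1L)
    len <- sample.int(min(k, length(lats)), 1L)
    start <- sample.int(length(lats) - len + 1L, 1L)
    lat <- lats[start:(start + len - 1L)]
    data.frame(species = s, cell_id = cell_id_of(lat, lon),
               lat = lat + 0.5, lon = lon + 0.5, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.scenario_label <- function(offset) {
  if (isTRUE(all.equal(offset, 0))) "current"
  else sprintf("plus%g", offset)
}

#' Simulate daily maximum operative body temperatures
#'
#' Statistical emulation of biophysically modelled microhabitat temperatures:
#' per cell, a latitudinal mean gradient plus a seasonal sinusoid plus
#' autocorrelated heavy-tailed heat-wave noise. The three microhabitats are
#' derived from the *same* latent weather per cell: arboreal damps the signal,
#' aquatic applies a trailing exponential smooth (thermal inertia), so daily
#' maxima satisfy var(aquatic) < var(arboreal) < var(terrestrial) and aquatic
#' lags terrestrial. Warming scenarios are pure additive offsets on top of the
#' same draws, so per-day scenario differences are exact.
#'
#' @param cells `data.frame` with cell_id, lat, lon (e.g. unique cells of
#'   [simulate_ranges()]), or a `grid` list to use all its cells
#' @param years integer years; the first is the burn-in
#' @param microhabitat one of `"terrestrial"`, `"arboreal"`, `"aquatic"`
#' @param warming_offset uniform offset in degC
#' @param seed integer master seed (per-cell streams derived from it)
#' @param climate climate parameter list (see [sim_config()])
#' @return `data.table`: cell_id, lat, lon, microhabitat, scenario, year, doy,
#'   day_index, daily_max
#' @export
simulate_operative_temps <- function(cells, years = 2005:2015,
                                     microhabitat = "terrestrial",
                                     warming_offset = 0, seed = 1L,
                                     climate = sim_config()$climate) {
  if (!microhabitat %in% c("terrestrial", "arboreal", "aquatic"))
    stop("unknown microhabitat: ", microhabitat)
  if (is.list(cells) && !is.data.frame(cells)) {
    lats <- seq(cells$lat[1], cells$lat[2] - 1L)
    lons <- seq(cells$lon[1], cells$lon[2] - 1L)
    cells <- expand.grid(lat = lats + 0.5, lon = lons + 0.5)
    cells$cell_id <- cell_id_of(cells$lat, cells$lon)
  }
  cells <- unique(as.data.frame(cells)[, c("cell_id", "lat", "lon")])
  years <- as.integer(years)
  n_days <- 365L * length(years)
  doy <- rep(1:365, length(years))
  year <- rep(years, each = 365L)
  cl <- climate
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    lat <- cells$lat[i]
    set.seed(derive_seed(seed, "temps", cells$cell_id[i]))
    # latent weather shared by all microhabitats of this cell
    df <- cl$noise_df
    z <- stats::rt(n_days, df = df) / sqrt(df / (df - 2))
    eps <- numeric(n_days)
    eps[1] <- z[1] * cl$noise_sd
    sc <- cl$noise_sd * sqrt(1 - cl$ar_phi^2)
    for (d in 2:n_days) eps[d] <- cl$ar_phi * eps[d - 1] + sc * z[d]
    peak <- if (lat >= 0) 196 else 15  # mid-July vs mid-January
    amp <- cl$seas_amp0 + cl$seas_amp_slope * abs(lat)
    signal <- amp * cos(2 * pi * (doy - peak) / 365) + eps
    base <- cl$base_t + cl$base_lat_slope * abs(lat)
    x <- switch(microhabitat,
      terrestrial = base + signal,
      arboreal = base + cl$arboreal_offset + cl$arboreal_damp * signal,
      aquatic = {
        # damped *and* smoothed: the exponential filter supplies the thermal
        # lag and kills high-frequency noise; the damp factor (< arboreal's)
        # attenuates the seasonal band the filter passes through
        a <- cl$aquatic_alpha
        sm <- numeric(n_days)
        sm[1] <- signal[1] * a
        for (d in 2:n_days) sm[d] <- a * signal[d] + (1 - a) * sm[d - 1]
        base + cl$aquatic_offset + cl$aquatic_damp * sm
      })
    out[[i]] <- data.table::data.table(
      cell_id = cells$cell_id[i], lat = lat, lon = cells$lon[i],
      microhabitat = microhabitat,
      scenario = .scenario_label(warming_offset),
      year = year, doy = doy, day_index = seq_len(n_days),
      daily_max = round(x + warming_offset, 3))
  }
  data.table::rbindlist(out)
}

#' Generate and write every pipeline input
#'
#' One call produces `tree.nwk`, `traits.csv`, `occurrences.csv`,
#' `temps_<microhabitat>_<scenario>.csv`, `truth.csv` (synthetic ground
#' truth, for recovery tests) and `sim_config.json` under `dir`.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed); `NULL` returns the
#'   objects without writing
#' @param microhabitats subset of microhabitats to simulate
#' @return invisibly, a list with `tree`, `truth`, `traits`, `occurrences`,
#'   `temps` (list by microhabitat/scenario), and `paths` (if written)
#' @export
simulate_inputs <- function(config = sim_config(), dir = NULL,
                            microhabitats = c("terrestrial", "arboreal",
                                              "aquatic")) {
  tree <- simulate_tree(config$n_species, seed = derive_seed(config$seed, "tree"))
  truth <- simulate_traits(tree, config)
  traits <- simulate_trait_table(truth, config)
  occ <- simulate_ranges(tree$tip.label, grid = config$grid,
                         seed = config$seed, k = config$k_range_cells)
  cells <- unique(occ[, c("cell_id", "lat", "lon")])
  temps <- list()
  for (mh in microhabitats) {
    for (off in config$warming_offsets) {
      key <- paste(mh, .scenario_label(off), sep = "_")
      temps[[key]] <- simulate_operative_temps(
        cells, years = config$years, microhabitat = mh,
        warming_offset = off, seed = config$seed, climate = config$climate)
    }
  }
  res <- list(tree = tree, truth = truth, traits = traits,
              occurrences = occ, temps = temps)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_newick(tree, file.path(dir, "tree.nwk"))
    utils::write.csv(traits, file.path(dir, "traits.csv"), row.names = FALSE)
    utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
    utils::write.csv(truth$species, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    for (key in names(temps))
      data.table::fwrite(temps[[key]],
                         file.path(dir, sprintf("temps_%s.csv", key)))
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$paths <- list(dir = dir)
  }
  invisible(res)
}
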