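#' Species-holdout cross-validation of the imputation
#'
#' Masks all CT_max values for a random fraction of the measured species,
#' reruns the full BACE procedure on the masked table, and scores the
#' standardized predictions against the held-out records. Held-out records
#' are standardized to the reference assay conditions via the fitted fixed
#' effects before comparison, so only comparable quantities are scored
#' (optionally restricted to adult records).
#'
#' @param table trait table
#' @param tree `phylo` covering the table's species
#' @param frac fraction of measured species to hold out (default 0.05)
#' @param min_species lower bound on the held-out species count (a Pearson r
#'   over fewer species is not meaningful at synthetic scale)
#' @param comparable_only score only adult records (the comparability rule)
#' @param seed integer seed
#' @param ... further arguments to [run_bace()] (cycles, MCMC settings)
#' @return list of class `crossval_report`: n_species_held, n_estimates,
#'   pearson_r, mean_obs, sd_obs, mean_imp, sd_imp, held_species, and the
#'   per-record score table
#' @export
crossval_holdout <- function(table, tree, frac = 0.05, min_species = 5L,
                             comparable_only = TRUE, seed = 1L, ...) {
  table <- as.data.frame(table)
  measured <- unique(table$species[!is.na(table$ctmax)])
  if (frac >= 1 || frac <= 0) stop("frac must be in (0, 1)")
  n_hold <- max(as.integer(min_species), round(frac * length(measured)))
  if (n_hold >= length(measured) - 1L)
    stop("cannot hold out ", n_hold, " of ", length(measured),
         " measured species and still train")
  set.seed(derive_seed(seed, "holdout"))
  held <- sample(measured, n_hold)

  train <- table
  hmask <- train$species %in% held
  train$ctmax[hmask] <- NA_real_
  train$ctmax_se[hmask] <- NA_real_
  stopifnot(all(is.na(train$ctmax[train$species %in% held])))  # no leakage

  res <- run_bace(train, tree, seed = derive_seed(seed, "bace"), ...)
  fit <- res$fit

  score <- table[table$species %in% held & !is.na(table$ctmax), , drop = FALSE]
  if (comparable_only && "life_stage" %in% names(score))
    score <- score[is.na(score$life_stage) | score$life_stage == "adult", ,
                   drop = FALSE]
  # complete covariates from the BACE working table (row-aligned with table)
  comp <- res$completed[match(rownames(score), rownames(res$completed)), ,
                        drop = FALSE]
  if (!nrow(score)) stop("no comparable held-out records to score")
  pred_ref <- standardized_predict(fit, comp$species, comp$t_acc)
  pred_rec <- .predict_rows(fit, comp)
  # standardize the observation to reference conditions: subtract the fixed-
  # effect difference between the record's assay conditions and the reference
  obs_std <- score$ctmax - (pred_rec$mean - pred_ref$ctmax_hat)
  r <- stats::cor(obs_std, pred_ref$ctmax_hat)
  structure(list(
    n_species_held = length(held), n_estimates = nrow(score),
    pearson_r = r,
    mean_obs = mean(obs_std), sd_obs = stats::sd(obs_std),
    mean_imp = mean(pred_ref$ctmax_hat), sd_imp = stats::sd(pred_ref$ctmax_hat),
    held_species = sort(held),
    scores = data.frame(species = comp$species, t_acc = comp$t_acc,
                        obs_std = obs_std, imputed = pred_ref$ctmax_hat,
                        imputed_se = pred_ref$ctmax_se,
                        stringsAsFactors = FALSE)
  ), class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("crossval_report: %d species held out, %d estimates\n",
              x$n_species_held, x$n_estimates))
  cat(sprintf("  r = %.3f; observed %.2f +/- %.2f; imputed %.2f +/- %.2f\n",
              x$pearson_r, x$mean_obs, x$sd_obs, x$mean_imp, x$sd_imp))
  invisible(x)
}

#' Parameter-recovery harness against synthetic truth
#'
#' For each replicate: simulate a tree and trait table under `config`, fit
#' the phylogenetic mixed model on the observed records, and record the
#' posterior mean and 95% CI of Pagel's lambda (with coverage of
#' `lambda_true`) and the recovered mean acclimatization response ratio (the
#' `t_acc` fixed effect).
#'
#' @param config a [sim_config()]
#' @param n_replicates number of replicates (>= 1)
#' @param seed master seed (per-replicate seeds derived from it)
#' @param mcmc MCMC settings of each fit
#' @return list of class `recovery_report`: `replicates` (data.frame with
#'   lambda_mean, lambda_lo, lambda_hi, covered, arr_hat), `lambda_coverage`,
#'   `lambda_mean`, `arr_bias`, `arr_rmse`
#' @export
recovery_suite <- function(config = sim_config(), n_replicates = 5L,
                           seed = 1L,
                           mcmc = hm_mcmc_control(2000L, 600L, 2L)) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(seed, "rep", r)
    tree <- simulate_tree(cfg$n_species, seed = derive_seed(cfg$seed, "tree"))
    truth <- simulate_traits(tree, cfg)
    tab <- simulate_trait_table(truth, cfg)
    tab <- initialize_missing(tab, seed = derive_seed(cfg$seed, "init"))
    fit <- fit_phylo_mixed_model(tab, tree, mcmc = mcmc,
                                 seed = derive_seed(cfg$seed, "fit"))
    ls <- fit$lambda_summary
    data.frame(replicate = r, lambda_mean = ls$lambda_mean,
               lambda_lo = ls$lambda_ci[1], lambda_hi = ls$lambda_ci[2],
               covered = ls$lambda_ci[1] <= cfg$lambda_true &
                 cfg$lambda_true <= ls$lambda_ci[2],
               arr_hat = unname(fit$fixed_effects$mean["t_acc"]))
  })
  reps <- do.call(rbind, rows)
  structure(list(
    replicates = reps,
    lambda_true = config$lambda_true,
    lambda_coverage = mean(reps$covered),
    lambda_mean = mean(reps$lambda_mean),
    arr_true = config$arr_mean,
    arr_bias = mean(reps$arr_hat) - config$arr_mean,
    arr_rmse = sqrt(mean((reps$arr_hat - config$arr_mean)^2))
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report (%d replicates): lambda %.3f (true %.2f), CI coverage %.0f%%; ARR bias %+.4f, RMSE %.4f\n",
              nrow(x$replicates), x$lambda_mean, x$lambda_true,
              100 * x$lambda_coverage, x$arr_bias, x$arr_rmse))
  invisible(x)
}
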