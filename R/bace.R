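#' Cycle-0 fill of missing predictor values
#'
#' Continuous gaps become the arithmetic mean of the column's observed
#' values; categorical gaps are drawn from the observed empirical
#' distribution. Observed entries are never touched. The response (CT_max)
#' is *not* filled here: records with missing CT_max stay missing and are
#' handled by posterior prediction.
#'
#' @param table trait table
#' @param columns columns to fill (default: the standard predictor set)
#' @param seed integer seed for the categorical draws
#' @return the completed table, with attribute `imputed`: a logical
#'   data.frame marking which entries were filled
#' @export
initialize_missing <- function(table,
                               columns = c("t_acc", "acc_duration",
                                           "ramp_rate", "endpoint", "medium",
                                           "life_stage", "ecotype",
                                           "body_mass"),
                               seed = 1L) {
  table <- as.data.frame(table)
  columns <- intersect(columns, names(table))
  set.seed(as.integer(seed))
  mask <- as.data.frame(lapply(table[columns], is.na))
  for (cv in columns) {
    v <- table[[cv]]
    miss <- is.na(v)
    if (!any(miss)) next
    if (all(miss)) stop("column '", cv, "' has no observed values")
    if (is.numeric(v)) {
      v[miss] <- mean(v[!miss])
    } else {
      v[miss] <- sample(as.character(v[!miss]), sum(miss), replace = TRUE)
    }
    table[[cv]] <- v
  }
  attr(table, "imputed") <- mask
  table
}

# posterior-mean prediction at arbitrary covariate rows (point values,
# used to feed imputed predictors into the next cycle)
.predict_rows <- function(fit, newdata) {
  Xr <- .design_row(fit$design, newdata)
  sp_i <- match(newdata$species, fit$species)
  D <- fit$draws
  pred <- Xr %*% t(D$beta) + t(D$u)[sp_i, , drop = FALSE]
  if (fit$include_slope)
    pred <- pred + t(D$b)[sp_i, , drop = FALSE] *
      (newdata$t_acc - fit$t_center)
  list(mean = rowMeans(pred), se = apply(pred, 1L, stats::sd))
}

# one-vs-rest binomial GLM imputation of a categorical predictor; the
# imputed value is the most probable class ("most likely values")
.impute_categorical <- function(df, col, covariates, miss) {
  obs <- !miss
  lv <- sort(unique(as.character(df[[col]][obs])))
  if (length(lv) == 1L) {
    df[[col]][miss] <- lv
    return(df)
  }
  des <- .build_design(df[intersect(covariates, names(df))],
                       intersect(covariates, names(df)))
  X <- des$X[, -1L, drop = FALSE]
  scores <- sapply(lv, function(l) {
    yy <- as.numeric(df[[col]][obs] == l)
    f <- suppressWarnings(stats::glm.fit(cbind(1, X[obs, , drop = FALSE]), yy,
                                         family = stats::binomial()))
    as.numeric(cbind(1, X[miss, , drop = FALSE]) %*% stats::coef(f))
  })
  if (sum(miss) == 1L) scores <- matrix(scores, nrow = 1L)
  df[[col]][miss] <- lv[max.col(scores)]
  df
}

#' Run Bayesian augmentation with chained equations (BACE)
#'
#' Iterative phylogenetic imputation of heat-tolerance limits. Cycle 0 fills
#' predictor gaps with [initialize_missing()]; each subsequent cycle
#' re-imputes every originally-missing predictor entry from a sub-model of
#' that predictor on the others (phylogenetic random intercepts, no slopes),
#' then refits the CT_max mixed model on records with observed CT_max and
#' refreshes working CT_max values for unmeasured records by posterior
#' prediction. Observed values are never overwritten. After `n_cycles`
#' cycles, a final (longer-chain) model fit drives standardized predictions
#' for every species at its three reference acclimatization temperatures.
#'
#' @param table trait table (`ctmax`, `ctmax_se`, covariates; NAs allowed)
#' @param tree `phylo` object; every species in `table` must be a tip
#' @param n_cycles chained-equation cycles (>= 1, default 5)
#' @param t_acc_ref `data.frame(species, t_p5, t_median, t_p95)` of reference
#'   acclimatization temperatures (typically range-wide operative temperature
#'   percentiles); default: the pooled 5th/50th/95th percentiles of observed
#'   `t_acc`, shared across species.
#' @param mcmc MCMC settings of the final model fit
#' @param mcmc_cycle,mcmc_sub shorter settings for the per-cycle CT_max
#'   refits and the predictor sub-models
#' @param seed integer seed
#' @return object of class `bace_result`: list with `imputed` (data.frame
#'   species/level/t_acc_ref/ctmax_hat/ctmax_se/provenance), `fit` (final
#'   `phylo_mixed_fit`), `drift` (per-cycle mean absolute change of imputed
#'   CT_max), `imputed_trace` (per-cycle imputed values for missing records)
#'   and `completed` (the final working table).
#' @export
run_bace <- function(table, tree, n_cycles = 5L, t_acc_ref = NULL,
                     mcmc = hm_mcmc_control(2500L, 800L, 2L),
                     mcmc_cycle = hm_mcmc_control(800L, 300L, 2L,
                                                  lambda_grid_n = 51L),
                     mcmc_sub = hm_mcmc_control(500L, 200L, 2L,
                                                lambda_grid_n = 41L),
                     seed = 1L) {
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) stop("n_cycles must be >= 1")
  table <- as.data.frame(table)
  missing_sp <- setdiff(unique(table$species), tree$tip.label)
  if (length(missing_sp))
    stop("species absent from tree: ",
         paste(utils::head(missing_sp, 5), collapse = ", "))
  tree <- prune_and_match(tree, unique(table$species))
  cache <- .phylo_eigen(tree)

  predictors <- intersect(c("t_acc", "acc_duration", "ramp_rate", "endpoint",
                            "medium", "life_stage", "ecotype", "body_mass"),
                          names(table))
  y_miss <- is.na(table$ctmax)
  any_to_impute <- any(vapply(table[predictors],
                              function(v) anyNA(v), logical(1)))

  completed <- initialize_missing(table, predictors,
                                  seed = derive_seed(seed, "init"))
  miss_mask <- attr(completed, "imputed")

  # cycle-0 working values for missing CT_max: the mean-fill rule
  trace <- NULL
  if (any(y_miss)) {
    trace <- matrix(NA_real_, sum(y_miss), n_cycles + 1L)
    trace[, 1L] <- mean(table$ctmax[!y_miss])
  }
  drift <- numeric(n_cycles)
  fit <- NULL

  for (cy in seq_len(n_cycles)) {
    if (any_to_impute) {
      for (cv in predictors) {
        m <- miss_mask[[cv]]
        if (is.null(m) || !any(m)) next
        others <- setdiff(predictors, cv)
        if (is.numeric(completed[[cv]])) {
          sub <- fit_phylo_mixed_model(
            completed, tree, response = cv, se_col = NULL,
            covariates = others, include_slope = FALSE, mcmc = mcmc_sub,
            seed = derive_seed(seed, "sub", cy, cv),
            phylo_cache = cache)
          pr <- .predict_rows(sub, completed[m, , drop = FALSE])
          val <- pr$mean
          if (cv == "body_mass") val <- pmax(val, 0.01)
          if (cv == "acc_duration") val <- pmax(val, 0)
          if (cv == "ramp_rate") val <- pmax(val, 0.01)
          completed[[cv]][m] <- val
        } else {
          completed <- .impute_categorical(completed, cv, others, m)
        }
      }
    }
    is_last <- cy == n_cycles
    fit <- fit_phylo_mixed_model(
      completed, tree,  # rows with missing CT_max are dropped from the
      covariates = predictors,  # likelihood but keep species attributes
      mcmc = if (is_last) mcmc else mcmc_cycle,
      seed = derive_seed(seed, "main", cy), phylo_cache = cache)
    if (any(y_miss)) {
      pr <- .predict_rows(fit, completed[y_miss, , drop = FALSE])
      trace[, cy + 1L] <- pr$mean
      drift[cy] <- mean(abs(trace[, cy + 1L] - trace[, cy]))
    }
  }

  # reference acclimatization temperatures
  sp <- sort(unique(table$species))
  if (is.null(t_acc_ref)) {
    qs <- stats::quantile(table$t_acc[!is.na(table$t_acc)],
                          c(0.05, 0.5, 0.95), names = FALSE)
    t_acc_ref <- data.frame(species = sp, t_p5 = qs[1], t_median = qs[2],
                            t_p95 = qs[3], stringsAsFactors = FALSE)
  }
  t_acc_ref <- as.data.frame(t_acc_ref)
  if (!all(sp %in% t_acc_ref$species))
    stop("t_acc_ref missing species: ",
         paste(utils::head(setdiff(sp, t_acc_ref$species), 5), collapse = ", "))
  ri <- match(sp, t_acc_ref$species)
  levels3 <- c("p5", "median", "p95")
  refcols <- c("t_p5", "t_median", "t_p95")
  measured <- unique(table$species[!y_miss])
  imp <- do.call(rbind, lapply(1:3, function(k) {
    pr <- standardized_predict(fit, sp, t_acc_ref[[refcols[k]]][ri])
    data.frame(species = sp, level = levels3[k],
               t_acc_ref = pr$t_acc, ctmax_hat = pr$ctmax_hat,
               ctmax_se = pr$ctmax_se,
               provenance = ifelse(sp %in% measured, "experimental-informed",
                                   "fully-imputed"),
               stringsAsFactors = FALSE)
  }))
  imp <- imp[order(imp$species, match(imp$level, levels3)), ]
  rownames(imp) <- NULL
  structure(list(imputed = imp, fit = fit, drift = drift,
                 imputed_trace = trace, completed = completed,
                 n_cycles = n_cycles),
            class = "bace_result")
}

#' @export
print.bace_result <- function(x, ...) {
  cat("bace_result:", length(unique(x$imputed$species)), "species x 3 levels;",
      x$n_cycles, "cycles\n")
  if (length(x$drift) && any(x$drift > 0))
    cat("  imputed CT_max drift by cycle:",
        paste(sprintf("%.3f", x$drift), collapse = " "), "\n")
  print(x$fit)
  invisible(x)
}
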