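#' Per-species meta-regression of CT_max on acclimatization temperature
#'
#' Inverse-variance weighted (fixed-effects) linear regression of the three
#' standardized CT_max estimates on their reference acclimatization
#' temperatures. The slope is the species' acclimatization response ratio
#' (ARR, degC per degC). Coefficient covariance is `(X'WX)^-1` from the
#' weighted normal equations; an optional residual heterogeneity `tau^2` is
#' estimated by the DerSimonian-Laird moment method (default off: with three
#' points it is rarely identifiable).
#'
#' @param points data.frame with columns `t_acc_ref` (or `t_acc`),
#'   `ctmax_hat`, `ctmax_se` for one species
#' @param species optional species label (else taken from `points$species`)
#' @param estimate_tau2 add the DL moment estimate of residual heterogeneity
#' @return object of class `plasticity_model`: species, intercept, slope_arr,
#'   coef_cov (2x2), residual_tau2, t_range, n
#' @export
fit_species_plasticity <- function(points, species = NULL,
                                   estimate_tau2 = FALSE) {
  points <- as.data.frame(points)
  t <- if (!is.null(points$t_acc_ref)) points$t_acc_ref else points$t_acc
  y <- points$ctmax_hat
  se <- points$ctmax_se
  if (is.null(t) || is.null(y) || is.null(se))
    stop("points must have t_acc_ref (or t_acc), ctmax_hat, ctmax_se")
  ok <- is.finite(t) & is.finite(y) & is.finite(se) & se > 0
  t <- t[ok]; y <- y[ok]; se <- se[ok]
  if (length(unique(t)) < 2L)
    stop("need >= 2 distinct acclimatization temperatures (slope unidentifiable)")
  if (is.null(species))
    species <- if (!is.null(points$species)) as.character(points$species[1]) else NA_character_
  w <- 1 / se^2
  X <- cbind(1, t)
  XtWX <- crossprod(X * sqrt(w))
  V <- solve(XtWX)
  beta <- as.numeric(V %*% crossprod(X * w, y))
  tau2 <- 0
  if (estimate_tau2 && length(y) > 2L) {
    r <- y - X %*% beta
    Q <- sum(w * r^2)
    # tr(P) for the DL moment equation, P = W - WX(X'WX)^-1 X'W
    trP <- sum(w) - sum(diag(V %*% crossprod(X * w)))
    tau2 <- max(0, (Q - (length(y) - 2)) / trP)
  }
  structure(list(species = species, intercept = beta[1], slope_arr = beta[2],
                 coef_cov = V, residual_tau2 = tau2, t_range = range(t),
                 n = length(y)),
            class = "plasticity_model")
}

#' @export
print.plasticity_model <- function(x, ...) {
  cat(sprintf("plasticity_model [%s]: CT_max = %.2f + %.4f * t_acc (ARR se %.4f, n = %d)\n",
              x$species, x$intercept, x$slope_arr, sqrt(x$coef_cov[2, 2]), x$n))
  invisible(x)
}

#' Fit plasticity models for every species in an imputed table
#'
#' @param imputed the `imputed` data.frame of a [run_bace()] result
#' @param estimate_tau2 see [fit_species_plasticity()]
#' @return data.frame: species, intercept, slope_arr, var_intercept,
#'   var_slope, cov_int_slope, residual_tau2, t_min, t_max, n
#' @export
fit_plasticity_table <- function(imputed, estimate_tau2 = FALSE) {
  sp <- split(as.data.frame(imputed), imputed$species)
  out <- lapply(sp, function(d) {
    m <- fit_species_plasticity(d, estimate_tau2 = estimate_tau2)
    data.frame(species = m$species, intercept = m$intercept,
               slope_arr = m$slope_arr,
               var_intercept = m$coef_cov[1, 1], var_slope = m$coef_cov[2, 2],
               cov_int_slope = m$coef_cov[1, 2],
               residual_tau2 = m$residual_tau2,
               t_min = m$t_range[1], t_max = m$t_range[2], n = m$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predict CT_max from a plasticity model
#'
#' @param model a `plasticity_model`
#' @param t_acc acclimatization temperature(s), degC
#' @param include_tau2 add residual heterogeneity to the prediction variance
#' @return data.frame: t_acc, ctmax, se, extrapolated
#' @export
predict_ctmax <- function(model, t_acc, include_tau2 = FALSE) {
  stopifnot(inherits(model, "plasticity_model"), all(is.finite(t_acc)))
  V <- model$coef_cov
  var_pred <- V[1, 1] + 2 * t_acc * V[1, 2] + t_acc^2 * V[2, 2]
  if (include_tau2) var_pred <- var_pred + model$residual_tau2
  data.frame(t_acc = t_acc,
             ctmax = model$intercept + model$slope_arr * t_acc,
             se = sqrt(var_pred),
             extrapolated = t_acc < model$t_range[1] | t_acc > model$t_range[2])
}

#' Daily plasticity-adjusted CT_max along an exposure series
#'
#' Each retained day's acclimatization temperature is the mean daily maximum
#' body temperature of the 7 days before it (`week_mean`, already computed by
#' [build_exposure()]; the conservative variant uses `week_max`). CT_max on
#' that day is the plasticity model's prediction at that temperature.
#'
#' @param model a `plasticity_model`
#' @param exposure retained-day exposure rows for one cell / scenario /
#'   microhabitat (columns `week_mean`, `week_max`, `day_index`)
#' @param acclim `"week_mean"` (default) or `"week_max"`
#' @param include_tau2 see [predict_ctmax()]
#' @return `exposure` with added columns `t_acc`, `ctmax_day`,
#'   `ctmax_day_se`; rows lacking trailing-week history are dropped with a
#'   warning naming the count
#' @export
project_daily_ctmax <- function(model, exposure,
                                acclim = c("week_mean", "week_max"),
                                include_tau2 = FALSE) {
  acclim <- match.arg(acclim)
  exposure <- as.data.frame(exposure)
  t_acc <- exposure[[acclim]]
  drop <- !is.finite(t_acc)
  if (any(drop)) {
    warning(sum(drop), " day(s) dropped: no trailing-week history")
    exposure <- exposure[!drop, , drop = FALSE]
    t_acc <- t_acc[!drop]
  }
  pr <- predict_ctmax(model, t_acc, include_tau2 = include_tau2)
  exposure$t_acc <- t_acc
  exposure$ctmax_day <- pr$ctmax
  exposure$ctmax_day_se <- pr$se
  exposure
}
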