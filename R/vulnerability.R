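#' Daily thermal safety margin
#'
#' Difference between the (plasticity-adjusted) critical thermal maximum and
#' the day's maximum operative body temperature; negative values mean the
#' day exceeds the limit.
#'
#' @param ctmax_day,daily_max degC (vectorized)
#' @return degC
#' @export
daily_tsm <- function(ctmax_day, daily_max) ctmax_day - daily_max

#' Inverse-variance weighted mean and its standard error
#'
#' `w_i = 1/se_i^2`; mean `= sum(w v)/sum(w)`; `se = sqrt(1/sum(w))`.
#'
#' @param values numeric vector
#' @param ses positive standard errors, same length
#' @return list with `mean` and `se`
#' @export
weighted_mean_se <- function(values, ses) {
  if (!length(values)) stop("empty input")
  if (length(values) != length(ses)) stop("values and ses differ in length")
  if (any(!is.finite(ses) | ses <= 0)) stop("ses must be positive and finite")
  w <- 1 / ses^2
  list(mean = sum(w * values) / sum(w), se = sqrt(1 / sum(w)))
}

#' Policy for capping the CT_max distribution s.d.
#'
#' Before computing exceedance probabilities the CT_max standard error is
#' capped so large imputation uncertainty cannot inflate overheating
#' probabilities: `fixed_cap` caps at `cap` (default 1 degC, i.e. simulated
#' distributions within ~3 degC of the mean); `biological_range` caps at the
#' cross-species s.d. of CT_max (`bio_cap`, default 2.0, within the observed
#' 1.84-2.17 band); `none` leaves SEs untouched.
#'
#' @param mode one of `"fixed_cap"`, `"biological_range"`, `"none"`
#' @param cap fixed cap in degC (> 0)
#' @param bio_cap biological-range cap in degC (> 0)
#' @return list of class `sigma_policy`
#' @export
sigma_policy <- function(mode = c("fixed_cap", "biological_range", "none"),
                         cap = 1.0, bio_cap = 2.0) {
  mode <- match.arg(mode)
  if (cap <= 0 || bio_cap <= 0) stop("caps must be > 0")
  structure(list(mode = mode, cap = cap, bio_cap = bio_cap),
            class = "sigma_policy")
}

# effective sigma under a policy
.apply_sigma <- function(se, policy) {
  switch(policy$mode,
         fixed_cap = pmin(se, policy$cap),
         biological_range = pmin(se, policy$bio_cap),
         none = se)
}

#' Probability that a day's temperature exceeds the CT_max distribution
#'
#' `p = Phi((daily_max - ctmax_day) / sigma)` with `sigma` the (capped)
#' CT_max standard error — the normal upper-tail probability that the
#' realized limit lies below the day's maximum temperature.
#'
#' @param daily_max,ctmax_day degC (vectorized)
#' @param ctmax_se positive CT_max standard error(s)
#' @param policy a [sigma_policy()]
#' @return probability in `[0, 1]`
#' @export
exceedance_probability <- function(daily_max, ctmax_day, ctmax_se,
                                   policy = sigma_policy()) {
  if (any(!is.finite(ctmax_se) | ctmax_se <= 0))
    stop("ctmax_se must be positive")
  sig <- .apply_sigma(ctmax_se, policy)
  stats::pnorm((daily_max - ctmax_day) / sig)
}

#' Expected overheating-day count with binomial standard error
#'
#' The mean daily exceedance probability times the number of simulated days,
#' with `se = sqrt(n_days * pbar * (1 - pbar))` from binomial properties
#' (days treated as independent).
#'
#' @param p daily exceedance probabilities
#' @param n_days total simulated days (910 = 91 days x 10 years)
#' @return list: `n` (expected days), `se` (days), `p_bar`
#' @export
overheating_days <- function(p, n_days = 910L) {
  if (!length(p)) stop("empty probability series")
  if (any(p < 0 | p > 1)) stop("probabilities outside [0, 1]")
  pbar <- mean(p)
  list(n = pbar * n_days, se = sqrt(n_days * pbar * (1 - pbar)), p_bar = pbar)
}

#' Binary overheating risk
#'
#' Default rule: 1 if the daily maximum exceeds the point-estimate CT_max on
#' at least one day. CI variant: 1 if the 95% interval of the expected
#' overheating-day count (`n +/- 1.96 se`) excludes zero from below.
#'
#' @param daily_max,ctmax_day aligned series (point variant)
#' @param variant `"point"` or `"ci"`
#' @param n,se expected overheating days and SE (required for `"ci"`)
#' @return 0 or 1
#' @export
binary_risk <- function(daily_max = NULL, ctmax_day = NULL,
                        variant = c("point", "ci"), n = NULL, se = NULL) {
  variant <- match.arg(variant)
  if (variant == "point") {
    if (length(daily_max) != length(ctmax_day)) stop("misaligned series")
    as.integer(any(daily_max > ctmax_day))
  } else {
    if (is.null(n) || is.null(se)) stop("ci variant needs n and se")
    as.integer(n - 1.96 * se > 0)
  }
}

#' Vulnerability metrics for one local species occurrence
#'
#' Assembles the three metrics from aligned daily series: the weighted-mean
#' thermal safety margin, the expected overheating-day count with binomial
#' SE, and the binary risk.
#'
#' @param daily_max daily maximum operative temperatures over the retained
#'   days (degC)
#' @param ctmax_day,ctmax_se plasticity-adjusted CT_max and its SE per day
#' @param year year of each retained day (used by the annual variants)
#' @param policy a [sigma_policy()]
#' @param tsm_variant `"daily"` (weighted mean of daily TSMs; default),
#'   `"annual_max"` (TSM at each year's hottest day, pooled across years —
#'   the classical definition), or `"annual_p95"` (vs each year's 95th
#'   percentile temperature)
#' @param risk_variant `"point"` or `"ci"` (see [binary_risk()])
#' @param trim drop days whose temperature falls outside the occurrence's
#'   5th-95th percentile band before computing any metric
#' @param n_days_total day count used to scale the binomial metrics
#'   (default: the series length, 910 for a full 2006-2015 run)
#' @return one-row data.frame: tsm_mean, tsm_se, p_bar, n_overheat_days,
#'   n_overheat_se, risk_binary, n_days_total
#' @export
tsm_summary <- function(daily_max, ctmax_day, ctmax_se, year = NULL,
                        policy = sigma_policy(),
                        tsm_variant = c("daily", "annual_max", "annual_p95"),
                        risk_variant = c("point", "ci"), trim = FALSE,
                        n_days_total = NULL) {
  tsm_variant <- match.arg(tsm_variant)
  risk_variant <- match.arg(risk_variant)
  n_in <- length(daily_max)
  if (length(ctmax_day) != n_in || length(ctmax_se) != n_in)
    stop("misaligned series: ", n_in, " temperature days vs ",
         length(ctmax_day), " CT_max days")
  if (is.null(year)) year <- rep(1L, n_in)
  if (trim) {
    q <- stats::quantile(daily_max, c(0.05, 0.95), names = FALSE)
    keep <- daily_max >= q[1] & daily_max <= q[2]
    daily_max <- daily_max[keep]; ctmax_day <- ctmax_day[keep]
    ctmax_se <- ctmax_se[keep]; year <- year[keep]
  }
  if (is.null(n_days_total)) n_days_total <- length(daily_max)
  tsm <- daily_tsm(ctmax_day, daily_max)
  if (tsm_variant == "daily") {
    wm <- weighted_mean_se(tsm, ctmax_se)
  } else {
    ix <- split(seq_along(tsm), year)
    per_year <- lapply(ix, function(i) {
      if (tsm_variant == "annual_max") {
        j <- i[which.max(daily_max[i])]
        c(tsm[j], ctmax_se[j])
      } else {
        ref <- stats::quantile(daily_max[i], 0.95, names = FALSE)
        wmy <- weighted_mean_se(ctmax_day[i], ctmax_se[i])
        c(wmy$mean - ref, wmy$se)
      }
    })
    m <- do.call(rbind, per_year)
    wm <- weighted_mean_se(m[, 1], m[, 2])
  }
  p <- exceedance_probability(daily_max, ctmax_day, ctmax_se, policy)
  od <- overheating_days(p, n_days_total)
  risk <- if (risk_variant == "point") {
    binary_risk(daily_max, ctmax_day, variant = "point")
  } else {
    binary_risk(variant = "ci", n = od$n, se = od$se)
  }
  data.frame(tsm_mean = wm$mean, tsm_se = wm$se, p_bar = od$p_bar,
             n_overheat_days = od$n, n_overheat_se = od$se,
             risk_binary = risk, n_days_total = n_days_total)
}

#' Assess vulnerability for every local species occurrence
#'
#' Joins occurrences to the exposure series of their cells, projects daily
#' plasticity-adjusted CT_max per species, and computes the three
#' vulnerability metrics per (species, cell).
#'
#' @param exposure retained-day exposure table ([build_exposure()]) for one
#'   scenario and microhabitat
#' @param plasticity per-species coefficient table ([fit_plasticity_table()])
#' @param occurrences data.frame: species, cell_id
#' @param policy a [sigma_policy()]
#' @param variant `"default"`, `"max-acclim"` (acclimatized to weekly maxima),
#'   `"p95-tsm"` (TSM vs annual 95th-percentile temperature), `"ci-risk"`
#'   (binary risk from the CI rule), or `"trimmed"` (5th-95th percentile
#'   temperature trim)
#' @param include_tau2 propagate residual heterogeneity into daily SEs
#' @param on_missing_species `"error"` (default) or `"drop"` occurrences of
#'   species without a plasticity model
#' @return data.frame, one row per occurrence: species, cell_id, lat, lon,
#'   microhabitat, scenario + the [tsm_summary()] columns
#' @export
assess_vulnerability <- function(exposure, plasticity, occurrences,
                                 policy = sigma_policy(),
                                 variant = c("default", "max-acclim",
                                             "p95-tsm", "ci-risk", "trimmed"),
                                 include_tau2 = FALSE,
                                 on_missing_species = c("error", "drop")) {
  variant <- match.arg(variant)
  on_missing_species <- match.arg(on_missing_species)
  exposure <- data.table::as.data.table(exposure)
  occurrences <- as.data.frame(occurrences)
  plasticity <- as.data.frame(plasticity)
  absent <- setdiff(unique(occurrences$species), plasticity$species)
  if (length(absent)) {
    if (on_missing_species == "error")
      stop("no plasticity model for: ",
           paste(utils::head(absent, 10), collapse = ", "))
    occurrences <- occurrences[!occurrences$species %in% absent, , drop = FALSE]
  }
  no_cell <- setdiff(unique(occurrences$cell_id), unique(exposure$cell_id))
  if (length(no_cell))
    stop("occurrence cells without exposure data: ",
         paste(utils::head(no_cell, 10), collapse = ", "))
  acclim_col <- if (variant == "max-acclim") "week_max" else "week_mean"
  tsm_variant <- if (variant == "p95-tsm") "annual_p95" else "daily"
  risk_variant <- if (variant == "ci-risk") "ci" else "point"
  trim <- variant == "trimmed"

  occ <- data.table::as.data.table(occurrences)[, c("species", "cell_id"),
                                                with = FALSE]
  dt <- merge(occ, exposure, by = "cell_id", allow.cartesian = TRUE)
  pi <- match(dt$species, plasticity$species)
  t_acc <- dt[[acclim_col]]
  if (anyNA(t_acc)) stop("exposure rows without trailing-week history")
  a <- plasticity$intercept[pi]; b <- plasticity$slope_arr[pi]
  v11 <- plasticity$var_intercept[pi]; v22 <- plasticity$var_slope[pi]
  v12 <- plasticity$cov_int_slope[pi]
  var_pred <- v11 + 2 * t_acc * v12 + t_acc^2 * v22
  if (include_tau2) var_pred <- var_pred + plasticity$residual_tau2[pi]
  dt$ctmax_day <- a + b * t_acc
  dt$ctmax_day_se <- sqrt(var_pred)

  # day-count alignment check per occurrence
  cnt <- dt[, .N, by = c("species", "cell_id")]
  if (length(unique(cnt$N)) > 1L)
    stop("misaligned series: per-occurrence day counts range ",
         min(cnt$N), "-", max(cnt$N))

  per <- dt[, tsm_summary(daily_max, ctmax_day, ctmax_day_se, year,
                          policy = policy, tsm_variant = tsm_variant,
                          risk_variant = risk_variant, trim = trim,
                          n_days_total = .N),
            by = c("species", "cell_id")]
  meta <- unique(exposure[, intersect(c("cell_id", "lat", "lon",
                                        "microhabitat", "scenario"),
                                      names(exposure)), with = FALSE])
  out <- merge(per, meta, by = "cell_id")
  data.table::setcolorder(out, c("species", "cell_id"))
  as.data.frame(out)
}
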