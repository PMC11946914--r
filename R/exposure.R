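#' Select the warmest quarter of one year of daily maxima
#'
#' Default: the contiguous 91-day window with the highest mean daily maximum
#' (a true quarter), tie-broken to the earliest start. The alternative takes
#' the 91 individually warmest days wherever they fall.
#'
#' @param x numeric vector of one cell-year of daily maxima (length >= 91)
#' @param len window length in days (91 = a quarter)
#' @param method `"contiguous"` (default) or `"top"`
#' @return sorted integer day indices (length `len`)
#' @export
select_warmest_quarter <- function(x, len = 91L, method = c("contiguous", "top")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < len) stop("year has ", n, " days; need >= ", len)
  if (method == "contiguous") {
    cs <- cumsum(c(0, x))
    sums <- cs[(len + 1L):(n + 1L)] - cs[1:(n - len + 1L)]
    s <- which.max(sums)  # earliest window on ties
    seq.int(s, s + len - 1L)
  } else {
    sort(order(x, decreasing = TRUE)[seq_len(len)])
  }
}

#' Trailing-week statistics of a daily series
#'
#' Mean and maximum of the `window` daily maxima strictly before day `d`
#' (days d-window ... d-1); the focal day is excluded.
#'
#' @param x numeric daily series (unrestricted, so early retained days can
#'   draw history from the burn-in year)
#' @param d focal day index (vectorized)
#' @param window trailing window length in days
#' @return data.frame: d, week_mean, week_max (`NA` where history is short)
#' @export
trailing_week_stats <- function(x, d, window = 7L) {
  wm <- vapply(d, function(i) {
    if (i - window < 1L) return(c(NA_real_, NA_real_))
    h <- x[(i - window):(i - 1L)]
    c(mean(h), max(h))
  }, numeric(2))
  data.frame(d = d, week_mean = wm[1, ], week_max = wm[2, ])
}

#' Build warmest-quarter exposure series from raw daily temperatures
#'
#' Computes trailing-week statistics on the full per-cell series (so the
#' burn-in year supplies history to the first retained year), drops the
#' burn-in (first) year, and restricts each remaining cell-year to its
#' warmest quarter. Exactly `quarter_len` rows per cell-year are retained.
#'
#' @param temps long table from [simulate_operative_temps()] (or matching
#'   schema: cell_id, lat, lon, microhabitat, scenario, year, doy, day_index,
#'   daily_max); a single microhabitat and scenario per call
#' @param window trailing window (days)
#' @param quarter_len days retained per year
#' @param method see [select_warmest_quarter()]
#' @param burn_in_years years to drop (default: the earliest year present)
#' @return `data.table` of retained days with added `week_mean`, `week_max`
#' @export
build_exposure <- function(temps, window = 7L, quarter_len = 91L,
                           method = c("contiguous", "top"),
                           burn_in_years = NULL) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(temps)
  req <- c("cell_id", "year", "doy", "day_index", "daily_max")
  if (!all(req %in% names(dt)))
    stop("temps must have columns: ", paste(req, collapse = ", "))
  if ("scenario" %in% names(dt) && length(unique(dt$scenario)) > 1L)
    stop("one scenario per build_exposure call")
  if ("microhabitat" %in% names(dt) && length(unique(dt$microhabitat)) > 1L)
    stop("one microhabitat per build_exposure call")
  if (is.null(burn_in_years)) burn_in_years <- min(dt$year)
  data.table::setorder(dt, cell_id, day_index)
  daily_max <- day_index <- year <- week_mean <- NULL  # R CMD check NSE
  dt[, `:=`(
    week_mean = data.table::shift(
      data.table::frollmean(daily_max, window, align = "right"), 1L),
    week_max = data.table::shift(
      data.table::frollapply(daily_max, window, max, align = "right"), 1L)
  ), by = "cell_id"]
  dt <- dt[!year %in% burn_in_years]
  keep <- dt[, .I[select_warmest_quarter(daily_max, quarter_len, method)],
             by = c("cell_id", "year")]$V1
  out <- dt[sort(keep)]
  if (anyNA(out$week_mean))
    warning(sum(is.na(out$week_mean)),
            " retained day(s) lack trailing-week history")
  out[]
}

#' Range-wide operative temperature percentiles per species
#'
#' Pools retained-day daily maxima over all cells a species occupies
#' (terrestrial, current scenario by convention) and returns the 5th, 50th
#' and 95th percentiles; these are the reference acclimatization temperatures
#' the imputation predicts at. Percentile convention: linear interpolation
#' between order statistics (R quantile type 7).
#'
#' @param occurrences data.frame: species, cell_id
#' @param exposure retained-day exposure table from [build_exposure()]
#' @return data.frame: species, t_p5, t_median, t_p95
#' @export
range_percentiles <- function(occurrences, exposure) {
  occurrences <- as.data.frame(occurrences)
  exposure <- data.table::as.data.table(exposure)
  by_cell <- split(exposure$daily_max, exposure$cell_id)
  sp_cells <- split(as.character(occurrences$cell_id), occurrences$species)
  orphan <- names(sp_cells)[vapply(sp_cells, function(cc)
    !any(cc %in% names(by_cell)), logical(1))]
  if (length(orphan))
    stop("no exposure data for the range of: ",
         paste(utils::head(orphan, 10), collapse = ", "))
  out <- lapply(names(sp_cells), function(s) {
    v <- unlist(by_cell[intersect(sp_cells[[s]], names(by_cell))],
                use.names = FALSE)
    q <- stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
    data.frame(species = s, t_p5 = q[1], t_median = q[2], t_p95 = q[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
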