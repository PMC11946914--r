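#' Aggregate occurrence-level vulnerability to one grid-cell assemblage
#'
#' @param records vulnerability rows ([assess_vulnerability()]) for a single
#'   cell, scenario and microhabitat
#' @param weighted inverse-variance weight species TSMs (default); `FALSE`
#'   gives the unweighted mean with `se = sd/sqrt(n)`
#' @return one-row data.frame: cell_id, lat, lon, microhabitat, scenario,
#'   n_species, tsm_mean, tsm_se, n_overheating_species, prop_overheating
#' @export
aggregate_cell <- function(records, weighted = TRUE) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("no records for this cell")
  for (cv in c("cell_id", "scenario", "microhabitat")) {
    if (cv %in% names(records) && length(unique(records[[cv]])) > 1L)
      stop("mixed ", cv, " values in one aggregate_cell call")
  }
  wm <- if (weighted) weighted_mean_se(records$tsm_mean, records$tsm_se)
        else list(mean = mean(records$tsm_mean),
                  se = stats::sd(records$tsm_mean) / sqrt(nrow(records)))
  n <- nrow(records)
  n_over <- sum(records$risk_binary)
  data.frame(cell_id = records$cell_id[1],
             lat = if ("lat" %in% names(records)) records$lat[1] else NA_real_,
             lon = if ("lon" %in% names(records)) records$lon[1] else NA_real_,
             microhabitat = if ("microhabitat" %in% names(records))
               records$microhabitat[1] else NA_character_,
             scenario = if ("scenario" %in% names(records))
               records$scenario[1] else NA_character_,
             n_species = n, tsm_mean = wm$mean, tsm_se = wm$se,
             n_overheating_species = n_over, prop_overheating = n_over / n,
             stringsAsFactors = FALSE)
}

#' Aggregate a whole vulnerability table to assemblages
#'
#' @param vuln vulnerability table, possibly spanning several scenarios and
#'   microhabitats (grouped automatically)
#' @param weighted see [aggregate_cell()]
#' @return data.frame of assemblage summaries, one row per cell x scenario x
#'   microhabitat
#' @export
aggregate_assemblages <- function(vuln, weighted = TRUE) {
  vuln <- as.data.frame(vuln)
  keys <- intersect(c("cell_id", "scenario", "microhabitat"), names(vuln))
  grp <- interaction(vuln[keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(vuln, grp), aggregate_cell,
                               weighted = weighted))
  rownames(out) <- NULL
  out[order(out$cell_id), , drop = FALSE]
}

#' Percentage of species affected, at the paper-style display precision
#'
#' @param n numerator (species count)
#' @param total denominator (species universe)
#' @param digits decimal places (0 for abstract-style integers, 1 elsewhere)
#' @return percentage, rounded
#' @export
pct_species <- function(n, total, digits = 1) {
  if (total == 0) return(NA_real_)
  round(100 * n / total, digits)
}

#' Percentage of simulated days represented by an overheating-day count
#' @param n_days overheating days
#' @param total total simulated days (910)
#' @param digits decimal places
#' @export
pct_days <- function(n_days, total = 910, digits = 1) {
  if (total == 0) return(NA_real_)
  round(100 * n_days / total, digits)
}

#' Percentage reduction in affected species between two microhabitats
#' @param n_ground species affected at ground level
#' @param n_refuge species affected in the refuge microhabitat
#' @param digits decimal places
#' @export
pct_reduction <- function(n_ground, n_refuge, digits = 1) {
  if (n_ground == 0) return(NA_real_)
  round(100 * (1 - n_refuge / n_ground), digits)
}

#' Headline ratio statistics across scenarios and microhabitats
#'
#' Computes, from an occurrence-level vulnerability table (or a pre-counted
#' summary), the report-style numbers: species overheating per scenario and
#' microhabitat (count and percentage of the species universe), fold changes
#' between scenarios, the percentage reduction afforded by each refuge
#' microhabitat relative to terrestrial conditions, and the maximum
#' overheating-day count as a percentage of the simulated days. Raw
#' numerators and denominators are always retained.
#'
#' @param vuln vulnerability table spanning scenarios/microhabitats (columns
#'   species, scenario, microhabitat, risk_binary, n_overheat_days,
#'   n_days_total)
#' @param n_species_total species universe size (default: distinct species
#'   in `vuln`)
#' @return list of class `headline_stats`: `by_group` (data.frame with
#'   counts, percentages, max overheating days and their day-percentage),
#'   `fold_change` between consecutive scenarios, `refuge_reduction`
#'   (terrestrial vs other microhabitats, per scenario), `n_species_total`
#' @export
headline_stats <- function(vuln, n_species_total = NULL) {
  vuln <- as.data.frame(vuln)
  if (is.null(n_species_total))
    n_species_total <- length(unique(vuln$species))
  if (n_species_total == 0) stop("empty species universe")
  if (!"microhabitat" %in% names(vuln)) vuln$microhabitat <- "terrestrial"
  if (!"scenario" %in% names(vuln)) vuln$scenario <- "current"
  grp <- split(vuln, interaction(vuln$scenario, vuln$microhabitat, drop = TRUE))
  by_group <- do.call(rbind, lapply(grp, function(d) {
    over_sp <- unique(d$species[d$risk_binary == 1])
    data.frame(scenario = d$scenario[1], microhabitat = d$microhabitat[1],
               n_overheating_species = length(over_sp),
               n_species_total = n_species_total,
               pct_overheating = pct_species(length(over_sp), n_species_total),
               max_overheat_days = max(d$n_overheat_days),
               pct_max_overheat_days = pct_days(max(d$n_overheat_days),
                                                d$n_days_total[1]),
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  scen <- unique(by_group$scenario)
  fold <- NULL
  if (length(scen) > 1L) {
    fold <- do.call(rbind, lapply(split(by_group, by_group$microhabitat),
      function(d) {
        d <- d[order(d$scenario), ]
        if (nrow(d) < 2L) return(NULL)
        data.frame(microhabitat = d$microhabitat[1],
                   from = d$scenario[-nrow(d)], to = d$scenario[-1],
                   fold = ifelse(d$n_overheating_species[-nrow(d)] > 0,
                                 d$n_overheating_species[-1] /
                                   d$n_overheating_species[-nrow(d)], NA),
                   stringsAsFactors = FALSE)
      }))
    if (!is.null(fold)) rownames(fold) <- NULL
  }
  refuge <- NULL
  if ("terrestrial" %in% by_group$microhabitat &&
      length(unique(by_group$microhabitat)) > 1L) {
    refuge <- do.call(rbind, lapply(split(by_group, by_group$scenario),
      function(d) {
        g <- d$n_overheating_species[d$microhabitat == "terrestrial"]
        if (!length(g)) return(NULL)
        r <- d[d$microhabitat != "terrestrial", , drop = FALSE]
        if (!nrow(r)) return(NULL)
        data.frame(scenario = r$scenario, microhabitat = r$microhabitat,
                   n_ground = g, n_refuge = r$n_overheating_species,
                   pct_reduction = vapply(r$n_overheating_species,
                                          function(nr) pct_reduction(g, nr),
                                          numeric(1)),
                   stringsAsFactors = FALSE)
      }))
    if (!is.null(refuge)) rownames(refuge) <- NULL
  }
  structure(list(by_group = by_group, fold_change = fold,
                 refuge_reduction = refuge,
                 n_species_total = n_species_total),
            class = "headline_stats")
}

#' @export
print.headline_stats <- function(x, ...) {
  cat("headline_stats over", x$n_species_total, "species:\n")
  print(x$by_group)
  invisible(x)
}
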