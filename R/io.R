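.hm_vocab <- list(
  endpoint = c("onset_of_spasms", "loss_of_righting", "other"),
  medium = c("water", "air"),
  life_stage = c("adult", "larva"),
  ecotype = c("ground-dwelling", "fossorial", "aquatic", "semi-aquatic",
              "stream-dwelling", "arboreal")
)

#' Read a trait table from CSV
#' @param path CSV file with the trait-record schema
#' @return data.frame
#' @export
read_trait_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  req <- c("species", "ctmax", "ctmax_se", "t_acc")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("traits file missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Read an occurrence table from CSV
#' @param path CSV with columns species, cell_id (lat/lon optional)
#' @return data.frame
#' @export
read_occurrences <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  miss <- setdiff(c("species", "cell_id"), names(df))
  if (length(miss)) stop("occurrence file missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Read a daily temperature table from CSV
#' @param path CSV with cell_id, year, doy, day_index, daily_max (+ metadata)
#' @return data.table
#' @export
read_temps <- function(path) {
  dt <- data.table::fread(path)
  miss <- setdiff(c("cell_id", "year", "doy", "day_index", "daily_max"),
                  names(dt))
  if (length(miss)) stop("temperature file missing columns: ",
                         paste(miss, collapse = ", "))
  dt
}

#' Schema and referential-integrity validation of pipeline inputs
#'
#' Checks column presence and types, closed categorical vocabularies,
#' positive sampling SEs, the CT_max/SE pairing invariant, duplicate tree
#' tips, species coverage of the tree, and cell coverage of the temperature
#' tables.
#'
#' @param traits,tree,occurrences paths (any may be `NULL` to skip)
#' @param temps character vector of temperature CSV paths (optional)
#' @return data.frame of violations (zero rows when everything checks out),
#'   columns `table`, `check`, `message`
#' @export
validate_tables <- function(traits = NULL, tree = NULL, occurrences = NULL,
                            temps = NULL) {
  v <- list()
  bad <- function(tb, ck, msg) v[[length(v) + 1L]] <<-
    data.frame(table = tb, check = ck, message = msg, stringsAsFactors = FALSE)
  tr <- NULL
  if (!is.null(tree)) {
    tr <- tryCatch(read_newick(tree), error = function(e) {
      bad("tree", "parse", conditionMessage(e)); NULL
    })
  }
  td <- NULL
  if (!is.null(traits)) {
    td <- tryCatch(read_trait_table(traits), error = function(e) {
      bad("traits", "schema", conditionMessage(e)); NULL
    })
    if (!is.null(td)) {
      if (any(!is.na(td$ctmax_se) & td$ctmax_se <= 0))
        bad("traits", "ctmax_se", "non-positive ctmax_se values present")
      if (any(!is.na(td$ctmax) & is.na(td$ctmax_se)))
        bad("traits", "se_pairing", "ctmax present without ctmax_se")
      for (cv in names(.hm_vocab)) {
        if (!cv %in% names(td)) next
        lv <- setdiff(unique(stats::na.omit(td[[cv]])), .hm_vocab[[cv]])
        if (length(lv))
          bad("traits", paste0("vocab_", cv),
              paste("unknown", cv, "levels:", paste(lv, collapse = ", ")))
      }
      if (!is.null(tr)) {
        ms <- setdiff(unique(td$species), tr$tip.label)
        if (length(ms))
          bad("traits", "species_in_tree",
              paste("species missing from tree:",
                    paste(utils::head(ms, 10), collapse = ", ")))
      }
    }
  }
  oc <- NULL
  if (!is.null(occurrences)) {
    oc <- tryCatch(read_occurrences(occurrences), error = function(e) {
      bad("occurrences", "schema", conditionMessage(e)); NULL
    })
    if (!is.null(oc) && !is.null(tr)) {
      ms <- setdiff(unique(oc$species), tr$tip.label)
      if (length(ms))
        bad("occurrences", "species_in_tree",
            paste("species missing from tree:",
                  paste(utils::head(ms, 10), collapse = ", ")))
    }
  }
  if (!is.null(temps)) {
    all_cells <- character()
    for (p in temps) {
      tp <- tryCatch(read_temps(p), error = function(e) {
        bad(basename(p), "schema", conditionMessage(e)); NULL
      })
      if (!is.null(tp)) all_cells <- union(all_cells,
                                           as.character(unique(tp$cell_id)))
    }
    if (!is.null(oc) && length(all_cells)) {
      ms <- setdiff(as.character(unique(oc$cell_id)), all_cells)
      if (length(ms))
        bad("occurrences", "cells_in_temps",
            paste("occurrence cells without temperatures:",
                  paste(utils::head(ms, 10), collapse = ", ")))
    }
  }
  if (!length(v))
    return(data.frame(table = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

# tiny rolling hash for the run manifest (no external digest dependency)
.hm_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (v in utf8ToInt(as.character(s))) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}
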