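#' Read a rooted phylogeny from Newick text or a file
#'
#' Thin wrapper around [ape::read.tree()] with the validation the rest of the
#' pipeline relies on: unique tip labels, non-negative branch lengths, and a
#' policy for edges written without a `:length`.
#'
#' @param x Newick string (must end in `;`) or path to a file containing one.
#' @param missing_branch Policy for edges with no branch length: `"error"`
#'   (default) or `"zero"` (set to 0 with a warning).
#' @param normalize Label normalization applied on read: `"underscore"`
#'   (spaces become underscores, the convention of most published trees) or
#'   `"none"`.
#' @return An [ape::phylo] object (rooted, branch lengths in the input's
#'   units). Internal node labels are dropped.
#' @export
read_newick <- function(x, missing_branch = c("error", "zero"),
                        normalize = c("underscore", "none")) {
  missing_branch <- match.arg(missing_branch)
  normalize <- match.arg(normalize)
  if (length(x) != 1L || !is.character(x))
    stop("`x` must be a single Newick string or file path")
  txt <- if (file.exists(x) && !grepl(";", x, fixed = TRUE)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  .check_parens(txt)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree found in input")
  if (normalize == "underscore") tr$tip.label <- gsub(" ", "_", tr$tip.label)
  if (anyDuplicated(tr$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    if (missing_branch == "error")
      stop("tree has no branch lengths (use missing_branch = \"zero\" to default them)")
    warning("branch lengths missing; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (missing_branch == "error")
      stop("some edges have no branch length (use missing_branch = \"zero\")")
    warning(sum(is.na(tr$edge.length)), " missing branch lengths set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  tr$node.label <- NULL
  tr
}

# balanced-parenthesis pre-check so parse failures name a position
.check_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  if (!grepl(";\\s*$", txt))
    stop("Newick parse error: input does not end with ';'")
  invisible(TRUE)
}

#' Serialize a phylogeny to Newick
#'
#' @param tree an `phylo` object
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly, if written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Phylogenetic covariance matrix with Pagel's lambda scaling
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j
#' (the Brownian-motion trait covariance implied by the tree); off-diagonal
#' entries are multiplied by `lambda`, the diagonal is left unchanged.
#'
#' @param tree a `phylo` object with >= 2 tips and branch lengths.
#' @param lambda phylogenetic signal in `[0, 1]`. `lambda = 0` gives a
#'   diagonal (star-phylogeny) matrix; `lambda = 1` the raw tree covariance.
#' @param correlation if `TRUE`, standardize to a correlation matrix
#'   (unit diagonal) before applying `lambda`; this is the form the
#'   imputation model consumes.
#' @return object of class `phylo_cov`: list with `labels` (tip order),
#'   `matrix` (symmetric PSD), and `lambda`.
#' @export
phylo_covariance <- function(tree, lambda = 1, correlation = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 tips")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  V <- ape::vcv(tree)
  if (correlation) V <- stats::cov2cor(V)
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  structure(list(labels = rownames(V), matrix = V, lambda = lambda),
            class = "phylo_cov")
}

#' @export
print.phylo_cov <- function(x, ...) {
  cat("phylo_cov:", length(x$labels), "species, lambda =", x$lambda, "\n")
  invisible(x)
}

#' Prune a phylogeny to a set of tip labels
#'
#' Induced subtree on the requested tips; path lengths between retained tips
#' are preserved (degree-2 nodes are collapsed and their branch lengths
#' summed).
#'
#' @param tree a `phylo` object
#' @param names species labels to retain
#' @param on_missing `"error"` if some names are absent from the tree, or
#'   `"drop"` to ignore them with a warning.
#' @export
prune_and_match <- function(tree, names, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(tree, "phylo"))
  names <- unique(as.character(names))
  absent <- setdiff(names, tree$tip.label)
  if (length(absent)) {
    if (on_missing == "error")
      stop("species not in tree: ", paste(absent, collapse = ", "))
    warning("dropping ", length(absent), " species not in tree")
    names <- setdiff(names, absent)
  }
  if (!length(names)) stop("no requested species present in the tree")
  if (length(names) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, names)
}
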