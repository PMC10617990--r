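#' Read a rooted Newick tree
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the
#' comparative machinery relies on: unique tip labels, branch lengths
#' present and non-negative, rooted topology.  Polytomies are preserved.
#'
#' @param path path to a Newick file.
#' @return an [ape] `phylo` object; query [is_ultrametric()] as needed.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick file: ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Is a tree ultrametric?
#'
#' All root-to-tip path lengths equal within a relative tolerance.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depths)) <= tol * max(depths)
}

tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Read a species-by-trait table
#'
#' CSV with a header row of trait names and a first column of species
#' identifiers.  Values are parsed as numbers; empty cells become `NA`
#' (missing).  Returned as a numeric matrix with species row names — the
#' container all comparative operations take.
#'
#' @param path path to the CSV file.
#' @return numeric matrix, rows = species, columns = traits.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("trait table needs a species column and >= 1 trait")
  species <- df[[1L]]
  if (anyDuplicated(species))
    stop("duplicate species: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  traits <- colnames(df)[-1L]
  if (anyDuplicated(traits))
    stop("duplicate trait names: ",
         paste(unique(traits[duplicated(traits)]), collapse = ", "))
  vals <- sapply(df[-1L], function(col) {
    col <- trimws(col)
    bad <- nzchar(col) & is.na(suppressWarnings(as.numeric(col)))
    if (any(bad))
      stop("non-numeric cell value(s): ", paste(col[bad], collapse = ", "))
    out <- suppressWarnings(as.numeric(col))
    out[!nzchar(col)] <- NA_real_
    out
  })
  vals <- matrix(vals, nrow = length(species),
                 dimnames = list(species, traits))
  vals
}

#' Write a species-by-trait table
#'
#' @param traits numeric matrix with species row names.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  df <- data.frame(species = rownames(traits), traits,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write result tables with a provenance manifest
#'
#' Each table is written as a headed CSV; a `manifest.json` alongside
#' records file names, package version, a hash of the configuration, and
#' the random seeds used, so a run can be reproduced from its outputs.
#'
#' @param tables named list of data frames (or matrices).
#' @param path output directory (created if needed).
#' @param config optional configuration list stored (hashed) in the manifest.
#' @param seeds optional named numeric vector of seeds used.
#' @return invisible character vector of written file paths (manifest last).
#' @export
write_results <- function(tables, path, config = list(), seeds = NULL) {
  if (length(tables) && is.null(names(tables)))
    stop("tables must be a named list")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    tb <- tables[[nm]]
    if (is.matrix(tb)) tb <- as.data.frame(tb)
    utils::write.csv(tb, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    files = basename(files),
    package = "foliametry",
    version = as.character(utils::packageVersion("foliametry")),
    config_hash = config_hash(config),
    seeds = as.list(seeds),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mf <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}

# order-stable structural hash of a configuration list (no extra deps)
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  raw <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Match tree tips against trait-table species
#'
#' Exact string matching; any mismatch on either side is reported, never
#' silently dropped.
#'
#' @param tree a `phylo` tree.
#' @param traits trait matrix with species row names.
#' @param on_mismatch `"error"` or `"prune"`; pruning drops unmatched tips
#'   and species with a warning listing the offending labels.
#' @return list with elements `tree` and `traits`, rows of `traits`
#'   reordered to `tree$tip.label`.
#' @export
match_tree_traits <- function(tree, traits, on_mismatch = c("error", "prune")) {
  on_mismatch <- match.arg(on_mismatch)
  tips <- tree$tip.label
  sp <- rownames(traits)
  only_tree <- setdiff(tips, sp)
  only_tab <- setdiff(sp, tips)
  if (length(only_tree) || length(only_tab)) {
    msg <- paste0(
      if (length(only_tree)) paste0("tips absent from trait table: ",
                                    paste(only_tree, collapse = ", ")),
      if (length(only_tree) && length(only_tab)) "; ",
      if (length(only_tab)) paste0("species absent from tree: ",
                                   paste(only_tab, collapse = ", ")))
    if (on_mismatch == "error") stop(msg)
    warning("pruning unmatched labels — ", msg)
    keep <- intersect(tips, sp)
    if (length(keep) < 3L) stop("fewer than 3 matched species remain")
    tree <- ape::keep.tip(tree, keep)
  }
  list(tree = tree, traits = traits[tree$tip.label, , drop = FALSE])
}

#' Drop species with missing trait values
#'
#' Comparative fits need complete cases; the default behaviour drops
#' incomplete species with a warning (set `action = "error"` to refuse).
#'
#' @param traits trait matrix.
#' @param action `"drop"` (default) or `"error"`.
#' @return trait matrix of complete rows.
#' @export
complete_trait_cases <- function(traits, action = c("drop", "error")) {
  action <- match.arg(action)
  bad <- rownames(traits)[!stats::complete.cases(traits)]
  if (length(bad)) {
    if (action == "error")
      stop("missing trait values for: ", paste(bad, collapse = ", "))
    warning("dropping species with missing traits: ",
            paste(bad, collapse = ", "))
    traits <- traits[stats::complete.cases(traits), , drop = FALSE]
  }
  traits
}
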