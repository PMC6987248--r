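# Shared helpers: seeded evaluation, tree bookkeeping, name normalisation.

#' Evaluate code under a fixed random seed, restoring the RNG state afterwards
#'
#' All stochastic functions in the package funnel their randomness through
#' this helper so that a `seed` argument gives bit-reproducible output without
#' clobbering the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Node ages of an ultrametric (or near-ultrametric) tree
#'
#' Ages are time before present: tips at (approximately) 0, root deepest.
#'
#' @param tree A rooted `phylo` object with edge lengths in time units.
#' @return Numeric vector of length `Ntip + Nnode`, indexed by node id.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Is a tree ultrametric to a relative tolerance?
#'
#' @param tree A rooted `phylo`.
#' @param tol Relative tolerance on tip-depth spread, as a fraction of root
#'   age.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  ra <- max(depth)
  if (ra == 0) return(TRUE)
  (max(depth) - min(depth)) < tol * ra
}

#' Bipartition keys for the internal nodes of a rooted tree
#'
#' Each internal node is identified by the sorted set of tip labels it
#' subtends, so matching survives arbitrary newick rotations and node
#' renumbering.
#'
#' @param tree A rooted `phylo`.
#' @return Character vector named by internal node id (as character); values
#'   are the sorted tip labels joined by `"\\r"`.
#' @export
clade_keys <- function(tree) {
  n <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "\r"), "")
  names(keys) <- as.character(n + seq_along(pp))
  keys
}

#' Normalise a binomial species name
#'
#' Collapses whitespace, capitalises the genus and lower-cases the epithet,
#' so checklist lookups are robust to case/whitespace variants.
#'
#' @param x Character vector of species names.
#' @return Character vector of normalised names.
#' @export
normalize_binomial <- function(x) {
  x <- gsub("_", " ", trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  vapply(x, function(nm) {
    if (!nzchar(nm)) return(nm)
    parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
    parts <- tolower(parts)
    substr(parts[1], 1, 1) <- toupper(substr(parts[1], 1, 1))
    paste(parts, collapse = " ")
  }, "", USE.NAMES = FALSE)
}

# Parent node of every node (NA for the root), from the edge matrix.
parent_vec <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  par <- rep(NA_integer_, ntot)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# Internal nodes in preorder (root first, parents before children).
preorder_internal <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  n <- ape::Ntip(tree)
  nodes <- unique(c(n + 1L, tr$edge[tr$edge[, 2] > n, 2]))
  nodes
}

# Strip bracketed header comments (e.g. provenance headers) from a newick
# file and read the first tree.
read_tree_file <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*\\[", txt)]
  tr <- ape::read.tree(text = paste(txt, collapse = "\n"))
  if (is.null(tr)) stop("no tree could be parsed from ", path)
  tr
}

# Write a tree with an optional bracket-comment header line.
write_tree_file <- function(tree, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("[", header, "]"), con)
  writeLines(ape::write.tree(tree), con)
  invisible(path)
}
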