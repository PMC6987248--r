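# Constraint-tree construction: an order-level backbone topology with
# families attached as polytomies inside their orders; genera and species
# impose no structure below the family level.

newick_label <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Build a topological constraint tree from a taxonomy and an order backbone
#'
#' Each tip of the backbone (an order name) is replaced by a polytomy of the
#' order's families; each family node is a polytomy of its species.  Genera
#' are ignored, monotypic families become a bare tip under their order, and
#' no branch lengths are written.
#'
#' @param taxonomy data.frame with columns `species`, `genus`, `family`,
#'   `order` (see [read_taxonomy()]).
#' @param backbone Rooted `phylo` whose tip labels are order names, covering
#'   every order in the taxonomy; backbone orders without sampled species
#'   are dropped.
#' @param internal_labels Write family/order labels on internal nodes?
#' @return Newick string (no branch lengths), parseable by
#'   `ape::read.tree()`.
#' @export
build_constraint <- function(taxonomy, backbone, internal_labels = TRUE) {
  stopifnot(is.data.frame(taxonomy), inherits(backbone, "phylo"))
  if (any(!nzchar(taxonomy$family)) || anyNA(taxonomy$family))
    stop("species with missing family: ",
         paste(taxonomy$species[!nzchar(taxonomy$family)], collapse = ", "))
  missing_orders <- setdiff(unique(taxonomy$order), backbone$tip.label)
  if (length(missing_orders))
    stop("order(s) in taxonomy absent from backbone: ",
         paste(missing_orders, collapse = ", "))
  used <- intersect(backbone$tip.label, unique(taxonomy$order))
  bb <- if (length(used) < ape::Ntip(backbone) && length(used) >= 2)
    ape::keep.tip(backbone, used) else backbone
  order_subtree <- function(ord) {
    tx <- taxonomy[taxonomy$order == ord, ]
    fams <- unique(tx$family)
    parts <- vapply(fams, function(fam) {
      sp <- newick_label(tx$species[tx$family == fam])
      if (length(sp) == 1L) sp  # monotypic family: bare tip under the order
      else sprintf("(%s)%s", paste(sp, collapse = ","),
                   if (internal_labels) newick_label(fam) else "")
    }, "")
    sprintf("(%s)%s", paste(parts, collapse = ","),
            if (internal_labels) newick_label(ord) else "")
  }
  n <- ape::Ntip(bb)
  if (n == 1L) return(paste0(order_subtree(bb$tip.label), ";"))
  kids <- split(bb$edge[, 2], bb$edge[, 1])
  rec <- function(v) {
    if (v <= n) return(order_subtree(bb$tip.label[v]))
    sprintf("(%s)", paste(vapply(kids[[as.character(v)]], rec, ""),
                          collapse = ","))
  }
  paste0(rec(n + 1L), ";")
}

#' Check that a tree honours a constraint topology
#'
#' A tree is compatible with a (partially resolved) constraint when every
#' clade of the constraint appears as a clade of the tree; polytomies in the
#' constraint permit any resolution.
#'
#' @param constraint Newick string or `phylo` (the constraint).
#' @param tree Newick string or `phylo` (the tree to check); must have the
#'   same tip set.
#' @return List of class `"constraint_report"`: `compatible` (logical),
#'   `violations` (data.frame of constraint clades not recovered: label,
#'   size).
#' @export
check_constraint_compatibility <- function(constraint, tree) {
  as_tree <- function(x) if (inherits(x, "phylo")) x
                         else ape::read.tree(text = x)
  con <- as_tree(constraint)
  tr <- as_tree(tree)
  only_con <- setdiff(con$tip.label, tr$tip.label)
  only_tr <- setdiff(tr$tip.label, con$tip.label)
  if (length(only_con) || length(only_tr))
    stop("tip sets differ; only in constraint: ",
         paste(only_con, collapse = ", "), "; only in tree: ",
         paste(only_tr, collapse = ", "))
  ckeys <- clade_keys(con)
  tkeys <- clade_keys(tr)
  n <- ape::Ntip(con)
  sizes <- vapply(strsplit(unname(ckeys), "\r", fixed = TRUE), length, 0L)
  nontrivial <- sizes > 1 & sizes < n
  labs <- if (!is.null(con$node.label) && length(con$node.label))
    con$node.label else rep("", con$Nnode)
  labs[!nzchar(labs)] <- paste0("clade_", names(ckeys)[!nzchar(labs)])
  missing <- nontrivial & !(ckeys %in% tkeys)
  violations <- data.frame(label = labs[missing],
                           size = sizes[missing],
                           stringsAsFactors = FALSE)
  structure(list(compatible = nrow(violations) == 0,
                 violations = violations),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  if (x$compatible) cat("Tree is compatible with the constraint.\n")
  else {
    cat("Constraint clades not recovered:\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}
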