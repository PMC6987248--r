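# Bootstrap confidence intervals on node ages: date each pseudo-replicate
# phylogram on the fixed topology, collect per-node age samples keyed by
# bipartition, and annotate the point-estimate chronogram with empirical
# intervals.

#' Date a set of bootstrap pseudo-replicate phylograms
#'
#' Every replicate must share the fixed topology; each is dated with the
#' same calibrations and smoothing as the template problem.  Replicates are
#' warm-started from the template fit, which both speeds the fits and keeps
#' them on the same optimum branch.  Failures are excluded and counted.
#'
#' @param replicates List of [phylogram()] objects
#'   ([make_bootstrap_phylograms()]).
#' @param problem The template [pl_problem()] (the full-data problem).
#' @param template_fit Optional [date_tree()] fit of `problem`, reused for
#'   warm starts (computed if missing).
#' @param maxit Optimiser iteration cap per replicate.
#' @return List of chronograms (`phylo`, edge lengths in My) with attributes
#'   `"ages"` (list of node-age vectors) and `"n_failed"`.
#' @export
date_replicates <- function(replicates, problem, template_fit = NULL,
                            maxit = 300) {
  stopifnot(inherits(problem, "pl_problem"))
  ref_keys <- sort(clade_keys(problem$tree))
  if (is.null(template_fit)) template_fit <- date_tree(problem)
  out <- list()
  ages <- list()
  n_failed <- 0L
  for (i in seq_along(replicates)) {
    rep_i <- replicates[[i]]
    if (!identical(sort(clade_keys(rep_i$tree)), ref_keys))
      stop("replicate ", i, " does not match the fixed topology")
    prob_i <- problem
    prob_i$phylogram <- rep_i
    prob_i$tree <- rep_i$tree
    fit <- tryCatch(
      date_tree(prob_i, n_starts = 1, maxit = maxit,
                init = template_fit$par),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    out[[length(out) + 1L]] <- fit$chronogram
    ages[[length(ages) + 1L]] <- fit$ages
  }
  if (n_failed > 0)
    message(n_failed, " replicate(s) failed to date and were excluded")
  attr(out, "ages") <- ages
  attr(out, "n_failed") <- n_failed
  out
}

# Highest-density interval of a sample (shortest window covering `level`).
hpd_interval <- function(x, level) {
  x <- sort(x)
  m <- length(x)
  k <- max(1L, ceiling(level * m))
  if (k >= m) return(c(x[1], x[m]))
  widths <- x[(k):m] - x[seq_len(m - k + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}

#' Summarise replicate chronograms into per-node confidence intervals
#'
#' Per internal node (identified by its tip-set bipartition, so newick
#' rotations are irrelevant), the interval is the equal-tailed empirical
#' quantile pair at `(1-level)/2` and `1-(1-level)/2`, using linear
#' interpolation between order statistics (quantile type 7).  A
#' highest-density option is available for comparison.
#'
#' @param chronograms List of dated trees on one fixed topology
#'   ([date_replicates()]), length >= 2.
#' @param point_estimate The point-estimate chronogram (the full-data fit)
#'   the annotation is written onto.
#' @param level Interval level, default 0.95.
#' @param method `"quantile"` (equal-tailed, default) or `"hpd"`.
#' @return List of class `"annotated_chronogram"`: `tree` (the point
#'   estimate), `table` (data.frame: `node`, `clade_size`, `point_age`,
#'   `lower`, `upper`), `level`, `method`.
#' @export
summarize_node_ages <- function(chronograms, point_estimate, level = 0.95,
                                method = c("quantile", "hpd")) {
  method <- match.arg(method)
  stopifnot(length(chronograms) >= 2, inherits(point_estimate, "phylo"),
            level > 0, level < 1)
  pt_keys <- clade_keys(point_estimate)
  n <- ape::Ntip(point_estimate)
  samples <- matrix(NA_real_, nrow = length(pt_keys),
                    ncol = length(chronograms),
                    dimnames = list(names(pt_keys), NULL))
  for (j in seq_along(chronograms)) {
    tr <- chronograms[[j]]
    keys_j <- clade_keys(tr)
    ages_j <- node_ages(tr)
    idx <- match(pt_keys, keys_j)
    if (anyNA(idx))
      stop("replicate ", j, " lacks a node present in the point estimate")
    samples[, j] <- ages_j[as.integer(names(keys_j)[idx])]
  }
  pt_ages <- node_ages(point_estimate)
  alpha <- (1 - level) / 2
  lims <- t(apply(samples, 1, function(a) {
    if (method == "quantile")
      stats::quantile(a, c(alpha, 1 - alpha), names = FALSE, type = 7)
    else hpd_interval(a, level)
  }))
  sizes <- vapply(strsplit(unname(pt_keys), "\r", fixed = TRUE), length, 0L)
  tab <- data.frame(node = as.integer(names(pt_keys)), clade_size = sizes,
                    point_age = pt_ages[as.integer(names(pt_keys))],
                    lower = lims[, 1], upper = lims[, 2],
                    stringsAsFactors = FALSE)
  structure(list(tree = point_estimate, table = tab, level = level,
                 method = method, samples = samples),
            class = "annotated_chronogram")
}

#' @export
print.annotated_chronogram <- function(x, ...) {
  cat(sprintf(
    "Annotated chronogram: %d internal nodes, %.0f%% %s intervals\n",
    nrow(x$table), 100 * x$level, x$method))
  root <- x$table[which.max(x$table$clade_size), ]
  cat(sprintf("  root age %.2f My, interval [%.2f, %.2f]\n",
              root$point_age, root$lower, root$upper))
  invisible(x)
}

# Newick with per-node interval comments, written recursively so the
# annotation sits after each internal node's closing parenthesis.
annotated_newick <- function(x) {
  tr <- x$tree
  n <- ape::Ntip(tr)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  elen <- stats::setNames(tr$edge.length, tr$edge[, 2])
  ci <- x$table
  comment <- function(v) {
    row <- ci[ci$node == v, ]
    sprintf("[&age_%d_CI={%.6g,%.6g}]", round(100 * x$level), row$lower,
            row$upper)
  }
  rec <- function(v) {
    if (v <= n) return(tr$tip.label[v])
    inner <- paste(vapply(kids[[as.character(v)]], function(w) {
      paste0(rec(w), ":", format(elen[[as.character(w)]], digits = 10))
    }, ""), collapse = ",")
    paste0("(", inner, ")", comment(v))
  }
  paste0(rec(n + 1L), ";")
}

#' Write an annotated chronogram as NEXUS plus a per-node TSV
#'
#' The NEXUS tree carries per-node comment fields
#' `[&age_95_CI={lower,upper}]`; the TSV lists bipartition, point age and
#' interval per internal node.
#'
#' @param x An [summarize_node_ages()] result.
#' @param nexus_path Output NEXUS file.
#' @param table_path Optional output TSV.
#' @return `nexus_path`, invisibly.
#' @export
write_annotated_nexus <- function(x, nexus_path, table_path = NULL) {
  stopifnot(inherits(x, "annotated_chronogram"))
  lines <- c("#NEXUS", "begin trees;",
             paste0("  tree annotated = [&R] ", annotated_newick(x)),
             "end;")
  writeLines(lines, nexus_path)
  if (!is.null(table_path)) {
    keys <- clade_keys(x$tree)
    tab <- x$table
    tab$bipartition <- vapply(
      strsplit(unname(keys[as.character(tab$node)]), "\r", fixed = TRUE),
      paste, "", collapse = "|")
    utils::write.table(
      tab[, c("bipartition", "point_age", "lower", "upper")], table_path,
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(nexus_path)
}
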