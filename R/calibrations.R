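# Fossil calibration handling: the calibration table, hard maximum-age
# generation from fossil minimum ages, crown/stem node mapping, and emission
# of the dating configuration.

#' Construct a calibration set
#'
#' A calibration set is a data.frame with one row per calibrated clade:
#' `clade_label`, `fossil_name`, `min_age`, `max_age` (My), `placement`
#' (`"crown"` or `"stem"`) and a list-column `taxa` of tip labels defining
#' the clade (>= 2 for crown; >= 1 for stem, whose node is the parent of the
#' group's MRCA).
#'
#' @param clade_label Character vector of unique clade labels.
#' @param min_age,max_age Numeric ages in My, `0 < min < max` rowwise.
#' @param placement `"crown"` or `"stem"`, recycled.
#' @param taxa List of character vectors of tip labels (or `NULL` if mapping
#'   is supplied later via a clade-definition table).
#' @param fossil_name Optional fossil names.
#' @return data.frame of class `"calibration_set"`.
#' @export
calibration_set <- function(clade_label, min_age, max_age,
                            placement = "crown", taxa = NULL,
                            fossil_name = NA_character_) {
  n <- length(clade_label)
  placement <- rep_len(placement, n)
  if (!all(placement %in% c("crown", "stem")))
    stop("placement must be 'crown' or 'stem'")
  if (anyDuplicated(clade_label))
    stop("duplicate clade labels: ",
         paste(unique(clade_label[duplicated(clade_label)]), collapse = ", "))
  # min == max is allowed here (a pinned node age); the table reader is
  # stricter because a fossil table should always have min < max.
  bad <- which(!(min_age > 0 & min_age <= max_age))
  if (length(bad))
    stop("need 0 < min_age <= max_age; violated for clade(s): ",
         paste(clade_label[bad], collapse = ", "))
  out <- data.frame(clade_label = clade_label,
                    fossil_name = rep_len(fossil_name, n),
                    min_age = min_age, max_age = max_age,
                    placement = placement, stringsAsFactors = FALSE)
  out$taxa <- if (is.null(taxa)) rep(list(NULL), n) else taxa
  class(out) <- c("calibration_set", "data.frame")
  out
}

#' Maximum-age bound scheme
#'
#' The maxima of the fossil table are the fossil minimum ages plus a constant
#' interval width; the width can either be resolved empirically from a
#' calibration table (mode `"empirical"`, default width 16.82 My as resolved
#' from the packaged table) or computed analytically as the upper quantile of
#' a log-normal distribution offset at the fossil age (mode `"analytic"`:
#' `exp(log_mean + z(quantile_level) * log_sd)` added My, about 14.08 for
#' mean 1, sd 1, level 0.95).  The two modes do not coincide; the empirical
#' mode reproduces the table and is the default.
#'
#' @param mode `"empirical"` or `"analytic"`.
#' @param interval_width Constant width in My (empirical mode).
#' @param log_mean,log_sd Log-normal parameters (analytic mode).
#' @param quantile_level Upper quantile defining the analytic maximum.
#' @return List of class `"bound_scheme"`.
#' @export
bound_scheme <- function(mode = c("empirical", "analytic"),
                         interval_width = 16.82, log_mean = 1, log_sd = 1,
                         quantile_level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(interval_width > 0, log_sd > 0,
            quantile_level > 0, quantile_level < 1)
  structure(list(mode = mode, interval_width = interval_width,
                 log_mean = log_mean, log_sd = log_sd,
                 quantile_level = quantile_level), class = "bound_scheme")
}

#' Hard maximum age from a fossil minimum age
#'
#' @param min_age Fossil minimum age(s) in My, > 0.
#' @param scheme A [bound_scheme()].
#' @return Maximum age(s) in My.
#' @examples
#' compute_max_age(37.8)  # 54.62
#' compute_max_age(11.6)  # 28.42
#' @export
compute_max_age <- function(min_age, scheme = bound_scheme()) {
  if (any(min_age <= 0)) stop("min_age must be positive")
  if (scheme$mode == "empirical") {
    min_age + scheme$interval_width
  } else {
    min_age + exp(scheme$log_mean +
                    stats::qnorm(scheme$quantile_level) * scheme$log_sd)
  }
}

#' The hard root age constraint
#'
#' Default window for the root: minimum 180 My, maximum 220 My, a
#' conventional hard bracket for the angiosperm crown age.
#'
#' @param min_age,max_age Hard bounds in My.
#' @return List of class `"root_constraint"`.
#' @export
root_constraint <- function(min_age = 180, max_age = 220) {
  stopifnot(min_age > 0, min_age < max_age)
  structure(list(min_age = min_age, max_age = max_age),
            class = "root_constraint")
}

#' Read a fossil calibration table
#'
#' Expects a TSV with columns `clade`, `fossil`, `period`, `locality`,
#' `min_age`, `max_age`, `crown_stem` (tokens `cr.`/`st.` or
#' `crown`/`stem`).  The packaged table of 55 fossil calibrations is at
#' `system.file("extdata", "fossil_calibrations.tsv", package = "pldater")`;
#' adding the root window makes the number of calibration points one higher
#' than the number of fossil rows (the parser report attribute records
#' both counts).
#'
#' @param path Path to the TSV file.
#' @return A [calibration_set()] (without taxa; see
#'   [read_clade_definitions()]), with attribute `"report"` (list:
#'   `n_fossil_rows`, `n_with_root`).
#' @export
read_calibration_table <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("could not read calibration table ", path,
                             ": ", conditionMessage(e)))
  if (nrow(tab) == 0) stop("calibration table ", path, " has no rows")
  need <- c("clade", "min_age", "max_age", "crown_stem")
  if (!all(need %in% names(tab)))
    stop("calibration table must have columns: ",
         paste(need, collapse = ", "))
  tok <- trimws(tab$crown_stem)
  placement <- ifelse(tok %in% c("cr.", "cr", "crown"), "crown",
               ifelse(tok %in% c("st.", "st", "stem"), "stem", NA))
  if (anyNA(placement))
    stop("unknown crown/stem token(s): ",
         paste(unique(tok[is.na(placement)]), collapse = ", "))
  bad <- which(tab$min_age >= tab$max_age)
  if (length(bad))
    stop("min_age >= max_age in row(s): ",
         paste(tab$clade[bad], collapse = ", "))
  out <- calibration_set(clade_label = tab$clade,
                         fossil_name = if ("fossil" %in% names(tab))
                           tab$fossil else NA_character_,
                         min_age = tab$min_age, max_age = tab$max_age,
                         placement = placement)
  attr(out, "report") <- list(n_fossil_rows = nrow(tab),
                              n_with_root = nrow(tab) + 1L)
  out
}

#' Resolve the constant interval width of a calibration table
#'
#' Computes `max_age - min_age` for every row, rounds to 2 decimals (the
#' table's maxima are printed to at most 4 significant figures, so rows with
#' three-digit ages carry one decimal less), and returns the modal value.
#'
#' @param cals A [calibration_set()] or data.frame with `min_age`,
#'   `max_age`.
#' @return The modal interval width in My.
#' @export
resolve_interval_width <- function(cals) {
  d <- round(cals$max_age - cals$min_age, 2)
  tb <- table(d)
  as.numeric(names(tb)[which.max(tb)])
}

#' Read clade definitions (clade label -> tip names)
#'
#' TSV with columns `clade_label` and `taxa` (comma-separated tip labels),
#' used to attach tree-specific tip sets to a calibration table that defines
#' clades by name only.
#'
#' @param path Path to the TSV.
#' @return Named list of character vectors.
#' @export
read_clade_definitions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!all(c("clade_label", "taxa") %in% names(tab)))
    stop("clade definition table needs columns clade_label, taxa")
  stats::setNames(lapply(strsplit(tab$taxa, ","), trimws), tab$clade_label)
}

#' Attach tip sets to a calibration set
#'
#' @param cals A [calibration_set()].
#' @param clades Named list of tip-label vectors ([read_clade_definitions()]).
#' @return The calibration set with its `taxa` column filled.
#' @export
assign_clade_taxa <- function(cals, clades) {
  miss <- setdiff(cals$clade_label, names(clades))
  if (length(miss))
    stop("no clade definition for: ", paste(miss, collapse = ", "))
  cals$taxa <- unname(clades[cals$clade_label])
  cals
}

#' Map a calibration to its node in a tree
#'
#' Crown calibrations map to the most recent common ancestor of the
#' calibration's taxa; stem calibrations to that node's parent.  If the taxa
#' are not monophyletic in the tree the MRCA is still returned, with a
#' warning.
#'
#' @param tree A rooted `phylo`.
#' @param cal One row of a [calibration_set()] (or a list with `taxa`,
#'   `placement`, `clade_label`).
#' @return Internal node id.
#' @export
map_to_node <- function(tree, cal) {
  taxa <- if (is.data.frame(cal)) cal$taxa[[1]] else cal$taxa
  placement <- if (is.data.frame(cal)) cal$placement[1] else cal$placement
  label <- if (is.data.frame(cal)) cal$clade_label[1] else cal$clade_label
  if (is.null(taxa) || length(taxa) == 0)
    stop("calibration '", label, "' has no taxa assigned")
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss))
    stop("calibration '", label, "': taxa absent from tree: ",
         paste(miss, collapse = ", "))
  n <- ape::Ntip(tree)
  root <- n + 1L
  if (length(taxa) == 1L) {
    mrca <- match(taxa, tree$tip.label)
  } else {
    mrca <- ape::getMRCA(tree, taxa)
    desc <- ape::extract.clade(tree, mrca)$tip.label
    if (length(desc) > length(taxa))
      warning("calibration '", label, "': taxa are not monophyletic; ",
              "using their MRCA (", length(desc), " tips)")
  }
  if (placement == "crown") {
    if (length(taxa) == 1L)
      stop("crown calibration '", label, "' needs >= 2 taxa")
    mrca
  } else {
    if (mrca == root)
      stop("stem of the root requested for calibration '", label, "'")
    parent_vec(tree)[mrca]
  }
}

#' Emit a dating configuration in the treePL dialect
#'
#' One `mrca` line plus `min`/`max` lines per calibration (ordered by clade
#' label for byte-determinism), the root constraint, the smoothing value and
#' the alignment length.  Optionally writes the text to `path` and a JSON
#' mirror to `paste0(path, ".json")`.
#'
#' @param tree_path Path of the phylogram file the configuration refers to.
#' @param calibrations A [calibration_set()] with taxa assigned.
#' @param root A [root_constraint()].
#' @param smoothing Smoothing parameter (lambda).
#' @param n_sites Alignment length.
#' @param path Optional output file.
#' @param outfile Path the dated tree should be written to (config field).
#' @return Character vector of configuration lines, invisibly if written.
#' @export
emit_dating_config <- function(tree_path, calibrations,
                               root = root_constraint(), smoothing = 0.0033,
                               n_sites, path = NULL,
                               outfile = "dated.tre") {
  lines <- c(sprintf("treefile = %s", tree_path),
             sprintf("numsites = %d", as.integer(n_sites)),
             sprintf("smooth = %.10g", smoothing),
             sprintf("outfile = %s", outfile))
  if (nrow(calibrations) > 0) {
    if (any(vapply(calibrations$taxa, is.null, TRUE)))
      stop("unmapped calibration(s): assign taxa before emitting the config")
    ord <- order(calibrations$clade_label, method = "radix")
    for (i in ord) {
      lab <- gsub("[[:space:]]+", "_", calibrations$clade_label[i])
      taxa <- gsub("[[:space:]]+", "_", calibrations$taxa[[i]])
      lines <- c(lines,
                 sprintf("mrca = %s %s", lab, paste(taxa, collapse = " ")),
                 sprintf("min = %s %.10g", lab, calibrations$min_age[i]),
                 sprintf("max = %s %.10g", lab, calibrations$max_age[i]))
    }
  }
  lines <- c(lines,
             sprintf("min = root %.10g", root$min_age),
             sprintf("max = root %.10g", root$max_age))
  if (!is.null(path)) {
    writeLines(lines, path)
    jsonlite::write_json(
      list(treefile = tree_path, numsites = as.integer(n_sites),
           smooth = smoothing,
           calibrations = if (nrow(calibrations)) data.frame(
             clade_label = calibrations$clade_label,
             min_age = calibrations$min_age,
             max_age = calibrations$max_age,
             placement = calibrations$placement) else list(),
           root = list(min = root$min_age, max = root$max_age)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(lines))
  }
  lines
}

#' Write a calibration set in the fossil-table schema
#'
#' TSV with columns `clade`, `fossil`, `period`, `locality`, `min_age`,
#' `max_age`, `crown_stem`; optionally a companion clade-definition TSV
#' (`clade_label`, comma-separated `taxa`) when tip sets are present.
#'
#' @param cals A [calibration_set()].
#' @param path Output TSV path.
#' @param clades_path Optional path for the clade-definition TSV.
#' @return `path`, invisibly.
#' @export
write_calibration_table <- function(cals, path, clades_path = NULL) {
  tab <- data.frame(clade = cals$clade_label, fossil = cals$fossil_name,
                    period = NA_character_, locality = NA_character_,
                    min_age = cals$min_age, max_age = cals$max_age,
                    crown_stem = ifelse(cals$placement == "crown",
                                        "cr.", "st."),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(clades_path)) {
    def <- data.frame(
      clade_label = cals$clade_label,
      taxa = vapply(cals$taxa, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    utils::write.table(def, clades_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
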