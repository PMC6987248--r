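# Quality-control cascade for database-mined barcode sequences: an offline,
# auditable re-implementation of the mining filters -- similarity screen
# against a reference panel, best-accession choice, ambiguity filter,
# conflicting-duplicate removal, reading-frame screen for protein-coding
# spans, and dual-checklist name validation.  Every record receives exactly
# one verdict and every dropped record names the rule that fired.

QC_MARKERS <- c("matK_trnK", "rbcL")

#' Construct a set of taxon sequence records
#'
#' @param species_name Binomial species names.
#' @param marker `"matK_trnK"` or `"rbcL"` (recycled).
#' @param accession Unique accession identifiers.
#' @param sequence IUPAC nucleotide strings (non-empty).
#' @return data.frame with class `"taxon_records"`.
#' @export
taxon_records <- function(species_name, marker, accession, sequence) {
  marker <- rep_len(marker, length(species_name))
  if (!all(marker %in% QC_MARKERS))
    stop("marker must be one of: ", paste(QC_MARKERS, collapse = ", "))
  if (any(!nzchar(sequence))) stop("empty sequence(s)")
  out <- data.frame(species_name = species_name, marker = marker,
                    accession = accession,
                    sequence = toupper(sequence),
                    stringsAsFactors = FALSE)
  out$length <- nchar(out$sequence)
  class(out) <- c("taxon_records", "data.frame")
  out
}

count_ambiguous <- function(seq) {
  nchar(seq) - nchar(gsub("[^ACGT]", "", toupper(seq)))
}

qc_verdict <- function(kept, rule, detail = "") {
  list(kept = kept, rule = rule, detail = detail)
}

# Unique k-mers of a sequence.
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

# Karlin-Altschul style E-value surrogate for an ungapped-ish local score
# under the +1/-2 scoring used below.
local_evalue <- function(score, m, n, lambda = 1.33, K = 0.621) {
  K * m * n * exp(-lambda * score)
}

qc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = FALSE)
}

#' Similarity screen against a reference panel
#'
#' Offline surrogate for a megablast identity check: candidate references
#' are seeded by exact shared `word_size`-mers (capped at `max_hits`
#' candidates), scored by local alignment (+1/-2), and the record is kept
#' if and only if its best significant hit (E-value at most `min_evalue`)
#' belongs to the record's own family-level group -- i.e. the sequence is
#' not anomalous against its identification.
#'
#' @param record One-row [taxon_records()] (or list with `species_name`,
#'   `sequence`).
#' @param references [taxon_records()]-like data.frame with an extra
#'   `group` column (family-level group of each reference).
#' @param groups Named character vector mapping species names to groups
#'   (must cover the record's species).
#' @param min_evalue Maximum E-value of an acceptable best hit.
#' @param word_size Seed word length.
#' @param max_hits Candidate reference cap.
#' @return A verdict list: `kept`, `rule`, `detail`.
#' @export
similarity_screen <- function(record, references, groups,
                              min_evalue = 0.0005, word_size = 8,
                              max_hits = 250) {
  if (nrow(as.data.frame(references)) == 0) stop("empty reference panel")
  seq <- toupper(record$sequence[1])
  if (nchar(seq) < word_size)
    return(qc_verdict(FALSE, "too_short",
                      sprintf("length %d < word size %d", nchar(seq),
                              word_size)))
  sp <- record$species_name[1]
  if (is.na(groups[sp]))
    stop("no group known for species ", sp)
  words <- kmer_set(seq, word_size)
  shared <- vapply(references$sequence, function(r)
    sum(kmer_set(toupper(r), word_size) %in% words), 0L, USE.NAMES = FALSE)
  cand <- order(shared, decreasing = TRUE)
  cand <- cand[shared[cand] > 0]
  if (length(cand) == 0)
    return(qc_verdict(FALSE, "no_hit", "no seed word shared with panel"))
  cand <- utils::head(cand, max_hits)
  scores <- vapply(cand, function(i)
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(references$sequence[i])),
      Biostrings::DNAString(seq), type = "local",
      substitutionMatrix = qc_submat(), gapOpening = 5, gapExtension = 2,
      scoreOnly = TRUE), 0)
  best <- cand[which.max(scores)]
  e <- local_evalue(max(scores), nchar(seq),
                    sum(nchar(references$sequence)))
  if (e > min_evalue)
    return(qc_verdict(FALSE, "no_significant_hit",
                      sprintf("best E-value %.3g > %.3g", e, min_evalue)))
  hit_group <- references$group[best]
  if (identical(unname(hit_group), unname(groups[[sp]])))
    qc_verdict(TRUE, "similarity_ok",
               sprintf("best hit %s (group %s)", references$accession[best],
                       hit_group))
  else
    qc_verdict(FALSE, "cross_group_hit",
               sprintf("best hit %s is in group %s, record is %s",
                       references$accession[best], hit_group, groups[[sp]]))
}

# Percent identity (0..1) of a global pairwise alignment.
pairwise_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = qc_submat(),
    gapOpening = 4, gapExtension = 1)
  Biostrings::pid(al) / 100
}

#' Uncorrected p-distance between two sequences on their aligned overlap
#'
#' Sequences are globally aligned; the distance is the mismatch fraction
#' over columns where both sequences have an unambiguous base.
#'
#' @param a,b Nucleotide strings.
#' @return p-distance in `[0, 1]` (`NA` if no comparable columns).
#' @export
p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = qc_submat(), gapOpening = 4, gapExtension = 1)
    ca <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    cb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  }
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  mean(ca[ok] != cb[ok])
}

#' Choose the best accession among a species' records for one marker
#'
#' Lexicographic criteria: fewest ambiguity symbols per base, then greatest
#' length, then highest mean pairwise identity to the species' other
#' accessions; remaining ties broken by accession string order.
#'
#' @param records [taxon_records()] rows, all one species and marker.
#' @return The single best record (one-row data.frame).
#' @export
select_best_accession <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("no records to choose from")
  if (length(unique(records$species_name)) > 1 ||
      length(unique(records$marker)) > 1)
    stop("records must share one species and one marker")
  if (nrow(records) == 1) return(records)
  amb <- count_ambiguous(records$sequence) / nchar(records$sequence)
  len <- nchar(records$sequence)
  sim <- vapply(seq_len(nrow(records)), function(i)
    mean(vapply(setdiff(seq_len(nrow(records)), i), function(j)
      pairwise_identity(records$sequence[i], records$sequence[j]), 0)), 0)
  o <- order(amb, -len, -sim, records$accession, method = "radix")
  records[o[1], , drop = FALSE]
}

#' Ambiguity filter
#'
#' Drops a sequence when its fraction of non-ACGT IUPAC symbols exceeds
#' `max_ambiguous_frac`, or -- reading "multiple ambiguities" literally for
#' short sequences where the fractional threshold would allow fewer than two
#' symbols -- when at least two ambiguity symbols are present.
#'
#' @param record One-row [taxon_records()] (or list with `sequence`).
#' @param max_ambiguous_frac Maximum tolerated ambiguous fraction.
#' @return A verdict list.
#' @export
filter_ambiguous <- function(record, max_ambiguous_frac = 0.01) {
  seq <- record$sequence[1]
  n <- nchar(seq)
  amb <- count_ambiguous(seq)
  frac <- amb / n
  if (frac > max_ambiguous_frac ||
      (n * max_ambiguous_frac < 2 && amb >= 2))
    qc_verdict(FALSE, "ambiguous",
               sprintf("%d ambiguous of %d bases (%.3g%%)", amb, n,
                       100 * frac))
  else qc_verdict(TRUE, "ambiguity_ok", sprintf("%d ambiguous bases", amb))
}

#' Remove species with conflicting duplicate sequences; collapse the rest
#'
#' Within each species x marker group, pairwise p-distances are computed on
#' the aligned overlap: if any pair diverges beyond `max_divergence` the
#' species' records are removed entirely (same name, different sequence);
#' otherwise the group is collapsed to its best accession.
#'
#' @param records A [taxon_records()] data.frame.
#' @param max_divergence Divergence ceiling (default 5% p-distance).
#' @return Kept records, with attribute `"report"` (a data.frame with one
#'   verdict per input record).
#' @export
drop_conflicting_duplicates <- function(records, max_divergence = 0.05) {
  records <- as.data.frame(records)
  key <- paste(records$species_name, records$marker, sep = "\r")
  verdicts <- vector("list", nrow(records))
  keep <- logical(nrow(records))
  for (grp in split(seq_len(nrow(records)), key)) {
    if (length(grp) == 1) {
      keep[grp] <- TRUE
      verdicts[[grp]] <- qc_verdict(TRUE, "single_accession", "")
      next
    }
    pairs <- utils::combn(grp, 2)
    dmax <- max(apply(pairs, 2, function(p)
      p_distance(records$sequence[p[1]], records$sequence[p[2]])))
    if (is.na(dmax) || dmax > max_divergence) {
      for (i in grp) verdicts[[i]] <- qc_verdict(
        FALSE, "conflicting_duplicates",
        sprintf("accessions {%s} diverge at %.3g > %.3g",
                paste(records$accession[grp], collapse = ","), dmax,
                max_divergence))
    } else {
      bestacc <- select_best_accession(records[grp, ])$accession
      for (i in grp) {
        if (records$accession[i] == bestacc) {
          keep[i] <- TRUE
          verdicts[[i]] <- qc_verdict(TRUE, "representative", "")
        } else {
          verdicts[[i]] <- qc_verdict(
            FALSE, "duplicate_collapsed",
            sprintf("represented by %s", bestacc))
        }
      }
    }
  }
  report <- data.frame(
    accession = records$accession,
    verdict = ifelse(keep, "kept", "dropped"),
    rule = vapply(verdicts, `[[`, "", "rule"),
    detail = vapply(verdicts, `[[`, "", "detail"),
    stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  attr(out, "report") <- report
  out
}

# Longest open reading frame (ATG to stop or sequence end) over the three
# forward frames; returns the substring or NULL.
longest_orf <- function(seq, genetic_code, min_orf = 300) {
  gc <- genetic_code
  best <- NULL
  n <- nchar(seq)
  for (off in 0:2) {
    len3 <- 3L * ((n - off) %/% 3L)
    if (len3 < 3) next
    s <- substring(seq, off + 1L, off + len3)
    codons <- substring(s, seq(1, len3, 3), seq(3, len3, 3))
    aa <- gc[codons]
    aa[is.na(aa)] <- "X"
    starts <- which(codons == "ATG")
    stops <- which(aa == "*")
    for (st in starts) {
      nxt <- stops[stops >= st]
      en <- if (length(nxt)) nxt[1] else length(codons)
      span <- 3L * (en - st + 1L)
      if (span >= min_orf && (is.null(best) || span > nchar(best)))
        best <- substring(s, 3L * (st - 1L) + 1L, 3L * en)
      if (length(nxt)) next
    }
  }
  best
}

#' Reading-frame screen for protein-coding sequences
#'
#' Applies to protein-coding spans (the whole record for rbcL, given its
#' frame offset; the longest open reading frame for matK inside trnK when
#' `frame` is `NA`/`NULL`).  A record is dropped when the coding span is not
#' a whole number of codons, when an internal stop codon appears, or when
#' the translated protein falls below `min_identity` identity to a
#' same-family reference protein (the "sudden amino-acid shift" surrogate).
#'
#' @param record One-row [taxon_records()].
#' @param frame 0-based frame offset of the coding span, or `NA`/`NULL` to
#'   locate the longest ORF.
#' @param genetic_code NCBI genetic code id (`"11"` for plastid).
#' @param reference Optional same-family reference record (coding from
#'   position 1) for the translated-identity check.
#' @param min_identity Identity floor for the protein comparison.
#' @param min_orf Minimum ORF length (nt) in ORF-scan mode.
#' @return A verdict list.
#' @export
screen_frameshift <- function(record, frame = 0, genetic_code = "11",
                              reference = NULL, min_identity = 0.7,
                              min_orf = 300) {
  gc <- tryCatch(Biostrings::getGeneticCode(as.character(genetic_code)),
                 error = function(e)
                   stop("unknown genetic code id: ", genetic_code))
  seq <- toupper(record$sequence[1])
  if (is.null(frame) || is.na(frame)) {
    span <- longest_orf(seq, gc, min_orf)
    if (is.null(span))
      return(qc_verdict(FALSE, "no_orf",
                        sprintf("no open reading frame >= %d nt", min_orf)))
  } else {
    span <- substring(seq, frame + 1L)
    if (nchar(span) %% 3 != 0)
      return(qc_verdict(FALSE, "frame_length",
                        sprintf("coding span of %d nt is not a whole ",
                                nchar(span)) |>
                          paste0("number of codons")))
  }
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(span), genetic.code = gc, if.fuzzy.codon = "X"))
  aa <- strsplit(prot, "")[[1]]
  if ("*" %in% aa[-length(aa)])
    return(qc_verdict(FALSE, "internal_stop",
                      sprintf("stop codon at residue %d of %d",
                              which(aa == "*")[1], length(aa))))
  if (!is.null(reference)) {
    refseq <- toupper(reference$sequence[1])
    reflen <- 3L * (nchar(refseq) %/% 3L)
    refprot <- as.character(Biostrings::translate(
      Biostrings::DNAString(substring(refseq, 1L, reflen)),
      genetic.code = gc, if.fuzzy.codon = "X"))
    refprot <- gsub("\\*$", "", refprot)
    qprot <- gsub("\\*$", "", prot)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(qprot), Biostrings::AAString(refprot),
      type = "global-local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    ident <- Biostrings::pid(al) / 100
    if (ident < min_identity)
      return(qc_verdict(FALSE, "aa_divergent",
                        sprintf("translated identity %.2f < %.2f", ident,
                                min_identity)))
  }
  qc_verdict(TRUE, "frame_ok", "")
}

#' A taxon-name checklist
#'
#' @param name Checklist name (e.g. the database it stands in for).
#' @param valid_names Character vector of binomials (normalised on
#'   construction).
#' @return List of class `"checklist"`.
#' @export
checklist <- function(name, valid_names) {
  structure(list(name = name,
                 valid_names = unique(normalize_binomial(valid_names))),
            class = "checklist")
}

#' Read a checklist file (one binomial per line, `#` comments)
#' @param path File path.
#' @param name Checklist name (default the file name).
#' @return A [checklist()].
#' @export
read_checklist <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  checklist(name, lines[nzchar(lines)])
}

#' Validate taxon names against two checklists
#'
#' A name is valid only when present in both checklists (after
#' normalisation) -- the conjunction rule of a dual-database check.
#'
#' @param names Character vector of binomials.
#' @param checklist_a,checklist_b [checklist()] objects (must be non-empty).
#' @return The normalised names found in both checklists, in input order.
#' @export
validate_names <- function(names, checklist_a, checklist_b) {
  for (cl in list(checklist_a, checklist_b)) {
    if (!inherits(cl, "checklist")) stop("checklists must be checklist objects")
    if (length(cl$valid_names) == 0)
      stop("checklist '", cl$name, "' is empty; refusing to drop everything")
  }
  norm <- normalize_binomial(names)
  norm[norm %in% checklist_a$valid_names &
         norm %in% checklist_b$valid_names]
}

#' Run the full quality-control cascade
#'
#' Chains, in order: dual-checklist name validation, the similarity screen,
#' the ambiguity filter, the reading-frame screen (with a same-family
#' reference protein when available), and conflicting-duplicate removal with
#' best-accession collapsing.  Every input record receives exactly one
#' verdict; kept + dropped = input for the chain and for each rule.
#'
#' @param records A [taxon_records()] data.frame.
#' @param references Reference panel (data.frame with `sequence`, `group`,
#'   `accession`, `marker` columns).
#' @param groups Named vector species -> family-level group.
#' @param checklist_a,checklist_b [checklist()] objects.
#' @param frames Named 0-based frame offsets per marker; `NA` triggers the
#'   ORF scan.
#' @param max_ambiguous_frac,min_evalue,word_size,max_hits,max_divergence,min_identity
#'   Rule thresholds (see the individual filters).
#' @return List of class `"qc_result"`: `records` (kept), `report` (one row
#'   per input record: accession, species, marker, verdict, rule, detail).
#' @export
run_qc <- function(records, references, groups, checklist_a, checklist_b,
                   frames = c(rbcL = 0, matK_trnK = NA),
                   max_ambiguous_frac = 0.01, min_evalue = 0.0005,
                   word_size = 8, max_hits = 250, max_divergence = 0.05,
                   min_identity = 0.7) {
  records <- as.data.frame(records)
  nrec <- nrow(records)
  rule <- character(nrec); detail <- character(nrec)
  alive <- rep(TRUE, nrec)
  valid <- validate_names(records$species_name, checklist_a, checklist_b)
  for (i in seq_len(nrec)) {
    if (!(normalize_binomial(records$species_name[i]) %in% valid)) {
      alive[i] <- FALSE; rule[i] <- "invalid_name"
      detail[i] <- "name not valid in both checklists"
    }
  }
  for (i in which(alive)) {
    v <- similarity_screen(records[i, ], references, groups, min_evalue,
                           word_size, max_hits)
    if (!v$kept) { alive[i] <- FALSE; rule[i] <- v$rule
                   detail[i] <- v$detail }
  }
  for (i in which(alive)) {
    v <- filter_ambiguous(records[i, ], max_ambiguous_frac)
    if (!v$kept) { alive[i] <- FALSE; rule[i] <- v$rule
                   detail[i] <- v$detail }
  }
  for (i in which(alive)) {
    fam <- groups[[records$species_name[i]]]
    refrow <- references[references$group == fam &
                           references$marker == records$marker[i], ]
    v <- screen_frameshift(
      records[i, ], frame = frames[[records$marker[i]]],
      reference = if (nrow(refrow)) refrow[1, ],
      min_identity = min_identity)
    if (!v$kept) { alive[i] <- FALSE; rule[i] <- v$rule
                   detail[i] <- v$detail }
  }
  if (any(alive)) {
    dedup <- drop_conflicting_duplicates(records[alive, ], max_divergence)
    rep_tab <- attr(dedup, "report")
    for (j in seq_len(nrow(rep_tab))) {
      i <- which(records$accession == rep_tab$accession[j])
      if (rep_tab$verdict[j] == "dropped") {
        alive[i] <- FALSE; rule[i] <- rep_tab$rule[j]
        detail[i] <- rep_tab$detail[j]
      }
    }
  }
  rule[alive] <- "kept"
  report <- data.frame(accession = records$accession,
                       species_name = records$species_name,
                       marker = records$marker,
                       verdict = ifelse(alive, "kept", "dropped"),
                       rule = rule, detail = detail,
                       stringsAsFactors = FALSE)
  structure(list(records = records[alive, , drop = FALSE],
                 report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: %d of %d records kept\n", nrow(x$records),
              nrow(x$report)))
  drops <- table(x$report$rule[x$report$verdict == "dropped"])
  if (length(drops)) {
    for (r in names(drops)) cat(sprintf("  dropped by %s: %d\n", r,
                                        drops[[r]]))
  }
  invisible(x)
}

#' Read species-labelled FASTA records
#'
#' Headers follow `Accession|Species_name|marker` with underscores for
#' spaces in the species name.
#'
#' @param path FASTA file.
#' @return A [taxon_records()] data.frame.
#' @export
read_fasta_records <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(dss), "|", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed FASTA header(s): ",
         paste(names(dss)[utils::head(bad, 3)], collapse = "; "))
  taxon_records(
    species_name = gsub("_", " ", vapply(parts, `[`, "", 2)),
    marker = vapply(parts, `[`, "", 3),
    accession = vapply(parts, `[`, "", 1),
    sequence = as.character(dss))
}

#' Write species-labelled FASTA records
#' @param records A [taxon_records()] data.frame.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_fasta_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(sprintf(">%s|%s|%s", records$accession[i],
                         gsub(" ", "_", records$species_name[i]),
                         records$marker[i]),
                 records$sequence[i]), con)
  }
  invisible(path)
}
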