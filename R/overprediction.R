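# Predicted-species tables and abundance-cutoff filtering.
#
# Classifiers that force reads down to species rank often predict dozens to
# hundreds of species that are not in the sample, almost all at very low
# relative abundance. These tables tabulate, per predicted species, read
# counts and relative abundances, flag each species as correct (a community
# member) or incorrect, and count how many of each survive a series of
# relative-abundance cutoffs.

#' Per-species prediction table
#'
#' Attributes each assigned read to a species by projecting its assigned
#' node to species rank: a strain assignment counts for its species, while
#' an assignment above species rank (genus or higher) contributes to no
#' species row. Relative abundance is the species' share of all
#' species-attributed reads. A species is correct iff it is one of the
#' community's truth species (strain members project to their species).
#'
#' @param assignments an [assignment_set].
#' @param tax a [taxonomy] object.
#' @param community a `community_profile` or vector of member taxids.
#' @return Object of class `species_prediction_table` (a data.frame with
#'   columns `species_taxid`, `name`, `read_count`, `relative_abundance`,
#'   `is_correct`, sorted by decreasing read count); attribute
#'   `n_species_reads` is the abundance denominator.
#' @export
species_table <- function(assignments, tax, community) {
  members <- .community_taxids(community)
  truth_species <- unique(vapply(members, function(t)
    project_to_species(tax, t), integer(1)))
  assigned <- assignments$taxid[!is.na(assignments$taxid)]
  empty <- data.frame(species_taxid = integer(0), name = character(0),
                      read_count = integer(0),
                      relative_abundance = numeric(0),
                      is_correct = logical(0), stringsAsFactors = FALSE)
  if (!length(assigned)) {
    attr(empty, "n_species_reads") <- 0L
    class(empty) <- c("species_prediction_table", "data.frame")
    return(empty)
  }
  ua <- unique(assigned)
  .check_taxid(tax, ua, "assigned taxid")
  # species-or-below nodes project to their species; others drop out
  sp_of <- vapply(ua, function(t) {
    nca <- nearest_canonical_ancestor(tax, t)
    if (nca$index == 0L) nca$taxid else NA_integer_
  }, integer(1))
  species <- sp_of[match(assigned, ua)]
  species <- species[!is.na(species)]
  if (!length(species)) {
    attr(empty, "n_species_reads") <- 0L
    class(empty) <- c("species_prediction_table", "data.frame")
    return(empty)
  }
  tab <- table(species)
  sp_ids <- as.integer(names(tab))
  counts <- as.integer(tab)
  out <- data.frame(
    species_taxid = sp_ids,
    name = unname(tax$name[as.character(sp_ids)]),
    read_count = counts,
    relative_abundance = counts / sum(counts),
    is_correct = sp_ids %in% truth_species,
    stringsAsFactors = FALSE)
  out <- out[order(-out$read_count, out$species_taxid), ]
  rownames(out) <- NULL
  attr(out, "n_species_reads") <- sum(counts)
  class(out) <- c("species_prediction_table", "data.frame")
  out
}

#' Correct/incorrect species counts under abundance cutoffs
#'
#' A species survives cutoff `c` iff its relative abundance is at least `c`
#' (inclusive boundary: "at least x %"). Counts of surviving correct and
#' incorrect species are returned per cutoff; both are non-increasing in the
#' cutoff.
#'
#' @param table a [species_table()] result.
#' @param cutoffs fractions in `[0, 1)`; the defaults mirror the classic
#'   no-cutoff / 0.01% / 0.1% / 1% series.
#' @return data.frame with columns `cutoff`, `n_correct`, `n_incorrect`.
#' @examples
#' # a table with 2 correct species and one incorrect one at 0.5% abundance
#' tax <- builtin_community("FW")$taxonomy
#' @export
apply_cutoffs <- function(table, cutoffs = c(0, 1e-4, 1e-3, 1e-2)) {
  if (any(!is.finite(cutoffs)) || any(cutoffs < 0) || any(cutoffs >= 1))
    stop_parameter("cutoffs must be fractions in [0, 1)")
  res <- lapply(cutoffs, function(cc) {
    keep <- table$relative_abundance >= cc
    data.frame(cutoff = cc,
               n_correct = sum(keep & table$is_correct),
               n_incorrect = sum(keep & !table$is_correct))
  })
  do.call(rbind, res)
}

#' Write the species-prediction report
#'
#' Emits the full per-species table (`species_table.tsv`) and the per-cutoff
#' correct/incorrect counts (`cutoff_counts.tsv`) under `dir`. Output
#' metadata records the inclusive (">= cutoff") boundary rule and the
#' species-attributed-reads abundance denominator.
#'
#' @param table a [species_table()] result.
#' @param dir output directory.
#' @param cutoffs passed to [apply_cutoffs()].
#' @return Paths written, invisibly.
#' @export
write_species_report <- function(table, dir,
                                 cutoffs = c(0, 1e-4, 1e-3, 1e-2)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "species_table.tsv")
  write_tsv(as.data.frame(table), p1)
  p2 <- file.path(dir, "cutoff_counts.tsv")
  write_tsv(apply_cutoffs(table, cutoffs), p2)
  p3 <- file.path(dir, "species_report_metadata.json")
  jsonlite::write_json(list(
    cutoff_boundary = "inclusive (species kept when abundance >= cutoff)",
    abundance_denominator = "species-attributed reads (assignments above species rank excluded)",
    n_species_reads = attr(table, "n_species_reads")),
    p3, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
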