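# Rank-level clade exclusion of reference genome sets.
#
# To measure how a classifier performs on taxa absent from its database,
# every reference genome belonging to the truth taxon's clade at a chosen
# rank is removed before the (external) classifier builds its database.
# Excluding at species leaves genus-level assignment achievable; excluding at
# genus leaves family; and so on — the "best possible rank" is one step above
# the exclusion rank.

#' Specify a clade-exclusion scenario
#'
#' @param truth_taxid the taxon whose clade is excluded (usually a community
#'   member's species or strain taxid). May be `NULL` when `rank = "none"`
#'   and the object is only used to configure scoring.
#' @param rank exclusion rank: one of `"none"`, `"species"`, `"genus"`,
#'   `"family"`, `"order"`, `"class"`.
#' @return Object of class `exclusion_spec` with fields `truth_taxid`,
#'   `rank`, and `best_rank_index` — the canonical index of the lowest rank
#'   at which a correct assignment remains achievable (0 when nothing is
#'   excluded, exclusion-rank index + 1 otherwise).
#' @examples
#' exclusion_spec(rank = "none")$best_rank_index     # 0 (species achievable)
#' exclusion_spec(42, rank = "species")$best_rank_index  # 1 (genus)
#' @export
exclusion_spec <- function(truth_taxid = NULL, rank = "none") {
  if (!rank %in% c("none", .EXCLUSION_RANKS))
    stop_parameter(paste0("exclusion rank must be one of: none, ",
                          paste(.EXCLUSION_RANKS, collapse = ", ")))
  best <- if (rank == "none") 0L else rank_index(rank) + 1L
  if (!is.null(truth_taxid)) truth_taxid <- as.integer(truth_taxid)
  structure(list(truth_taxid = truth_taxid, rank = rank,
                 best_rank_index = best),
            class = "exclusion_spec")
}

#' @export
print.exclusion_spec <- function(x, ...) {
  cat("Exclusion spec: rank =", x$rank,
      if (!is.null(x$truth_taxid)) paste0("(truth taxid ", x$truth_taxid, ")"),
      "; best possible rank index =", x$best_rank_index, "\n")
  invisible(x)
}

#' Partition a reference genome set by clade exclusion
#'
#' Removes every genome whose lineage contains the truth taxon's ancestor at
#' the exclusion rank; membership is decided on lineages, never on name
#' matching, so strain and subspecies labelling cannot leak genomes through.
#' Genomes whose lineage has no node at the exclusion rank (rank gaps) are
#' treated as outside the clade and kept, with a warning.
#'
#' @param reference data.frame with columns `genome_id` and `taxid`.
#' @param tax a [taxonomy] object.
#' @param spec an [exclusion_spec] with a non-`NULL` `truth_taxid` unless
#'   `rank = "none"`.
#' @return list with `kept` and `removed` (disjoint subsets of `reference`
#'   whose union is the input) and `clade_taxid` (the excluded ancestor, or
#'   `NA` for rank "none").
#' @examples
#' fw <- builtin_community("FW")
#' ref <- data.frame(genome_id = fw$members$genome_id,
#'                   taxid = fw$members$taxid)
#' pa <- fw$members$taxid[fw$members$organism == "Pseudomonas aeruginosa"][1]
#' out <- exclude_clade(ref, fw$taxonomy, exclusion_spec(pa, "species"))
#' out$removed$genome_id  # the three P. aeruginosa strain genomes
#' @export
exclude_clade <- function(reference, tax, spec) {
  if (!all(c("genome_id", "taxid") %in% names(reference)))
    stop_format("reference must have columns genome_id and taxid")
  if (!inherits(spec, "exclusion_spec"))
    stop_parameter("spec must be an exclusion_spec")
  if (spec$rank == "none")
    return(list(kept = reference, removed = reference[0, ],
                clade_taxid = NA_integer_))
  if (is.null(spec$truth_taxid))
    stop_spec("exclusion at a rank requires a truth_taxid")
  clade <- canonical_ancestor_at(tax, spec$truth_taxid, spec$rank)
  if (is.na(clade))
    stop_spec(paste0("truth taxon ", spec$truth_taxid,
                     " has no ancestor at rank '", spec$rank, "'"))
  uniq <- unique(reference$taxid)
  .check_taxid(tax, uniq, "reference taxid")
  in_clade_uniq <- vapply(uniq, function(t) clade %in% lineage_taxids(tax, t),
                          logical(1))
  # rank-gap diagnostics: genomes with no node at the exclusion rank at all
  gap_uniq <- !in_clade_uniq & vapply(uniq, function(t)
    is.na(canonical_ancestor_at(tax, t, spec$rank)), logical(1))
  if (any(gap_uniq))
    warning(sprintf("%d reference taxid(s) have no ancestor at rank '%s'; kept (treated as outside the clade)",
                    sum(gap_uniq), spec$rank), call. = FALSE)
  in_clade <- in_clade_uniq[match(reference$taxid, uniq)]
  list(kept = reference[!in_clade, , drop = FALSE],
       removed = reference[in_clade, , drop = FALSE],
       clade_taxid = clade)
}

#' Prune a reference FASTA by clade exclusion
#'
#' Materializes the excluded reference database: the output FASTA contains
#' exactly the kept genomes' records, in their original order, ready for an
#' external classifier's database builder.
#'
#' @param fasta path to the reference multi-FASTA; record IDs (first header
#'   token) must all appear in `mapping`.
#' @param mapping genome_id -> taxid table (data.frame or TSV path).
#' @param tax a [taxonomy] object.
#' @param spec an [exclusion_spec].
#' @param output path for the pruned FASTA, or `NULL` to skip writing.
#' @return list with `kept` (`DNAStringSet`), `report` (data.frame:
#'   `genome_id`, `taxid`, `status` kept/removed, `reason`), and `output`.
#' @export
prune_fasta <- function(fasta, mapping, tax, spec, output = NULL) {
  if (!file.exists(fasta)) stop_data(paste0("FASTA not found: ", fasta))
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(mapping)) mapping <- read_tsv(mapping)
  unmapped <- setdiff(names(seqs), mapping$genome_id)
  if (length(unmapped))
    stop_data(paste0("FASTA record(s) missing from mapping: ",
                     paste(unmapped, collapse = ", ")))
  ref <- data.frame(genome_id = names(seqs),
                    taxid = as.integer(
                      mapping$taxid[match(names(seqs), mapping$genome_id)]),
                    stringsAsFactors = FALSE)
  parts <- exclude_clade(ref, tax, spec)
  removed_ids <- parts$removed$genome_id
  status <- ifelse(ref$genome_id %in% removed_ids, "removed", "kept")
  reason <- ifelse(status == "removed",
                   paste0("lineage contains excluded clade ",
                          parts$clade_taxid, " (rank ", spec$rank, ")"),
                   "outside excluded clade")
  if (spec$rank == "none") reason <- "no exclusion"
  report <- data.frame(genome_id = ref$genome_id, taxid = ref$taxid,
                       status = status, reason = reason,
                       stringsAsFactors = FALSE)
  kept <- seqs[status == "kept"]
  if (!is.null(output)) Biostrings::writeXStringSet(kept, output)
  list(kept = kept, report = report, output = output)
}
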