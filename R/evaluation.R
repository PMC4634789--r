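# Path-based read scoring.
#
# A read is a true positive when its assignment lies anywhere on the path
# from the correct species up to the superkingdom (and root) of the
# taxonomic tree; an assignment off that path is a false positive; an
# unassigned read is a false negative. Sensitivity = TP/(TP+FN), precision =
# TP/(TP+FP). Taxonomic distance, computed over correctly assigned reads, is
# the number of canonical-rank steps the assignment sits above the best
# possible rank (one rank above the exclusion level; species when nothing is
# excluded). In the overpredictions-as-correct mode, an off-path assignment
# is rescued when its ancestor at the best possible rank matches the truth
# lineage at that rank — e.g. a wrong species in the right genus under
# species exclusion.

#' Sensitivity and precision from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `precision = TP / (TP + FP)`; `NA` when
#' the denominator is zero.
#'
#' @param tp,fp,fn non-negative counts (vectorized).
#' @return data.frame with columns `sensitivity` and `precision`.
#' @export
confusion_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop_parameter("counts must be non-negative")
  data.frame(sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
             precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_))
}

#' Evaluation configuration
#'
#' @param exclusion an [exclusion_spec]; its rank sets the best possible
#'   rank against which taxonomic distance is measured.
#' @param overpredictions_correct when `TRUE`, an off-path assignment is
#'   reclassified as correct if it projects to the truth's clade at the best
#'   possible rank (wrong species, right genus under species exclusion).
#' @param aggregation `"per_genome_mean"` (metrics per genome, then an
#'   unweighted mean so every species counts equally) or `"pooled"` (one
#'   computation over all reads; an assignment on the truth path of *any*
#'   community member is correct — the mode used for in vitro data where
#'   per-read source genomes are unknowable).
#' @param pooled_community a `community_profile` (or vector of member
#'   taxids); required iff `aggregation = "pooled"`.
#' @return Object of class `eval_config`.
#' @export
eval_config <- function(exclusion = exclusion_spec(),
                        overpredictions_correct = FALSE,
                        aggregation = c("per_genome_mean", "pooled"),
                        pooled_community = NULL) {
  aggregation <- match.arg(aggregation)
  if (!inherits(exclusion, "exclusion_spec"))
    stop_parameter("exclusion must be an exclusion_spec")
  if (aggregation == "pooled" && is.null(pooled_community))
    stop_parameter("pooled aggregation requires pooled_community")
  if (aggregation != "pooled" && !is.null(pooled_community))
    stop_parameter("pooled_community is only meaningful with pooled aggregation")
  structure(list(exclusion = exclusion,
                 overpredictions_correct = isTRUE(overpredictions_correct),
                 aggregation = aggregation,
                 pooled_community = pooled_community),
            class = "eval_config")
}

.community_taxids <- function(community) {
  if (inherits(community, "community_profile")) community$members$taxid
  else as.integer(community)
}

# Memoized per-unique-taxid lookups used by the vectorized scorer.
.assigned_info <- function(tax, assigned, best_index, overpred) {
  ua <- unique(assigned[!is.na(assigned)])
  .check_taxid(tax, ua, "assigned taxid")
  proj <- vapply(ua, function(t) project_to_species(tax, t), integer(1))
  nca_idx <- vapply(ua, function(t) nearest_canonical_ancestor(tax, t)$index,
                    integer(1))
  anc_best <- if (overpred && best_index <= 6L) {
    best_rank <- .CANONICAL_RANKS[best_index + 1L]
    vapply(ua, function(t) canonical_ancestor_at(tax, t, best_rank),
           integer(1))
  } else rep(NA_integer_, length(ua))
  list(taxid = ua, proj = proj, nca_idx = nca_idx, anc_best = anc_best)
}

# Vectorized per-read scoring. `truth_species` is NULL in pooled mode, where
# `members` gives the community taxids instead. Returns status ("TP", "FP",
# "FN") and, for TP reads, the taxonomic distance.
.score_reads <- function(tax, assigned, truth_species, config,
                         members = NULL) {
  n <- length(assigned)
  best <- config$exclusion$best_rank_index
  overpred <- config$overpredictions_correct
  info <- .assigned_info(tax, assigned, best, overpred)
  ai <- match(assigned, info$taxid)           # NA for unassigned

  status <- rep("FN", n)
  distance <- rep(NA_real_, n)
  has <- !is.na(ai)
  if (!any(has))
    return(list(status = status, distance = distance))

  if (is.null(truth_species)) {
    msp <- unique(vapply(members, function(t) project_to_species(tax, t),
                         integer(1)))
    path_union <- unique(unlist(lapply(msp, function(s)
      lineage_taxids(tax, s))))
    on_path <- info$proj[ai[has]] %in% path_union
    st <- ifelse(on_path, "TP", "FP")
    if (overpred && best <= 6L) {
      best_rank <- .CANONICAL_RANKS[best + 1L]
      truth_best <- unique(stats::na.omit(vapply(msp, function(s)
        canonical_ancestor_at(tax, s, best_rank), integer(1))))
      rescue <- st == "FP" & info$anc_best[ai[has]] %in% truth_best
      st[rescue] <- "TP"
    }
    status[has] <- st
    tp <- has & status == "TP"
    distance[tp] <- pmax(0, info$nca_idx[ai[tp]] - best)
    return(list(status = status, distance = distance))
  }

  uts <- unique(truth_species)
  .check_taxid(tax, uts, "truth taxid")
  for (t in uts) {
    sp <- project_to_species(tax, t)
    path <- lineage_taxids(tax, sp)
    sel <- has & truth_species == t
    if (!any(sel)) next
    on_path <- info$proj[ai[sel]] %in% path
    st <- ifelse(on_path, "TP", "FP")
    if (overpred && best <= 6L) {
      best_rank <- .CANONICAL_RANKS[best + 1L]
      truth_best <- canonical_ancestor_at(tax, sp, best_rank)
      if (!is.na(truth_best)) {
        rescue <- st == "FP" & !is.na(info$anc_best[ai[sel]]) &
          info$anc_best[ai[sel]] == truth_best
        st[rescue] <- "TP"
      }
    }
    status[sel] <- st
  }
  tp <- has & status == "TP"
  distance[tp] <- pmax(0, info$nca_idx[ai[tp]] - best)
  list(status = status, distance = distance)
}

#' Classify a single read as TP, FP or FN
#'
#' Unassigned reads are false negatives; assignments anywhere on the path
#' from the truth species to the superkingdom (strains projecting to their
#' species first) are true positives; anything else is a false positive,
#' unless the overpredictions-as-correct mode rescues it at the best
#' possible rank.
#'
#' @param assigned_taxid assigned node, or `NA` for unassigned.
#' @param truth_species_taxid the read's true source species.
#' @param tax a [taxonomy] object.
#' @param config an [eval_config].
#' @return `"TP"`, `"FP"` or `"FN"`.
#' @export
classify_read <- function(assigned_taxid, truth_species_taxid, tax,
                          config = eval_config()) {
  .score_reads(tax, as.integer(assigned_taxid),
               as.integer(truth_species_taxid), config)$status
}

#' Taxonomic distance of a correctly assigned read
#'
#' The number of canonical-rank steps the assignment sits above the best
#' possible rank (clamped at zero). Defined only for reads that are TP under
#' [classify_read()]; calling it on an FP or FN read is a usage error.
#'
#' @inheritParams classify_read
#' @return Non-negative integer distance.
#' @export
taxonomic_distance_of_read <- function(assigned_taxid, truth_species_taxid,
                                       tax, config = eval_config()) {
  sc <- .score_reads(tax, as.integer(assigned_taxid),
                     as.integer(truth_species_taxid), config)
  if (sc$status != "TP")
    stop_usage(paste0("taxonomic distance is defined only for TP reads (read is ",
                      sc$status, ")"))
  sc$distance
}

#' Proportion of reads assigned at each taxonomic rank
#'
#' Each assigned read contributes to the canonical rank of its nearest
#' canonical ancestor (a strain counts at species; a "no rank" clade counts
#' at the first canonical rank above it). Fractions are reported against two
#' denominators — assigned reads and all reads — and unassigned reads are
#' reported separately.
#'
#' @param assignments an [assignment_set] (or data.frame with `read_id`,
#'   `taxid`).
#' @param tax a [taxonomy] object.
#' @return data.frame with columns `rank`, `n_reads`, `frac_assigned`,
#'   `frac_all`; attributes `n_total`, `n_assigned` and
#'   `unassigned_fraction`.
#' @export
rank_distribution <- function(assignments, tax) {
  assigned <- assignments$taxid
  n_total <- length(assigned)
  has <- !is.na(assigned)
  n_assigned <- sum(has)
  levels_all <- c(.CANONICAL_RANKS, "above_superkingdom")
  counts <- stats::setNames(rep(0L, length(levels_all)), levels_all)
  if (n_assigned) {
    ua <- unique(assigned[has])
    .check_taxid(tax, ua, "assigned taxid")
    idx <- vapply(ua, function(t) nearest_canonical_ancestor(tax, t)$index,
                  integer(1))
    lab <- levels_all[pmin(idx, 7L) + 1L]
    tab <- table(factor(lab[match(assigned[has], ua)], levels = levels_all))
    counts[names(tab)] <- as.integer(tab)
  }
  out <- data.frame(rank = levels_all, n_reads = as.integer(counts),
                    frac_assigned = if (n_assigned) as.numeric(counts) /
                      n_assigned else rep(NA_real_, length(levels_all)),
                    frac_all = if (n_total) as.numeric(counts) / n_total
                    else rep(NA_real_, length(levels_all)),
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- n_total
  attr(out, "n_assigned") <- n_assigned
  attr(out, "unassigned_fraction") <-
    if (n_total) (n_total - n_assigned) / n_total else NA_real_
  out
}

#' Evaluate classifier output against ground truth
#'
#' Scores every truth read as TP/FP/FN (see [classify_read()]) and computes
#' sensitivity, precision and taxonomic distance. In `per_genome_mean` mode
#' the metrics are computed per genome and the aggregate is their unweighted
#' mean, so every species carries equal weight regardless of genome size.
#' Per-genome precision is undefined (and excluded from the mean) when the
#' genome has no assigned reads, and distance when it has no TP reads; the
#' counts of such genomes are reported. In `pooled` mode a single
#' computation runs over all reads, with an assignment correct when it lies
#' on the truth path of any community member, and the distance baseline
#' chosen as the member giving the smallest distance.
#'
#' @param assignments an [assignment_set].
#' @param truth truth sidecar data.frame (or `read_simulation`): `read_id`,
#'   `genome_id`, `taxid`. In pooled mode only `read_id` is required.
#' @param tax a [taxonomy] object.
#' @param config an [eval_config].
#' @return Object of class `evaluation_result`: list with `per_genome`
#'   (data.frame of counts and metrics; `NULL` in pooled mode), `aggregate`
#'   (one-row data.frame), `rank_distribution`, `config` and `n_reads`.
#' @examples
#' w <- make_synthetic_world(3, genome_length_range = c(2000, 2000), seed = 1)
#' sim <- simulate_reads(w, read_length = 100, seed = 1)
#' perfect <- assignment_set(data.frame(read_id = sim$truth$read_id,
#'                                      taxid = sim$truth$taxid), "oracle")
#' res <- evaluate_assignments(perfect, sim, w$taxonomy)
#' res$aggregate$sensitivity  # 1
#' @export
evaluate_assignments <- function(assignments, truth, tax,
                                 config = eval_config()) {
  if (inherits(truth, "read_simulation")) truth <- truth$truth
  if (!nrow(truth)) stop_parameter("zero truth reads")
  joined <- join_with_truth(assignments, truth)

  if (config$aggregation == "pooled") {
    members <- .community_taxids(config$pooled_community)
    sc <- .score_reads(tax, joined$assigned_taxid, NULL, config,
                       members = members)
    tp <- sum(sc$status == "TP"); fp <- sum(sc$status == "FP")
    fn <- sum(sc$status == "FN")
    m <- confusion_metrics(tp, fp, fn)
    aggregate <- data.frame(
      tp = tp, fp = fp, fn = fn,
      sensitivity = m$sensitivity, precision = m$precision,
      taxonomic_distance = if (tp) mean(sc$distance[sc$status == "TP"])
      else NA_real_,
      n_genomes = NA_integer_, n_precision_undefined = NA_integer_,
      n_distance_undefined = NA_integer_)
    per_genome <- NULL
  } else {
    need <- c("genome_id", "taxid")
    if (!all(need %in% names(joined)))
      stop_parameter("per-genome evaluation requires truth columns genome_id and taxid")
    truth_species <- vapply(joined$taxid, function(t)
      project_to_species(tax, t), integer(1))
    sc <- .score_reads(tax, joined$assigned_taxid, truth_species, config)
    gid <- joined$genome_id
    genomes <- unique(gid)
    tp <- vapply(genomes, function(g) sum(sc$status[gid == g] == "TP"),
                 integer(1))
    fp <- vapply(genomes, function(g) sum(sc$status[gid == g] == "FP"),
                 integer(1))
    fn <- vapply(genomes, function(g) sum(sc$status[gid == g] == "FN"),
                 integer(1))
    dist <- vapply(genomes, function(g) {
      d <- sc$distance[gid == g & sc$status == "TP"]
      if (length(d)) mean(d) else NA_real_
    }, numeric(1))
    m <- confusion_metrics(tp, fp, fn)
    per_genome <- data.frame(
      genome_id = genomes,
      taxid = joined$taxid[match(genomes, gid)],
      n_reads = as.integer(table(gid)[genomes]),
      tp = tp, fp = fp, fn = fn,
      sensitivity = m$sensitivity, precision = m$precision,
      taxonomic_distance = dist,
      stringsAsFactors = FALSE)
    rownames(per_genome) <- NULL
    aggregate <- data.frame(
      tp = sum(tp), fp = sum(fp), fn = sum(fn),
      sensitivity = mean(per_genome$sensitivity, na.rm = TRUE),
      precision = if (all(is.na(per_genome$precision))) NA_real_
      else mean(per_genome$precision, na.rm = TRUE),
      taxonomic_distance = if (all(is.na(dist))) NA_real_
      else mean(dist, na.rm = TRUE),
      n_genomes = length(genomes),
      n_precision_undefined = sum(is.na(per_genome$precision)),
      n_distance_undefined = sum(is.na(dist)))
  }

  rd <- rank_distribution(
    data.frame(read_id = joined$read_id, taxid = joined$assigned_taxid,
               stringsAsFactors = FALSE), tax)
  structure(list(per_genome = per_genome, aggregate = aggregate,
                 rank_distribution = rd, config = config,
                 n_reads = nrow(joined),
                 source_label = attr(assignments, "source_label")),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  a <- x$aggregate
  cat("Evaluation (", x$config$aggregation, ", exclusion rank ",
      x$config$exclusion$rank,
      if (x$config$overpredictions_correct) ", overpredictions correct",
      "): ", x$n_reads, " reads\n", sep = "")
  cat(sprintf("  TP %d  FP %d  FN %d\n", a$tp, a$fp, a$fn))
  cat(sprintf("  sensitivity %.4f  precision %s  taxonomic distance %s\n",
              a$sensitivity,
              ifelse(is.na(a$precision), "NA", sprintf("%.4f", a$precision)),
              ifelse(is.na(a$taxonomic_distance), "NA",
                     sprintf("%.4f", a$taxonomic_distance))))
  invisible(x)
}

#' Write an evaluation result as TSV tables plus a JSON summary
#'
#' Emits `per_genome.tsv` (omitted in pooled mode), `aggregate.tsv`,
#' `rank_distribution.tsv` and `summary.json` under `dir`.
#'
#' @param result an `evaluation_result`.
#' @param dir output directory (created if absent).
#' @return Character vector of paths written, invisibly.
#' @export
write_evaluation <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if (!is.null(result$per_genome)) {
    p <- file.path(dir, "per_genome.tsv")
    write_tsv(result$per_genome, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "aggregate.tsv")
  write_tsv(result$aggregate, p)
  paths <- c(paths, p)
  p <- file.path(dir, "rank_distribution.tsv")
  write_tsv(result$rank_distribution, p)
  paths <- c(paths, p)
  p <- file.path(dir, "summary.json")
  summary <- list(
    source_label = result$source_label,
    n_reads = result$n_reads,
    aggregation = result$config$aggregation,
    exclusion_rank = result$config$exclusion$rank,
    best_rank_index = result$config$exclusion$best_rank_index,
    overpredictions_correct = result$config$overpredictions_correct,
    aggregate = as.list(result$aggregate),
    unassigned_fraction = attr(result$rank_distribution,
                               "unassigned_fraction"))
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
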