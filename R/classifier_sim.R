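# Synthetic classifier with programmable error behaviour.
#
# Emulates, per read and independently, the behaviours real classifiers
# exhibit: leaving reads unassigned, assigning correctly at a configurable
# distribution of ranks (conservative tools sit at family/order, aggressive
# ones at species), or misassigning — to a congeneric sibling species, to a
# random species outside the truth genus, or to the LCA of the truth and a
# confused sibling. Enables closed-loop parameter-recovery testing of the
# whole evaluation stack without running any external tool.

#' Specify a synthetic classifier
#'
#' Per read: unassigned with probability `p_unassigned`; otherwise correct
#' with probability `p_correct`, emitted at a canonical rank drawn from
#' `rank_profile` (the truth lineage's node at that rank); the residual
#' probability mass is misassigned according to `misassignment_mode`.
#'
#' @param p_unassigned probability a read is left unassigned.
#' @param p_correct probability a read is assigned on its truth path;
#'   `p_unassigned + p_correct` must be <= 1.
#' @param rank_profile named numeric distribution over canonical ranks at
#'   which correct assignments are emitted (names from [rank_ladder()];
#'   must sum to 1). Default: everything at species.
#' @param misassignment_mode `"sibling_species"` (random congeneric species,
#'   falling back to `"random_other_clade"` for singleton genera, logged),
#'   `"random_other_clade"` (random species outside the truth genus), or
#'   `"lca_of_confusion_set"` (LCA of the truth species and a random
#'   sibling).
#' @return Object of class `classifier_model`.
#' @export
classifier_model <- function(p_unassigned = 0, p_correct = 1,
                             rank_profile = c(species = 1),
                             misassignment_mode = c("sibling_species",
                                                    "random_other_clade",
                                                    "lca_of_confusion_set")) {
  misassignment_mode <- match.arg(misassignment_mode)
  if (p_unassigned < 0 || p_correct < 0 || p_unassigned + p_correct > 1 + 1e-12)
    stop_parameter("need p_unassigned, p_correct >= 0 and p_unassigned + p_correct <= 1")
  if (is.null(names(rank_profile)) ||
      !all(names(rank_profile) %in% .CANONICAL_RANKS))
    stop_parameter("rank_profile must be named with canonical ranks")
  if (abs(sum(rank_profile) - 1) > 1e-9)
    stop_parameter("rank_profile must sum to 1")
  structure(list(p_unassigned = p_unassigned, p_correct = p_correct,
                 p_misassigned = max(0, 1 - p_unassigned - p_correct),
                 rank_profile = rank_profile,
                 misassignment_mode = misassignment_mode),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("Classifier model: P(unassigned) = %.3f, P(correct) = %.3f, P(misassigned) = %.3f\n",
              x$p_unassigned, x$p_correct, x$p_misassigned))
  cat("  correct-rank profile:",
      paste(names(x$rank_profile), signif(x$rank_profile, 3),
            sep = "=", collapse = ", "), "\n")
  cat("  misassignment mode:", x$misassignment_mode, "\n")
  invisible(x)
}

#' Simulate classifier output over a truth set
#'
#' Draws one assignment per truth read under the model, independently across
#' reads, deterministically for a given seed.
#'
#' @param truth truth data.frame (or `read_simulation`) with `read_id` and
#'   `taxid`.
#' @param tax a [taxonomy] object.
#' @param model a [classifier_model].
#' @param seed RNG seed.
#' @return An [assignment_set] (source label records the model parameters).
#' @examples
#' w <- make_synthetic_world(4, n_congeneric_pairs = 1,
#'                           genome_length_range = c(2000, 2000), seed = 1)
#' sim <- simulate_reads(w, read_length = 100, seed = 1)
#' m <- classifier_model(p_unassigned = 0.1, p_correct = 0.7)
#' a <- simulate_classifier(sim, w$taxonomy, m, seed = 2)
#' mean(is.na(a$taxid))  # ~0.1
#' @export
simulate_classifier <- function(truth, tax, model, seed = 1) {
  if (inherits(truth, "read_simulation")) truth <- truth$truth
  if (!inherits(model, "classifier_model"))
    stop_parameter("model must be a classifier_model")
  n <- nrow(truth)
  if (!n) stop_parameter("empty truth set")
  ut <- unique(truth$taxid)
  .check_taxid(tax, ut, "truth taxid")

  # per-species precomputation: truth species, ladder nodes, sibling and
  # other-clade candidate species
  all_species <- tax$taxid[tax$rank[as.character(tax$taxid)] == "species"]
  sp_of <- vapply(ut, function(t) project_to_species(tax, t), integer(1))
  usp <- unique(sp_of)
  genus_of <- vapply(usp, function(s)
    canonical_ancestor_at(tax, s, "genus"), integer(1))
  ladder <- lapply(usp, function(s)
    vapply(.CANONICAL_RANKS, function(r) canonical_ancestor_at(tax, s, r),
           integer(1)))
  names(ladder) <- as.character(usp)
  siblings <- lapply(seq_along(usp), function(i) {
    if (is.na(genus_of[i])) return(integer(0))
    g <- genus_of[i]
    cand <- all_species[all_species != usp[i]]
    cand[vapply(cand, function(s) {
      ga <- canonical_ancestor_at(tax, s, "genus")
      !is.na(ga) && ga == g
    }, logical(1))]
  })
  others <- lapply(seq_along(usp), function(i) {
    g <- genus_of[i]
    cand <- all_species[all_species != usp[i]]
    if (is.na(g)) return(cand)
    cand[vapply(cand, function(s) {
      ga <- canonical_ancestor_at(tax, s, "genus")
      is.na(ga) || ga != g
    }, logical(1))]
  })
  names(siblings) <- names(others) <- as.character(usp)

  set.seed(seed)
  u <- stats::runif(n)
  cat_unassigned <- u < model$p_unassigned
  cat_correct <- !cat_unassigned &
    u < model$p_unassigned + model$p_correct
  cat_mis <- !cat_unassigned & !cat_correct

  assigned <- rep(NA_integer_, n)
  read_species <- sp_of[match(truth$taxid, ut)]

  if (any(cat_correct)) {
    ranks <- sample(names(model$rank_profile), sum(cat_correct),
                    replace = TRUE, prob = model$rank_profile)
    idx <- which(cat_correct)
    for (j in seq_along(idx)) {
      lad <- ladder[[as.character(read_species[idx[j]])]]
      node <- lad[[ranks[j]]]
      # rank gaps walk up to the next canonical rank that exists, else root
      if (is.na(node)) {
        ri <- rank_index(ranks[j])
        node <- tax$root
        if (ri < 6L) {
          higher <- lad[(ri + 2L):7L]
          if (any(!is.na(higher))) node <- higher[!is.na(higher)][1]
        }
      }
      assigned[idx[j]] <- node
    }
  }

  if (any(cat_mis)) {
    idx <- which(cat_mis)
    mode <- model$misassignment_mode
    fallback_logged <- FALSE
    for (j in idx) {
      sp <- as.character(read_species[j])
      sibs <- siblings[[sp]]
      oth <- others[[sp]]
      m <- mode
      if (m %in% c("sibling_species", "lca_of_confusion_set") &&
          !length(sibs)) {
        if (!fallback_logged && m == "sibling_species") {
          message("truth genus has a single species; falling back to random_other_clade")
          fallback_logged <- TRUE
        }
        m <- "random_other_clade"
      }
      assigned[j] <- switch(m,
        sibling_species = sibs[sample.int(length(sibs), 1L)],
        random_other_clade = {
          if (!length(oth))
            stop_parameter("taxonomy has no species outside the truth genus to misassign to")
          oth[sample.int(length(oth), 1L)]
        },
        lca_of_confusion_set = {
          partner <- sibs[sample.int(length(sibs), 1L)]
          lca(tax, as.integer(sp), partner)$taxid
        })
    }
  }

  label <- sprintf("sim(pU=%g,pC=%g,%s)", model$p_unassigned,
                   model$p_correct, model$misassignment_mode)
  assignment_set(data.frame(read_id = truth$read_id, taxid = assigned,
                            stringsAsFactors = FALSE), label)
}
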