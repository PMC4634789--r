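# Independent brute-force re-derivation of the scoring rules, written
# directly against a raw node table with plain loops. Used as the oracle for
# the vectorized implementation; deliberately shares no code with it.

oracle_rank_idx <- c(species = 0, genus = 1, family = 2, order = 3,
                     class = 4, phylum = 5, superkingdom = 6)

# taxids from the node itself up to the root (node first)
oracle_ancestors <- function(nodes, taxid) {
  path <- taxid
  cur <- taxid
  repeat {
    p <- nodes$parent[nodes$taxid == cur]
    if (p == cur) break
    path <- c(path, p)
    cur <- p
  }
  path
}

# strain/subspecies -> its species; nodes at/above species unchanged
oracle_species_of <- function(nodes, taxid) {
  if (nodes$rank[nodes$taxid == taxid] == "species") return(taxid)
  anc <- oracle_ancestors(nodes, taxid)
  for (a in anc[-1]) if (nodes$rank[nodes$taxid == a] == "species") return(a)
  taxid
}

# canonical index of the nearest canonical ancestor-or-self (7 if none)
oracle_nca_index <- function(nodes, taxid) {
  for (a in oracle_ancestors(nodes, taxid)) {
    r <- nodes$rank[nodes$taxid == a]
    if (r %in% names(oracle_rank_idx)) return(unname(oracle_rank_idx[r]))
  }
  7
}

# ancestor-or-self at exactly the given canonical rank, or NA
oracle_at_rank <- function(nodes, taxid, rank) {
  for (a in oracle_ancestors(nodes, taxid))
    if (nodes$rank[nodes$taxid == a] == rank) return(a)
  NA_integer_
}

# literal restatement of the read-level rule: unassigned -> FN; anywhere on
# the path from the correct species to the root -> TP; otherwise FP unless
# the overprediction mode rescues it at the best possible rank
oracle_classify <- function(nodes, assigned, truth, best_index, overpred) {
  if (is.na(assigned)) return("FN")
  a <- oracle_species_of(nodes, assigned)
  t <- oracle_species_of(nodes, truth)
  if (a %in% oracle_ancestors(nodes, t)) return("TP")
  if (overpred && best_index <= 6) {
    best_rank <- names(oracle_rank_idx)[best_index + 1]
    aa <- oracle_at_rank(nodes, assigned, best_rank)
    tt <- oracle_at_rank(nodes, t, best_rank)
    if (!is.na(aa) && !is.na(tt) && aa == tt) return("TP")
  }
  "FP"
}

oracle_distance <- function(nodes, assigned, best_index) {
  max(0, oracle_nca_index(nodes, assigned) - best_index)
}

# full per-genome evaluation by loops over a joined table with columns
# read_id, genome_id, taxid (source), assigned_taxid
oracle_evaluate <- function(nodes, joined, best_index, overpred) {
  genomes <- unique(joined$genome_id)
  per <- data.frame(genome_id = genomes, tp = 0L, fp = 0L, fn = 0L,
                    sensitivity = NA_real_, precision = NA_real_,
                    taxonomic_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (gi in seq_along(genomes)) {
    rows <- joined[joined$genome_id == genomes[gi], ]
    dists <- numeric(0)
    for (k in seq_len(nrow(rows))) {
      st <- oracle_classify(nodes, rows$assigned_taxid[k], rows$taxid[k],
                            best_index, overpred)
      if (st == "TP") {
        per$tp[gi] <- per$tp[gi] + 1L
        dists <- c(dists, oracle_distance(nodes, rows$assigned_taxid[k],
                                          best_index))
      } else if (st == "FP") per$fp[gi] <- per$fp[gi] + 1L
      else per$fn[gi] <- per$fn[gi] + 1L
    }
    if (per$tp[gi] + per$fn[gi] > 0)
      per$sensitivity[gi] <- per$tp[gi] / (per$tp[gi] + per$fn[gi])
    if (per$tp[gi] + per$fp[gi] > 0)
      per$precision[gi] <- per$tp[gi] / (per$tp[gi] + per$fp[gi])
    if (length(dists)) per$taxonomic_distance[gi] <- mean(dists)
  }
  agg <- list(
    tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn),
    sensitivity = mean(per$sensitivity, na.rm = TRUE),
    precision = if (all(is.na(per$precision))) NA_real_
    else mean(per$precision, na.rm = TRUE),
    taxonomic_distance = if (all(is.na(per$taxonomic_distance))) NA_real_
    else mean(per$taxonomic_distance, na.rm = TRUE))
  list(per_genome = per, aggregate = agg)
}
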