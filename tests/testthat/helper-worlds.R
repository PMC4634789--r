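# Random test-world generators. Node tables are built directly (not via the
# fixtures module) so taxonomy-structure properties are exercised on inputs
# the package did not construct, including "no rank" clades inserted into
# ladders and strain nodes below species.

random_tax_nodes <- function(seed, n_genera = NULL, max_species = 3,
                             p_norank = 0.3, p_strain = 0.5) {
  set.seed(seed)
  if (is.null(n_genera)) n_genera <- sample(2:4, 1)
  nodes <- data.frame(taxid = c(1L, 2L), parent = c(1L, 1L),
                      rank = c("no rank", "superkingdom"),
                      name = c("root", "Bacteria"), stringsAsFactors = FALSE)
  nid <- 3L
  add <- function(parent, rank, name) {
    nodes[nrow(nodes) + 1L, ] <<- list(nid, parent, rank, name)
    nid <<- nid + 1L
    nid - 1L
  }
  species <- integer(0)
  strains <- integer(0)
  for (g in seq_len(n_genera)) {
    parent <- 2L
    for (r in c("phylum", "class", "order", "family", "genus")) {
      # occasionally insert an unranked clade into the ladder
      if (stats::runif(1) < p_norank)
        parent <- add(parent, "no rank", sprintf("clade_g%d_%s", g, r))
      parent <- add(parent, r, sprintf("%s_%d", r, g))
    }
    for (s in seq_len(sample(seq_len(max_species), 1))) {
      sp <- add(parent, "species", sprintf("species_%d_%d", g, s))
      species <- c(species, sp)
      if (stats::runif(1) < p_strain)
        strains <- c(strains, add(sp, "no rank",
                                  sprintf("strain_%d_%d", g, s)))
    }
  }
  list(nodes = nodes, species = species, strains = strains)
}

# A randomized scoring scenario over a random taxonomy: reads drawn from
# random species (sometimes recorded as their strain), assignments mixing
# correct species, path ancestors (canonical and unranked), strains,
# siblings, unrelated nodes and unassigned.
random_scenario <- function(seed, n_reads = NULL) {
  world <- random_tax_nodes(seed)
  nodes <- world$nodes
  tax <- taxonomy(nodes)
  set.seed(seed + 1000003L)
  if (is.null(n_reads)) n_reads <- sample(50:300, 1)
  n_genomes <- min(length(world$species), sample(2:5, 1))
  genome_species <- sample(world$species, n_genomes)
  source_taxid <- vapply(genome_species, function(sp) {
    st <- nodes$taxid[nodes$parent == sp & nodes$rank == "no rank"]
    if (length(st) && stats::runif(1) < 0.5) st[1] else sp
  }, integer(1))
  gid <- sprintf("G%02d", seq_len(n_genomes))
  pick <- sample.int(n_genomes, n_reads, replace = TRUE)
  truth <- data.frame(read_id = sprintf("r%04d", seq_len(n_reads)),
                      genome_id = gid[pick],
                      taxid = source_taxid[pick],
                      stringsAsFactors = FALSE)
  all_ids <- nodes$taxid
  assigned <- vapply(seq_len(n_reads), function(i) {
    sp <- genome_species[pick[i]]
    anc <- oracle_ancestors(nodes, sp)
    kind <- sample(c("correct", "ancestor", "strain", "random", "none"),
                   1, prob = c(0.3, 0.25, 0.1, 0.25, 0.1))
    switch(kind,
           correct = sp,
           ancestor = anc[sample.int(length(anc), 1)],
           strain = {
             st <- nodes$taxid[nodes$parent == sp & nodes$rank == "no rank"]
             if (length(st)) st[1] else sp
           },
           random = all_ids[sample.int(length(all_ids), 1)],
           none = NA_integer_)
  }, integer(1))
  aset <- assignment_set(data.frame(read_id = truth$read_id,
                                    taxid = assigned,
                                    stringsAsFactors = FALSE), "random")
  list(tax = tax, nodes = nodes, truth = truth, assignments = aset,
       species = world$species)
}
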