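toy_nodes <- data.frame(
  taxid = c(1L, 2L, 3L, 4L),
  parent = c(1L, 1L, 2L, 3L),
  rank = c("no rank", "superkingdom", "genus", "species"),
  name = c("root", "Bacteria", "Pseudomonas", "Pseudomonas aeruginosa"),
  stringsAsFactors = FALSE)

test_that("taxonomy builds from a 4-column TSV and validates structure", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("taxid\tparent\trank\tname",
               "1\t1\tno rank\troot",
               "2\t1\tsuperkingdom\tBacteria",
               "3\t2\tgenus\tPseudomonas",
               "4\t3\tspecies\tPseudomonas aeruginosa"), tsv)
  tax <- load_taxonomy(tsv)
  expect_s3_class(tax, "taxonomy")
  expect_equal(length(tax), 4L)
  expect_equal(tax$root, 1L)
  # headerless variant parses identically
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(readLines(tsv)[-1], tsv2)
  expect_equal(as.data.frame(load_taxonomy(tsv2)), as.data.frame(tax))
})

test_that("structural defects are rejected: orphan, duplicate, cycle, no root", {
  orphan <- toy_nodes
  orphan$parent[3] <- 99L
  expect_error(taxonomy(orphan), class = "cladebench_structural_error")
  expect_error(taxonomy(orphan), "99")

  dup <- rbind(toy_nodes, toy_nodes[4, ])
  expect_error(taxonomy(dup), class = "cladebench_structural_error")

  cyc <- toy_nodes
  cyc$parent[2] <- 3L  # 2 -> 3 -> 2, disconnected from root
  expect_error(taxonomy(cyc), class = "cladebench_structural_error")

  noroot <- toy_nodes
  noroot$parent[1] <- 2L
  expect_error(taxonomy(noroot), class = "cladebench_structural_error")
})

test_that("taxdump dialect loads identically to the TSV dialect", {
  nodes_dmp <- tempfile()
  names_dmp <- tempfile()
  writeLines(c("1\t|\t1\t|\tno rank\t|\t\t|",
               "2\t|\t1\t|\tsuperkingdom\t|\t\t|",
               "3\t|\t2\t|\tgenus\t|\t\t|",
               "4\t|\t3\t|\tspecies\t|\t\t|"), nodes_dmp)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
               "2\t|\tbacteria\t|\t\t|\tblast name\t|",
               "3\t|\tPseudomonas\t|\t\t|\tscientific name\t|",
               "4\t|\tPseudomonas aeruginosa\t|\t\t|\tscientific name\t|"),
             names_dmp)
  from_dmp <- load_taxonomy(nodes_dmp, names_dmp)
  expect_equal(as.data.frame(from_dmp), as.data.frame(taxonomy(toy_nodes)))
})

test_that("lineage runs root-to-node with parent-child adjacency", {
  fw <- builtin_community("FW")
  tax <- fw$taxonomy
  expect_equal(lineage(tax, tax$root)$taxid, tax$root)

  pa_species <- unique(
    fw$members$species_taxid[fw$members$organism == "Pseudomonas aeruginosa"])
  lin <- lineage(tax, pa_species)
  expect_equal(lin$name,
               c("root", "Bacteria", "Proteobacteria", "Gammaproteobacteria",
                 "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas",
                 "Pseudomonas aeruginosa"))
  for (i in seq_len(nrow(lin) - 1))
    expect_equal(unname(tax$parent[[as.character(lin$taxid[i + 1])]]),
                 lin$taxid[i])

  # a strain's lineage is its species' lineage plus the strain
  pao1 <- fw$members$taxid[fw$members$strain == "PAO1"]
  expect_equal(lineage(tax, pao1)$taxid, c(lin$taxid, pao1))

  expect_error(lineage(tax, 99999L), class = "cladebench_lookup_error")
})

test_that("nearest canonical ancestor projects strains and unranked clades", {
  fw <- builtin_community("FW")
  tax <- fw$taxonomy
  pa_species <- unique(
    fw$members$species_taxid[fw$members$organism == "Pseudomonas aeruginosa"])
  nca <- nearest_canonical_ancestor(tax, pa_species)
  expect_equal(nca$taxid, pa_species)
  expect_equal(nca$index, 0L)

  pao1 <- fw$members$taxid[fw$members$strain == "PAO1"]
  nca <- nearest_canonical_ancestor(tax, pao1)
  expect_equal(nca$taxid, pa_species)
  expect_equal(nca$index, 0L)

  # "no rank" clade inserted between phylum and superkingdom projects to the
  # superkingdom
  nodes <- data.frame(
    taxid = 1:4, parent = c(1L, 1L, 2L, 3L),
    rank = c("no rank", "superkingdom", "no rank", "phylum"),
    name = c("root", "Bacteria", "Terrabacteria group", "Firmicutes"),
    stringsAsFactors = FALSE)
  tax2 <- taxonomy(nodes)
  nca <- nearest_canonical_ancestor(tax2, 3L)
  expect_equal(nca$taxid, 2L)
  expect_equal(nca$index, 6L)
  # root has no canonical ancestor: index 7, one step above superkingdom
  expect_equal(nearest_canonical_ancestor(tax2, 1L)$index, 7L)
})

test_that("truth-path membership follows the species-to-superkingdom rule", {
  fw <- builtin_community("FW")
  tax <- fw$taxonomy
  pa <- unique(
    fw$members$species_taxid[fw$members$organism == "Pseudomonas aeruginosa"])
  pf <- unique(
    fw$members$species_taxid[fw$members$organism == "Pseudomonas fluorescens"])
  genus <- lineage(tax, pa)$taxid[7]

  expect_true(is_on_truth_path(tax, pa, pa))
  expect_true(is_on_truth_path(tax, genus, pa))      # ancestor rank
  expect_false(is_on_truth_path(tax, pf, pa))        # congeneric sibling
  # strain of the truth species projects up and is on the path
  pao1 <- fw$members$taxid[fw$members$strain == "PAO1"]
  expect_true(is_on_truth_path(tax, pao1, pa))
  # truth given as a strain is projected too
  expect_true(is_on_truth_path(tax, genus, pao1))
})

test_that("lca matches lineage intersection on the community fixture", {
  fw <- builtin_community("FW")
  tax <- fw$taxonomy
  pa <- unique(
    fw$members$species_taxid[fw$members$organism == "Pseudomonas aeruginosa"])
  pf <- unique(
    fw$members$species_taxid[fw$members$organism == "Pseudomonas fluorescens"])
  ec <- unique(
    fw$members$species_taxid[fw$members$organism == "Escherichia coli"])

  expect_equal(lca(tax, pa, pa)$taxid, pa)
  expect_equal(lca(tax, pa, pf)$name, "Pseudomonas")
  expect_equal(lca(tax, pa, ec)$name, "Gammaproteobacteria")
})

test_that("path membership, lca and canonical projection agree with brute-force oracles on random trees", {
  for (seed in 1:25) {
    world <- random_tax_nodes(seed)
    nodes <- world$nodes
    tax <- taxonomy(nodes)
    set.seed(seed + 5000L)
    ids <- nodes$taxid
    for (k in 1:10) {
      a <- ids[sample.int(length(ids), 1)]
      t <- world$species[sample.int(length(world$species), 1)]
      expect_equal(
        is_on_truth_path(tax, a, t),
        oracle_species_of(nodes, a) %in%
          oracle_ancestors(nodes, oracle_species_of(nodes, t)),
        info = sprintf("seed %d: assigned %d truth %d", seed, a, t))

      b <- ids[sample.int(length(ids), 1)]
      l1 <- lca(tax, a, b)$taxid
      expect_equal(l1, lca(tax, b, a)$taxid)     # commutative
      expect_equal(lca(tax, a, a)$taxid, a)      # idempotent
      expect_true(l1 %in% oracle_ancestors(nodes, a))
      expect_true(l1 %in% oracle_ancestors(nodes, b))

      # canonical index is monotone non-decreasing walking to the root
      anc <- oracle_ancestors(nodes, a)
      idx <- vapply(anc, function(x)
        nearest_canonical_ancestor(tax, x)$index, integer(1))
      expect_true(all(diff(idx) >= 0))
    }
  }
})
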