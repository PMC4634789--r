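fw <- builtin_community("FW")
fwtax <- fw$taxonomy
pa <- unique(fw$members$species_taxid[fw$members$organism ==
                                        "Pseudomonas aeruginosa"])
pf <- unique(fw$members$species_taxid[fw$members$organism ==
                                        "Pseudomonas fluorescens"])
pa_lin <- lineage(fwtax, pa)
genus_node <- pa_lin$taxid[pa_lin$rank == "genus"]
family_node <- pa_lin$taxid[pa_lin$rank == "family"]

test_that("read classification follows the truth-path and overprediction rules", {
  strict <- eval_config()
  expect_equal(classify_read(NA, pa, fwtax, strict), "FN")
  expect_equal(classify_read(pa, pa, fwtax, strict), "TP")
  expect_equal(classify_read(family_node, pa, fwtax, strict), "TP")
  expect_equal(classify_read(pf, pa, fwtax, strict), "FP")

  # wrong species, right genus is rescued under species exclusion with
  # overpredictions considered correct
  lenient <- eval_config(exclusion_spec(pa, "species"),
                         overpredictions_correct = TRUE)
  expect_equal(classify_read(pf, pa, fwtax, lenient), "TP")
  # but a wrong genus is not
  ec <- unique(fw$members$species_taxid[fw$members$organism ==
                                          "Escherichia coli"])
  expect_equal(classify_read(ec, pa, fwtax, lenient), "FP")
  # strict mode never rescues
  strict_excl <- eval_config(exclusion_spec(pa, "species"))
  expect_equal(classify_read(pf, pa, fwtax, strict_excl), "FP")
})

test_that("taxonomic distance counts rank steps above the best possible rank", {
  strict <- eval_config()
  expect_equal(taxonomic_distance_of_read(pa, pa, fwtax, strict), 0)
  expect_equal(taxonomic_distance_of_read(genus_node, pa, fwtax, strict), 1)
  # species exclusion: best possible rank is genus (index 1); family sits 1 above
  excl <- eval_config(exclusion_spec(pa, "species"))
  expect_equal(taxonomic_distance_of_read(family_node, pa, fwtax, excl), 1)
  # an on-path species hit under species exclusion clamps at 0
  expect_equal(taxonomic_distance_of_read(pa, pa, fwtax, excl), 0)
  # undefined for non-TP reads
  expect_error(taxonomic_distance_of_read(pf, pa, fwtax, strict),
               class = "cladebench_usage_error")
  expect_error(taxonomic_distance_of_read(NA, pa, fwtax, strict),
               class = "cladebench_usage_error")
})

test_that("a perfect assignment set scores 1/1/0 everywhere", {
  w <- make_synthetic_world(4, genome_length_range = c(2000, 2000), seed = 2)
  sim <- simulate_reads(w, 100, 1, seed = 1)
  perfect <- assignment_set(data.frame(read_id = sim$truth$read_id,
                                       taxid = sim$truth$taxid), "oracle")
  res <- evaluate_assignments(perfect, sim, w$taxonomy)
  expect_true(all(res$per_genome$sensitivity == 1))
  expect_true(all(res$per_genome$precision == 1))
  expect_true(all(res$per_genome$taxonomic_distance == 0))
  expect_equal(res$aggregate$sensitivity, 1)
  expect_equal(res$aggregate$tp, res$n_reads)
})

test_that("the printed formulas hold on a constructed 3 TP / 1 FN genome", {
  nodes <- data.frame(taxid = 1:4, parent = c(1L, 1L, 2L, 3L),
                      rank = c("no rank", "superkingdom", "genus", "species"),
                      name = c("root", "Bacteria", "G", "G s"),
                      stringsAsFactors = FALSE)
  tax <- taxonomy(nodes)
  truth <- data.frame(read_id = paste0("r", 1:4), genome_id = "G1",
                      taxid = 4L, stringsAsFactors = FALSE)
  a <- assignment_set(data.frame(read_id = paste0("r", 1:4),
                                 taxid = c(4L, 4L, 4L, NA)), "t")
  res <- evaluate_assignments(a, truth, tax)
  expect_equal(res$per_genome$tp, 3L)
  expect_equal(res$per_genome$fn, 1L)
  expect_equal(res$per_genome$sensitivity, 0.75)
  expect_equal(res$per_genome$precision, 1)
  expect_equal(res$aggregate$tp + res$aggregate$fp + res$aggregate$fn, 4L)
})

test_that("undefined per-genome metrics are excluded from the aggregate and counted", {
  # genome G2 gets nothing assigned: precision and distance undefined there
  nodes <- data.frame(taxid = 1:6, parent = c(1L, 1L, 2L, 3L, 2L, 5L),
                      rank = c("no rank", "superkingdom", "genus", "species",
                               "genus", "species"),
                      name = c("root", "Bacteria", "G1", "G1 s", "G2", "G2 s"),
                      stringsAsFactors = FALSE)
  tax <- taxonomy(nodes)
  truth <- data.frame(read_id = paste0("r", 1:4),
                      genome_id = c("A", "A", "B", "B"),
                      taxid = c(4L, 4L, 6L, 6L), stringsAsFactors = FALSE)
  a <- assignment_set(data.frame(read_id = paste0("r", 1:4),
                                 taxid = c(4L, 4L, NA, NA)), "t")
  res <- evaluate_assignments(a, truth, tax)
  expect_equal(res$aggregate$n_precision_undefined, 1L)
  expect_equal(res$aggregate$n_distance_undefined, 1L)
  expect_equal(res$aggregate$precision, 1)        # mean over defined genomes
  expect_equal(res$aggregate$sensitivity, 0.5)    # mean(1, 0)
})

test_that("evaluation matches the brute-force oracle across modes on random scenarios", {
  configs <- list(
    list(rank = "none", overpred = FALSE),
    list(rank = "species", overpred = FALSE),
    list(rank = "species", overpred = TRUE),
    list(rank = "genus", overpred = TRUE),
    list(rank = "class", overpred = FALSE))
  for (seed in 1:12) {
    sc <- random_scenario(seed, n_reads = 120)
    joined <- suppressMessages(join_with_truth(sc$assignments, sc$truth))
    for (cf in configs) {
      config <- eval_config(exclusion_spec(rank = cf$rank),
                            overpredictions_correct = cf$overpred)
      res <- evaluate_assignments(sc$assignments, sc$truth, sc$tax, config)
      orc <- oracle_evaluate(sc$nodes, joined,
                             config$exclusion$best_rank_index, cf$overpred)
      expect_equal(res$per_genome$tp,
                   orc$per_genome$tp[match(res$per_genome$genome_id,
                                           orc$per_genome$genome_id)],
                   info = sprintf("seed %d rank %s", seed, cf$rank))
      expect_equal(res$aggregate$tp, orc$aggregate$tp)
      expect_equal(res$aggregate$fp, orc$aggregate$fp)
      expect_equal(res$aggregate$fn, orc$aggregate$fn)
      expect_equal(res$aggregate$sensitivity, orc$aggregate$sensitivity)
      expect_equal(res$aggregate$precision, orc$aggregate$precision)
      expect_equal(res$aggregate$taxonomic_distance,
                   orc$aggregate$taxonomic_distance)
    }
  }
})

test_that("pooled scoring accepts a hit to any community member as correct", {
  # two genera; truth reads all from species A, one read assigned to species B
  fwref <- fw$members$taxid
  truth <- data.frame(read_id = paste0("r", 1:3),
                      genome_id = "x", taxid = pa, stringsAsFactors = FALSE)
  ec <- unique(fw$members$species_taxid[fw$members$organism ==
                                          "Escherichia coli"])
  a <- assignment_set(data.frame(read_id = paste0("r", 1:3),
                                 taxid = c(pa, ec, NA)), "t")
  pooled <- eval_config(aggregation = "pooled", pooled_community = fw)
  res <- evaluate_assignments(a, truth, fwtax, pooled)
  # E. coli is in the community, so that read is correct in pooled mode
  expect_equal(res$aggregate$tp, 2L)
  expect_equal(res$aggregate$fn, 1L)
  expect_equal(res$aggregate$sensitivity, 2 / 3)
  expect_equal(res$aggregate$precision, 1)
  expect_null(res$per_genome)

  # per-genome mode scores the same assignment as FP
  strict <- evaluate_assignments(a, truth, fwtax, eval_config())
  expect_equal(strict$aggregate$fp, 1L)

  # a node outside every member's path stays FP in pooled mode
  out_node <- fwtax$taxid[fwtax$name == "Archaeoglobus fulgidus"]
  b <- assignment_set(data.frame(read_id = paste0("r", 1:3),
                                 taxid = c(pa, pf, pf)), "t")
  res2 <- evaluate_assignments(b, truth, fwtax, pooled)
  expect_equal(res2$aggregate$tp, 3L)  # pf is a community member too
})

test_that("rank distribution buckets assigned reads by nearest canonical rank", {
  a <- assignment_set(data.frame(
    read_id = paste0("r", 1:4),
    taxid = c(pa, pa, genus_node, NA)), "t")
  rd <- rank_distribution(a, fwtax)
  expect_equal(rd$frac_assigned[rd$rank == "species"], 2 / 3)
  expect_equal(rd$frac_assigned[rd$rank == "genus"], 1 / 3)
  expect_equal(sum(rd$frac_assigned), 1, tolerance = 1e-9)
  expect_equal(attr(rd, "unassigned_fraction"), 0.25)
  expect_equal(rd$frac_all[rd$rank == "species"], 0.5)

  # strains count at species rank
  pao1 <- fw$members$taxid[fw$members$strain == "PAO1"]
  b <- assignment_set(data.frame(read_id = "r1", taxid = pao1), "t")
  rd2 <- rank_distribution(b, fwtax)
  expect_equal(rd2$frac_assigned[rd2$rank == "species"], 1)

  # all unassigned: empty distribution, unassigned fraction 1
  c0 <- assignment_set(data.frame(read_id = paste0("r", 1:2),
                                  taxid = c(NA_integer_, NA_integer_)), "t")
  rd3 <- rank_distribution(c0, fwtax)
  expect_true(all(rd3$n_reads == 0))
  expect_equal(attr(rd3, "unassigned_fraction"), 1)
})

test_that("evaluation results serialize to TSV tables and a JSON summary", {
  w <- make_synthetic_world(3, genome_length_range = c(2000, 2000), seed = 4)
  sim <- simulate_reads(w, 100, 1, seed = 1)
  a <- simulate_classifier(sim, w$taxonomy,
                           classifier_model(p_unassigned = 0.2,
                                            p_correct = 0.8), seed = 2)
  res <- evaluate_assignments(a, sim, w$taxonomy)
  dir <- tempfile()
  paths <- write_evaluation(res, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(file.path(dir, "per_genome.tsv"))
  expect_equal(back$tp, res$per_genome$tp)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$aggregate$tp, res$aggregate$tp)
})

test_that("zero truth reads is a parameter error", {
  truth0 <- data.frame(read_id = character(0), genome_id = character(0),
                       taxid = integer(0))
  a <- assignment_set(data.frame(read_id = character(0),
                                 taxid = integer(0)), "t")
  expect_error(evaluate_assignments(a, truth0, fwtax),
               class = "cladebench_parameter_error")
})
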