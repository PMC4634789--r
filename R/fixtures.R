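# Packaged mock-community definitions and fully synthetic test worlds.
#
# The two built-in profiles describe the organisms of the classic benchmark
# communities: MetaSimHC (11 diverse Bacteria and Archaea) and FW, a
# freshwater community of 11 bacterial species represented by 13 genomes
# (Pseudomonas aeruginosa contributes three strains). Each profile ships with
# a hand-built companion taxonomy carrying the full canonical ladder
# (superkingdom..species) for every member, using circa-2013 NCBI rank names,
# plus a strain node per genome. Taxids are internal synthetic IDs; real NCBI
# species taxids are recorded as metadata only. Genome sequences are NOT
# bundled: members carry metadata and intended coverage, and users point the
# read simulator at their own FASTA files (or at a synthetic world).

# columns: genome_id, genus, species epithet-or-name, strain, ncbi species taxid
.METASIMHC_MEMBERS <- list(
  c("HC01", "Agrobacterium",  "Agrobacterium tumefaciens",   "C58",        "358"),
  c("HC02", "Anabaena",       "Anabaena variabilis",         "ATCC 29413", ""),
  c("HC03", "Archaeoglobus",  "Archaeoglobus fulgidus",      "DSM 4304",   "2234"),
  c("HC04", "Bdellovibrio",   "Bdellovibrio bacteriovorus",  "HD100",      "959"),
  c("HC05", "Campylobacter",  "Campylobacter jejuni",        "81-176",     "197"),
  c("HC06", "Clostridium",    "Clostridium acetobutylicum",  "ATCC 824",   "1488"),
  c("HC07", "Lactococcus",    "Lactococcus lactis",          "SK11",       "1358"),
  c("HC08", "Nitrosomonas",   "Nitrosomonas europaea",       "ATCC 19718", "915"),
  c("HC09", "Pseudomonas",    "Pseudomonas aeruginosa",      "PAO1",       "287"),
  c("HC10", "Streptomyces",   "Streptomyces coelicolor",     "A3(2)",      "1902"),
  c("HC11", "Sulfolobus",     "Sulfolobus tokodaii",         "str. 7",     "111955"))

.FW_MEMBERS <- list(
  c("FW01", "Bacillus",      "Bacillus amyloliquefaciens", "FZB42",      "1390"),
  c("FW02", "Bacillus",      "Bacillus cereus",            "ATCC 14579", "1396"),
  c("FW03", "Burkholderia",  "Burkholderia cenocepacia",   "J2315",      "95486"),
  c("FW04", "Escherichia",   "Escherichia coli",           "K-12",       "562"),
  c("FW05", "Frankia",       "Frankia sp. CcI3",           "CcI3",       "106370"),
  c("FW06", "Micrococcus",   "Micrococcus luteus",         "NCTC 2665",  "1270"),
  c("FW07", "Pseudomonas",   "Pseudomonas aeruginosa",     "PAO1",       "287"),
  c("FW08", "Pseudomonas",   "Pseudomonas aeruginosa",     "UCBPP-PA14", "287"),
  c("FW09", "Pseudomonas",   "Pseudomonas aeruginosa",     "PA7",        "287"),
  c("FW10", "Pseudomonas",   "Pseudomonas fluorescens",    "Pf-5",       "294"),
  c("FW11", "Pseudomonas",   "Pseudomonas putida",         "KT2440",     "303"),
  c("FW12", "Rhodobacter",   "Rhodobacter capsulatus",     "SB 1003",    "1061"),
  c("FW13", "Streptomyces",  "Streptomyces coelicolor",    "A3(2)",      "1902"))

# superkingdom..genus ladder per genus (2013-era NCBI names).
.GENUS_LADDERS <- list(
  Agrobacterium = c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                    "Rhizobiales", "Rhizobiaceae"),
  Anabaena      = c("Bacteria", "Cyanobacteria", "Cyanophyceae",
                    "Nostocales", "Nostocaceae"),
  Archaeoglobus = c("Archaea", "Euryarchaeota", "Archaeoglobi",
                    "Archaeoglobales", "Archaeoglobaceae"),
  Bdellovibrio  = c("Bacteria", "Proteobacteria", "Deltaproteobacteria",
                    "Bdellovibrionales", "Bdellovibrionaceae"),
  Campylobacter = c("Bacteria", "Proteobacteria", "Epsilonproteobacteria",
                    "Campylobacterales", "Campylobacteraceae"),
  Clostridium   = c("Bacteria", "Firmicutes", "Clostridia",
                    "Clostridiales", "Clostridiaceae"),
  Lactococcus   = c("Bacteria", "Firmicutes", "Bacilli",
                    "Lactobacillales", "Streptococcaceae"),
  Nitrosomonas  = c("Bacteria", "Proteobacteria", "Betaproteobacteria",
                    "Nitrosomonadales", "Nitrosomonadaceae"),
  Pseudomonas   = c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                    "Pseudomonadales", "Pseudomonadaceae"),
  Streptomyces  = c("Bacteria", "Actinobacteria", "Actinobacteria",
                    "Actinomycetales", "Streptomycetaceae"),
  Sulfolobus    = c("Archaea", "Crenarchaeota", "Thermoprotei",
                    "Sulfolobales", "Sulfolobaceae"),
  Bacillus      = c("Bacteria", "Firmicutes", "Bacilli",
                    "Bacillales", "Bacillaceae"),
  Burkholderia  = c("Bacteria", "Proteobacteria", "Betaproteobacteria",
                    "Burkholderiales", "Burkholderiaceae"),
  Escherichia   = c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                    "Enterobacteriales", "Enterobacteriaceae"),
  Frankia       = c("Bacteria", "Actinobacteria", "Actinobacteria",
                    "Actinomycetales", "Frankiaceae"),
  Micrococcus   = c("Bacteria", "Actinobacteria", "Actinobacteria",
                    "Actinomycetales", "Micrococcaceae"),
  Rhodobacter   = c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                    "Rhodobacterales", "Rhodobacteraceae"))

.LADDER_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                   "genus", "species")

# Build a taxonomy from per-member lineage name vectors. Nodes are shared by
# (rank, name) key; the class "Actinobacteria" is distinct from the phylum of
# the same name because the key includes the rank. Strain nodes get rank
# "no rank".
.build_toy_taxonomy <- function(members) {
  nodes <- data.frame(taxid = 1L, parent = 1L, rank = "no rank",
                      name = "root", stringsAsFactors = FALSE)
  index <- new.env(parent = emptyenv())
  next_id <- 2L
  add_node <- function(rank, name, parent_id) {
    key <- paste0(rank, "|", name)
    if (!is.null(index[[key]])) return(index[[key]])
    id <- next_id
    next_id <<- next_id + 1L
    nodes[nrow(nodes) + 1L, ] <<- list(id, parent_id, rank, name)
    index[[key]] <- id
    id
  }
  member_taxid <- integer(0)
  species_taxid <- integer(0)
  for (m in members) {
    ladder <- .GENUS_LADDERS[[m[2]]]
    chain <- c(ladder, m[2], m[3])
    parent_id <- 1L
    for (i in seq_along(chain))
      parent_id <- add_node(.LADDER_RANKS[i], chain[i], parent_id)
    sp_id <- parent_id
    strain_name <- paste(m[3], m[4])
    st_id <- add_node("no rank", strain_name, sp_id)
    member_taxid <- c(member_taxid, st_id)
    species_taxid <- c(species_taxid, sp_id)
  }
  list(taxonomy = taxonomy(nodes), member_taxid = member_taxid,
       species_taxid = species_taxid)
}

#' Built-in mock-community profiles
#'
#' Returns one of the two packaged benchmark communities with its companion
#' toy taxonomy. `"MetaSimHC"` holds 11 diverse genomes spanning Bacteria and
#' Archaea; `"FW"` (freshwater) holds 13 genomes from 11 bacterial species,
#' including three Pseudomonas species (and three P. aeruginosa strains) so
#' that congeneric confusion can be exercised. Members are metadata only —
#' no genome sequence is bundled; `genome_length` is `NA` and intended
#' coverage is 1 for every member.
#'
#' @param name `"MetaSimHC"` or `"FW"`.
#' @return An object of class `community_profile`: a list with `name`,
#'   `members` (data.frame: `genome_id`, `organism`, `strain`, `taxid`,
#'   `species_taxid`, `ncbi_species_taxid`, `coverage`, `genome_length`) and
#'   `taxonomy` (the companion [taxonomy]).
#' @examples
#' fw <- builtin_community("FW")
#' nrow(fw$members)                          # 13 genomes
#' length(unique(fw$members$species_taxid))  # 11 species
#' @export
builtin_community <- function(name) {
  members <- switch(name,
                    MetaSimHC = .METASIMHC_MEMBERS,
                    FW = .FW_MEMBERS,
                    stop_lookup(paste0("unknown community: '", name,
                                       "' (available: MetaSimHC, FW)")))
  built <- .build_toy_taxonomy(members)
  df <- data.frame(
    genome_id = vapply(members, `[[`, "", 1),
    organism  = vapply(members, `[[`, "", 3),
    strain    = vapply(members, `[[`, "", 4),
    taxid     = built$member_taxid,
    species_taxid = built$species_taxid,
    ncbi_species_taxid = suppressWarnings(
      as.integer(vapply(members, `[[`, "", 5))),
    coverage = 1,
    genome_length = NA_integer_,
    stringsAsFactors = FALSE)
  structure(list(name = name, members = df, taxonomy = built$taxonomy),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat("Community profile '", x$name, "': ", nrow(x$members), " genomes, ",
      length(unique(x$members$species_taxid)), " species\n", sep = "")
  print(x$members[, c("genome_id", "organism", "strain", "taxid")])
  invisible(x)
}

#' Number of distinct species in a community profile
#'
#' Strain genomes of the same species count once.
#'
#' @param community a `community_profile`.
#' @return Integer count.
#' @export
community_n_species <- function(community) {
  length(unique(community$members$species_taxid))
}

#' Generate a synthetic test world
#'
#' Builds a random but fully structured benchmark world: a taxonomy in which
#' every species carries a complete canonical ladder (each genus gets its own
#' family/order/class/phylum chain under a shared Bacteria superkingdom),
#' i.i.d. uniform-base random genome sequences, and a community profile with
#' every member at 1X intended coverage. Congeneric pairs place a second
#' species in an existing genus, mirroring communities that contain closely
#' related species. Output is byte-deterministic for a given seed and
#' parameter set.
#'
#' @param n_species number of species (>= 1).
#' @param n_congeneric_pairs how many species are added as a second congener
#'   of an existing genus (0 <= pairs <= n_species - 1).
#' @param genome_length_range length-2 integer range (min >= 1000) from which
#'   genome lengths are drawn uniformly.
#' @param seed RNG seed.
#' @return Object of class `synthetic_world`: list with `taxonomy`, `genomes`
#'   (named [Biostrings::DNAStringSet]), `community` (a `community_profile`)
#'   and `seed`.
#' @examples
#' w <- make_synthetic_world(4, n_congeneric_pairs = 1,
#'                           genome_length_range = c(2000, 3000), seed = 7)
#' names(w$genomes)
#' @export
make_synthetic_world <- function(n_species, n_congeneric_pairs = 0,
                                 genome_length_range = c(5000, 20000),
                                 seed = 1) {
  if (!is.numeric(n_species) || n_species < 1)
    stop_parameter("n_species must be >= 1")
  n_species <- as.integer(n_species)
  n_congeneric_pairs <- as.integer(n_congeneric_pairs)
  if (n_congeneric_pairs < 0 || n_congeneric_pairs > n_species - 1L)
    stop_parameter("n_congeneric_pairs must be between 0 and n_species - 1")
  glr <- as.integer(genome_length_range)
  if (length(glr) != 2L || any(glr < 1000L) || glr[1] > glr[2])
    stop_parameter("genome_length_range must be an increasing pair with min >= 1000")

  set.seed(seed)
  n_genera <- n_species - n_congeneric_pairs
  # genus of each species: first n_genera species found their own genus, the
  # remaining ones join genera 1, 2, ... as congeners
  genus_of <- c(seq_len(n_genera), seq_len(n_congeneric_pairs))

  nodes <- data.frame(taxid = c(1L, 2L), parent = c(1L, 1L),
                      rank = c("no rank", "superkingdom"),
                      name = c("root", "Bacteria"), stringsAsFactors = FALSE)
  next_id <- 3L
  genus_id <- integer(n_genera)
  chain_ranks <- c("phylum", "class", "order", "family", "genus")
  for (g in seq_len(n_genera)) {
    parent <- 2L
    for (r in chain_ranks) {
      nodes[nrow(nodes) + 1L, ] <- list(next_id, parent, r,
                                        sprintf("%s_%d", r, g))
      parent <- next_id
      next_id <- next_id + 1L
    }
    genus_id[g] <- parent
  }
  species_id <- integer(n_species)
  for (s in seq_len(n_species)) {
    nodes[nrow(nodes) + 1L, ] <- list(next_id, genus_id[genus_of[s]],
                                      "species",
                                      sprintf("genus_%d species_%d",
                                              genus_of[s], s))
    species_id[s] <- next_id
    next_id <- next_id + 1L
  }
  tax <- taxonomy(nodes)

  lens <- if (glr[1] == glr[2]) rep(glr[1], n_species) else
    sample(glr[1]:glr[2], n_species, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  genome_id <- sprintf("SYN%03d", seq_len(n_species))
  genomes <- Biostrings::DNAStringSet(stats::setNames(seqs, genome_id))

  members <- data.frame(
    genome_id = genome_id,
    organism = unname(tax$name[as.character(species_id)]),
    strain = "",
    taxid = species_id,
    species_taxid = species_id,
    ncbi_species_taxid = NA_integer_,
    coverage = 1,
    genome_length = lens,
    stringsAsFactors = FALSE)
  community <- structure(list(name = "synthetic", members = members,
                              taxonomy = tax),
                         class = "community_profile")
  structure(list(taxonomy = tax, genomes = genomes, community = community,
                 seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", length(x$genomes), "genomes,",
      length(x$taxonomy$taxid), "taxonomy nodes, seed", x$seed, "\n")
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Writes the genomes as multi-FASTA, the genome-to-taxid mapping as TSV
#' (`genome_id`, `taxid`), the taxonomy in the 4-column TSV dialect, and the
#' community member table.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genomes = file.path(dir, "genomes.fasta"),
             mapping = file.path(dir, "mapping.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             community = file.path(dir, "community.tsv"))
  Biostrings::writeXStringSet(world$genomes, paths[["genomes"]])
  write_tsv(world$community$members[, c("genome_id", "taxid")],
            paths[["mapping"]])
  write_taxonomy(world$taxonomy, paths[["taxonomy"]])
  write_tsv(world$community$members, paths[["community"]])
  invisible(paths)
}
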