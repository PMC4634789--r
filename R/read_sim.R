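# Error-free shotgun read simulation with a ground-truth sidecar.
#
# Reads are sampled per genome with replacement from a uniform start
# distribution, both strands equiprobable; minus-strand reads are
# reverse-complemented; bases are copied exactly (no error model). The number
# of reads per genome is round(coverage * genome_length / read_length), so a
# 10,000 bp genome at 1X coverage and 100 bp reads yields exactly 100 reads.
# Reads never wrap a (circular) origin.

.as_genome_set <- function(genomes, mapping) {
  if (inherits(genomes, "synthetic_world")) {
    return(list(seqs = genomes$genomes,
                mapping = genomes$community$members[, c("genome_id", "taxid")]))
  }
  if (is.character(genomes) && length(genomes) == 1L) {
    if (!file.exists(genomes))
      stop_data(paste0("genome FASTA not found: ", genomes))
    genomes <- Biostrings::readDNAStringSet(genomes)
    # keep only the first whitespace-delimited token of each header
    names(genomes) <- sub("\\s.*$", "", names(genomes))
  }
  if (!methods::is(genomes, "DNAStringSet"))
    stop_parameter("genomes must be a synthetic_world, a DNAStringSet, or a FASTA path")
  if (is.null(mapping))
    stop_parameter("a genome_id -> taxid mapping is required with raw genome input")
  if (is.character(mapping)) mapping <- read_tsv(mapping)
  if (!all(c("genome_id", "taxid") %in% names(mapping)))
    stop_format("mapping must have columns genome_id and taxid")
  missing <- setdiff(names(genomes), mapping$genome_id)
  if (length(missing))
    stop_data(paste0("genomes missing from mapping: ",
                     paste(missing, collapse = ", ")))
  list(seqs = genomes, mapping = mapping)
}

#' Simulate error-free shotgun reads with ground truth
#'
#' Samples fixed-length single-end reads from each genome at the requested
#' coverage. Per genome the read count is
#' `round(coverage * genome_length / read_length)`; start positions are
#' uniform with replacement, strands equiprobable, and minus-strand reads are
#' reverse-complemented. Bases are copied exactly — no sequencing-error
#' model. The same seed and inputs give byte-identical output.
#'
#' @param genomes a `synthetic_world`, a named [Biostrings::DNAStringSet], or
#'   a path to a multi-FASTA file.
#' @param read_length read length in bp; must not exceed any genome length.
#' @param coverage per-genome fold coverage (> 0); every genome is sampled at
#'   this same depth.
#' @param seed RNG seed.
#' @param mapping genome_id -> taxid table (data.frame or TSV path); not
#'   needed when `genomes` is a `synthetic_world`.
#' @return Object of class `read_simulation`: list with `reads` (a named
#'   `DNAStringSet`) and `truth` (data.frame: `read_id`, `genome_id`,
#'   `taxid`, `start` 0-based on the forward strand, `strand` "+"/"-"), plus
#'   the simulation parameters.
#' @examples
#' w <- make_synthetic_world(2, genome_length_range = c(2000, 2000), seed = 1)
#' sim <- simulate_reads(w, read_length = 100, coverage = 1, seed = 1)
#' length(sim$reads)  # 2 genomes x 20 reads
#' @export
simulate_reads <- function(genomes, read_length, coverage = 1, seed = 1,
                           mapping = NULL) {
  gs <- .as_genome_set(genomes, mapping)
  if (!length(gs$seqs)) stop_parameter("empty genome set")
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 1L)
    stop_parameter("read_length must be a positive integer")
  if (!is.numeric(coverage) || coverage <= 0)
    stop_parameter("coverage must be > 0")
  lens <- Biostrings::width(gs$seqs)
  too_short <- names(gs$seqs)[lens < read_length]
  if (length(too_short))
    stop_parameter(paste0("read_length ", read_length,
                          " exceeds genome length for: ",
                          paste(too_short, collapse = ", ")))

  taxid_of <- stats::setNames(as.integer(gs$mapping$taxid),
                              gs$mapping$genome_id)
  set.seed(seed)
  per <- vector("list", length(gs$seqs))
  for (i in seq_along(gs$seqs)) {
    gid <- names(gs$seqs)[i]
    L <- lens[i]
    n <- round(coverage * L / read_length)
    if (n == 0L) {
      per[[i]] <- NULL
      next
    }
    start0 <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gseq <- as.character(gs$seqs[[i]])
    frag <- substring(gseq, start0 + 1L, start0 + read_length)
    rc <- strand == "-"
    if (any(rc))
      frag[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(frag[rc])))
    per[[i]] <- data.frame(
      read_id = sprintf("%s_r%06d", gid, seq_len(n)),
      genome_id = gid,
      taxid = taxid_of[[gid]],
      start = start0,
      strand = strand,
      seq = frag,
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, per)
  if (is.null(all) || !nrow(all))
    stop_parameter("no reads produced; coverage too low for these genome lengths")
  reads <- Biostrings::DNAStringSet(stats::setNames(all$seq, all$read_id))
  truth <- all[, c("read_id", "genome_id", "taxid", "start", "strand")]
  rownames(truth) <- NULL
  structure(list(reads = reads, truth = truth, read_length = read_length,
                 coverage = coverage, seed = seed),
            class = "read_simulation")
}

#' @export
print.read_simulation <- function(x, ...) {
  cat("Read simulation:", length(x$reads), "reads of", x$read_length,
      "bp from", length(unique(x$truth$genome_id)), "genomes at",
      x$coverage, "X (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Write simulated reads as FASTA
#'
#' @param sim a `read_simulation`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_read_fasta <- function(sim, path) {
  Biostrings::writeXStringSet(sim$reads, path)
  invisible(path)
}

#' Write simulated reads as FASTQ with constant Q40 qualities
#'
#' The simulation is error-free, so a flat Q40 is attached for tools that
#' insist on FASTQ input.
#'
#' @inheritParams write_read_fasta
#' @export
write_read_fastq <- function(sim, path) {
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(sim$reads),
           function(w) paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(sim$reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Write / read the ground-truth sidecar TSV
#'
#' Columns: `read_id`, `genome_id`, `taxid`, `start` (0-based), `strand`.
#'
#' @param truth truth data.frame (or a `read_simulation`).
#' @param path file path.
#' @return `write_truth`: the path, invisibly. `read_truth`: the data.frame.
#' @export
write_truth <- function(truth, path) {
  if (inherits(truth, "read_simulation")) truth <- truth$truth
  write_tsv(truth, path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_data(paste0("truth file not found: ", path))
  df <- read_tsv(path, colClasses = c(read_id = "character",
                                      genome_id = "character"))
  need <- c("read_id", "genome_id", "taxid")
  if (!all(need %in% names(df)))
    stop_format("truth TSV must have columns read_id, genome_id, taxid")
  df
}
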