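# The canonical rank ladder used for all distance arithmetic. Indices count
# steps up from species: species = 0 ... superkingdom = 6. Any other rank
# label ("no rank", "strain", "subspecies", ...) is non-canonical: such nodes
# participate in path membership but are projected to the nearest canonical
# ancestor before any rank arithmetic.

.CANONICAL_RANKS <- c("species", "genus", "family", "order", "class",
                      "phylum", "superkingdom")

# Ranks at which clade exclusion is supported (species through class).
.EXCLUSION_RANKS <- .CANONICAL_RANKS[1:5]

#' Canonical taxonomic rank ladder
#'
#' The seven canonical ranks used throughout the package, with their integer
#' indices. Index 0 is species and index 6 is superkingdom; taxonomic distance
#' is counted in steps on this ladder.
#'
#' @return A data.frame with columns `rank` and `index`.
#' @examples
#' rank_ladder()
#' @export
rank_ladder <- function() {
  data.frame(rank = .CANONICAL_RANKS, index = 0:6, stringsAsFactors = FALSE)
}

# 0-based index of a canonical rank label; NA for non-canonical labels.
rank_index <- function(rank) {
  match(rank, .CANONICAL_RANKS) - 1L
}

is_canonical_rank <- function(rank) {
  rank %in% .CANONICAL_RANKS
}
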