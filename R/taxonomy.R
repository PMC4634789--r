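#' Construct a taxonomy from a node table
#'
#' Builds and validates a rooted taxonomy from a table of nodes. The root is
#' the unique node whose parent is itself (NCBI convention, taxid 1 in real
#' dumps). Validation rejects duplicate taxids, unresolved parents, missing or
#' multiple roots, and parent cycles.
#'
#' @param nodes data.frame with columns `taxid` (positive integer), `parent`
#'   (positive integer; the root points to itself), `rank` (free-text rank
#'   label, e.g. "species", "no rank") and `name` (scientific name).
#' @return An object of class `taxonomy`.
#' @examples
#' tax <- taxonomy(data.frame(
#'   taxid = c(1, 2, 3, 4),
#'   parent = c(1, 1, 2, 3),
#'   rank = c("no rank", "superkingdom", "genus", "species"),
#'   name = c("root", "Bacteria", "Pseudomonas", "Pseudomonas aeruginosa")))
#' lineage(tax, 4)
#' @seealso [load_taxonomy()] to read taxonomy files, [lineage()], [lca()]
#' @export
taxonomy <- function(nodes) {
  required <- c("taxid", "parent", "rank", "name")
  if (!all(required %in% names(nodes)))
    stop_format(paste0("node table must have columns: ",
                       paste(required, collapse = ", ")))
  taxid  <- as.integer(nodes$taxid)
  parent <- as.integer(nodes$parent)
  if (anyNA(taxid) || anyNA(parent) || any(taxid < 1) || any(parent < 1))
    stop_format("taxids and parents must be positive integers")

  dup <- taxid[duplicated(taxid)]
  if (length(dup))
    stop_structural(paste0("duplicate taxid: ",
                           paste(unique(dup), collapse = ", ")))

  orphan <- setdiff(parent, taxid)
  if (length(orphan))
    stop_structural(paste0("parent taxid not present in node table (orphan parent): ",
                           paste(orphan, collapse = ", ")))

  root <- taxid[taxid == parent]
  if (length(root) != 1L)
    stop_structural(paste0("taxonomy must have exactly one root (taxid == parent); found ",
                           length(root)))

  key <- as.character(taxid)
  parent_vec <- stats::setNames(parent, key)
  rank_vec   <- stats::setNames(as.character(nodes$rank), key)
  name_vec   <- stats::setNames(as.character(nodes$name), key)

  # Depth computation doubles as cycle detection: walking parents from any
  # node must reach the root within n steps.
  n <- length(taxid)
  depth <- stats::setNames(rep(NA_integer_, n), key)
  depth[as.character(root)] <- 0L
  for (t in key) {
    if (!is.na(depth[[t]])) next
    path <- character(0)
    cur <- t
    while (is.na(depth[[cur]])) {
      if (length(path) > n)
        stop_structural(paste0("cycle detected in parent pointers near taxid ", cur))
      path <- c(path, cur)
      cur <- as.character(parent_vec[[cur]])
    }
    base <- depth[[cur]]
    depth[path] <- base + rev(seq_along(path))
  }

  structure(list(taxid = taxid, parent = parent_vec, rank = rank_vec,
                 name = name_vec, depth = depth, root = root),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy with", length(x$taxid), "nodes; root taxid", x$root, "\n")
  tab <- table(x$rank)
  cat("Ranks:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.taxonomy <- function(x) length(x$taxid)

#' @export
as.data.frame.taxonomy <- function(x, ...) {
  data.frame(taxid = x$taxid,
             parent = unname(x$parent[as.character(x$taxid)]),
             rank = unname(x$rank[as.character(x$taxid)]),
             name = unname(x$name[as.character(x$taxid)]),
             stringsAsFactors = FALSE)
}

.check_taxid <- function(tax, taxid, what = "taxid") {
  key <- as.character(taxid)
  bad <- key[!key %in% names(tax$parent)]
  if (length(bad))
    stop_lookup(paste0("unknown ", what, ": ", paste(bad, collapse = ", ")))
  key
}

# --- file loading ------------------------------------------------------------

.parse_dmp_lines <- function(lines) {
  # NCBI taxdump records: fields separated by "\t|\t", record terminated "\t|".
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Load a taxonomy from file
#'
#' Reads either the NCBI taxdump dialect (pipe-delimited `nodes.dmp` plus
#' `names.dmp`, of which only "scientific name" records are used) or the
#' package's own 4-column TSV dialect (`taxid`, `parent`, `rank`, `name`,
#' header optional). The result is validated: all parent references must
#' resolve, there must be exactly one root, and no cycles.
#'
#' @param nodes_source path to a nodes file: 4-column TSV when `names_source`
#'   is `NULL`, otherwise an NCBI-style `nodes.dmp`.
#' @param names_source optional path to an NCBI-style `names.dmp`.
#' @return A validated [taxonomy] object.
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL) {
  if (!file.exists(nodes_source))
    stop_data(paste0("taxonomy file not found: ", nodes_source))
  if (is.null(names_source)) {
    lines <- readLines(nodes_source)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop_format("empty taxonomy file")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4))
      stop_format("4-column TSV taxonomy requires taxid, parent, rank, name")
    first <- fields[[1]]
    has_header <- is.na(suppressWarnings(as.integer(first[1])))
    if (has_header) fields <- fields[-1]
    nodes <- data.frame(
      taxid  = suppressWarnings(as.integer(vapply(fields, `[[`, "", 1))),
      parent = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2))),
      rank   = vapply(fields, `[[`, "", 3),
      name   = vapply(fields, `[[`, "", 4),
      stringsAsFactors = FALSE)
    if (anyNA(nodes$taxid) || anyNA(nodes$parent))
      stop_format("non-integer taxid or parent in taxonomy TSV")
  } else {
    if (!file.exists(names_source))
      stop_data(paste0("taxonomy names file not found: ", names_source))
    nf <- .parse_dmp_lines(readLines(nodes_source))
    nf <- nf[lengths(nf) >= 3]
    nodes <- data.frame(
      taxid  = suppressWarnings(as.integer(vapply(nf, `[[`, "", 1))),
      parent = suppressWarnings(as.integer(vapply(nf, `[[`, "", 2))),
      rank   = vapply(nf, `[[`, "", 3),
      stringsAsFactors = FALSE)
    if (anyNA(nodes$taxid) || anyNA(nodes$parent))
      stop_format("non-integer taxid or parent in nodes.dmp")
    mf <- .parse_dmp_lines(readLines(names_source))
    mf <- mf[lengths(mf) >= 4]
    cls <- vapply(mf, `[[`, "", 4)
    mf <- mf[cls == "scientific name"]
    name_map <- stats::setNames(vapply(mf, `[[`, "", 2),
                                vapply(mf, `[[`, "", 1))
    nodes$name <- unname(name_map[as.character(nodes$taxid)])
    nodes$name[is.na(nodes$name)] <- paste0("taxid:", nodes$taxid[is.na(nodes$name)])
  }
  taxonomy(nodes)
}

#' Write a taxonomy in the 4-column TSV dialect
#'
#' @param tax a [taxonomy] object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  write_tsv(as.data.frame(tax), path)
}

# --- queries -----------------------------------------------------------------

# Integer vector of taxids from root down to `taxid` (inclusive).
lineage_taxids <- function(tax, taxid) {
  key <- .check_taxid(tax, taxid)
  path <- integer(tax$depth[[key]] + 1L)
  cur <- key
  for (i in seq_along(path)) {
    path[length(path) - i + 1L] <- as.integer(cur)
    cur <- as.character(tax$parent[[cur]])
  }
  path
}

#' Root-to-node lineage
#'
#' Returns the full path from the root to the queried node, including
#' non-canonical ("no rank") nodes. The first row is the root and the last is
#' the queried node; consecutive rows are parent and child.
#'
#' @param tax a [taxonomy] object.
#' @param taxid node to query.
#' @return data.frame with columns `taxid`, `rank`, `name`, ordered root
#'   first.
#' @export
lineage <- function(tax, taxid) {
  ids <- lineage_taxids(tax, taxid)
  key <- as.character(ids)
  data.frame(taxid = ids, rank = unname(tax$rank[key]),
             name = unname(tax$name[key]), stringsAsFactors = FALSE)
}

#' Nearest canonical ancestor
#'
#' Walks from a node toward the root until a node whose rank is on the
#' canonical ladder (see [rank_ladder()]) is found; a node that is itself
#' canonical is returned unchanged, and a strain maps to its species. If no
#' ancestor has a canonical rank the root is returned with index 7 (one step
#' above superkingdom).
#'
#' @inheritParams lineage
#' @return list with elements `taxid`, `rank`, `name` and `index` (0 =
#'   species ... 6 = superkingdom; 7 = above superkingdom).
#' @export
nearest_canonical_ancestor <- function(tax, taxid) {
  key <- .check_taxid(tax, taxid)
  cur <- key
  repeat {
    r <- tax$rank[[cur]]
    if (is_canonical_rank(r))
      return(list(taxid = as.integer(cur), rank = r,
                  name = tax$name[[cur]], index = rank_index(r)))
    if (cur == as.character(tax$root))
      return(list(taxid = as.integer(cur), rank = tax$rank[[cur]],
                  name = tax$name[[cur]], index = 7L))
    cur <- as.character(tax$parent[[cur]])
  }
}

# Taxid of the ancestor-or-self at exactly the canonical rank `rank`, or NA
# if the node's lineage has no node at that rank.
canonical_ancestor_at <- function(tax, taxid, rank) {
  key <- .check_taxid(tax, taxid)
  cur <- key
  repeat {
    if (identical(tax$rank[[cur]], rank)) return(as.integer(cur))
    if (cur == as.character(tax$root)) return(NA_integer_)
    cur <- as.character(tax$parent[[cur]])
  }
}

# Project strain/subspecies nodes up to their species; nodes at or above
# species rank are returned unchanged.
project_to_species <- function(tax, taxid) {
  key <- .check_taxid(tax, taxid)
  if (identical(tax$rank[[key]], "species")) return(as.integer(key))
  cur <- key
  while (cur != as.character(tax$root)) {
    cur <- as.character(tax$parent[[cur]])
    if (identical(tax$rank[[cur]], "species")) return(as.integer(cur))
  }
  as.integer(key)
}

#' Is an assignment on the truth path?
#'
#' A read assignment is on the truth path when the assigned node is an
#' ancestor-or-self of the truth species, with membership computed on the full
#' lineage including non-canonical nodes (the path from the species up to the
#' superkingdom and root). An assigned node strictly below the truth species
#' (a strain of it) is first projected to its species.
#'
#' @param tax a [taxonomy] object.
#' @param assigned_taxid the classifier's assigned node.
#' @param truth_species_taxid the true source species (a strain taxid is
#'   projected to its species).
#' @return TRUE or FALSE.
#' @export
is_on_truth_path <- function(tax, assigned_taxid, truth_species_taxid) {
  a <- project_to_species(tax, assigned_taxid)
  t <- project_to_species(tax, truth_species_taxid)
  a %in% lineage_taxids(tax, t)
}

#' Lowest common ancestor
#'
#' The deepest node shared by the two lineages.
#'
#' @param tax a [taxonomy] object.
#' @param taxid_a,taxid_b nodes to compare.
#' @return list with `taxid`, `rank`, `name`.
#' @export
lca <- function(tax, taxid_a, taxid_b) {
  la <- lineage_taxids(tax, taxid_a)
  lb <- lineage_taxids(tax, taxid_b)
  m <- min(length(la), length(lb))
  same <- la[seq_len(m)] == lb[seq_len(m)]
  i <- max(which(same))
  key <- as.character(la[i])
  list(taxid = la[i], rank = tax$rank[[key]], name = tax$name[[key]])
}
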