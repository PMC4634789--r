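# Normalized classifier output: one assignment (taxid or unassigned) per
# read. Two input dialects are supported — a generic two-column TSV
# (read_id, taxid; 0 or "U" marks unassigned) and Kraken's standard
# five-column output. Other tools' formats should be converted to the
# generic TSV by the user.

#' Construct an assignment set
#'
#' @param df data.frame with columns `read_id` (character, unique) and
#'   `taxid` (integer; `NA` = unassigned).
#' @param source_label free-text label for the classifier/run.
#' @return Object of class `assignment_set` (a data.frame with attribute
#'   `source_label`).
#' @export
assignment_set <- function(df, source_label = "unknown") {
  if (!all(c("read_id", "taxid") %in% names(df)))
    stop_format("assignment set requires columns read_id and taxid")
  dup <- which(duplicated(df$read_id))
  if (length(dup))
    stop_format(paste0("duplicate read_id '", df$read_id[dup[1]],
                       "' at record ", dup[1]))
  out <- data.frame(read_id = as.character(df$read_id),
                    taxid = as.integer(df$taxid),
                    stringsAsFactors = FALSE)
  attr(out, "source_label") <- source_label
  class(out) <- c("assignment_set", "data.frame")
  out
}

.source_lines <- function(source) {
  if (length(source) == 1L && !grepl("[\t\n]", source)) {
    if (!file.exists(source))
      stop_data(paste0("assignment file not found: ", source))
    readLines(source)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
}

#' Parse generic two-column assignment TSV
#'
#' Dialect: tab-separated `read_id`, `taxid` with an optional header line
#' (recognized by the literal column names `read_id`/`taxid`); a taxid of
#' `0` or `U` marks an unassigned read. Duplicate read IDs are rejected with
#' the offending line number.
#'
#' @param source path to a TSV file, or a character vector of lines.
#' @param source_label label recorded on the result.
#' @return An [assignment_set].
#' @export
parse_generic_tsv <- function(source, source_label = "generic") {
  lines <- .source_lines(source)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(assignment_set(
    data.frame(read_id = character(0), taxid = integer(0)), source_label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop_format(paste0("line ", short[1], ": expected 2 tab-separated columns"))
  col1 <- vapply(fields, `[[`, "", 1)
  col2 <- vapply(fields, `[[`, "", 2)
  offset <- 0L
  if (tolower(col1[1]) == "read_id" ||
      tolower(col2[1]) %in% c("taxid", "tax_id")) {   # header line
    col1 <- col1[-1]; col2 <- col2[-1]; offset <- 1L
  }
  taxid <- suppressWarnings(as.integer(col2))
  unass <- col2 %in% c("U", "u") | (!is.na(taxid) & taxid == 0L)
  bad <- which(is.na(taxid) & !unass)
  if (length(bad))
    stop_format(paste0("line ", bad[1] + offset, ": taxid '", col2[bad[1]],
                       "' is neither an integer nor 'U'"))
  taxid[unass] <- NA_integer_
  dup <- which(duplicated(col1))
  if (length(dup))
    stop_format(paste0("duplicate read_id '", col1[dup[1]], "' at line ",
                       dup[1] + offset))
  assignment_set(data.frame(read_id = col1, taxid = taxid,
                            stringsAsFactors = FALSE), source_label)
}

#' Parse Kraken standard output
#'
#' Kraken's five-column format: classification flag (`C`/`U`), read ID,
#' taxid, sequence length, k-mer map. Columns beyond the third are ignored;
#' `U` lines (and taxid 0) become unassigned.
#'
#' @inheritParams parse_generic_tsv
#' @return An [assignment_set].
#' @export
parse_kraken_output <- function(source, source_label = "kraken") {
  lines <- .source_lines(source)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(assignment_set(
    data.frame(read_id = character(0), taxid = integer(0)), source_label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_format(paste0("line ", short[1],
                       ": expected at least 3 tab-separated columns"))
  flag <- vapply(fields, `[[`, "", 1)
  bad <- which(!flag %in% c("C", "U"))
  if (length(bad))
    stop_format(paste0("line ", bad[1], ": classification flag '",
                       flag[bad[1]], "' is not 'C' or 'U'"))
  read_id <- vapply(fields, `[[`, "", 2)
  taxid <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  badt <- which(flag == "C" & is.na(taxid))
  if (length(badt))
    stop_format(paste0("line ", badt[1], ": non-integer taxid on a 'C' line"))
  taxid[flag == "U" | (!is.na(taxid) & taxid == 0L)] <- NA_integer_
  dup <- which(duplicated(read_id))
  if (length(dup))
    stop_format(paste0("duplicate read_id '", read_id[dup[1]], "' at line ",
                       dup[1]))
  assignment_set(data.frame(read_id = read_id, taxid = taxid,
                            stringsAsFactors = FALSE), source_label)
}

#' Write an assignment set in the generic TSV dialect
#'
#' Unassigned reads are written with taxid `U`.
#'
#' @param assignments an [assignment_set].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- data.frame(read_id = assignments$read_id,
                    taxid = ifelse(is.na(assignments$taxid), "U",
                                   as.character(assignments$taxid)),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Join classifier assignments with the simulation ground truth
#'
#' Every truth read appears exactly once in the result. Reads present in the
#' truth but absent from the classifier output are joined as unassigned —
#' classifiers that silently drop reads are thereby counted as
#' false-negatives. An assignment for a read the truth does not know is a
#' consistency error.
#'
#' @param assignments an [assignment_set].
#' @param truth truth data.frame (or `read_simulation`) with at least
#'   `read_id`; usually also `genome_id` and `taxid`.
#' @return data.frame with the truth columns plus `assigned_taxid` (`NA` =
#'   unassigned); attribute `n_missing` counts truth reads absent from the
#'   classifier output.
#' @export
join_with_truth <- function(assignments, truth) {
  if (inherits(truth, "read_simulation")) truth <- truth$truth
  unknown <- setdiff(assignments$read_id, truth$read_id)
  if (length(unknown))
    stop_consistency(paste0("assignment(s) for read_id absent from truth: ",
                            paste(utils::head(unknown, 5), collapse = ", "),
                            if (length(unknown) > 5) " ..."))
  idx <- match(truth$read_id, assignments$read_id)
  joined <- truth
  joined$assigned_taxid <- assignments$taxid[idx]
  n_missing <- sum(is.na(idx))
  if (n_missing)
    message(n_missing, " truth read(s) missing from classifier output; treated as unassigned")
  attr(joined, "n_missing") <- n_missing
  joined
}
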