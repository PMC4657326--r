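#' Construct a protein record
#'
#' A `protein_record` is the unit every feature in this package is computed
#' on: an identifier, a validated sequence over the 20-letter amino-acid
#' alphabet, its length and the per-type residue counts (all 20 types
#' present, absent residues counted 0).
#'
#' @param id character identifier.
#' @param sequence amino-acid sequence (upper-cased internally).
#' @param policy how to treat nonstandard residues, see
#'   [sanitize_sequence()]. Default `"drop"`.
#' @return An object of class `protein_record` with elements `id`,
#'   `sequence`, `length` and `counts` (named integer vector over
#'   [AMINO_ACIDS]).
#' @export
#' @examples
#' rec <- protein_record("p1", "ACDKK")
#' rec$counts[["K"]]
protein_record <- function(id, sequence, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string")
  seq <- sanitize_sequence(sequence, policy = policy)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = AMINO_ACIDS))
  counts <- stats::setNames(as.integer(counts), AMINO_ACIDS)
  structure(list(id = id, sequence = seq, length = nchar(seq),
                 counts = counts),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (L = %d)\n", x$id, x$length))
  invisible(x)
}

#' Validate and clean an amino-acid sequence
#'
#' Upper-cases the input and handles characters outside the 20-letter
#' standard alphabet. Under `strict`, any nonstandard character (ambiguity
#' codes X/B/Z/J, the rare U/O, stops `*`, gaps, whitespace) is an error
#' naming the first offending position (1-based). Under `drop` (the
#' default everywhere), nonstandard characters are removed with a warning
#' reporting how many were dropped.
#'
#' @param raw character scalar, the raw sequence.
#' @param policy `"strict"` or `"drop"`.
#' @return The cleaned upper-case sequence.
#' @export
#' @examples
#' suppressWarnings(sanitize_sequence("ACXD", "drop"))  # "ACD"
sanitize_sequence <- function(raw, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L)
    stop("'raw' must be a single string")
  if (!nzchar(raw)) stop("sequence is empty")
  up <- toupper(raw)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% AMINO_ACIDS)
  if (!any(bad)) return(up)
  if (policy == "strict") {
    pos <- which(bad)[1L]
    stop(sprintf(
      "nonstandard residue '%s' at position %d (strict policy)",
      chars[pos], pos))
  }
  kept <- chars[!bad]
  warning(sprintf("dropped %d nonstandard residue(s)", sum(bad)),
          call. = FALSE)
  if (length(kept) == 0L) stop("sequence empty after dropping nonstandard residues")
  paste(kept, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file (multi-record, wrapped or unwrapped).
#' @param policy nonstandard-residue policy passed to [sanitize_sequence()].
#' @return A list of [protein_record()] objects, one per FASTA entry; an
#'   empty list for an empty file.
#' @export
read_fasta <- function(path, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0L) return(list())
  aas <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop(sprintf(
                    "failed to parse FASTA '%s': %s", path,
                    conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- unname(as.character(aas))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1L]))
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    if (!nzchar(ids[i]))
      stop(sprintf("FASTA entry %d has an empty header", i))
    if (!nzchar(seqs[i]))
      stop(sprintf("FASTA record '%s' has an empty sequence", ids[i]))
    recs[[i]] <- protein_record(ids[i], seqs[i], policy = policy)
  }
  recs
}

#' Write protein records to FASTA
#'
#' @param records list of [protein_record()].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(sprintf(">%s", rec$id), con)
    s <- rec$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Join protein records with binary crystallization labels
#'
#' Reads a two-column table (id, label in {0,1}); comma or tab delimited,
#' auto-detected, with an optional header row (detected by a non-numeric
#' second field). Ids without a record, and records without a label, are
#' reported via warnings; records without labels are dropped from the
#' dataset.
#'
#' @param path path to the label table.
#' @param records list of [protein_record()].
#' @return A `labeled_dataset`: list with `records` (labelled ones only)
#'   and `labels` (named integer vector of 0/1, 1 = crystallized).
#' @export
read_labels <- function(path, records) {
  if (!file.exists(path)) stop(sprintf("label file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("label file is empty")
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop(sprintf("label line %d has fewer than 2 fields", bad[1L]))
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  vals <- trimws(vapply(parts, `[[`, "", 2L))
  if (suppressWarnings(is.na(as.numeric(vals[1L])))) {  # header row
    ids <- ids[-1L]; vals <- vals[-1L]
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate id in label file: %s", ids[duplicated(ids)][1L]))
  num <- suppressWarnings(as.numeric(vals))
  if (any(is.na(num)) || !all(num %in% c(0, 1)))
    stop(sprintf("non-binary label value '%s' for id '%s'",
                 vals[which(!(num %in% c(0, 1)))[1L]],
                 ids[which(!(num %in% c(0, 1)))[1L]]))
  labels <- stats::setNames(as.integer(num), ids)
  labeled_dataset(records, labels)
}

#' Construct a labeled dataset
#'
#' @param records list of [protein_record()].
#' @param labels named 0/1 vector keyed by record id.
#' @return A `labeled_dataset` object with `records` and `labels` aligned.
#' @export
labeled_dataset <- function(records, labels) {
  rec_ids <- vapply(records, function(r) r$id, "")
  unlabeled <- setdiff(rec_ids, names(labels))
  orphans <- setdiff(names(labels), rec_ids)
  if (length(unlabeled))
    warning(sprintf("%d record(s) without a label dropped: %s",
                    length(unlabeled),
                    paste(utils::head(unlabeled, 5L), collapse = ", ")),
            call. = FALSE)
  if (length(orphans))
    warning(sprintf("%d label(s) without a record ignored: %s",
                    length(orphans),
                    paste(utils::head(orphans, 5L), collapse = ", ")),
            call. = FALSE)
  keep <- rec_ids %in% names(labels)
  records <- records[keep]
  rec_ids <- rec_ids[keep]
  if (length(records) == 0L) stop("no record has a label")
  labels <- labels[rec_ids]
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  structure(list(records = records, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> n = %d, positives = %d (prevalence %.3f)\n",
              length(x$records), sum(x$labels), mean(x$labels)))
  invisible(x)
}

#' Dataset prevalence
#' @param dataset a `labeled_dataset`.
#' @return Fraction of positive (crystallized) labels.
#' @export
prevalence <- function(dataset) mean(dataset$labels)
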