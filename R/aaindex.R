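# AAIndex1 flat-file I/O and constant-characteristic encodings.
#
# AAIndex1 records are "H/D/R/A/T/J/C/I" blocks terminated by "//".  The I
# line header lists residues in the database's native order
#   A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V
# i.e. the first numeric row is A R N D C Q E G H I and the second is
# L K M F P S T W Y V.  Values are re-ordered to AMINO_ACIDS (alphabetical)
# at parse time.

AAINDEX_ROW1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
AAINDEX_ROW2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a constant-characteristic table
#'
#' One AAIndex1 entry: an accession, a descriptive title and one numeric
#' value per amino acid (the benchmark unit). Missing values stay `NA` and
#' are recorded in `na_mask`.
#'
#' @param accession AAIndex accession (e.g. `"CHAM830106"`).
#' @param values named numeric vector over [AMINO_ACIDS] (any order;
#'   re-ordered); `NA` allowed.
#' @param title free-text description.
#' @return A `characteristic_table` object.
#' @export
characteristic_table <- function(accession, values, title = "") {
  if (!is.character(accession) || !nzchar(accession))
    stop("'accession' must be a non-empty string")
  if (is.null(names(values)) || !setequal(names(values), AMINO_ACIDS))
    stop("'values' must be named by the 20 standard amino acids")
  values <- values[AMINO_ACIDS]
  structure(list(accession = accession, title = title,
                 values = values,
                 na_mask = AMINO_ACIDS[is.na(values)]),
            class = "characteristic_table")
}

#' @export
print.characteristic_table <- function(x, ...) {
  cat(sprintf("<characteristic_table> %s: %s (%d NA)\n",
              x$accession, x$title, length(x$na_mask)))
  invisible(x)
}

#' Parse an AAIndex1 flat file
#'
#' @param path path to an AAIndex1-format file (entries delimited by `//`).
#' @return List of [characteristic_table()] objects. Entries without an I
#'   block are skipped with a warning; an I block with fewer than 20
#'   numeric fields is a parse error naming the accession.
#' @export
parse_aaindex1 <- function(path) {
  if (!file.exists(path)) stop(sprintf("AAIndex file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0L) return(list())
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:(ends[k] - 1L)]
    if (!length(block) || all(!nzchar(trimws(block)))) next
    h <- grep("^H ", block, value = TRUE)
    accession <- if (length(h)) trimws(sub("^H ", "", h[1L])) else
      sprintf("(entry %d)", k)
    d <- grep("^D ", block)
    title <- if (length(d)) trimws(sub("^D ", "", block[d[1L]])) else ""
    i_line <- grep("^I ", block)
    if (!length(i_line) || i_line[1L] + 2L > length(block)) {
      warning(sprintf("AAIndex entry %s: missing I block, skipped",
                      accession), call. = FALSE)
      next
    }
    fields <- unlist(strsplit(trimws(
      block[c(i_line[1L] + 1L, i_line[1L] + 2L)]), "\\s+"))
    if (length(fields) != 20L)
      stop(sprintf("AAIndex entry %s: expected 20 values, found %d",
                   accession, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    vals[toupper(fields) == "NA"] <- NA_real_
    if (any(is.na(vals) & toupper(fields) != "NA"))
      stop(sprintf("AAIndex entry %s: non-numeric value '%s'",
                   accession, fields[which(is.na(vals) &
                                             toupper(fields) != "NA")[1L]]))
    names(vals) <- c(AAINDEX_ROW1, AAINDEX_ROW2)
    out[[length(out) + 1L]] <- characteristic_table(accession, vals, title)
  }
  out
}

#' Write characteristic tables in AAIndex1 format
#'
#' Round-trips through [parse_aaindex1()].
#'
#' @param tables list of [characteristic_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aaindex1 <- function(tables, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) paste(ifelse(is.na(v), "NA", sprintf("%g", v)),
                           collapse = " ")
  for (tb in tables) {
    writeLines(c(
      sprintf("H %s", tb$accession),
      sprintf("D %s", tb$title),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("  ", fmt(tb$values[AAINDEX_ROW1])),
      paste0("  ", fmt(tb$values[AAINDEX_ROW2])),
      "//"), con)
  }
  invisible(path)
}

#' Encode a protein with a constant characteristic
#'
#' The benchmark encoding. `weighted` (the default scheme) multiplies each
#' residue's index value by its occurrence count in the protein,
#' x_a = value_a * counts\[a\]; `raw` uses the bare index values, which are
#' identical for every protein and retained only to demonstrate the
#' inflexibility of unweighted constant characteristics.
#'
#' @param record a [protein_record()].
#' @param table a [characteristic_table()].
#' @param mode `"weighted"` or `"raw"`.
#' @param impute_na value substituted for masked residues; `NULL` (default)
#'   errors if a masked residue occurs in the protein.
#' @return An `encoded_protein`: list with `id`, `x` (named 20-vector),
#'   `y` (NA until labelled) and `source`.
#' @export
encode_constant <- function(record, table, mode = c("weighted", "raw"),
                            impute_na = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "protein_record"),
            inherits(table, "characteristic_table"))
  vals <- table$values
  present_masked <- intersect(table$na_mask,
                              AMINO_ACIDS[record$counts > 0L])
  if (length(present_masked)) {
    if (is.null(impute_na))
      stop(sprintf("characteristic %s has NA for residue(s) %s present in %s",
                   table$accession, paste(present_masked, collapse = ","),
                   record$id))
    vals[is.na(vals)] <- impute_na
  }
  vals[is.na(vals)] <- 0  # masked residues absent from the protein
  x <- if (mode == "weighted") vals * record$counts else vals
  encoded_protein(record$id, x, source = paste0("aaindex:", table$accession))
}

#' Encode a protein with a dynamic characteristic
#'
#' @param record a [protein_record()].
#' @param which `"distribution"` ([distribution_vector()]) or `"future"`
#'   ([future_composition()]).
#' @param matrix mutation matrix for the future encoding.
#' @return An `encoded_protein`.
#' @export
encode_dynamic <- function(record, which = c("distribution", "future"),
                           matrix = build_mutation_matrix()) {
  which <- match.arg(which)
  x <- switch(which,
              distribution = distribution_vector(record),
              future = future_composition(record, matrix))
  encoded_protein(record$id, x, source = which)
}

#' Construct an encoded protein
#' @param id record id.
#' @param x named numeric 20-vector of predictors (finite).
#' @param source label of the producing encoding.
#' @param y binary label or NA.
#' @return An `encoded_protein` object.
#' @export
encoded_protein <- function(id, x, source = "custom", y = NA_integer_) {
  if (length(x) != 20L || !all(is.finite(x)))
    stop("'x' must be 20 finite values")
  structure(list(id = id, x = stats::setNames(as.numeric(x), AMINO_ACIDS),
                 y = y, source = source),
            class = "encoded_protein")
}

#' Encode every record of a dataset into a predictor matrix
#'
#' @param dataset a `labeled_dataset`.
#' @param encoder function mapping a [protein_record()] to a numeric
#'   20-vector (e.g. `distribution_vector`, or a closure over
#'   [encode_constant()]).
#' @return List with `X` (n x 20 matrix, rownames = ids) and `y` (0/1).
#' @export
encode_dataset <- function(dataset, encoder) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  X <- t(vapply(dataset$records, function(r) as.numeric(encoder(r)),
                numeric(20L)))
  colnames(X) <- AMINO_ACIDS
  rownames(X) <- vapply(dataset$records, function(r) r$id, "")
  list(X = X, y = as.integer(dataset$labels))
}

#' Build the standard encoder set for screening
#'
#' One weighted constant encoder per characteristic table plus the two
#' dynamic encodings, as a named list of `record -> 20-vector` functions.
#'
#' @param tables list of [characteristic_table()] (may be empty).
#' @param dynamic include the distribution/future encoders.
#' @param matrix mutation matrix for the future encoding.
#' @return Named list of encoder functions.
#' @export
encoder_set <- function(tables = list(), dynamic = TRUE,
                        matrix = build_mutation_matrix()) {
  enc <- list()
  for (tb in tables) {
    local({
      tbl <- tb
      enc[[paste0("aaindex:", tbl$accession)]] <<-
        function(r) encode_constant(r, tbl)$x
    })
  }
  if (dynamic) {
    enc[["distribution"]] <- function(r) distribution_vector(r)
    enc[["future"]] <- function(r) future_composition(r, matrix)
  }
  enc
}
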