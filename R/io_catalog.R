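# FASTA and catalog I/O. Samples travel as a plain data.frame ("sample table")
# with columns sample_id, country, region, marker, residues; one row per record.

# IUPAC nucleotide codes plus the alignment gap character
IUPAC_DNA <- c("A", "C", "G", "T", "U", "N",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "-")
MARKERS <- c("CYTB", "COI", "COICOII")

#' Assemble a sample table
#'
#' @param sample_id character vector of unique identifiers.
#' @param residues uppercase DNA strings (IUPAC alphabet).
#' @param marker one of `"CYTB"`, `"COI"`, `"COICOII"` (recycled).
#' @param country ISO-3166 alpha-3 codes (recycled; `NA` allowed).
#' @param region free-text region labels (recycled; `NA` allowed).
#' @return data.frame with columns sample_id, country, region, marker, residues.
#' @export
sample_table <- function(sample_id, residues, marker = "COICOII",
                         country = NA_character_, region = NA_character_) {
  sample_id <- as.character(sample_id)
  residues <- toupper(as.character(residues))
  if (length(sample_id) != length(residues)) {
    stop("sample_id and residues must have the same length")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1L])
  }
  marker <- match.arg(toupper(marker), MARKERS, several.ok = TRUE)
  if (any(!nzchar(residues))) stop("residues must be non-empty")
  bad <- check_alphabet(residues)
  if (!is.null(bad)) {
    stop(sprintf("non-IUPAC character '%s' in '%s' at position %d",
                 bad$char, sample_id[bad$record], bad$position))
  }
  data.frame(sample_id = sample_id,
             country = rep_len(as.character(country), length(sample_id)),
             region = rep_len(as.character(region), length(sample_id)),
             marker = rep_len(marker, length(sample_id)),
             residues = residues,
             stringsAsFactors = FALSE)
}

# first offending (record, position, char) over the IUPAC DNA alphabet, or NULL
check_alphabet <- function(residues) {
  ok <- paste0("[", paste(IUPAC_DNA, collapse = ""), "]")
  for (i in seq_along(residues)) {
    chars <- strsplit(residues[[i]], "", fixed = TRUE)[[1L]]
    hit <- which(!grepl(ok, chars))
    if (length(hit)) {
      return(list(record = i, position = hit[1L], char = chars[hit[1L]]))
    }
  }
  NULL
}

#' Read sample sequences from a FASTA file
#'
#' Record identifiers are the first whitespace-delimited token of each header;
#' headers are never parsed for metadata. Country/region come from the optional
#' sidecar metadata table (see [read_metadata()]), joined by `sample_id`.
#' Residues are uppercased; record order is preserved.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param marker marker code for all records in the file.
#' @param metadata optional data.frame with columns `sample_id`, `country` and
#'   optionally `region`.
#' @return sample table (see [sample_table()]).
#' @export
read_fasta <- function(path, marker = "COICOII", metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1L])
  }
  res <- sample_table(ids, as.character(set), marker = marker)
  if (!is.null(metadata)) {
    m <- match(res$sample_id, metadata$sample_id)
    res$country <- as.character(metadata$country)[m]
    if (!is.null(metadata$region)) res$region <- as.character(metadata$region)[m]
  }
  res
}

#' Write a sample table to FASTA
#'
#' @param samples sample table.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(samples, path, width = 70L) {
  set <- Biostrings::BStringSet(samples$residues)
  names(set) <- samples$sample_id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Trim ambiguous sequence ends
#'
#' Removes the maximal leading and trailing runs of non-\{A,C,G,T\} characters
#' (the usual cleanup of Sanger read ends); interior characters are untouched.
#' Idempotent.
#'
#' @param x character vector of residues, or a sample table whose `residues`
#'   column is trimmed in place.
#' @return same shape as the input.
#' @export
trim_ambiguous_ends <- function(x) {
  if (is.data.frame(x)) {
    x$residues <- trim_ambiguous_ends(x$residues)
    return(x)
  }
  out <- sub("[^ACGT]+$", "", sub("^[^ACGT]+", "", toupper(x)))
  if (any(!nzchar(out))) {
    stop("sequence entirely ambiguous after trimming: record ",
         which(!nzchar(out))[1L])
  }
  out
}

CATALOG_COLUMNS <- c("name", "lineage", "structure", "length", "nfrag",
                     "country", "sequence", "accession")

#' Read a reference haplotype catalog
#'
#' Tab-separated with header
#' `name lineage structure length nfrag country sequence accession`.
#' Lineage defaults to `"unknown"` when blank; `length` must equal the
#' sequence length whenever a sequence is present.
#'
#' @param path TSV file.
#' @return data.frame with the catalog columns, one reference per row.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty catalog file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, CATALOG_COLUMNS)) {
    stop("catalog header must be: ", paste(CATALOG_COLUMNS, collapse = " "))
  }
  body <- lines[-1L]
  if (length(body) == 0L) return(empty_catalog())
  rows <- strsplit(body, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) > 8L) stop("malformed catalog row at line ", i + 1L,
                             ": too many fields")
    length(f) <- 8L  # trailing empty fields are dropped by strsplit
    f[is.na(f)] <- ""
    if (!nzchar(f[[1L]])) stop("malformed catalog row at line ", i + 1L)
    len <- suppressWarnings(as.integer(f[[4L]]))
    nfrag <- suppressWarnings(as.integer(f[[5L]]))
    if (is.na(len) || is.na(nfrag)) {
      stop("malformed catalog row at line ", i + 1L,
           ": length and nfrag must be integers")
    }
    if (nfrag < 1L) stop("malformed catalog row at line ", i + 1L,
                         ": nfrag must be >= 1")
    seqres <- toupper(f[[7L]])
    if (nzchar(seqres) && nchar(seqres) != len) {
      stop("malformed catalog row at line ", i + 1L,
           ": length field does not match sequence length")
    }
    out[[i]] <- data.frame(
      name = f[[1L]],
      lineage = if (nzchar(f[[2L]])) f[[2L]] else "unknown",
      structure = f[[3L]],
      length = len,
      nfrag = nfrag,
      country = f[[6L]],
      sequence = seqres,
      accession = f[[8L]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a reference haplotype catalog
#'
#' @param catalog data.frame with the catalog columns.
#' @param path output TSV file.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(all(CATALOG_COLUMNS %in% names(catalog)))
  utils::write.table(catalog[, CATALOG_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata sidecar table
#'
#' TSV with header `sample_id country region marker`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Build an empty haplotype catalog
#' @return zero-row catalog data.frame.
#' @export
empty_catalog <- function() {
  data.frame(name = character(), lineage = character(), structure = character(),
             length = integer(), nfrag = integer(), country = character(),
             sequence = character(), accession = character(),
             stringsAsFactors = FALSE)
}
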