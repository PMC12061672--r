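# The in-silico DmCC test: DraI digestion of the COI-COII amplicon, haplotype
# matching against a reference catalog, and universal novel-haplotype naming.

#' In-silico restriction digest
#'
#' Locates every (possibly overlapping) occurrence of the recognition site and
#' cuts once per occurrence at a fixed intra-site offset. DraI (TTTAAA,
#' blunt cut TTT^AAA, offset 3) is the default; both are configurable.
#'
#' @param seq sample (one-row sample table, list, or bare sequence string).
#' @param site recognition site over \{A,C,G,T\}.
#' @param cut_offset 0-based cut position within the site.
#' @return object of class `digest_profile`: list with `sample_id`,
#'   `recognition_site`, `cut_positions` (0-based, strictly increasing),
#'   `fragment_lengths` (amplicon order) and `fragment_count`.
#' @export
digest <- function(seq, site = "TTTAAA", cut_offset = 3L) {
  s <- as_sample_row(seq)
  x <- toupper(s$residues)
  site <- toupper(site)
  if (!nzchar(site) || grepl("[^ACGT]", site)) {
    stop("recognition site must be a non-empty string over A/C/G/T")
  }
  if (cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut_offset must lie within the recognition site")
  }
  L <- nchar(x)
  cuts <- site_starts0(x, site) + cut_offset
  cuts <- cuts[cuts > 0L & cuts < L]
  frags <- diff(c(0L, cuts, L))
  stopifnot(sum(frags) == L)  # conservation, by construction
  structure(list(sample_id = if (is.null(s$sample_id)) "query" else s$sample_id,
                 recognition_site = site,
                 cut_positions = cuts,
                 fragment_lengths = frags,
                 fragment_count = length(frags)),
            class = "digest_profile")
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf("<%s> %s digest: %d fragment(s): %s\n", x$sample_id,
              x$recognition_site, x$fragment_count,
              paste(x$fragment_lengths, collapse = "/")))
  invisible(x)
}

#' Sequence identity between a query and a reference
#'
#' Exact matches over the aligned columns of a global end-free (overlap)
#' alignment with unit scores. Identity 1.0 requires equal length and zero
#' mismatches (case-insensitive). When the forward identity falls below
#' `revcomp_below`, the reverse complement is tried and the better value
#' returned.
#'
#' @param query,reference residue strings.
#' @param revcomp_below forward-identity threshold triggering the
#'   reverse-complement attempt.
#' @return list with `identity` and logical `revcomp`.
#' @export
seq_identity <- function(query, reference, revcomp_below = 0.5) {
  q <- toupper(query)
  r <- toupper(reference)
  if (identical(q, r)) return(list(identity = 1.0, revcomp = FALSE))
  fwd <- overlap_identity(q, r)
  if (fwd >= revcomp_below) return(list(identity = fwd, revcomp = FALSE))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  rev <- overlap_identity(rc, r)
  if (rev > fwd) list(identity = rev, revcomp = TRUE)
  else list(identity = fwd, revcomp = FALSE)
}

# identity = matches / aligned columns (incl. internal gap columns) of an
# end-free global alignment; 1.0 only for equal-length, mismatch-free pairs
overlap_identity <- function(q, r) {
  if (identical(q, r)) return(1.0)
  pa <- unit_align(q, r, type = "overlap")
  ncol <- nchar(as.character(Biostrings::alignedPattern(pa)))
  if (ncol == 0L) return(0)
  Biostrings::nmatch(pa) / max(ncol, nchar(q), nchar(r))
}

#' Name a novel haplotype by the universal nomenclature
#'
#' `{lineage}{serial}-{length}-{fragments}-{country}`, e.g. `A1-838-6-OMN`:
#' lineage letter, per-(lineage, country) serial number, amplicon length in
#' bp, restriction fragment count, ISO-3166 alpha-3 country code.
#'
#' @param lineage lineage letter (A/M/C/O).
#' @param serial integer >= 1.
#' @param total_length amplicon length in bp.
#' @param fragment_count restriction fragment count.
#' @param country ISO alpha-3 code (3 alphabetic characters).
#' @return the haplotype name string.
#' @export
name_novel_haplotype <- function(lineage, serial, total_length,
                                 fragment_count, country) {
  if (is.na(country) || !grepl("^[A-Za-z]{3}$", country)) {
    stop("country must be a 3-letter ISO-3166 alpha-3 code, got: ",
         if (is.na(country)) "NA" else country)
  }
  serial <- as.integer(serial)
  if (is.na(serial) || serial < 1L) stop("serial must be an integer >= 1")
  sprintf("%s%d-%d-%d-%s", lineage, serial, as.integer(total_length),
          as.integer(fragment_count), toupper(country))
}

#' Assign a haplotype to one annotated, digested sample
#'
#' Exact full-length identity (1.0, case-insensitive) with a catalog entry
#' gives status `known` and that entry's name. Otherwise the sample is
#' `novel`: the nearest catalog entry is reported with its identity and a new
#' name is generated with [name_novel_haplotype()].
#'
#' @param seq the sample (one-row sample table or list; `country` is used for
#'   novel naming).
#' @param ann its [annotate_structure()] result.
#' @param prof its [digest()] profile.
#' @param catalog reference catalog data.frame (see [read_catalog()]).
#' @param lineage its [call_lineage()] result.
#' @param serial serial number to use if the sample turns out novel
#'   ([classify_dataset()] supplies the per-(lineage, country) counter).
#' @return one-row data.frame: sample_id, status, name, matched_reference,
#'   identity, lineage, structure, length, fragment_count.
#' @export
assign_haplotype <- function(seq, ann, prof, catalog, lineage, serial = 1L) {
  s <- as_sample_row(seq)
  x <- toupper(s$residues)
  row <- function(status, name, ref, identity) {
    data.frame(sample_id = ann$sample_id, status = status, name = name,
               matched_reference = ref, identity = identity,
               lineage = lineage$lineage, structure = ann$structure_label,
               length = ann$total_length, fragment_count = prof$fragment_count,
               stringsAsFactors = FALSE)
  }
  with_seq <- which(nzchar(catalog$sequence))
  exact <- with_seq[toupper(catalog$sequence[with_seq]) == x]
  if (length(exact)) {
    e <- exact[[1L]]
    return(row("known", catalog$name[[e]], catalog$name[[e]], 1.0))
  }
  best_ref <- ""
  best_id <- NA_real_
  if (length(with_seq)) {
    ids <- vapply(with_seq, function(i)
      seq_identity(x, catalog$sequence[[i]])$identity, numeric(1L))
    top <- which.max(ids)
    best_ref <- catalog$name[[with_seq[top]]]
    best_id <- ids[[top]]
    if (best_id == 1.0) {  # reverse-complement exact match
      return(row("known", best_ref, best_ref, 1.0))
    }
  }
  name <- name_novel_haplotype(lineage$lineage, serial, ann$total_length,
                               prof$fragment_count, s$country)
  row("novel", name, best_ref, best_id)
}

#' Classify a COI-COII dataset end to end
#'
#' Runs annotate -> digest -> assign for every sample. Byte-identical samples
#' share one assignment; novel serial numbers restart per (lineage, country)
#' and follow first appearance in input order, so the result is deterministic
#' given the input order.
#'
#' @param samples sample table (marker COICOII).
#' @param catalog reference catalog data.frame.
#' @param lib element library.
#' @param site,cut_offset restriction specificity (DraI defaults).
#' @return data.frame with one row per sample: sample_id, country, status,
#'   name, matched_reference, identity, lineage, structure, length,
#'   fragment_count, n_deletions, deletion_offsets, deletion_lengths. The
#'   per-sample structure annotations are attached as attribute
#'   `"annotations"`.
#' @export
classify_dataset <- function(samples, catalog = empty_catalog(),
                             lib = build_element_library(),
                             site = "TTTAAA", cut_offset = 3L) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) {
    out <- data.frame(sample_id = character(), country = character(),
                      status = character(), name = character(),
                      matched_reference = character(), identity = numeric(),
                      lineage = character(), structure = character(),
                      length = integer(), fragment_count = integer(),
                      n_deletions = integer(), deletion_offsets = character(),
                      deletion_lengths = character(), stringsAsFactors = FALSE)
    attr(out, "annotations") <- list()
    return(out)
  }
  if (any(samples$marker != "COICOII")) {
    stop("classify_dataset requires marker COICOII for all samples")
  }
  serials <- new.env(parent = emptyenv())  # per (lineage, country) counters
  by_class <- new.env(parent = emptyenv()) # residues -> finished assignment
  anns <- vector("list", nrow(samples))
  rows <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    key <- paste0("k", smp$residues)
    cached <- if (!is.null(by_class[[key]])) by_class[[key]] else NULL
    res <- tryCatch({
      ann <- annotate_structure(smp, lib)
      if (is.null(cached)) {
        prof <- digest(smp, site = site, cut_offset = cut_offset)
        lin <- call_lineage(ann)
        skey <- paste(lin$lineage, smp$country, sep = "|")
        serial <- if (is.null(serials[[skey]])) 1L else serials[[skey]] + 1L
        asg <- assign_haplotype(smp, ann, prof, catalog, lin, serial = serial)
        if (asg$status == "novel") serials[[skey]] <- serial
        by_class[[key]] <- asg
      } else {
        asg <- cached
        asg$sample_id <- smp$sample_id
      }
      list(ann = ann, asg = asg)
    }, error = function(e) {
      stop("sample ", smp$sample_id, ": ", conditionMessage(e), call. = FALSE)
    })
    ann <- res$ann
    asg <- res$asg
    dels <- ann$deletions
    asg$n_deletions <- nrow(dels)
    asg$deletion_offsets <- paste(dels$offset, collapse = ",")
    asg$deletion_lengths <- paste(dels$length, collapse = ",")
    asg$country <- smp$country
    anns[[i]] <- ann
    rows[[i]] <- asg
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[, c("sample_id", "country", "status", "name",
                 "matched_reference", "identity", "lineage", "structure",
                 "length", "fragment_count", "n_deletions",
                 "deletion_offsets", "deletion_lengths")]
  names(anns) <- samples$sample_id
  attr(out, "annotations") <- anns
  out
}

#' Append novel assignments to a catalog
#'
#' Builds catalog rows for the distinct novel haplotypes of a
#' [classify_dataset()] result so a re-classification finds them as known.
#'
#' @param catalog existing catalog data.frame.
#' @param assignments [classify_dataset()] output.
#' @param samples the sample table that was classified (for residues).
#' @return the extended catalog.
#' @export
extend_catalog <- function(catalog, assignments, samples) {
  nov <- assignments[assignments$status == "novel", , drop = FALSE]
  nov <- nov[!duplicated(nov$name), , drop = FALSE]
  if (nrow(nov) == 0L) return(catalog)
  res <- samples$residues[match(nov$sample_id, samples$sample_id)]
  rbind(catalog, data.frame(
    name = nov$name, lineage = nov$lineage, structure = nov$structure,
    length = nov$length, nfrag = nov$fragment_count, country = nov$country,
    sequence = res, accession = "", stringsAsFactors = FALSE))
}
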