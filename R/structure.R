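# Structural annotation of COI-COII intergenic amplicons: locate the tRNA-Leu
# stub, the P0/P element and the Q tandem run, render the structure label and
# call the evolutionary lineage. All coordinates are 0-based half-open; element
# deletions are reported in canonical-element coordinates.

unit_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE, type = "DNA")
}

# unit match/mismatch with an affine gap-opening cost: per-column gap cost is
# ~1 but opening is penalized so indel blocks stay contiguous (gap runs
# maximal), which is what deletion reporting relies on
unit_align <- function(pattern, subject, type) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = type, substitutionMatrix = unit_submat(),
    gapOpening = 5, gapExtension = 1)
}

# identity over aligned (non-gap) columns
aln_identity <- function(pa) {
  m <- Biostrings::nmatch(pa)
  mm <- Biostrings::nmismatch(pa)
  if (m + mm == 0L) 0 else m / (m + mm)
}

# best semi-global placement of `pattern` inside `subject` (pattern global,
# subject local); returns 1-based inclusive subject coords + identity
locate_element <- function(pattern, subject) {
  pa <- unit_align(pattern, subject, type = "global-local")
  rng <- pa@subject@range
  list(start = BiocGenerics::start(rng), end = BiocGenerics::end(rng),
       identity = aln_identity(pa))
}

# maximal gap runs of the observed sequence against a canonical element,
# end-free alignment with unit scores; offsets are 0-based positions in the
# canonical element
gap_runs_vs_canonical <- function(observed, canonical) {
  none <- data.frame(offset = integer(), length = integer())
  if (!nzchar(observed)) return(none)
  pa <- unit_align(observed, canonical, type = "overlap")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  canon0 <- BiocGenerics::start(pa@subject@range) - 1L  # clipped canonical prefix
  runs <- none
  cpos <- canon0
  run_start <- NA_integer_
  run_len <- 0L
  for (j in seq_along(pat)) {
    is_del <- pat[[j]] == "-" && sub[[j]] != "-"
    if (is_del) {
      if (run_len == 0L) run_start <- cpos
      run_len <- run_len + 1L
    } else if (run_len > 0L) {
      runs <- rbind(runs, data.frame(offset = run_start, length = run_len))
      run_len <- 0L
    }
    if (sub[[j]] != "-") cpos <- cpos + 1L
  }
  if (run_len > 0L) {
    runs <- rbind(runs, data.frame(offset = run_start, length = run_len))
  }
  runs
}

as_sample_row <- function(seq) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    return(as.list(seq))
  }
  if (is.character(seq) && length(seq) == 1L) {
    return(list(sample_id = "query", marker = "COICOII",
                residues = toupper(seq)))
  }
  stopifnot(is.list(seq), !is.null(seq$residues))
  seq
}

#' Annotate the P0/P/Q structure of a COI-COII amplicon
#'
#' Greedy left-to-right semi-global matching of the library elements: the
#' tRNA-Leu stub is located first, the Q tandem run is found and extended copy
#' by copy (adjacent copies, <5 bp slack), and the span between tRNA and the
#' first Q is classified as P0 or P by best identity (exact ties broken toward
#' the longer element, P0). Elements are accepted at identity >=
#' `lib$min_identity` over aligned columns, so an internal deletion does not
#' disqualify its element; deletions are reported in canonical-element
#' coordinates.
#'
#' @param seq a one-row sample table, a list with `sample_id`/`residues`, or a
#'   bare sequence string (marker COICOII assumed).
#' @param lib an [build_element_library()].
#' @return object of class `structure_annotation`: list with `sample_id`,
#'   `elements` (kind, start, end, identity; 0-based half-open), `q_count`,
#'   `structure_label`, `deletions` (element, offset, length) and
#'   `total_length`.
#' @export
annotate_structure <- function(seq, lib = build_element_library()) {
  s <- as_sample_row(seq)
  if (!is.null(s$marker) && !is.na(s$marker) && s$marker != "COICOII") {
    stop("structure annotation applies to COICOII amplicons, not ", s$marker)
  }
  x <- toupper(s$residues)
  L <- nchar(x)
  qlen <- nchar(lib$q)
  if (L <= qlen) stop("sequence shorter than one Q element")
  slack <- 5L

  trna <- locate_element(lib$trna_leu, x)
  has_trna <- trna$identity >= lib$min_identity
  search_from <- if (has_trna) trna$end + 1L else 1L

  # seed Q: best placement downstream of the tRNA
  if (search_from > L - 10L) stop("not a recognizable COI-COII intergenic amplicon")
  seed <- locate_element(lib$q, substr(x, search_from, L))
  if (seed$identity < lib$min_identity) {
    stop("not a recognizable COI-COII intergenic amplicon")
  }
  q_start <- search_from + seed$start - 1L
  q_end <- search_from + seed$end - 1L
  q_hits <- data.frame(start = q_start, end = q_end, identity = seed$identity)
  # extend left toward the tRNA
  repeat {
    w_end <- q_hits$start[1L] - 1L
    w_start <- max(search_from, w_end - qlen - slack + 1L)
    if (w_end - w_start + 1L < qlen - slack) break
    hit <- locate_element(lib$q, substr(x, w_start, w_end))
    if (hit$identity < lib$min_identity) break
    abs_end <- w_start + hit$end - 1L
    if (q_hits$start[1L] - abs_end - 1L > slack) break
    q_hits <- rbind(data.frame(start = w_start + hit$start - 1L, end = abs_end,
                               identity = hit$identity), q_hits)
  }
  # extend right toward the 3' flank
  repeat {
    w_start <- q_hits$end[nrow(q_hits)] + 1L
    w_end <- min(L, w_start + qlen + slack - 1L)
    if (w_end - w_start + 1L < qlen - slack) break
    hit <- locate_element(lib$q, substr(x, w_start, w_end))
    if (hit$identity < lib$min_identity) break
    if (hit$start - 1L > slack) break
    q_hits <- rbind(q_hits,
                    data.frame(start = w_start + hit$start - 1L,
                               end = w_start + hit$end - 1L,
                               identity = hit$identity))
  }

  # P-region between the tRNA end and the first Q copy
  p_kind <- NA_character_
  p_identity <- NA_real_
  p_start <- NA_integer_
  deletions <- data.frame(element = character(), offset = integer(),
                          length = integer(), stringsAsFactors = FALSE)
  if (has_trna) {
    region <- substr(x, trna$end + 1L, q_hits$start[1L] - 1L)
    if (nchar(region) >= 15L) {
      id_p0 <- aln_identity(unit_align(region, lib$p0, type = "global"))
      id_p <- aln_identity(unit_align(region, lib$p, type = "global"))
      best <- max(id_p0, id_p)
      if (best >= lib$min_identity) {
        p_kind <- if (id_p0 >= id_p) "P0" else "P"  # tie -> longer element
        p_identity <- best
        p_start <- trna$end + 1L
        canonical <- if (p_kind == "P0") lib$p0 else lib$p
        runs <- gap_runs_vs_canonical(region, canonical)
        if (nrow(runs)) {
          deletions <- cbind(element = p_kind, runs, stringsAsFactors = FALSE)
        }
      }
    }
  }

  elements <- rbind(
    if (has_trna) data.frame(kind = "TRNA", start = trna$start - 1L,
                             end = trna$end, identity = trna$identity),
    if (!is.na(p_kind)) data.frame(kind = p_kind, start = p_start - 1L,
                                   end = q_hits$start[1L] - 1L,
                                   identity = p_identity),
    data.frame(kind = "Q", start = q_hits$start - 1L, end = q_hits$end,
               identity = q_hits$identity))
  structure(list(
    sample_id = if (is.null(s$sample_id)) "query" else s$sample_id,
    elements = elements,
    q_count = nrow(q_hits),
    structure_label = render_structure_label(identical(p_kind, "P0"),
                                             identical(p_kind, "P"),
                                             nrow(q_hits)),
    deletions = deletions,
    total_length = L), class = "structure_annotation")
}

#' @export
print.structure_annotation <- function(x, ...) {
  cat(sprintf("<%s> %s, %d bp, %d deletion(s)\n", x$sample_id,
              x$structure_label, x$total_length, nrow(x$deletions)))
  print(x$elements)
  invisible(x)
}

#' Detect internal deletions in the P0 element
#'
#' Re-aligns the annotated P0 span against the canonical P0 (end-free, unit
#' scores) and reports maximal gap runs of the observed sequence as deletions.
#'
#' @param ann a [annotate_structure()] result containing a P0 element.
#' @param lib the element library used for annotation.
#' @param seq the annotated sample (same forms as [annotate_structure()]).
#' @return data.frame with 0-based `offset` (in canonical P0 coordinates) and
#'   `length`; zero rows when the span aligns gap-free.
#' @export
detect_p0_deletion <- function(ann, lib, seq) {
  stopifnot(inherits(ann, "structure_annotation"))
  el <- ann$elements
  hit <- which(el$kind == "P0")
  if (length(hit) == 0L) stop("annotation has no P0 element")
  s <- as_sample_row(seq)
  span <- substr(toupper(s$residues), el$start[hit[1L]] + 1L, el$end[hit[1L]])
  gap_runs_vs_canonical(span, lib$p0)
}

#' Call the evolutionary lineage from a structure annotation
#'
#' African (A) if a P0 element is present (deletion-bearing P0 included),
#' West-Mediterranean (M) if the 54 bp P element is present without P0,
#' North-Mediterranean (C) if only Q elements are found; unknown otherwise.
#'
#' @param ann a [annotate_structure()] result.
#' @return list of class `lineage_call` with `lineage` and `evidence`.
#' @export
call_lineage <- function(ann) {
  stopifnot(inherits(ann, "structure_annotation"))
  kinds <- ann$elements$kind
  out <- if ("P0" %in% kinds) {
    list(lineage = "A", evidence = "P0 element present (68 bp class)")
  } else if ("P" %in% kinds) {
    list(lineage = "M", evidence = "P element present (54 bp class), no P0")
  } else if (sum(kinds == "Q") >= 1L) {
    list(lineage = "C", evidence = "Q element(s) only, no P-type element")
  } else {
    list(lineage = "unknown", evidence = "no diagnostic element found")
  }
  structure(out, class = "lineage_call")
}
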