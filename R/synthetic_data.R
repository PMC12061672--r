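# Synthetic COI-COII amplicons (and coding fragments) with known planted truth.
# Canonical element strings are pseudo-random, seeded -- internally consistent,
# deliberately not copied from any real accession.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# all 0-based start positions of `site` in `s` (overlapping occurrences included)
site_starts0 <- function(s, site) {
  L <- nchar(s)
  k <- nchar(site)
  if (L < k) return(integer())
  starts <- seq_len(L - k + 1L)
  hits <- vapply(starts, function(i) substr(s, i, i + k - 1L) == site, logical(1L))
  starts[hits] - 1L
}

# destroy every occurrence of `site` except those starting inside `keep0`
# (0-based starts), by flipping the middle base of the offending occurrence
scrub_site <- function(s, site, keep0 = integer()) {
  k <- nchar(site)
  repeat {
    st <- setdiff(site_starts0(s, site), keep0)
    if (length(st) == 0L) return(s)
    pos <- st[[1L]] + (k %/% 2L)  # 0-based position inside the occurrence
    cur <- substr(s, pos + 1L, pos + 1L)
    substr(s, pos + 1L, pos + 1L) <- setdiff(DNA_BASES, cur)[[1L]]
  }
}

plant_site <- function(s, site, offset0) {
  stopifnot(offset0 >= 0L, offset0 + nchar(site) <= nchar(s))
  substr(s, offset0 + 1L, offset0 + nchar(site)) <- site
  s
}

#' Build the canonical element library
#'
#' Generates seeded pseudo-random canonical strings for the COI-COII
#' intergenic elements: P0 (68 bp, diagnostic of the African A lineage),
#' P (54 bp, diagnostic of the West-Mediterranean M lineage, constructed as a
#' suffix variant of P0 so P0-vs-P discrimination is non-trivial), the Q
#' repeat unit, a tRNA-Leu stub, and 5'/3' flank stubs standing in for the
#' COI/COII gene ends captured by the amplification primers. DraI sites
#' (TTTAAA) are planted at fixed offsets (two in the 5' flank, one in P0 at
#' offset 45 -- downstream of the classic 18 bp deletion window -- and one in
#' each Q copy) and scrubbed everywhere else, so a full P0Q2 amplicon digests
#' into 6 fragments.
#'
#' @param seed integer RNG seed; same seed, identical strings.
#' @param q_length Q repeat length in bp. 196 by default so that
#'   flank5 + tRNA + P0 + 2Q + flank3 = 838 bp, the modal length of African
#'   P0Q2 amplicons (observed envelope 818-839 bp).
#' @param trna_length,flank5_length,flank3_length stub lengths in bp.
#' @param min_identity per-element acceptance identity used downstream.
#' @param site restriction recognition site planted/scrubbed.
#' @return object of class `element_library`: list with canonical strings
#'   `p0`, `p`, `q`, `trna_leu`, `flank5`, `flank3` plus `min_identity` and
#'   `site`.
#' @export
build_element_library <- function(seed = 1L, q_length = 196L,
                                  trna_length = 65L, flank5_length = 193L,
                                  flank3_length = 120L, min_identity = 0.80,
                                  site = "TTTAAA") {
  stopifnot(q_length > 20L, trna_length > 20L,
            flank5_length > 130L, flank3_length > 20L)
  set.seed(seed)
  p0 <- scrub_site(random_dna(68L), site)
  p0 <- plant_site(p0, site, 45L)
  p0 <- scrub_site(p0, site, keep0 = 45L)
  # P: suffix of P0 (positions 15..68, 54 bp) with 6 substitutions outside the
  # planted DraI site (p0 offsets 45..50 -> p offsets 31..36)
  p <- substr(p0, 15L, 68L)
  forbidden <- 32:37  # 1-based positions of the site inside p
  subs <- sample(setdiff(seq_len(54L), forbidden), 6L)
  for (i in subs) {
    cur <- substr(p, i, i)
    substr(p, i, i) <- setdiff(DNA_BASES, cur)[[1L]]
  }
  p <- scrub_site(p, site, keep0 = 31L)
  q <- scrub_site(random_dna(q_length), site)
  q <- plant_site(q, site, 100L)
  q <- scrub_site(q, site, keep0 = 100L)
  trna <- scrub_site(random_dna(trna_length), site)
  flank5 <- scrub_site(random_dna(flank5_length), site)
  flank5 <- plant_site(flank5, site, 30L)
  flank5 <- plant_site(flank5, site, 120L)
  flank5 <- scrub_site(flank5, site, keep0 = c(30L, 120L))
  flank3 <- scrub_site(random_dna(flank3_length), site)
  structure(list(p0 = p0, p = p, q = q, trna_leu = trna,
                 flank5 = flank5, flank3 = flank3,
                 min_identity = min_identity, site = site),
            class = "element_library")
}

#' Simulation configuration
#'
#' @param seed integer RNG seed.
#' @param n_samples number of samples; must equal `sum(haplotype_spectrum)`.
#' @param structure structure label(s), e.g. `"P0Q2"`; one per haplotype class
#'   (recycled). Members of a class are byte-identical, so structure is a
#'   class property.
#' @param snp_rate substitutions per site planted per haplotype class.
#' @param haplotype_spectrum integer class sizes summing to `n_samples`.
#' @param p0_deletion_prob per-class probability of an internal P0 deletion
#'   (only applies to classes whose structure contains P0).
#' @param deletion_classes explicit class indices carrying the deletion
#'   (overrides `p0_deletion_prob` for those classes).
#' @param deletion_length deletion length in bp (default 18, the classic
#'   East-African P0 deletion).
#' @param deletion_offset fixed 0-based offset of the deletion inside the
#'   canonical P0 (default 20); set `deletion_uniform = TRUE` for uniform
#'   placement instead.
#' @param deletion_uniform place each deletion uniformly inside P0.
#' @param within_class_snp_rate extra per-sample substitution rate; 0 by
#'   default so haplotype counts are exact.
#' @param countries ISO alpha-3 codes, recycled over samples.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_samples = 15L, structure = "P0Q2",
                              snp_rate = 0.005, haplotype_spectrum = NULL,
                              p0_deletion_prob = 0, deletion_classes = integer(),
                              deletion_length = 18L, deletion_offset = 20L,
                              deletion_uniform = FALSE,
                              within_class_snp_rate = 0,
                              countries = "SAU") {
  if (is.null(haplotype_spectrum)) haplotype_spectrum <- rep(1L, n_samples)
  haplotype_spectrum <- as.integer(haplotype_spectrum)
  if (any(haplotype_spectrum < 1L)) stop("haplotype_spectrum entries must be >= 1")
  if (sum(haplotype_spectrum) != n_samples) {
    stop("haplotype_spectrum must sum to n_samples (",
         sum(haplotype_spectrum), " != ", n_samples, ")")
  }
  if (snp_rate < 0 || within_class_snp_rate < 0) stop("snp rates must be >= 0")
  if (p0_deletion_prob < 0 || p0_deletion_prob > 1) {
    stop("p0_deletion_prob must be in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 structure = toupper(structure), snp_rate = snp_rate,
                 haplotype_spectrum = haplotype_spectrum,
                 p0_deletion_prob = p0_deletion_prob,
                 deletion_classes = as.integer(deletion_classes),
                 deletion_length = as.integer(deletion_length),
                 deletion_offset = as.integer(deletion_offset),
                 deletion_uniform = isTRUE(deletion_uniform),
                 within_class_snp_rate = within_class_snp_rate,
                 countries = toupper(countries)),
            class = "simulation_config")
}

#' Parse a structure label
#' @param label e.g. `"P0Q2"`, `"PQ1"`, `"Q3"`.
#' @return list with logicals `p0`, `p` and integer `q`.
#' @export
parse_structure_label <- function(label) {
  m <- regmatches(label, regexec("^(P0|P)?Q([0-9]+)$", toupper(label)))[[1L]]
  if (length(m) == 0L) stop("unrecognized structure label: ", label)
  list(p0 = identical(m[[2L]], "P0"), p = identical(m[[2L]], "P"),
       q = as.integer(m[[3L]]))
}

#' Render a structure label
#' @param p0,p logical element presence flags.
#' @param q integer Q tandem copy count.
#' @return label string such as `"P0Q2"`.
#' @export
render_structure_label <- function(p0, p, q) {
  paste0(if (p0) "P0" else if (p) "P" else "", "Q", q)
}

structure_lineage <- function(label) {
  st <- parse_structure_label(label)
  if (st$p0) "A" else if (st$p) "M" else "C"
}

apply_snps <- function(s, pos, alt) {
  for (i in seq_along(pos)) substr(s, pos[[i]], pos[[i]]) <- alt[[i]]
  s
}

draw_snps <- function(s, rate) {
  L <- nchar(s)
  n <- stats::rbinom(1L, L, rate)
  if (n == 0L) return(data.frame(pos = integer(), ref = character(),
                                 alt = character(), stringsAsFactors = FALSE))
  pos <- sort(sample.int(L, n))
  ref <- vapply(pos, function(i) substr(s, i, i), character(1L))
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1L))
  data.frame(pos = pos, ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Simulate a COI-COII amplicon dataset with known truth
#'
#' Each haplotype class is the canonical concatenation
#' `flank5 + tRNA-Leu + (P0|P|nothing) + Q x q + flank3` for its structure,
#' with a class-specific set of planted substitutions (classes are guaranteed
#' pairwise distinct) and, where configured, an internal P0 deletion. Members
#' of a class are byte-identical unless `within_class_snp_rate > 0`. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param lib an [build_element_library()] result.
#' @return list with `samples` (sample table), `truth` (one row per sample:
#'   class, structure, lineage, length, deletion fields), `elements`
#'   (per-sample element coordinates, 0-based half-open) and `snps`
#'   (per-sample planted substitutions, 1-based positions).
#' @export
simulate_dataset <- function(config, lib = build_element_library()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(lib, "element_library"))
  set.seed(config$seed)
  k <- length(config$haplotype_spectrum)
  labels <- rep_len(config$structure, k)
  del_classes <- logical(k)
  del_classes[config$deletion_classes] <- TRUE
  if (config$p0_deletion_prob > 0) {
    del_classes <- del_classes | (stats::runif(k) < config$p0_deletion_prob)
  }

  class_seq <- character(k)
  class_snps <- vector("list", k)
  class_elems <- vector("list", k)
  class_del <- vector("list", k)
  for (ci in seq_len(k)) {
    st <- parse_structure_label(labels[[ci]])
    parts <- c(list(FLANK5 = lib$flank5, TRNA = lib$trna_leu),
               if (st$p0) list(P0 = lib$p0) else if (st$p) list(P = lib$p),
               stats::setNames(rep(list(lib$q), st$q), rep("Q", st$q)),
               list(FLANK3 = lib$flank3))
    has_del <- del_classes[[ci]] && st$p0
    del <- NULL
    if (has_del) {
      off <- if (config$deletion_uniform) {
        sample.int(nchar(lib$p0) - config$deletion_length, 1L) - 1L
      } else config$deletion_offset
      stopifnot(off + config$deletion_length <= nchar(lib$p0))
      parts$P0 <- paste0(substr(parts$P0, 1L, off),
                         substr(parts$P0, off + config$deletion_length + 1L,
                                nchar(lib$p0)))
      del <- data.frame(element = "P0", offset = off,
                        length = config$deletion_length,
                        stringsAsFactors = FALSE)
    }
    widths <- vapply(parts, nchar, integer(1L))
    ends <- cumsum(widths)
    elems <- data.frame(element = names(parts),
                        start = c(0L, ends[-length(ends)]), end = unname(ends),
                        stringsAsFactors = FALSE)
    base_seq <- paste(unlist(parts), collapse = "")
    for (attempt in seq_len(200L)) {
      snps <- draw_snps(base_seq, config$snp_rate)
      cand <- apply_snps(base_seq, snps$pos, snps$alt)
      if (!cand %in% class_seq[seq_len(ci - 1L)]) break
      if (attempt == 200L) stop("could not make haplotype class ", ci,
                                " distinct; raise snp_rate")
    }
    class_seq[[ci]] <- cand
    class_snps[[ci]] <- snps
    class_elems[[ci]] <- elems
    class_del[[ci]] <- del
  }

  cls <- rep(seq_len(k), times = config$haplotype_spectrum)
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  residues <- class_seq[cls]
  snps_out <- vector("list", n)
  for (i in seq_len(n)) {
    snps <- class_snps[[cls[[i]]]]
    if (config$within_class_snp_rate > 0) {
      extra <- draw_snps(residues[[i]], config$within_class_snp_rate)
      residues[[i]] <- apply_snps(residues[[i]], extra$pos, extra$alt)
      snps <- rbind(snps, extra)
    }
    snps_out[i] <- list(if (nrow(snps)) cbind(sample_id = ids[[i]], snps,
                                              stringsAsFactors = FALSE))
  }
  truth <- data.frame(
    sample_id = ids,
    class = cls,
    structure = labels[cls],
    lineage = vapply(labels[cls], structure_lineage, character(1L)),
    length = nchar(residues),
    has_deletion = vapply(class_del[cls], Negate(is.null), logical(1L)),
    deletion_offset = vapply(class_del[cls], function(d)
      if (is.null(d)) NA_integer_ else d$offset, integer(1L)),
    deletion_length = vapply(class_del[cls], function(d)
      if (is.null(d)) NA_integer_ else d$length, integer(1L)),
    stringsAsFactors = FALSE)
  elements <- do.call(rbind, c(lapply(seq_len(n), function(i)
    cbind(sample_id = ids[[i]], class_elems[[cls[[i]]]])),
    list(make.row.names = FALSE)))
  samples <- sample_table(ids, residues, marker = "COICOII",
                          country = rep_len(config$countries, n))
  list(samples = samples, truth = truth, elements = elements,
       snps = do.call(rbind, c(snps_out, list(make.row.names = FALSE))))
}

#' Simulate identical-by-class coding gene fragments
#'
#' Emulates short Sanger fragments of coding markers (cyt b, COI): one random
#' reference sequence, haplotype classes separated by planted substitutions at
#' distinct sites, class sizes from a frequency spectrum. Class 1 is the
#' unmutated reference.
#'
#' @param seed RNG seed.
#' @param length fragment length in bp.
#' @param spectrum integer class sizes; samples are `sum(spectrum)`.
#' @param marker marker code (`"CYTB"` or `"COI"`).
#' @param snps_per_class substitutions distinguishing each non-reference class.
#' @param countries recycled ISO alpha-3 codes.
#' @return list with `samples` (sample table), `truth` (sample_id, class) and
#'   `reference` (the class-1 sequence).
#' @export
simulate_coding_fragments <- function(seed = 1L, length = 359L,
                                      spectrum = rep(1L, 10L),
                                      marker = "CYTB", snps_per_class = 1L,
                                      countries = "SAU") {
  set.seed(seed)
  spectrum <- as.integer(spectrum)
  k <- length(spectrum)
  ref <- random_dna(length)
  need <- (k - 1L) * snps_per_class
  if (need > length) stop("fragment too short for ", k, " distinct classes")
  pool <- sample.int(length, need)
  class_seq <- character(k)
  class_seq[[1L]] <- ref
  for (ci in seq_len(k)[-1L]) {
    pos <- pool[((ci - 2L) * snps_per_class + 1L):((ci - 1L) * snps_per_class)]
    s <- ref
    for (p in pos) {
      substr(s, p, p) <- sample(setdiff(DNA_BASES, substr(ref, p, p)), 1L)
    }
    class_seq[[ci]] <- s
  }
  cls <- rep(seq_len(k), times = spectrum)
  n <- sum(spectrum)
  ids <- sprintf("%s%03d", tolower(marker), seq_len(n))
  samples <- sample_table(ids, class_seq[cls], marker = marker,
                          country = rep_len(toupper(countries), n))
  list(samples = samples,
       truth = data.frame(sample_id = ids, class = cls,
                          stringsAsFactors = FALSE),
       reference = ref)
}

#' Simulate a neutral-coalescent alignment (infinite sites)
#'
#' Standard Kingman coalescent for `n` tips with mutations dropped on branches
#' at rate `theta/2` per unit (2N generations) of branch length; each mutation
#' occupies its own alignment column (infinite-sites). Used to check that
#' Tajima's D behaves neutrally under the model it assumes.
#'
#' @param n number of sequences.
#' @param theta population-scaled mutation rate per locus.
#' @param length alignment length in bp (columns without mutations are
#'   monomorphic `"A"`).
#' @return character vector of `n` equal-length sequences.
#' @export
simulate_neutral_alignment <- function(n, theta = 5, length = 1000L) {
  carriers <- list()          # tip sets, one per mutation
  active <- as.list(seq_len(n))
  while (length(active) > 1L) {
    kk <- length(active)
    t_k <- stats::rexp(1L, rate = kk * (kk - 1L) / 2)
    nmut <- stats::rpois(kk, theta / 2 * t_k)  # per active branch
    for (b in which(nmut > 0L)) {
      carriers <- c(carriers, rep(list(active[[b]]), nmut[[b]]))
    }
    pair <- sample.int(kk, 2L)
    merged <- c(active[[pair[[1L]]]], active[[pair[[2L]]]])
    active <- c(active[-pair], list(merged))
  }
  # drop mutations fixed in the whole sample (root-edge artifacts can't occur
  # here, but a carrier set of size n would be invisible anyway)
  carriers <- Filter(function(x) length(x) < n, carriers)
  S <- length(carriers)
  if (S > length) carriers <- carriers[seq_len(length)]
  mat <- matrix("A", nrow = n, ncol = length)
  if (S > 0L) {
    cols <- sample.int(length, min(S, length))
    for (j in seq_along(cols)) mat[carriers[[j]], cols[[j]]] <- "G"
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Write / read an element library as JSON
#'
#' @param lib an `element_library`.
#' @param path JSON file.
#' @return `read_element_library` returns an `element_library`.
#' @export
write_element_library <- function(lib, path) {
  stopifnot(inherits(lib, "element_library"))
  jsonlite::write_json(unclass(lib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_element_library
#' @export
read_element_library <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("p0", "p", "q", "trna_leu", "min_identity", "site") %in%
                names(x)))
  structure(x, class = "element_library")
}
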