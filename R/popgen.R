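# Exact-identity sequence grouping (SG/HG), haplotype and nucleotide
# diversity, Tajima's D with normal and beta p-values, per-site SNP reports.

#' Group byte-identical sequences
#'
#' Equivalence classes of identical trimmed residues (the survey-style
#' "sequence groups"/"haplotype groups"); group indices follow first
#' appearance.
#'
#' @param samples sample table, all of one marker.
#' @return list of class `group_partition`: `marker`, `groups` (group,
#'   sample_id), `sizes` (per group), `n_samples`, `n_groups`.
#' @export
group_identical <- function(samples) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L)
  if (length(unique(samples$marker)) > 1L) {
    stop("mixed markers: group sequences of one marker at a time")
  }
  key <- toupper(samples$residues)
  idx <- match(key, unique(key))
  groups <- data.frame(group = idx, sample_id = samples$sample_id,
                       stringsAsFactors = FALSE)
  sizes <- as.integer(table(factor(idx, levels = seq_len(max(idx)))))
  # partition check: disjoint by construction, covering by construction
  stopifnot(sum(sizes) == nrow(samples), all(sizes >= 1L))
  structure(list(marker = samples$marker[[1L]], groups = groups,
                 sizes = sizes, n_samples = nrow(samples),
                 n_groups = max(idx)),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("%d %s sequences in %d identical-sequence group(s); sizes: %s\n",
              x$n_samples, x$marker, x$n_groups,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Unbiased haplotype diversity
#'
#' H = (n/(n-1)) (1 - sum((s_i/n)^2)): the sample-size-corrected probability
#' that two randomly drawn samples carry different haplotypes.
#'
#' @param group_sizes integer haplotype class sizes (or a `group_partition`).
#' @return H in \[0, 1\].
#' @export
haplotype_diversity <- function(group_sizes) {
  if (inherits(group_sizes, "group_partition")) group_sizes <- group_sizes$sizes
  s <- as.numeric(group_sizes)
  if (any(s < 1)) stop("group sizes must be >= 1")
  n <- sum(s)
  if (n < 2) stop("haplotype diversity needs at least 2 samples")
  (n / (n - 1)) * (1 - sum((s / n)^2))
}

aln_matrix <- function(alignment) {
  if (is.data.frame(alignment)) alignment <- alignment$residues
  alignment <- toupper(alignment)
  L <- unique(nchar(alignment))
  if (length(L) != 1L) {
    stop("sequences have unequal lengths; align them first")
  }
  if (L < 1L) stop("alignment has zero columns")
  matrix(unlist(strsplit(alignment, "", fixed = TRUE), use.names = FALSE),
         nrow = length(alignment), byrow = TRUE)
}

#' Nucleotide diversity per site
#'
#' Mean over all sequence pairs of (differing columns / comparable columns).
#' Columns where either member of a pair carries a gap or ambiguity character
#' (anything outside A/C/G/T) are excluded from both the difference count and
#' the column count for that pair (pairwise deletion); indels therefore never
#' count as differences.
#'
#' @param alignment character vector of equal-length sequences (or a sample
#'   table).
#' @return pi per site.
#' @export
nucleotide_diversity <- function(alignment) {
  m <- aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("nucleotide diversity needs at least 2 sequences")
  valid <- matrix(m %in% DNA_BASES, nrow = n)
  acc <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      Lp <- sum(ok)
      if (Lp == 0L) next
      acc <- acc + sum(m[i, ok] != m[j, ok]) / Lp
      npairs <- npairs + 1L
    }
  }
  if (npairs == 0L) stop("no pair of sequences shares a comparable column")
  acc / npairs
}

# mean pairwise difference count and segregating sites over columns where all
# sequences are unambiguous A/C/G/T (complete deletion)
pairwise_counts <- function(m) {
  keep <- apply(matrix(m %in% DNA_BASES, nrow = nrow(m)), 2L, all)
  mm <- m[, keep, drop = FALSE]
  n <- nrow(mm)
  S <- sum(apply(mm, 2L, function(col) length(unique(col)) > 1L))
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) tot <- tot + sum(mm[i, ] != mm[j, ])
  }
  list(pi_total = tot / (n * (n - 1L) / 2), S = S, L = ncol(mm))
}

#' Tajima's D with normal and beta p-values
#'
#' Standardized difference between the mean-pairwise-difference and
#' segregating-sites estimators of the population mutation parameter,
#' computed over columns where every sequence is unambiguous A/C/G/T
#' (complete deletion; indel and ambiguity columns never contribute).
#' p-values are two-sided: `p_normal` from the standard normal, `p_beta` from
#' the rescaled beta approximation over \[D_min, D_max\] of the original
#' derivation.
#'
#' @param alignment character vector of equal-length sequences (or a sample
#'   table).
#' @return list of class `tajima_d`: `n`, `S`, `pi_total` (mean pairwise
#'   differences, a count, not per site), `D`, `p_normal`, `p_beta`, and
#'   logical `defined` (`FALSE` with D = NA and p = 1 when S = 0).
#' @export
tajimas_d <- function(alignment) {
  m <- aln_matrix(alignment)
  n <- nrow(m)
  if (n < 4L) stop("Tajima's D needs at least 4 sequences")
  pc <- pairwise_counts(m)
  if (pc$S == 0L) {
    return(structure(list(n = n, S = 0L, pi_total = 0, D = NA_real_,
                          p_normal = 1, p_beta = 1, defined = FALSE),
                     class = "tajima_d"))
  }
  k <- tajima_constants(n)
  S <- pc$S
  D <- (pc$pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  p_normal <- 2 * stats::pnorm(-abs(D))
  # beta approximation: D rescaled to [Dmin, Dmax], mean 0, variance 1
  u <- (D - k$Dmin) / (k$Dmax - k$Dmin)
  u <- min(max(u, 0), 1)
  pb <- stats::pbeta(u, k$beta_b, k$beta_a)
  p_beta <- min(1, 2 * min(pb, 1 - pb))
  structure(list(n = n, S = S, pi_total = pc$pi_total, D = D,
                 p_normal = p_normal, p_beta = p_beta, defined = TRUE),
            class = "tajima_d")
}

# the standard a1..e2 constants plus the beta-approximation bounds and shapes
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  Dmin <- (2 / n - 1 / a1) / sqrt(e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
  tmp <- 1 + Dmin * Dmax
  beta_a <- -tmp * Dmax / (Dmax - Dmin)
  beta_b <- tmp * Dmin / (Dmax - Dmin)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1,
       e2 = e2, Dmin = Dmin, Dmax = Dmax, beta_a = beta_a, beta_b = beta_b)
}

#' @export
print.tajima_d <- function(x, ...) {
  if (!x$defined) {
    cat("Tajima's D undefined (no segregating sites); p = 1\n")
  } else {
    cat(sprintf("Tajima's D = %.4f (n = %d, S = %d); p_normal = %.3f, p_beta = %.3f\n",
                x$D, x$n, x$S, x$p_normal, x$p_beta))
  }
  invisible(x)
}

#' Combined diversity statistics for one marker
#'
#' @param samples sample table of aligned, equal-length sequences.
#' @return list of class `diversity_stats`: n, h (haplotype count), H
#'   (unbiased haplotype diversity), pi (per site), S, D, p_normal, p_beta.
#' @export
diversity_stats <- function(samples) {
  part <- group_identical(samples)
  td <- tajimas_d(samples)
  structure(list(n = part$n_samples, h = part$n_groups,
                 H = haplotype_diversity(part$sizes),
                 pi = nucleotide_diversity(samples),
                 S = td$S, D = td$D,
                 p_normal = td$p_normal, p_beta = td$p_beta),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("n = %d, haplotypes = %d, H = %.3f, pi = %.4f, S = %d\n",
              x$n, x$h, x$H, x$pi, x$S))
  cat(sprintf("Tajima's D = %s (p_normal = %.3f, p_beta = %.3f)\n",
              if (is.na(x$D)) "undefined" else sprintf("%.3f", x$D),
              x$p_normal, x$p_beta))
  invisible(x)
}

#' Report substitutions of a sample against a reference
#'
#' @param sample,reference equal-length residue strings (or one-row sample
#'   tables).
#' @return data.frame with 1-based `position`, `ref` and `alt` bases; only
#'   columns where both characters are A/C/G/T and differ are reported.
#' @export
report_snps <- function(sample, reference) {
  s <- toupper(as_sample_row(sample)$residues)
  r <- toupper(as_sample_row(reference)$residues)
  if (nchar(s) != nchar(r)) stop("sample and reference have unequal lengths")
  sv <- strsplit(s, "", fixed = TRUE)[[1L]]
  rv <- strsplit(r, "", fixed = TRUE)[[1L]]
  hit <- which(sv != rv & sv %in% DNA_BASES & rv %in% DNA_BASES)
  data.frame(position = hit, ref = rv[hit], alt = sv[hit],
             stringsAsFactors = FALSE)
}
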