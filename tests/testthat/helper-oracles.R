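# Independent oracles: deliberately written with different primitives than
# the implementation they check.

# two-pointer scan for end-trimming
oracle_trim <- function(x) {
  ch <- strsplit(toupper(x), "")[[1L]]
  lo <- 1L
  hi <- length(ch)
  while (lo <= hi && !ch[lo] %in% c("A", "C", "G", "T")) lo <- lo + 1L
  while (hi >= lo && !ch[hi] %in% c("A", "C", "G", "T")) hi <- hi - 1L
  if (lo > hi) stop("all ambiguous")
  paste(ch[lo:hi], collapse = "")
}

# position-by-position site scan via regex lookahead (overlapping hits)
oracle_digest <- function(s, site = "TTTAAA", cut_offset = 3L) {
  hits <- gregexpr(paste0("(?=", site, ")"), s, perl = TRUE)[[1L]]
  starts <- if (hits[1L] == -1L) integer() else as.integer(hits) - 1L
  cuts <- starts + cut_offset
  cuts <- cuts[cuts > 0L & cuts < nchar(s)]
  diff(c(0L, cuts, nchar(s)))
}

# all-pairs per-site diversity with explicit loops over characters
oracle_pi <- function(seqs) {
  mats <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- nrow(mats)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 0L
    l <- 0L
    for (k in seq_len(ncol(mats))) {
      a <- mats[i, k]
      b <- mats[j, k]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        l <- l + 1L
        if (a != b) d <- d + 1L
      }
    }
    vals <- c(vals, d / l)
  }
  mean(vals)
}

# Tajima's D rebuilt on ape's distance and segregating-site machinery
oracle_tajima <- function(seqs) {
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  n <- length(seqs)
  pi_total <- mean(ape::dist.dna(bin, model = "N", as.matrix = FALSE))
  S <- length(ape::seg.sites(bin))
  if (S == 0L) return(list(D = NA_real_, p_beta = 1))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  Dmin <- (2 / n - 1 / a1) / sqrt(e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
  aa <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
  bb <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
  u <- (D - Dmin) / (Dmax - Dmin)
  pb <- pbeta(min(max(u, 0), 1), bb, aa)
  list(D = D, p_beta = min(1, 2 * min(pb, 1 - pb)))
}

# column-scan distance: substitutions plus one change per indel block
oracle_changes <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  subs <- 0L
  blocks <- 0L
  in_block <- FALSE
  for (k in seq_along(av)) {
    ga <- av[k] == "-"
    gb <- bv[k] == "-"
    if (ga != gb) {
      if (!in_block) blocks <- blocks + 1L
      in_block <- TRUE
    } else {
      in_block <- FALSE
      if (!ga && av[k] != bv[k]) subs <- subs + 1L
    }
  }
  subs + blocks
}

# exhaustive minimum spanning-tree weight by Pruefer enumeration (n <= 7)
prufer_weight <- function(code, dmat) {
  n <- nrow(dmat)
  degree <- tabulate(code, n) + 1L
  w <- 0
  for (v in code) {
    leaf <- which.min(ifelse(degree == 1L, seq_len(n), Inf))
    w <- w + dmat[leaf, v]
    degree[leaf] <- 0L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  w + dmat[last[1L], last[2L]]
}

oracle_mst_weight <- function(dmat) {
  n <- nrow(dmat)
  if (n == 2L) return(dmat[1L, 2L])
  codes <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  min(apply(codes, 1L, prufer_weight, dmat = dmat))
}

random_alignment <- function(n, L) {
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  vapply(seq_len(n), function(i) {
    s <- ref
    k <- sample.int(max(1L, L %/% 10L), 1L)
    pos <- sample.int(L, k)
    s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(s, collapse = "")
  }, character(1L))
}

random_distance_matrix <- function(n, max_w = 12L) {
  m <- matrix(0L, n, n)
  w <- sample.int(max_w, n * (n - 1L) / 2L, replace = TRUE)
  m[upper.tri(m)] <- w
  m + t(m)
}

# the default mimic of the published 15-sample study design: 13 haplotype
# classes (two doubletons), three singleton classes carrying the 18 bp P0
# deletion, catalog covering 5 classes (one of them a doubleton)
table3_mimic <- function(seed = 11L, lib = build_element_library()) {
  countries <- c("SAU", "SAU", "OMN", "OMN", "ETH", "ETH", "YEM", "ETH",
                 "JOR", "SAU", "SAU", "SAU", "YEM", "YEM", "OMN")
  cfg <- simulation_config(
    seed = seed, n_samples = 15L, structure = "P0Q2",
    haplotype_spectrum = c(2L, 2L, rep(1L, 11L)),
    deletion_classes = c(5L, 6L, 7L), snp_rate = 0.005,
    countries = countries)
  sim <- simulate_dataset(cfg, lib)
  known_classes <- c(1L, 8L, 9L, 10L, 11L)
  reps <- sim$samples$residues[match(known_classes, sim$truth$class)]
  nfrag <- vapply(reps, function(r) digest(r)$fragment_count, integer(1L))
  catalog <- data.frame(
    name = c("KSA4e", "KSA6b", "KSA6d", "KSA4f", "A1-837-6-USA"),
    lineage = "A", structure = "P0Q2", length = nchar(reps),
    nfrag = nfrag, country = "SAU", sequence = reps,
    accession = sprintf("SYN%04d", seq_along(reps)),
    stringsAsFactors = FALSE)
  list(sim = sim, catalog = catalog)
}
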