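#!/usr/bin/env Rscript
# Stage 1: simulate the study-design dataset.
#
# Builds the canonical element library (seed 1) and a 15-sample P0Q2 amplicon
# set mirroring the published survey design: 13 haplotype classes (two
# doubletons), three singleton classes carrying the 18 bp P0 deletion, and a
# 5-entry reference catalog covering one doubleton class and four singletons.
# Also simulates the coding-gene sets used for sequence grouping: 44 cyt b
# fragments (359 bp, 11 classes) and 15 COI fragments (218 bp, 5 classes).

suppressPackageStartupMessages(library(dmcc))
outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

lib <- build_element_library(seed = 1L)
write_element_library(lib, file.path(outdir, "library.json"))

countries <- c("SAU", "SAU", "OMN", "OMN", "ETH", "ETH", "YEM", "ETH",
               "JOR", "SAU", "SAU", "SAU", "YEM", "YEM", "OMN")
cfg <- simulation_config(seed = 11L, n_samples = 15L, structure = "P0Q2",
                         haplotype_spectrum = c(2L, 2L, rep(1L, 11L)),
                         deletion_classes = c(5L, 6L, 7L), snp_rate = 0.005,
                         countries = countries)
sim <- simulate_dataset(cfg, lib)
write_fasta(sim$samples, file.path(outdir, "coicoii.fa"))
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$samples[, c("sample_id", "country", "region", "marker")],
            file.path(outdir, "metadata.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# catalog: five classes "already published", named in the style of known
# African haplotypes (sequences are synthetic; labels are labels only)
known_classes <- c(1L, 8L, 9L, 10L, 11L)
reps <- sim$samples$residues[match(known_classes, sim$truth$class)]
catalog <- data.frame(
  name = c("KSA4e", "KSA6b", "KSA6d", "KSA4f", "A1-837-6-USA"),
  lineage = "A", structure = "P0Q2", length = nchar(reps),
  nfrag = vapply(reps, function(r) digest(r)$fragment_count, integer(1L)),
  country = "SAU", sequence = reps,
  accession = sprintf("SYN%04d", seq_along(reps)))
write_catalog(catalog, file.path(outdir, "catalog.tsv"))

cytb <- simulate_coding_fragments(seed = 21L, length = 359L,
                                  spectrum = c(16, 9, 3, 2, 2, 2, 2, 2, 2, 2, 2),
                                  marker = "CYTB")
write_fasta(cytb$samples, file.path(outdir, "cytb.fa"))
coi <- simulate_coding_fragments(seed = 22L, length = 218L,
                                 spectrum = c(11, 1, 1, 1, 1), marker = "COI")
write_fasta(coi$samples, file.path(outdir, "coi.fa"))

cat(sprintf("simulated %d COI-COII amplicons (%d haplotype classes, %d deletion carriers)\n",
            nrow(sim$samples), length(unique(sim$truth$class)),
            sum(sim$truth$has_deletion)))
cat(sprintf("amplicon lengths: %s bp\n",
            paste(sort(unique(sim$truth$length)), collapse = ", ")))
cat(sprintf("coding sets: %d cyt b (11 classes), %d COI (5 classes)\n",
            nrow(cytb$samples), nrow(coi$samples)))
cat("outputs in", outdir, "\n")
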