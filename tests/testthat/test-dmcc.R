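lib <- build_element_library(1L)

test_that("digest follows the DraI definition on worked examples", {
  d <- digest("AAATTTAAACCC")
  expect_equal(d$cut_positions, 6L)
  expect_equal(d$fragment_lengths, c(6L, 6L))
  expect_equal(d$fragment_count, 2L)
  # no site -> one fragment spanning the amplicon
  d0 <- digest("ACGTACGTACGT")
  expect_equal(d0$fragment_lengths, 12L)
  # overlapping occurrences each cut (general scanner)
  d1 <- digest("AAAAA", site = "AA", cut_offset = 1L)
  expect_equal(d1$cut_positions, c(1L, 2L, 3L, 4L))
  expect_error(digest("ACGT", site = "TTN"), "A/C/G/T")
  expect_error(digest("ACGT", site = ""), "non-empty")
})

test_that("digest agrees with the brute-force scan and conserves length", {
  set.seed(23)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(50:400, 1L), TRUE),
               collapse = "")
    d <- digest(s)
    expect_equal(d$fragment_lengths, oracle_digest(s))
    expect_equal(sum(d$fragment_lengths), nchar(s))
    expect_equal(d$fragment_count, length(d$cut_positions) + 1L)
    expect_true(all(diff(d$cut_positions) > 0L))
  }
})

test_that("novel-haplotype names follow the universal grammar", {
  expect_equal(name_novel_haplotype("A", 1, 838, 6, "OMN"), "A1-838-6-OMN")
  expect_equal(name_novel_haplotype("M", 2, 820, 5, "eth"), "M2-820-5-ETH")
  expect_error(name_novel_haplotype("A", 1, 838, 6, "OM"), "alpha-3")
  expect_error(name_novel_haplotype("A", 1, 838, 6, "O1N"), "alpha-3")
  expect_error(name_novel_haplotype("A", 0, 838, 6, "OMN"), "serial")
})

test_that("haplotype assignment separates known and novel correctly", {
  mimic <- table3_mimic(seed = 11L, lib = lib)
  sim <- mimic$sim
  catalog <- mimic$catalog
  smp <- sim$samples[1L, ]  # class 1 == catalog entry KSA4e
  ann <- annotate_structure(smp, lib)
  prof <- digest(smp)
  lin <- call_lineage(ann)
  asg <- assign_haplotype(smp, ann, prof, catalog, lin)
  expect_equal(asg$status, "known")
  expect_equal(asg$name, "KSA4e")
  expect_equal(asg$identity, 1.0)

  # case-insensitive exact match
  smp_lc <- smp
  smp_lc$residues <- tolower(smp$residues)
  smp_lc$residues <- toupper(smp_lc$residues)  # sample tables store uppercase
  cat_lc <- catalog
  cat_lc$sequence[1L] <- tolower(cat_lc$sequence[1L])
  expect_equal(assign_haplotype(smp_lc, ann, prof, cat_lc, lin)$status, "known")

  # one SNP away -> novel at identity ~ (L-1)/L
  smp1 <- smp
  substr(smp1$residues, 500L, 500L) <- "A"
  if (identical(smp1$residues, smp$residues)) {
    substr(smp1$residues, 500L, 500L) <- "C"
  }
  asg1 <- assign_haplotype(smp1, annotate_structure(smp1, lib), digest(smp1),
                           catalog, lin)
  expect_equal(asg1$status, "novel")
  expect_equal(asg1$matched_reference, "KSA4e")
  expect_equal(asg1$identity, (838 - 1) / 838, tolerance = 1e-12)

  # empty catalog -> novel with no nearest reference
  asg2 <- assign_haplotype(smp, ann, prof, empty_catalog(), lin)
  expect_equal(asg2$status, "novel")
  expect_equal(asg2$matched_reference, "")
  expect_true(is.na(asg2$identity))

  # reverse-complement submission still resolves to the reference
  smp_rc <- smp
  smp_rc$residues <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(smp$residues)))
  expect_equal(
    seq_identity(smp_rc$residues, catalog$sequence[[1L]])$revcomp, TRUE)
})

test_that("classify_dataset reproduces the study-design counts", {
  mimic <- table3_mimic(seed = 11L, lib = lib)
  res <- classify_dataset(mimic$sim$samples, mimic$catalog, lib)
  expect_equal(length(unique(res$name)), 13L)
  expect_equal(length(unique(res$name[res$status == "novel"])), 8L)
  expect_equal(length(unique(res$name[res$status == "known"])), 5L)
  expect_equal(sum(res$n_deletions > 0L), 3L)
  # byte-identical samples share one name and status
  cls1 <- res[mimic$sim$truth$class == 2L, ]
  expect_equal(length(unique(cls1$name)), 1L)
  expect_equal(length(unique(cls1$status)), 1L)
  # serials restart per (lineage, country): names are unique overall
  novel <- unique(res$name[res$status == "novel"])
  expect_false(any(duplicated(novel)))
})

test_that("classification is deterministic and order-stable in substance", {
  mimic <- table3_mimic(seed = 13L, lib = lib)
  res <- classify_dataset(mimic$sim$samples, mimic$catalog, lib)
  res2 <- classify_dataset(mimic$sim$samples, mimic$catalog, lib)
  expect_identical(res$name, res2$name)

  perm <- c(15:1)
  resp <- classify_dataset(mimic$sim$samples[perm, ], mimic$catalog, lib)
  m <- match(res$sample_id, resp$sample_id)
  # statuses and the partition of samples into shared names survive any
  # input order; only novel serial digits may change
  expect_equal(res$status, resp$status[m])
  expect_equal(sub("^[A-Z]+[0-9]+", "", res$name),
               sub("^[A-Z]+[0-9]+", "", resp$name[m]))
  same_partition <- function(x) match(x, unique(x))
  expect_equal(same_partition(res$name), same_partition(resp$name[m]))
})

test_that("appending novel haplotypes to the catalog closes the loop", {
  mimic <- table3_mimic(seed = 19L, lib = lib)
  res <- classify_dataset(mimic$sim$samples, mimic$catalog, lib)
  cat2 <- extend_catalog(mimic$catalog, res, mimic$sim$samples)
  res2 <- classify_dataset(mimic$sim$samples, cat2, lib)
  expect_true(all(res2$status == "known"))
  expect_equal(res2$name, res$name)  # names unchanged
})

test_that("classify_dataset handles empty input and bad markers", {
  empty <- sample_table(character(), character())
  expect_equal(nrow(classify_dataset(empty, empty_catalog(), lib)), 0L)
  wrong <- sample_table("s", strrep("ACGT", 250L), marker = "COI")
  expect_error(classify_dataset(wrong, empty_catalog(), lib), "COICOII")
})
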