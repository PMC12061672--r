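test_that("identical-sequence grouping forms first-appearance classes", {
  smp <- sample_table(c("a", "b", "c"), c("ACGT", "ACGT", "ACGA"),
                      marker = "COI")
  part <- group_identical(smp)
  expect_equal(part$n_groups, 2L)
  expect_equal(part$sizes, c(2L, 1L))
  expect_equal(part$groups$group, c(1L, 1L, 2L))

  single <- group_identical(sample_table("x", "ACGT", marker = "COI"))
  expect_equal(single$n_groups, 1L)

  mixed <- sample_table(c("a", "b"), c("ACGT", "ACGT"),
                        marker = c("COI", "CYTB"))
  expect_error(group_identical(mixed), "mixed markers")
})

test_that("a planted 44-sequence cyt b set yields its 11 groups", {
  sim <- simulate_coding_fragments(seed = 21L, length = 359L,
                                   spectrum = c(16, 9, 3, 2, 2, 2, 2, 2, 2, 2, 2),
                                   marker = "CYTB")
  part <- group_identical(sim$samples)
  expect_equal(part$n_samples, 44L)
  expect_equal(part$n_groups, 11L)
  # the partition matches the generator's truth classes exactly
  expect_equal(part$groups$group, sim$truth$class)
})

test_that("haplotype diversity follows the unbiased estimator", {
  expect_equal(haplotype_diversity(c(2, 2, rep(1, 11))),
               (15 / 14) * (1 - 19 / 225))
  expect_equal(haplotype_diversity(10), 0)        # monomorphic
  expect_equal(haplotype_diversity(c(1, 1)), 1)   # all distinct, n = 2
  # invariant under relabeling/permutation of groups
  set.seed(3)
  for (i in 1:10) {
    sizes <- sample(1:5, sample(2:8, 1L), replace = TRUE)
    expect_equal(haplotype_diversity(sizes),
                 haplotype_diversity(sample(sizes)))
  }
  expect_error(haplotype_diversity(1), "at least 2")
})

test_that("nucleotide diversity matches definition and brute-force oracle", {
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT")), 0)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT")), 0.25)
  # ambiguity columns are excluded pairwise
  expect_equal(nucleotide_diversity(c("AANA", "AATA")), 0)
  expect_equal(nucleotide_diversity(c("AANT", "AATA")), 1 / 3)
  expect_error(nucleotide_diversity(c("AC", "ACG")), "align")

  set.seed(31)
  aln <- random_alignment(15L, 80L)
  expect_equal(nucleotide_diversity(aln), oracle_pi(aln), tolerance = 1e-12)
  expect_equal(nucleotide_diversity(sample(aln)), nucleotide_diversity(aln))

  # duplicating every row rescales pi only through the pair counts:
  # pi_dup = pi * (2n - 2) / (2n - 1) for distinct-row alignments
  n <- 15L
  expect_equal(nucleotide_diversity(rep(aln, each = 2L)),
               nucleotide_diversity(aln) * (2 * n - 2) / (2 * n - 1),
               tolerance = 1e-12)
})

test_that("Tajima's D matches an independent implementation to 1e-9", {
  set.seed(37)
  for (i in 1:30) {
    aln <- random_alignment(sample(4:12, 1L), 60L)
    got <- tajimas_d(aln)
    want <- oracle_tajima(aln)
    if (is.na(want$D)) {
      expect_false(got$defined)
    } else {
      expect_equal(got$D, want$D, tolerance = 1e-9)
      expect_equal(got$p_beta, want$p_beta, tolerance = 1e-9)
    }
  }
})

test_that("Tajima's D handles degenerate inputs", {
  flat <- tajimas_d(rep("ACGTACGT", 5L))
  expect_false(flat$defined)
  expect_true(is.na(flat$D))
  expect_equal(flat$p_normal, 1)
  expect_equal(flat$p_beta, 1)
  expect_error(tajimas_d(c("AC", "AC", "AC")), "at least 4")
})

test_that("SNP reports use 1-based positions with ref then alt", {
  expect_equal(report_snps("ACGA", "ACGT"),
               data.frame(position = 4L, ref = "T", alt = "A",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(report_snps("ACGT", "ACGT")), 0L)
  expect_error(report_snps("ACG", "ACGT"), "unequal")

  # planted T -> C at position 155 of a 218 bp coding fragment
  set.seed(55)
  ref <- paste(sample(c("A", "C", "G", "T"), 218L, TRUE), collapse = "")
  substr(ref, 155L, 155L) <- "T"
  smp <- ref
  substr(smp, 155L, 155L) <- "C"
  snps <- report_snps(smp, ref)
  expect_equal(snps$position, 155L)
  expect_equal(snps$ref, "T")
  expect_equal(snps$alt, "C")
})

test_that("diversity_stats bundles the marker summary", {
  sim <- simulate_coding_fragments(seed = 61L, length = 218L,
                                   spectrum = c(2, 2, rep(1, 11)),
                                   marker = "COI")
  st <- diversity_stats(sim$samples)
  expect_equal(st$n, 15L)
  expect_equal(st$h, 13L)
  expect_equal(st$H, haplotype_diversity(c(2, 2, rep(1, 11))))
  expect_true(st$pi >= 0 && st$S >= 1)
  expect_true(st$p_normal >= 0 && st$p_normal <= 1)
})
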