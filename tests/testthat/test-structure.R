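lib <- build_element_library(1L)

test_that("zero-noise amplicons annotate to their built structure", {
  labels <- c("Q1", "Q2", "PQ1", "PQ2", "P0Q1", "P0Q2")
  sim <- simulate_dataset(simulation_config(seed = 4L, n_samples = 6L,
                                            structure = labels, snp_rate = 0,
                                            haplotype_spectrum = rep(1L, 6L)),
                          lib)
  for (i in seq_len(6L)) {
    ann <- annotate_structure(sim$samples[i, ], lib)
    expect_equal(ann$structure_label, sim$truth$structure[[i]])
    expect_equal(ann$q_count, parse_structure_label(labels[[i]])$q)
    expect_equal(call_lineage(ann)$lineage, sim$truth$lineage[[i]])
  }
})

test_that("element coordinates are ordered, non-overlapping and 0-based", {
  sim <- simulate_dataset(simulation_config(seed = 4L, n_samples = 1L,
                                            structure = "P0Q2", snp_rate = 0),
                          lib)
  ann <- annotate_structure(sim$samples[1L, ], lib)
  el <- ann$elements
  expect_true(all(diff(el$start) > 0))
  expect_true(all(el$end[-nrow(el)] <= el$start[-1L]))
  # zero noise: annotation coordinates equal the generator's truth for the
  # tRNA / P0 / Q block (flanks are not elements)
  truth <- sim$elements[sim$elements$sample_id == "S001" &
                        !grepl("FLANK", sim$elements$element), ]
  expect_equal(el$start, truth$start)
  expect_equal(el$end, truth$end)
})

test_that("structure labels render and parse as an identity", {
  for (pre in c("", "P", "P0")) for (x in 1:5) {
    label <- paste0(pre, "Q", x)
    st <- parse_structure_label(label)
    expect_equal(render_structure_label(st$p0, st$p, st$q), label)
  }
  expect_error(parse_structure_label("ZQ1"), "unrecognized")
})

test_that("P0 deletions are recovered at canonical offsets", {
  # canonical P0 -> no deletion
  sim0 <- simulate_dataset(simulation_config(seed = 6L, n_samples = 1L,
                                             snp_rate = 0), lib)
  ann0 <- annotate_structure(sim0$samples[1L, ], lib)
  expect_equal(nrow(detect_p0_deletion(ann0, lib, sim0$samples[1L, ])), 0L)

  # planted 18 bp deletion at offset 20
  sim1 <- simulate_dataset(simulation_config(seed = 6L, n_samples = 1L,
                                             snp_rate = 0,
                                             deletion_classes = 1L), lib)
  ann1 <- annotate_structure(sim1$samples[1L, ], lib)
  dels <- detect_p0_deletion(ann1, lib, sim1$samples[1L, ])
  expect_equal(dels$offset, 20L)
  expect_equal(dels$length, 18L)
  expect_equal(ann1$structure_label, "P0Q2")  # deletion keeps the P0 call
  expect_equal(call_lineage(ann1)$lineage, "A")

  # two separate 3 bp excisions
  p0cut <- paste0(substr(lib$p0, 1, 10), substr(lib$p0, 14, 40),
                  substr(lib$p0, 44, 68))
  amplicon <- paste0(lib$flank5, lib$trna_leu, p0cut, lib$q, lib$q, lib$flank3)
  ann2 <- annotate_structure(amplicon, lib)
  dels2 <- ann2$deletions
  expect_equal(nrow(dels2), 2L)
  expect_equal(dels2$offset, c(10L, 40L))
  expect_equal(dels2$length, c(3L, 3L))
})

test_that("unrecognizable and mistyped inputs error clearly", {
  set.seed(99)
  junk <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  expect_error(annotate_structure(junk, lib), "not a recognizable")
  smp <- sample_table("x", strrep("ACGT", 250), marker = "COI")
  expect_error(annotate_structure(smp[1L, ], lib), "COICOII")
  expect_error(annotate_structure("ACGT", lib), "shorter")
})

test_that("lineage call is a pure function of element kinds", {
  fake_ann <- function(kinds) {
    structure(list(sample_id = "f", q_count = sum(kinds == "Q"),
                   elements = data.frame(kind = kinds, start = 0L, end = 1L,
                                         identity = 1),
                   structure_label = "", deletions = NULL, total_length = 1L),
              class = "structure_annotation")
  }
  set.seed(17)
  for (i in 1:40) {
    kinds <- c(sample(c("TRNA", ""), 1L),
               sample(c("P0", "P", ""), 1L),
               rep("Q", sample(0:3, 1L)))
    kinds <- kinds[nzchar(kinds)]
    expected <- if ("P0" %in% kinds) "A" else if ("P" %in% kinds) "M"
                else if ("Q" %in% kinds) "C" else "unknown"
    expect_equal(call_lineage(fake_ann(kinds))$lineage, expected)
  }
})

test_that("structure recovery is exact on noisy mixed structures", {
  labels <- rep(c("Q1", "Q2", "PQ1", "PQ2", "P0Q1", "P0Q2"), length.out = 60L)
  sim <- simulate_dataset(simulation_config(seed = 7L, n_samples = 60L,
                                            structure = labels,
                                            snp_rate = 0.005,
                                            haplotype_spectrum = rep(1L, 60L),
                                            p0_deletion_prob = 0.3), lib)
  for (i in seq_len(60L)) {
    ann <- annotate_structure(sim$samples[i, ], lib)
    expect_equal(ann$structure_label, sim$truth$structure[[i]],
                 label = paste("sample", i))
    expect_equal(call_lineage(ann)$lineage, sim$truth$lineage[[i]])
  }
})
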