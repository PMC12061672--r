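# Optional reproduction of a full study from user-downloaded GenBank records.
# Nothing here ships sequence data: the caller supplies a directory of FASTA
# files plus a real element library and reference catalog.

#' Re-run the full haplotyping analysis on user-supplied accession data
#'
#' Integration entry point for reproducing a published dataset from records
#' the user has downloaded themselves. The directory must contain:
#' \describe{
#'   \item{`coicoii.fa`}{COI-COII intergenic amplicons, one record per sample.}
#'   \item{`coicoii_aln.fa`}{the same 15-sample set aligned (for diversity).}
#'   \item{`cytb.fa`, `coi.fa`}{optional coding-gene fragments.}
#'   \item{`metadata.tsv`}{sidecar table (see [read_metadata()]).}
#'   \item{`catalog.tsv`}{reference haplotype catalog (see [read_catalog()]).}
#'   \item{`library.json`}{real canonical element strings
#'     (see [read_element_library()]); the synthetic default library only
#'     matches synthetic amplicons.}
#' }
#'
#' @param dir directory with the files above.
#' @return list with `classification` (the [classify_dataset()] table),
#'   `n_haplotypes`, `n_novel`, `n_deletion_samples`, `diversity`
#'   (a [diversity_stats()] result on the aligned set), and, when coding
#'   files are present, `cytb_groups` / `coi_groups`.
#' @export
run_accession_reproduction <- function(dir) {
  need <- c("coicoii.fa", "coicoii_aln.fa", "metadata.tsv", "catalog.tsv",
            "library.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("accession directory is missing: ", paste(missing, collapse = ", "))
  }
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  lib <- read_element_library(file.path(dir, "library.json"))
  catalog <- read_catalog(file.path(dir, "catalog.tsv"))
  samples <- trim_ambiguous_ends(
    read_fasta(file.path(dir, "coicoii.fa"), marker = "COICOII",
               metadata = meta))
  cls <- classify_dataset(samples, catalog, lib)
  aligned <- read_fasta(file.path(dir, "coicoii_aln.fa"), marker = "COICOII",
                        metadata = meta)
  out <- list(classification = cls,
              n_haplotypes = length(unique(cls$name)),
              n_novel = length(unique(cls$name[cls$status == "novel"])),
              n_deletion_samples = sum(cls$n_deletions > 0L),
              diversity = diversity_stats(aligned))
  for (gene in c("cytb", "coi")) {
    fa <- file.path(dir, paste0(gene, ".fa"))
    if (file.exists(fa)) {
      smp <- trim_ambiguous_ends(read_fasta(fa, marker = toupper(gene),
                                            metadata = meta))
      out[[paste0(gene, "_groups")]] <- group_identical(smp)
    }
  }
  out
}
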