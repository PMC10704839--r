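# MAF reading, category assignment, filters, count tensor.

test_that("categorize_mutation implements the 7-category scheme", {
  expect_equal(categorize_mutation("C", "T", "ACG"), 1L)  # CpG transition
  expect_equal(categorize_mutation("G", "A", "CGT"), 1L)  # CpG, other strand
  expect_equal(categorize_mutation("C", "G", "ACG"), 2L)  # CpG transversion
  expect_equal(categorize_mutation("C", "T", "ACT"), 3L)  # C:G non-CpG transition
  expect_equal(categorize_mutation("C", "A", "TCA"), 4L)  # C:G non-CpG transversion
  expect_equal(categorize_mutation("A", "G", "TAT"), 5L)  # A:T transition
  expect_equal(categorize_mutation("T", "A", "TTT"), 6L)  # A:T transversion
  expect_equal(categorize_mutation("-", "TT"), 7L)        # insertion
  expect_equal(categorize_mutation("AC", "-"), 7L)        # deletion
  expect_error(categorize_mutation("A", "A", "TAT"), "ref equals alt")
})

test_that("category assignment is pair-symmetric over all 192 combinations", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  for (ref in bases) for (alt in setdiff(bases, ref)) {
    for (prev in bases) for (nxt in bases) {
      ctx <- paste0(prev, ref, nxt)
      ctx_rc <- paste0(comp[nxt], comp[ref], comp[prev])
      expect_equal(categorize_mutation(ref, alt, ctx),
                   categorize_mutation(comp[ref], comp[alt], ctx_rc),
                   info = paste(ref, alt, ctx))
    }
  }
})

write_toy_maf <- function(rows) {
  path <- tempfile(fileext = ".maf")
  hdr <- paste(c("Hugo_Symbol", "Chromosome", "Start_position",
                 "Reference_Allele", "Tumor_Seq_Allele2",
                 "Tumor_Sample_Barcode", "Variant_Classification"),
               collapse = "\t")
  writeLines(c(hdr, rows), path)
  path
}

test_that("read_maf parses, splits multi-allelic rows, flags unmapped genes", {
  maf <- write_toy_maf(c(
    "GA\tchrT\t19\tG\tA\tP1\tSilent",
    "GA\tT\t14\tA\tG,C\tP1\tMissense_Mutation",
    "ZZZ\tT\t5\tA\tC\tP2\tIntron"))
  muts <- read_maf(maf, gene_ids = "GA")
  expect_equal(nrow(muts), 4L)                 # multi-allelic row split
  expect_equal(muts$chrom, rep("T", 4L))       # chr prefix stripped
  expect_equal(sum(muts$unmapped), 1L)
  # empty file with header
  empty <- read_maf(write_toy_maf(character()))
  expect_equal(nrow(empty), 0L)
  # missing mandatory column is a configuration error
  bad <- tempfile(); writeLines("Hugo_Symbol\tChromosome", bad)
  expect_error(read_maf(bad), class = "synsig_config_error")
})

test_that("annotate_mutations zones SNVs by site lookup and indels by position", {
  se <- toy_site_effects()
  muts <- data.table::data.table(
    patient_id = "P1", gene_id = "GA", chrom = "T",
    pos = c(19L, 14L, 26L, 5L, 20L, 15L),
    ref = c("G", "A", "C", "A", "A", "T"),
    alt = c("A", "G", "T", "C", "-", "A"),
    variant_class = c(NA, NA, NA, NA, "Frame_Shift_Del", "Nonsense_Mutation"))
  ann <- annotate_mutations(muts, se)
  expect_equal(ann$zone, c(1L, 2L, 3L, 0L, 2L, 2L))
  expect_equal(ann$category[3], 1L)            # intronic CpG transition
  expect_equal(ann$category[5], 7L)            # indel
  expect_equal(ann$category[6], 7L)            # null-flagged SNV
})

test_that("hypermutators are excluded strictly above the threshold", {
  manifest <- data.frame(patient_id = c("HYPER", "EDGE", "LOW"),
                         cohort = "C")
  muts <- data.table::data.table(
    patient_id = c(rep("HYPER", 50001L), rep("EDGE", 50000L), rep("LOW", 3L)))
  out <- filter_hypermutators(manifest, muts)
  expect_setequal(out$manifest$patient_id, c("EDGE", "LOW"))
  expect_equal(out$report[out$report$patient_id == "HYPER", ]$excluded, TRUE)
  # empty cohort
  empty <- filter_hypermutators(manifest[0, ], muts[0])
  expect_equal(nrow(empty$manifest), 0L)
})

test_that("non-transcribed mutations are dropped; intron/UTR retained", {
  se <- toy_site_effects()
  muts <- annotate_mutations(data.table::data.table(
    patient_id = "P1", gene_id = "GA", chrom = "T",
    pos = c(5L, 26L, 12L),                  # intergenic, intron, 5'UTR
    ref = c("A", "C", "T"), alt = c("C", "T", "A"),
    variant_class = NA_character_), se)
  kept <- filter_nontranscribed(muts)
  expect_equal(attr(kept, "n_excluded"), 1L)
  expect_equal(kept$zone, c(3L, 3L))
})

test_that("count tensor aggregates exactly and conserves records", {
  se <- toy_site_effects()
  muts <- annotate_mutations(data.table::data.table(
    patient_id = c("P1", "P1", "P2"), gene_id = "GA", chrom = "T",
    pos = c(19L, 19L, 26L), ref = c("G", "G", "C"), alt = c("A", "A", "T"),
    variant_class = NA_character_), se)
  tensor <- build_count_tensor(muts, "GA", c("P1", "P2"))
  cat19 <- se[pos == 19L & alt == "A", category]
  expect_equal(tensor["GA", cat19, "P1", "synonymous"], 2L)
  expect_equal(tensor["GA", 1L, "P2", "noncoding"], 1L)
  # total slot equals the category sum; grand total conserves records
  expect_equal(tensor[, 8L, , ], apply(tensor[, 1:7, , ], c(2, 3), sum))
  expect_equal(sum(tensor[, 1:7, , ]), nrow(muts))
  # empty input: all-zero tensor
  zero <- build_count_tensor(muts[0], "GA", "P1")
  expect_true(all(zero == 0L))
})
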