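# Hand-built single-gene fixture with fully known coordinates, plus small
# generator worlds shared across test files.
#
# chrT layout (1-based):
#   1-10   intergenic ACGTACGTAC
#   11-13  5'UTR      TTT
#   14-22  CDS exon 1 ATGCTGAAA   (codons ATG CTG AAA)
#   23-28  intron     GTACGT      (CpG at 26-27)
#   29-34  CDS exon 2 CCGTAA      (codons CCG TAA)
#   35-38  3'UTR      GGCC
#   39-50  intergenic ACGTACGTACGT
# Gene A territory = 15 (coding) + 6 (intron) + 7 (UTR) = 28 bp.

TOY_SEQ <- paste0("ACGTACGTAC", "TTT", "ATGCTGAAA", "GTACGT", "CCGTAA",
                  "GGCC", "ACGTACGTACGT")

toy_genome <- function() {
  g <- Biostrings::DNAStringSet(c(T = TOY_SEQ))
  g
}

toy_gtf <- function() {
  at <- function(tx) {
    sprintf(paste0('gene_id "GA"; transcript_id "%s"; gene_type ',
                   '"protein_coding"; gene_status "KNOWN"; gene_name "GA";'), tx)
  }
  c(
    sprintf("chrT\tTEST\tgene\t11\t38\t.\t+\t.\t%s", at("GA.t1")),
    # long transcript t1: exons 11-22 and 29-38 (length 22)
    sprintf("chrT\tTEST\ttranscript\t11\t38\t.\t+\t.\t%s", at("GA.t1")),
    sprintf("chrT\tTEST\texon\t11\t22\t.\t+\t.\t%s", at("GA.t1")),
    sprintf("chrT\tTEST\texon\t29\t38\t.\t+\t.\t%s", at("GA.t1")),
    sprintf("chrT\tTEST\tCDS\t14\t22\t.\t+\t.\t%s", at("GA.t1")),
    sprintf("chrT\tTEST\tCDS\t29\t34\t.\t+\t.\t%s", at("GA.t1")),
    # short transcript t2: exon/CDS 14-22 only (length 9)
    sprintf("chrT\tTEST\ttranscript\t14\t22\t.\t+\t.\t%s", at("GA.t2")),
    sprintf("chrT\tTEST\texon\t14\t22\t.\t+\t.\t%s", at("GA.t2")),
    sprintf("chrT\tTEST\tCDS\t14\t22\t.\t+\t.\t%s", at("GA.t2")),
    # excluded: pseudogene and non-KNOWN gene
    "chrT\tTEST\tgene\t40\t45\t.\t+\t.\tgene_id \"GP\"; gene_type \"pseudogene\"; gene_status \"KNOWN\";",
    "chrT\tTEST\tgene\t40\t45\t.\t+\t.\tgene_id \"GN\"; gene_type \"protein_coding\"; gene_status \"NOVEL\";"
  )
}

toy_genes <- function(principal = NULL) load_gene_models(toy_gtf(), principal)

toy_site_effects <- function() enumerate_site_effects(toy_genes(), toy_genome())

# small generator world reused by several files (cached per session)
.tw_env <- new.env()
tiny_world <- function() {
  if (is.null(.tw_env$w)) {
    cfg <- sim_config(seed = 404L, n_genes = 30L, n_patients = 8L,
                      genes_per_chrom = 15L, coding_length = 300L,
                      intron_length = 400L, utr5_length = 60L,
                      utr3_length = 90L, base_rate = 1e-4, n_decoy_genes = 1L,
                      expression_intercept = 0.5)  # ~1/3 non-expressed
    .tw_env$w <- simulate_cohort(cfg)
  }
  .tw_env$w
}

# independent codon-effect oracle: classify (codon, position, alt) via direct
# translation with Biostrings, no shared lookup machinery
oracle_is_synonymous <- function(codon, pos, alt) {
  gc <- Biostrings::GENETIC_CODE
  mut <- codon
  substr(mut, pos, pos) <- alt
  identical(gc[[mut]], gc[[codon]])
}

# oracle for the summed synonymous weight of a gene: enumerate its CDS codons
# from the genome and count synonymous (position, alt) pairs / 3
oracle_syn_weight <- function(gene, genome) {
  civ <- gene$coding[order(IRanges::start(gene$coding))]
  seqs <- vapply(seq_along(civ), function(i) {
    as.character(Biostrings::subseq(genome[[gene$chrom]],
                                    IRanges::start(civ)[i], IRanges::end(civ)[i]))
  }, "")
  cds <- paste0(seqs, collapse = "")
  if (identical(gene$strand, "-")) {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  n_syn <- 0L
  for (i in seq_len(nchar(cds))) {
    ci <- (i - 1L) %/% 3L
    codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
    p <- i - ci * 3L
    b <- substr(cds, i, i)
    for (alt in setdiff(c("A", "C", "G", "T"), b)) {
      if (oracle_is_synonymous(codon, p, alt)) n_syn <- n_syn + 1L
    }
  }
  n_syn / 3
}
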