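# Gene model loading and site-effect enumeration.

test_that("GTF loading applies the KNOWN/protein_coding filters and picks transcripts", {
  genes <- toy_genes()
  expect_named(genes, "GA")
  log <- attr(genes, "exclusion_log")
  expect_setequal(log$gene_id, c("GP", "GN"))
  expect_equal(log[log$gene_id == "GP", ]$reason, "not_protein_coding")
  expect_equal(log[log$gene_id == "GN", ]$reason, "not_KNOWN")

  # longest transcript (t1, 22 nt of exon) wins over t2 (9 nt)
  expect_equal(genes$GA$transcript_id, "GA.t1")
  expect_equal(sum(IRanges::width(genes$GA$coding)), 15L)
  expect_equal(sum(IRanges::width(genes$GA$intron)), 6L)
  expect_equal(sum(IRanges::width(genes$GA$utr)), 7L)

  # principal transcript overrides the longest rule
  genes2 <- toy_genes(principal = c(GA = "GA.t2"))
  expect_equal(genes2$GA$transcript_id, "GA.t2")

  # empty annotation: empty set, no error
  expect_length(load_gene_models(character()), 0L)
})

test_that("malformed GTF lines are reported with their line number", {
  lines <- c(toy_gtf()[1:2], "chrT\tbroken line with\ttoo few fields")
  expect_error(load_gene_models(lines), "line 3", class = "synsig_parse_error")
})

test_that("site effects classify codon changes, assign categories, weight 1/3", {
  se <- toy_site_effects()
  # every position carries exactly 3 alternate alleles of weight 1/3
  per_pos <- se[, .N, by = pos]
  expect_true(all(per_pos$N == 3L))
  expect_true(all(se$weight == 1 / 3))
  # gene A territory: 28 positions
  expect_equal(nrow(se), 28L * 3L)

  # third base of CTG (Leu) at genomic 19: all three alts synonymous
  p19 <- se[pos == 19L]
  expect_equal(p19$zone, rep(1L, 3L))
  # first base of ATG at genomic 14: no synonymous alternative for Met
  p14 <- se[pos == 14L]
  expect_equal(p14$zone, rep(2L, 3L))
  # intronic C at 26 followed by G: alt T is a CpG transition, category 1
  p26 <- se[pos == 26L & alt == "T"]
  expect_equal(p26$zone, 3L)
  expect_equal(p26$category, 1L)
  # coding positions map only to synonymous/nonsynonymous zones
  coding_pos <- c(14:22, 29:34)
  expect_true(all(se[pos %in% coding_pos, zone] %in% 1:2))
  expect_true(all(se[!pos %in% coding_pos, zone] == 3L))
})

test_that("summed synonymous weight matches the brute-force codon oracle", {
  w <- tiny_world()
  se <- w$site_effects
  syn <- se[zone == 1L, .(w = sum(weight)), by = gene_id]
  for (g in names(w$genes)[1:5]) {
    expect_equal(syn[gene_id == g, w], oracle_syn_weight(w$genes[[g]], w$genome),
                 tolerance = 1e-12, info = g)
  }
})

test_that("zone classification is strand-invariant under reverse complement", {
  # same CDS written on + and on - (reverse-complemented genome segment)
  cds <- "ATGCTGAAACCGTAA"
  fwd_seq <- paste0("AAAA", cds, "AAAA")
  rev_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd_seq)))
  at <- function(g, tx) sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_type "protein_coding"; gene_status "KNOWN";', g, tx)
  gtf <- c(
    sprintf("chrF\tT\texon\t5\t19\t.\t+\t.\t%s", at("GF", "GF.t")),
    sprintf("chrF\tT\tCDS\t5\t19\t.\t+\t.\t%s", at("GF", "GF.t")),
    sprintf("chrR\tT\texon\t5\t19\t.\t-\t.\t%s", at("GR", "GR.t")),
    sprintf("chrR\tT\tCDS\t5\t19\t.\t-\t.\t%s", at("GR", "GR.t"))
  )
  genome <- Biostrings::DNAStringSet(c(F = fwd_seq, R = rev_seq))
  se <- enumerate_site_effects(load_gene_models(gtf), genome)
  # map each entry to its CDS offset; zones must agree position by position
  fwd <- se[gene_id == "GF"][, cds_pos := pos - 4L]
  rev <- se[gene_id == "GR"][, cds_pos := 20L - pos]
  key <- function(dt) dt[order(cds_pos, zone), .(n = .N), by = .(cds_pos, zone)]
  expect_equal(key(fwd), key(rev))
})

test_that("reference N bases are skipped and counted", {
  seq_n <- paste0("AAAA", "ATGCNGAAACCGTAA", "AAAA")  # N inside codon 2
  gtf <- c(
    "chrZ\tT\texon\t5\t19\t.\t+\t.\tgene_id \"GZ\"; transcript_id \"GZ.t\"; gene_type \"protein_coding\"; gene_status \"KNOWN\";",
    "chrZ\tT\tCDS\t5\t19\t.\t+\t.\tgene_id \"GZ\"; transcript_id \"GZ.t\"; gene_type \"protein_coding\"; gene_status \"KNOWN\";"
  )
  se <- enumerate_site_effects(load_gene_models(gtf),
                               Biostrings::DNAStringSet(c(Z = seq_n)))
  expect_equal(attr(se, "skip_log"), 3L)      # the whole codon is skipped
  expect_equal(nrow(se), (15L - 3L) * 3L)
})

test_that("gene consistency validation flags zone disagreements only", {
  gene <- toy_genes()$GA
  maf <- data.frame(pos = c(15L, 25L), zone = c("coding", "intron"))
  model <- data.frame(pos = c(15L, 25L), zone = c("coding", "intron"))
  expect_true(validate_gene_consistency(gene, maf, model))
  maf_bad <- data.frame(pos = 25L, zone = "coding")
  expect_false(validate_gene_consistency(gene, maf_bad,
                                         data.frame(pos = 25L, zone = "intron")))
  expect_true(validate_gene_consistency(gene, maf[0, ], model))
})
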