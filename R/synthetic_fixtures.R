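# Synthetic cohort generator.
#
# Emits a complete toy dataset in the exact dialects the readers accept:
# genome FASTA, Gencode-style GTF, principal-transcript mapping, MAF, WIG
# coverage masks (when dropout > 0), covariate/synonym/expression tables, and
# a patient manifest. Mutation counts are drawn per (gene, patient, zone,
# category) as Poisson with mean
#   base_rate * gene_factor * rho_p * rho_c * site_count [* spike fold in the
#   synonymous zone of spike-in genes]
# so patient-, category-, and gene-level heterogeneity are all present and
# their magnitudes are known ground truth. Gene factors are log-linear in the
# covariates plus residual noise, which is what makes covariate bagels
# informative. All randomness flows from the mandatory seed through fixed
# per-stage sub-streams, so a bundle is byte-identical on rerun.

#' Simulation configuration
#'
#' Defaults describe a heterogeneous null cohort: 1000 genes, 50 patients,
#' a 10x patient rate spread, skewed mutation categories (CpG transitions
#' dominant), gene-level rates spanning ~2 orders of magnitude linked to
#' covariates, and a synonymous-site rate of about 20 mutations per Mbp of
#' synonymous sites (a highly mutated indication).
#'
#' @param seed mandatory integer seed.
#' @param n_genes,n_patients cohort dimensions.
#' @param cohort cohort (histology) label.
#' @param coding_length CDS length in nt (multiple of 3, includes start/stop).
#' @param n_coding_exons number of coding exons (introns = gaps between them).
#' @param intron_length total intronic nt per gene.
#' @param utr5_length,utr3_length UTR lengths in nt.
#' @param intergenic_gap untranscribed gap between genes (bp).
#' @param genes_per_chrom genes placed per synthetic chromosome.
#' @param base_rate per-site per-patient SNV rate for a gene with unit
#'   covariate factor (2e-5 ~ 20/Mbp).
#' @param category_rates relative rates of categories 1-6 (normalized
#'   internally to a coverage-weighted mean of 1).
#' @param indel_fraction indel (category 7) rate as a fraction of the SNV
#'   rate.
#' @param patient_spread max/min ratio of patient rate multipliers
#'   (log-uniform).
#' @param covariate_effects log10 gene-factor slope per standardized
#'   covariate.
#' @param covariate_noise sd of the unexplained log10 gene factor.
#' @param gc_content GC fraction of non-coding sequence.
#' @param n_decoy_genes pseudogene decoys written to the GTF (excluded by the
#'   loader, never mutated).
#' @param spike_genes number of spike-in genes (or explicit gene ids) whose
#'   synonymous-zone rate is multiplied by `spike_fold`.
#' @param spike_fold synonymous fold-enrichment of spike-ins.
#' @param coverage_dropout fraction of each patient's territory reported
#'   uncovered in a per-patient WIG (0 = full coverage, no WIGs written).
#' @param synonym_fraction fraction of covariate rows renamed to a synonym
#'   (resolved through the emitted synonym mapping).
#' @param expression_intercept,expression_slope,expression_noise log-FPKM
#'   model: `log(FPKM) = intercept + slope * z_expression + N(0, noise)`;
#'   with the defaults ~10% of genes are non-expressed (FPKM < 1),
#'   forming the FDR null class.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 1000L,
                       n_patients = 50L,
                       cohort = "SIM-CohortA",
                       coding_length = 1500L,
                       n_coding_exons = 3L,
                       intron_length = 3000L,
                       utr5_length = 200L,
                       utr3_length = 600L,
                       intergenic_gap = 300L,
                       genes_per_chrom = 100L,
                       base_rate = 2e-5,
                       category_rates = c(10, 1.5, 3, 1.5, 2.5, 1),
                       indel_fraction = 0.05,
                       patient_spread = 10,
                       covariate_effects = c(expression = 0.45,
                                             reptime = 0.35, hic = 0.25),
                       covariate_noise = 0.10,
                       gc_content = 0.45,
                       n_decoy_genes = 2L,
                       spike_genes = 0L,
                       spike_fold = 10,
                       coverage_dropout = 0,
                       synonym_fraction = 0.02,
                       expression_intercept = 2,
                       expression_slope = 1.5,
                       expression_noise = 0.3) {
  if (missing(seed)) stop_synsig("sim_config: seed is mandatory")
  if (coding_length %% 3L != 0L || coding_length < 9L) {
    stop_synsig("coding_length must be a multiple of 3 and >= 9")
  }
  if (base_rate < 0 || patient_spread < 1 || spike_fold < 0) {
    stop_synsig("rates and spreads must be non-negative (spread >= 1)")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(config) {
  sprintf("G%04d", seq_len(config$n_genes))
}

# deterministic sub-stream draws shared by simulate_cohort() and the
# config-only helpers (truth_table, sim_spike_ids)
sim_covariates <- function(config) {
  ids <- sim_gene_ids(config)
  with_seed(config$seed + 12L, {
    z <- matrix(stats::rnorm(3L * length(ids)), ncol = 3L,
                dimnames = list(ids, names(config$covariate_effects)))
    noise <- stats::rnorm(length(ids), 0, config$covariate_noise)
    f <- 10^(as.vector(z %*% config$covariate_effects) + noise)
    list(z = z, f = stats::setNames(f, ids))
  })
}

sim_fpkm <- function(config, z) {
  with_seed(config$seed + 14L, {
    exp(config$expression_intercept + config$expression_slope * z[, 1L] +
          stats::rnorm(nrow(z), 0, config$expression_noise))
  })
}

#' Spike-in gene ids for a simulation configuration
#'
#' Spike-ins are sampled among expressed genes (FPKM >= 1) only: the FDR null
#' class is defined as non-expressed genes assumed to play no role, so a
#' spiked non-expressed gene would contradict the stated world.
#'
#' @param config a `sim_config`.
#' @return character vector of spiked gene ids.
#' @export
sim_spike_ids <- function(config) {
  ids <- sim_gene_ids(config)
  sg <- config$spike_genes
  if (is.character(sg)) return(intersect(sg, ids))
  if (sg <= 0) return(character())
  covs <- sim_covariates(config)
  eligible <- ids[sim_fpkm(config, covs$z) >= 1]
  with_seed(config$seed + 17L, sample(eligible, min(sg, length(eligible))))
}

#' Ground truth table for a simulation configuration
#'
#' @param config a `sim_config`.
#' @return data.table(gene_id, enriched, fold).
#' @export
truth_table <- function(config) {
  ids <- sim_gene_ids(config)
  spikes <- sim_spike_ids(config)
  data.table(gene_id = ids,
             enriched = ids %in% spikes,
             fold = ifelse(ids %in% spikes, config$spike_fold, 1))
}

NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))

random_noncoding <- function(n, gc) {
  if (n == 0L) return("")
  paste0(sample(BASES, n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

random_cds <- function(len) {
  ncod <- len %/% 3L
  paste0(c("ATG", sample(NONSTOP_CODONS, ncod - 2L, replace = TRUE), "TAA"),
         collapse = "")
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

gtf_line <- function(chrom, feature, start, end, strand, attrs) {
  sprintf("chr%s\tSIM\t%s\t%d\t%d\t.\t%s\t.\t%s",
          chrom, feature, start, end, strand, attrs)
}

# Build genome sequence + GTF for one gene; returns list(seq, gtf, width).
build_gene_locus <- function(gid, chrom, offset, strand, config) {
  cl <- config$coding_length
  nex <- config$n_coding_exons
  cuts <- if (nex > 1L) {
    sort(sample(seq_len(cl - 1L), nex - 1L))
  } else integer()
  cds_piece_len <- diff(c(0L, cuts, cl))
  intron_len <- if (nex > 1L) {
    li <- rep(config$intron_length %/% (nex - 1L), nex - 1L)
    li[1L] <- li[1L] + config$intron_length %% (nex - 1L)
    li
  } else integer()

  cds <- random_cds(cl)
  cds_pieces <- substring(cds, cumsum(c(1L, head(cds_piece_len, -1L))),
                          cumsum(cds_piece_len))
  introns <- vapply(intron_len, random_noncoding, "", gc = config$gc_content)
  u5 <- random_noncoding(config$utr5_length, config$gc_content)
  u3 <- random_noncoding(config$utr3_length, config$gc_content)

  # pre-mRNA (transcript order) pieces with labels
  labels <- c("utr5", rbind(rep("cds", nex),
                            c(rep("intron", nex - 1L), "utr3")))
  seqs <- c(u5, rbind(cds_pieces, c(introns, u3)))
  keep <- nchar(seqs) > 0L
  labels <- labels[keep]; seqs <- seqs[keep]
  widths <- nchar(seqs)

  if (strand == "-") {
    glabels <- rev(labels)
    gseq <- revcomp_str(paste0(seqs, collapse = ""))
    gwidths <- rev(widths)
  } else {
    glabels <- labels
    gseq <- paste0(seqs, collapse = "")
    gwidths <- widths
  }
  ends <- offset + cumsum(gwidths)
  starts <- ends - gwidths + 1L

  piece <- data.table(label = glabels, start = starts, end = ends)
  cdsiv <- piece[label == "cds"]
  # exons: union of cds+utr pieces merged when adjacent
  exiv <- IRanges::reduce(with(piece[label %in% c("cds", "utr5", "utr3")],
                               IRanges::IRanges(start, end)))
  attrs <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; gene_type ',
                          '"protein_coding"; transcript_type "protein_coding"; ',
                          'gene_status "KNOWN"; gene_name "%s";'),
                   gid, paste0(gid, ".t1"), gid)
  gattrs <- sprintf('gene_id "%s"; gene_type "protein_coding"; gene_status "KNOWN"; gene_name "%s";',
                    gid, gid)
  span <- c(min(starts), max(ends))
  gtf <- c(
    gtf_line(chrom, "gene", span[1L], span[2L], strand, gattrs),
    gtf_line(chrom, "transcript", span[1L], span[2L], strand, attrs),
    vapply(seq_along(exiv), function(i) {
      gtf_line(chrom, "exon", IRanges::start(exiv)[i], IRanges::end(exiv)[i],
               strand, attrs)
    }, ""),
    vapply(seq_len(nrow(cdsiv)), function(i) {
      gtf_line(chrom, "CDS", cdsiv$start[i], cdsiv$end[i], strand, attrs)
    }, "")
  )
  list(seq = gseq, gtf = gtf, width = sum(gwidths))
}

#' Simulate a toy cancer cohort
#'
#' Builds the synthetic world (genome, annotation, covariates, expression,
#' patients), draws mutations, and optionally writes the full file bundle.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, all input files are
#'   written there and their paths returned in `$files`.
#' @return a `sim_bundle` list: gene models, genome, site-effect table,
#'   covariate/synonym/expression tables, manifest, per-patient masks (when
#'   dropout > 0), the drawn mutation records (`$mutations`), ground-truth
#'   rate components (`$rho_p`, `$rho_c`, `$gene_factors`), the truth table,
#'   and file paths when written.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  spikes <- sim_spike_ids(config)

  ## --- stage 1: genome + annotation -------------------------------------
  world <- with_seed(config$seed + 11L, {
    chrom_of <- ceiling(seq_along(ids) / config$genes_per_chrom)
    seqs <- list(); gtf <- character(); gap <- config$intergenic_gap
    for (ch in unique(chrom_of)) {
      offset <- 0L; parts <- character()
      for (gi in which(chrom_of == ch)) {
        pad <- random_noncoding(gap, config$gc_content)
        parts <- c(parts, pad); offset <- offset + gap
        strand <- if (gi %% 2L == 0L) "-" else "+"
        locus <- build_gene_locus(ids[gi], ch, offset, strand, config)
        parts <- c(parts, locus$seq); offset <- offset + locus$width
        gtf <- c(gtf, locus$gtf)
      }
      parts <- c(parts, random_noncoding(gap, config$gc_content))
      seqs[[as.character(ch)]] <- paste0(parts, collapse = "")
    }
    # pseudogene decoys at the end of the last chromosome (loader must drop)
    for (k in seq_len(config$n_decoy_genes)) {
      ch <- max(chrom_of)
      did <- sprintf("DECOY%02d", k)
      dl <- 300L
      st <- nchar(seqs[[as.character(ch)]]) + 1L
      seqs[[as.character(ch)]] <- paste0(seqs[[as.character(ch)]],
                                         random_noncoding(dl + gap, config$gc_content))
      at <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_type "pseudogene"; gene_status "KNOWN"; gene_name "%s";',
                    did, did, did)
      gtf <- c(gtf,
               gtf_line(ch, "gene", st, st + dl - 1L, "+", at),
               gtf_line(ch, "transcript", st, st + dl - 1L, "+", at),
               gtf_line(ch, "exon", st, st + dl - 1L, "+", at))
    }
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(seqs)
    list(genome = genome, gtf = gtf)
  })
  genes <- load_gene_models(world$gtf)
  se <- enumerate_site_effects(genes, world$genome)

  ## --- stage 2: covariates, gene factors --------------------------------
  covs <- sim_covariates(config)
  covariates <- data.table(gene_id = ids,
                           expression = covs$z[, 1L],
                           reptime = covs$z[, 2L],
                           hic = covs$z[, 3L])
  # synonym drift: rename a fraction of covariate rows; mapping restores them
  synonyms <- with_seed(config$seed + 18L, {
    n_syn <- floor(config$synonym_fraction * length(ids))
    if (n_syn > 0L) {
      renamed <- sample(ids, n_syn)
      data.table(old_name = paste0(renamed, "_ALT"), new_name = renamed)
    } else {
      data.table(old_name = character(), new_name = character())
    }
  })
  if (nrow(synonyms) > 0L) {
    covariates[match(synonyms$new_name, gene_id),
               gene_id := synonyms$old_name]
  }

  ## --- stage 3: patients ------------------------------------------------
  patients <- sprintf("P%03d", seq_len(config$n_patients))
  rho_p <- with_seed(config$seed + 13L, {
    s <- log10(config$patient_spread)
    r <- 10^stats::runif(config$n_patients, -s / 2, s / 2)
    stats::setNames(r / mean(r), patients)
  })
  manifest <- data.table(patient_id = patients, cohort = config$cohort)

  ## --- stage 4: expression ----------------------------------------------
  expression <- data.table(gene = ids, cohort = config$cohort,
                           fpkm = sim_fpkm(config, covs$z))

  ## --- stage 5: coverage dropout ----------------------------------------
  masks <- NULL
  uncovered <- NULL
  if (config$coverage_dropout > 0) {
    territory <- unique(se[, .(chrom, pos)])
    uncovered <- with_seed(config$seed + 16L, {
      lapply(stats::setNames(patients, patients), function(p) {
        n_unc <- floor(config$coverage_dropout * nrow(territory))
        territory[sample(.N, n_unc)]
      })
    })
    masks <- lapply(uncovered, function(unc) {
      cov <- list(); rep_ <- list()
      for (ch in unique(unc$chrom)) {
        rep_[[ch]] <- IRanges::reduce(IRanges::IRanges(sort(unc[chrom == ch, pos]),
                                                       width = 1L))
      }
      structure(list(covered = cov, reported = rep_, covered_min = 0),
                class = "coverage_mask")
    })
  }

  ## --- stage 6: mutation draws -------------------------------------------
  rho_c <- normalize_category_rates(config$category_rates, se)
  mutations <- with_seed(config$seed + 15L, {
    draw_mutations(se, world$genome, ids, patients, covs$f, rho_p, rho_c,
                   config, spikes, uncovered)
  })

  bundle <- structure(list(
    config = config, gene_ids = ids, patients = patients,
    genes = genes, genome = world$genome, gtf = world$gtf,
    site_effects = se, covariates = covariates, synonyms = synonyms,
    expression = expression, manifest = manifest, masks = masks,
    mutations = mutations, rho_p = rho_p, rho_c = rho_c,
    gene_factors = covs$f, truth = truth_table(config)
  ), class = "sim_bundle")

  if (!is.null(dir)) bundle$files <- write_bundle(bundle, dir)
  bundle
}

# normalize relative category rates to coverage-weighted mean 1 over the
# genome-wide site composition
normalize_category_rates <- function(rates, se) {
  w <- se[, .(w = sum(weight)), by = category]
  w <- stats::setNames(w$w, w$category)[as.character(1:6)]
  w[is.na(w)] <- 0
  r <- rates / sum(rates * w / sum(w))
  stats::setNames(r, as.character(1:6))
}

# Poisson draws + placement over the site table
draw_mutations <- function(se, genome, ids, patients, f, rho_p, rho_c,
                           config, spikes, uncovered = NULL) {
  np <- length(patients)

  draw_for_sites <- function(sites) {
    # sites: site table (possibly patient-specific); returns mutation records
    bins <- attr(sites, "sim_bins", exact = TRUE)
    if (is.null(bins)) {
      bins <- sites[, .(w = sum(weight)), by = .(gene_id, zone, category)]
      data.table::setattr(sites, "sim_bins", bins)
    }
    mu <- config$base_rate * f[bins$gene_id] *
      rho_c[as.character(bins$category)] * bins$w
    spiked <- bins$zone == 1L & bins$gene_id %in% spikes
    mu[spiked] <- mu[spiked] * config$spike_fold
    # same grouping and order as `bins`, so groups align by row index;
    # cached on the table since it is constant across replicate draws
    grp <- attr(sites, "sim_groups", exact = TRUE)
    if (is.null(grp)) {
      grp <- sites[, .(rows = list(.I)), by = .(gene_id, zone, category)]
      data.table::setattr(sites, "sim_groups", grp)
    }
    all_picks <- vector("list", np)
    all_pat <- vector("list", np)
    for (pi in seq_len(np)) {
      k <- stats::rpois(nrow(bins), mu * rho_p[pi])
      nz <- which(k > 0L)
      if (length(nz) == 0L) next
      picks <- unlist(lapply(nz, function(j) {
        rows <- grp$rows[[j]]
        rows[sample.int(length(rows), k[j], replace = TRUE)]
      }), use.names = FALSE)
      all_picks[[pi]] <- picks
      all_pat[[pi]] <- rep.int(pi, length(picks))
    }
    picks <- unlist(all_picks, use.names = FALSE)
    if (length(picks) == 0L) {
      return(data.table(patient_id = character(), gene_id = character(),
                        chrom = character(), pos = integer(), alt = character(),
                        zone = integer(), category = integer()))
    }
    sub <- sites[picks, .(gene_id, chrom, pos, alt, zone, category)]
    sub[, patient_id := patients[unlist(all_pat, use.names = FALSE)]]
    sub
  }

  if (is.null(uncovered)) {
    snvs <- draw_for_sites(se)
  } else {
    # per-patient covered site tables (small worlds only)
    snv_list <- list()
    for (pi in seq_along(patients)) {
      unc <- uncovered[[patients[pi]]]
      sites <- se[!unc, on = c("chrom", "pos")]
      one <- draw_for_sites_single(sites, patients[pi], rho_p[pi], f, rho_c,
                                   config, spikes)
      snv_list[[pi]] <- one
    }
    snvs <- rbindlist(snv_list)
  }

  # indels (category 7): uniform over gene territory (cached; constant
  # across replicate draws)
  terr <- attr(se, "sim_territory", exact = TRUE)
  if (is.null(terr)) {
    terr <- unique(se[, .(gene_id, chrom, pos, zone)])
    terr[, zone := data.table::fifelse(zone == 3L, 3L, 2L)]
    terr <- unique(terr, by = c("gene_id", "chrom", "pos"))
    data.table::setattr(se, "sim_territory", terr)
  }
  tgrp <- attr(se, "sim_territory_groups", exact = TRUE)
  if (is.null(tgrp)) {
    tgrp <- terr[, .(rows = list(.I)), by = gene_id]
    data.table::setattr(se, "sim_territory_groups", tgrp)
  }
  indel_mu <- config$base_rate * config$indel_fraction *
    f[tgrp$gene_id] * lengths(tgrp$rows)
  ind <- list()
  for (pi in seq_len(length(patients))) {
    k <- stats::rpois(nrow(tgrp), indel_mu * rho_p[pi])
    nz <- which(k > 0L)
    if (length(nz) == 0L) next
    picks <- unlist(lapply(nz, function(j) {
      rows <- tgrp$rows[[j]]
      rows[sample.int(length(rows), k[j], replace = TRUE)]
    }), use.names = FALSE)
    sub <- terr[picks, .(gene_id, chrom, pos, zone)]
    sub[, `:=`(patient_id = patients[pi], alt = "-", category = 7L)]
    ind[[length(ind) + 1L]] <- sub
  }
  muts <- rbindlist(c(list(snvs), ind), use.names = TRUE, fill = TRUE)
  if (nrow(muts) == 0L) {
    return(data.table(patient_id = character(), gene_id = character(),
                      chrom = character(), pos = integer(), ref = character(),
                      alt = character(), zone = integer(), category = integer()))
  }
  muts[, ref := NA_character_]
  for (ch in unique(muts$chrom)) {
    idx <- which(muts$chrom == ch)
    at <- IRanges::IRanges(muts$pos[idx], width = 1L)
    muts[idx, ref := toupper(as.character(Biostrings::extractAt(genome[[ch]], at)))]
  }
  setorder(muts, patient_id, chrom, pos)
  muts[]
}

# single-patient variant of draw_for_sites used under coverage dropout
draw_for_sites_single <- function(sites, patient, rp, f, rho_c, config, spikes) {
  bins <- sites[, .(w = sum(weight)), by = .(gene_id, zone, category)]
  bins[, mu := config$base_rate * f[gene_id] * rho_c[as.character(category)] * w]
  bins[zone == 1L & gene_id %in% spikes, mu := mu * config$spike_fold]
  k <- stats::rpois(nrow(bins), bins$mu * rp)
  nz <- which(k > 0L)
  out <- list()
  for (j in nz) {
    sub <- sites[gene_id == bins$gene_id[j] & zone == bins$zone[j] &
                   category == bins$category[j]]
    pick <- sub[sample.int(.N, k[j], replace = TRUE)]
    out[[length(out) + 1L]] <- data.table(
      patient_id = patient, gene_id = pick$gene_id, chrom = pick$chrom,
      pos = pick$pos, alt = pick$alt, zone = pick$zone, category = pick$category)
  }
  rbindlist(out)
}

#' Redraw mutations for an existing simulated world
#'
#' Reuses the bundle's genome, annotation, covariates and patients but draws
#' a fresh mutation set under a new seed; used for replicate simulations
#' without regenerating (and re-enumerating) the world.
#'
#' @param bundle a `sim_bundle`.
#' @param seed integer seed for the new draw.
#' @return mutation records as in `bundle$mutations`.
#' @export
resimulate_mutations <- function(bundle, seed) {
  unc <- NULL
  if (!is.null(bundle$masks)) {
    unc <- lapply(bundle$masks, function(m) {
      data.table::rbindlist(lapply(names(m$reported), function(ch) {
        r <- m$reported[[ch]]
        data.table(chrom = ch,
                   pos = unlist(Map(seq.int, IRanges::start(r), IRanges::end(r))))
      }))
    })
  }
  with_seed(seed, {
    draw_mutations(bundle$site_effects, bundle$genome, bundle$gene_ids,
                   bundle$patients, bundle$gene_factors, bundle$rho_p,
                   bundle$rho_c, bundle$config, sim_spike_ids(bundle$config),
                   unc)
  })
}

VARIANT_CLASS_OF_ZONE <- c("Silent", "Missense_Mutation", "Intron")

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    principal = file.path(dir, "principal_transcripts.tsv"),
    maf = file.path(dir, "cohort.maf"),
    manifest = file.path(dir, "manifest.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    synonyms = file.path(dir, "synonyms.tsv"),
    expression = file.path(dir, "expression.tsv")
  )
  genome_out <- bundle$genome
  names(genome_out) <- paste0("chr", names(genome_out))
  Biostrings::writeXStringSet(genome_out, files$genome)
  writeLines(bundle$gtf, files$annotation)
  data.table::fwrite(
    data.table(gene_id = bundle$gene_ids,
               transcript_id = paste0(bundle$gene_ids, ".t1")),
    files$principal, sep = "\t")
  m <- bundle$mutations
  maf <- data.table(
    Hugo_Symbol = m$gene_id,
    Chromosome = m$chrom,
    Start_position = m$pos,
    Reference_Allele = m$ref,
    Tumor_Seq_Allele2 = m$alt,
    Tumor_Sample_Barcode = m$patient_id,
    Variant_Classification = ifelse(
      m$category == 7L, "Frame_Shift_Del", VARIANT_CLASS_OF_ZONE[m$zone])
  )
  data.table::fwrite(maf, files$maf, sep = "\t")
  data.table::fwrite(bundle$manifest, files$manifest, sep = "\t")
  data.table::fwrite(bundle$covariates, files$covariates, sep = "\t")
  data.table::fwrite(bundle$synonyms, files$synonyms, sep = "\t")
  data.table::fwrite(bundle$expression, files$expression, sep = "\t")
  if (!is.null(bundle$masks)) {
    wigdir <- file.path(dir, "wig")
    dir.create(wigdir, showWarnings = FALSE)
    files$wig <- character()
    for (p in names(bundle$masks)) {
      path <- file.path(wigdir, paste0(p, ".wig"))
      lines <- character()
      rep_ <- bundle$masks[[p]]$reported
      for (ch in names(rep_)) {
        pos <- unlist(Map(seq.int, IRanges::start(rep_[[ch]]),
                          IRanges::end(rep_[[ch]])))
        lines <- c(lines, sprintf("variableStep chrom=chr%s", ch),
                   sprintf("%d 0", sort(pos)))
      }
      writeLines(lines, path)
      files$wig[p] <- path
    }
  }
  files
}
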