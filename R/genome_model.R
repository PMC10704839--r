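# Gene models and per-position effect enumeration.
#
# Genes come from a Gencode-v19-dialect GTF. Only KNOWN protein-coding genes
# are analyzable; one transcript represents each gene (the supplied principal
# transcript if present, otherwise the longest by summed exon length). Each
# gene partitions its territory into three effect zones: coding (classified
# per alternate allele as synonymous/nonsynonymous by codon translation),
# intron, and UTR (both noncoding). Every position carries three alternate
# alleles, each weighted 1/3 site.

GTF_COLS <- c("chrom", "source", "feature", "start", "end",
              "score", "strand", "frame", "attributes")

gtf_attr <- function(attrs, key) {
  pat <- paste0(key, "\\s+\"([^\"]*)\"")
  m <- regexpr(pat, attrs, perl = TRUE)
  out <- rep(NA_character_, length(attrs))
  hit <- m != -1L
  if (any(hit)) {
    out[hit] <- sub(pat, "\\1",
                    regmatches(attrs, m)[seq_len(sum(hit))], perl = TRUE)
  }
  out
}

parse_gtf <- function(annotation) {
  lines <- if (length(annotation) == 1L && file.exists(annotation)) {
    readLines(annotation)
  } else {
    as.character(annotation)
  }
  keep <- !grepl("^(#|\\s*$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.table(chrom = character(), feature = character(),
                      start = integer(), end = integer(), strand = character(),
                      gene_id = character(), transcript_id = character(),
                      gene_name = character(), gene_type = character(),
                      gene_status = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop_synsig("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                lineno[bad], nf[bad], class = "synsig_parse_error")
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  colnames(m) <- GTF_COLS
  start <- suppressWarnings(as.integer(m[, "start"]))
  end <- suppressWarnings(as.integer(m[, "end"]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop_synsig("malformed GTF line %d: non-integer coordinates", lineno[bad],
                class = "synsig_parse_error")
  }
  attrs <- m[, "attributes"]
  data.table(
    chrom = norm_chrom(m[, "chrom"]),
    feature = m[, "feature"],
    start = start, end = end,
    strand = m[, "strand"],
    gene_id = gtf_attr(attrs, "gene_id"),
    transcript_id = gtf_attr(attrs, "transcript_id"),
    gene_name = gtf_attr(attrs, "gene_name"),
    gene_type = gtf_attr(attrs, "gene_type"),
    gene_status = gtf_attr(attrs, "gene_status")
  )
}

new_gene_model <- function(gene_id, gene_name, chrom, strand, transcript_id,
                           coding, intron, utr) {
  structure(list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
                 strand = strand, transcript_id = transcript_id,
                 coding = coding, intron = intron, utr = utr),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) chr%s%s tx=%s coding=%dnt intron=%dnt utr=%dnt\n",
              x$gene_id, x$gene_name, x$chrom, x$strand, x$transcript_id,
              sum(IRanges::width(x$coding)), sum(IRanges::width(x$intron)),
              sum(IRanges::width(x$utr))))
  invisible(x)
}

gene_territory <- function(gene) {
  sum(IRanges::width(gene$coding)) + sum(IRanges::width(gene$intron)) +
    sum(IRanges::width(gene$utr))
}

#' Load analyzable gene models from a GTF annotation
#'
#' Retains KNOWN protein-coding genes (a missing `gene_status` attribute is
#' treated as KNOWN) and selects one transcript per gene: the principal
#' transcript when supplied, otherwise the longest by summed exon length
#' (ties broken by transcript id). UTR intervals are derived as exon minus
#' CDS; introns as transcript span minus exons. Genes without a CDS, or whose
#' CDS length is not a multiple of 3, are excluded with a logged reason.
#'
#' @param annotation path to a GTF file, or a character vector of GTF lines.
#' @param principal_transcripts optional mapping from gene id to principal
#'   transcript id: a 2-column data frame / TSV path (gene_id, transcript_id)
#'   or a named character vector.
#' @return a `gene_set`: named list of `gene_model` objects with an
#'   `exclusion_log` attribute (data.table of gene_id, reason).
#' @export
load_gene_models <- function(annotation, principal_transcripts = NULL) {
  gtf <- parse_gtf(annotation)
  principal <- character()
  if (!is.null(principal_transcripts)) {
    if (is.character(principal_transcripts) && length(principal_transcripts) == 1L &&
        file.exists(principal_transcripts)) {
      principal_transcripts <- read_tsv(principal_transcripts)
    }
    if (is.data.frame(principal_transcripts)) {
      principal <- stats::setNames(as.character(principal_transcripts[[2L]]),
                                   as.character(principal_transcripts[[1L]]))
    } else {
      principal <- principal_transcripts
    }
  }

  log <- list()
  models <- list()
  if (nrow(gtf) > 0L) {
    gtf[, gene_status := data.table::fifelse(is.na(gene_status), "KNOWN", gene_status)]
    ginfo <- gtf[!is.na(gene_id),
                 .(gene_type = gene_type[!is.na(gene_type)][1L],
                   gene_status = gene_status[1L],
                   gene_name = gene_name[!is.na(gene_name)][1L]),
                 by = gene_id]
    for (i in seq_len(nrow(ginfo))) {
      gid <- ginfo$gene_id[i]
      if (!identical(ginfo$gene_type[i], "protein_coding")) {
        log[[gid]] <- "not_protein_coding"; next
      }
      if (!identical(ginfo$gene_status[i], "KNOWN")) {
        log[[gid]] <- "not_KNOWN"; next
      }
      rows <- gtf[gene_id == gid & !is.na(transcript_id)]
      if (nrow(rows) == 0L) { log[[gid]] <- "no_transcript"; next }
      exlen <- rows[feature == "exon",
                    .(len = sum(end - start + 1L)), by = transcript_id]
      if (nrow(exlen) == 0L) { log[[gid]] <- "no_exons"; next }
      tx <- if (gid %in% names(principal) &&
                principal[[gid]] %in% exlen$transcript_id) {
        principal[[gid]]
      } else {
        setorder(exlen, -len, transcript_id)
        exlen$transcript_id[1L]
      }
      trows <- rows[transcript_id == tx]
      ir <- function(dt) IRanges::reduce(IRanges::IRanges(dt$start, dt$end))
      exons <- ir(trows[feature == "exon"])
      cds <- ir(trows[feature %in% c("CDS", "stop_codon")])
      if (sum(IRanges::width(cds)) == 0L) { log[[gid]] <- "no_CDS"; next }
      if (sum(IRanges::width(cds)) %% 3L != 0L) {
        log[[gid]] <- "CDS_length_not_multiple_of_3"; next
      }
      span <- IRanges::IRanges(min(IRanges::start(exons)),
                               max(IRanges::end(exons)))
      intron <- IRanges::setdiff(span, exons)
      utr <- IRanges::setdiff(exons, cds)
      models[[gid]] <- new_gene_model(
        gene_id = gid,
        gene_name = ginfo$gene_name[i] %||% gid,
        chrom = trows$chrom[1L],
        strand = trows$strand[1L],
        transcript_id = tx,
        coding = cds, intron = intron, utr = utr
      )
    }
  }
  excl <- if (length(log)) {
    data.table(gene_id = names(log), reason = unlist(log))
  } else {
    data.table(gene_id = character(), reason = character())
  }
  structure(models, class = "gene_set", exclusion_log = excl)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d genes (%d excluded at load)\n",
              length(x), nrow(attr(x, "exclusion_log"))))
  invisible(x)
}

#' Load a genome FASTA with normalized chromosome names
#'
#' @param fasta path to a FASTA file or a [Biostrings::DNAStringSet].
#' @return a DNAStringSet named by normalized chromosome.
#' @export
load_genome <- function(fasta) {
  genome <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else fasta
  names(genome) <- norm_chrom(sub("\\s.*$", "", names(genome)))
  genome
}

# the 3 alternate bases for each reference base, fixed order
ALT_TABLE <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Enumerate per-position per-allele mutation effects for a gene set
#'
#' For every genomic position in every gene's territory and each of the 3
#' alternate alleles (weight 1/3 site each), assigns the effect zone
#' (synonymous/nonsynonymous for coding positions by codon translation,
#' noncoding for intron/UTR) and the mutation category 1-6 from the
#' reference-strand triplet context. Codons containing a non-ACGT base are
#' skipped and counted in the `skip_log` attribute.
#'
#' @param genes a `gene_set` from [load_gene_models()].
#' @param genome FASTA path or DNAStringSet covering all gene intervals.
#' @return data.table (class `site_effects`) with columns gene_id, chrom,
#'   pos (1-based), alt, zone (1=synonymous, 2=nonsynonymous, 3=noncoding),
#'   category (1-6), weight (1/3).
#' @export
enumerate_site_effects <- function(genes, genome) {
  genome <- load_genome(genome)
  lookup <- synonymy_lookup()
  codon_names <- dimnames(lookup)[[1L]]
  skip <- 0L

  by_chrom <- split(unname(genes), vapply(genes, `[[`, "", "chrom"))
  pieces <- vector("list", 0L)
  for (chrom in names(by_chrom)) {
    if (!chrom %in% names(genome)) {
      stop_synsig("genome lacks chromosome '%s' required by the annotation", chrom)
    }
    chars <- strsplit(toupper(as.character(genome[[chrom]])), "", fixed = TRUE)[[1L]]
    clen <- length(chars)
    base_at <- function(p) {
      out <- rep("N", length(p))
      ok <- p >= 1L & p <= clen
      out[ok] <- chars[p[ok]]
      out
    }
    for (gene in by_chrom[[chrom]]) {
      ## --- coding zone ---
      civ <- gene$coding[order(IRanges::start(gene$coding))]
      gpos <- unlist(Map(seq.int, IRanges::start(civ), IRanges::end(civ)),
                     use.names = FALSE)
      if (identical(gene$strand, "-")) gpos <- rev(gpos)
      fwd_ref <- base_at(gpos)
      cds_base <- if (identical(gene$strand, "-")) complement_base(fwd_ref) else fwd_ref
      ncds <- length(cds_base)
      if (ncds %% 3L != 0L) {
        stop_synsig("gene %s: coding length %d is not a multiple of 3",
                    gene$gene_id, ncds)
      }
      ok <- logical(0L)
      if (ncds > 0L) {
        cod_i <- ((seq_len(ncds) - 1L) %/% 3L) + 1L
        within <- ((seq_len(ncds) - 1L) %% 3L) + 1L
        codons <- paste0(cds_base[seq.int(1L, ncds, 3L)],
                         cds_base[seq.int(2L, ncds, 3L)],
                         cds_base[seq.int(3L, ncds, 3L)])
        cod_idx <- match(codons, codon_names)[cod_i]
        ok <- !is.na(cod_idx)
        if (any(!ok)) skip <- skip + sum(!ok)
      }
      if (any(ok)) {
        gp <- gpos[ok]; cb <- cds_base[ok]; fr <- fwd_ref[ok]
        ci <- cod_idx[ok]; wi <- within[ok]
        ctx <- paste0(base_at(gp - 1L), fr, base_at(gp + 1L))
        n <- length(gp)
        alt_cds <- as.vector(ALT_TABLE[cb, ])           # n x 3 column-major
        syn <- lookup[cbind(rep.int(ci, 3L), rep.int(wi, 3L),
                            match(alt_cds, BASES))]
        alt_g <- if (identical(gene$strand, "-")) complement_base(alt_cds) else alt_cds
        cat6 <- categorize_mutation(rep.int(fr, 3L), alt_g, rep.int(ctx, 3L))
        pieces[[length(pieces) + 1L]] <- data.table(
          gene_id = gene$gene_id, chrom = chrom,
          pos = rep.int(gp, 3L), alt = alt_g,
          zone = ifelse(syn, 1L, 2L), category = cat6, weight = 1 / 3)
      }
      ## --- noncoding zone (intron + UTR) ---
      nc <- IRanges::reduce(c(gene$intron, gene$utr))
      if (sum(IRanges::width(nc)) > 0L) {
        np <- unlist(Map(seq.int, IRanges::start(nc), IRanges::end(nc)),
                     use.names = FALSE)
        r <- base_at(np)
        okn <- r %in% BASES
        if (any(!okn)) skip <- skip + sum(!okn)
        if (any(okn)) {
          np <- np[okn]; r <- r[okn]
          ctx <- paste0(base_at(np - 1L), r, base_at(np + 1L))
          alt_g <- as.vector(ALT_TABLE[r, ])
          cat6 <- categorize_mutation(rep.int(r, 3L), alt_g, rep.int(ctx, 3L))
          pieces[[length(pieces) + 1L]] <- data.table(
            gene_id = gene$gene_id, chrom = chrom,
            pos = rep.int(np, 3L), alt = alt_g,
            zone = 3L, category = cat6, weight = 1 / 3)
        }
      }
    }
  }
  out <- if (length(pieces)) rbindlist(pieces) else {
    data.table(gene_id = character(), chrom = character(), pos = integer(),
               alt = character(), zone = integer(), category = integer(),
               weight = numeric())
  }
  setkeyv(out, c("chrom", "pos", "alt"))
  # deliberately a plain data.table (an extra S3 class would make every
  # as.data.table() call deep-copy this, the largest object in a run)
  data.table::setattr(out, "skip_log", skip)
  data.table::setattr(out, "gene_ids",
                      sort(unique(vapply(genes, `[[`, "", "gene_id"))))
  out[]
}

#' Check zone agreement between mutation calls and the gene model
#'
#' A gene is excluded (returns `FALSE`) iff any mutation position carries a
#' zone annotation in the MAF source that disagrees with the zone implied by
#' the coverage/gene model at the same position. A gene with no mutations
#' vacuously passes.
#'
#' @param gene a `gene_model` (used for reporting only).
#' @param maf_positions data.frame with columns `pos`, `zone` as annotated in
#'   the mutation source.
#' @param coverage_positions data.frame with columns `pos`, `zone` as implied
#'   by the gene model / coverage source.
#' @return logical scalar.
#' @export
validate_gene_consistency <- function(gene, maf_positions, coverage_positions) {
  a <- as.data.table(maf_positions)
  b <- as.data.table(coverage_positions)
  if (nrow(a) == 0L) return(TRUE)
  merged <- merge(a, b, by = "pos", suffixes = c("_maf", "_model"))
  if (nrow(merged) == 0L) return(TRUE)
  all(merged$zone_maf == merged$zone_model)
}
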