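# MAF-style mutation reading, zoning, filtering and count aggregation.

#' Default MAF column mapping (PCAWG/TCGA dialect)
#'
#' @param chrom,pos,ref,alt,patient,gene,variant_class column names in the
#'   input file; `variant_class` is optional (set to `NULL` if absent) and is
#'   only used to flag null-type events (nonsense/splice) into category 7.
#' @return named list of column names.
#' @export
maf_columns <- function(chrom = "Chromosome", pos = "Start_position",
                        ref = "Reference_Allele", alt = "Tumor_Seq_Allele2",
                        patient = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
                        variant_class = "Variant_Classification") {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt, patient = patient,
       gene = gene, variant_class = variant_class)
}

# MAF variant classifications treated as null-type (category 7) even for SNVs
NULL_CLASSES <- c("Nonsense_Mutation", "Nonstop_Mutation", "Splice_Site",
                  "Translation_Start_Site")

#' Read a MAF-style tab-delimited mutation file
#'
#' Multi-allelic rows (comma-separated alternate alleles) are split into one
#' record per allele. When `gene_ids` is given, records whose gene is not in
#' the analyzable set are retained but flagged `unmapped` (they are excluded
#' from all downstream tensors).
#'
#' @param path MAF file path.
#' @param columns column mapping from [maf_columns()].
#' @param gene_ids optional character vector of analyzable gene ids.
#' @return data.table with columns patient_id, gene_id, chrom, pos, ref, alt,
#'   variant_class, unmapped.
#' @export
read_maf <- function(path, columns = maf_columns(), gene_ids = NULL) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  mandatory <- c("chrom", "pos", "ref", "alt", "patient", "gene")
  for (key in mandatory) {
    if (!columns[[key]] %in% names(raw)) {
      stop_synsig("MAF is missing mandatory column '%s' (mapped as '%s')",
                  columns[[key]], key, class = "synsig_config_error")
    }
  }
  vc <- if (!is.null(columns$variant_class) &&
            columns$variant_class %in% names(raw)) {
    as.character(raw[[columns$variant_class]])
  } else {
    rep(NA_character_, nrow(raw))
  }
  muts <- data.table(
    patient_id = as.character(raw[[columns$patient]]),
    gene_id = as.character(raw[[columns$gene]]),
    chrom = norm_chrom(raw[[columns$chrom]]),
    pos = as.integer(raw[[columns$pos]]),
    ref = toupper(as.character(raw[[columns$ref]])),
    alt = toupper(as.character(raw[[columns$alt]])),
    variant_class = vc
  )
  # split multi-allelic rows: category is per-substitution
  if (any(grepl(",", muts$alt, fixed = TRUE))) {
    alts <- strsplit(muts$alt, ",", fixed = TRUE)
    muts <- muts[rep(seq_len(.N), lengths(alts))]
    muts[, alt := unlist(alts)]
  }
  muts[, unmapped := if (is.null(gene_ids)) FALSE else !(gene_id %in% gene_ids)]
  muts[]
}

#' Assign effect zones and mutation categories to mutation records
#'
#' SNVs are zoned and categorized by lookup in the site-effect table (so zone
#' assignment is consistent with the coverage model by construction). Indels
#' and null-flagged records are category 7; their zone is the zone class of
#' their position (coding positions map to the nonsynonymous zone). Records
#' at positions absent from every gene's transcript territory (intergenic,
#' promoter, up-/downstream) get `zone = 0` ("excluded").
#'
#' @param mutations data.table from [read_maf()].
#' @param site_effects table from [enumerate_site_effects()].
#' @return the mutations with added integer columns `zone`
#'   (0=excluded, 1=synonymous, 2=nonsynonymous, 3=noncoding) and `category`
#'   (1-7), and gene_id replaced by the site-table gene when mapped by
#'   position.
#' @export
annotate_mutations <- function(mutations, site_effects) {
  muts <- copy(as_dt(mutations))
  if (!"variant_class" %in% names(muts)) muts[, variant_class := NA_character_]
  if (!"unmapped" %in% names(muts)) muts[, unmapped := FALSE]
  se <- as_dt(site_effects)
  is_snv <- is_single_base(muts$ref) & is_single_base(muts$alt)
  is_null <- !is.na(muts$variant_class) & muts$variant_class %in% NULL_CLASSES

  # per-allele lookup for SNVs
  hit <- se[muts[, .(chrom, pos, alt)], on = c("chrom", "pos", "alt"),
            mult = "first", .(gene_hit = gene_id, zone_hit = zone, cat_hit = category)]
  # position-level zone class (any allele at the position), for indels/null
  pos_hit <- se[muts[, .(chrom, pos)], on = c("chrom", "pos"), mult = "first",
                .(gene_pos = gene_id, zone_pos = zone)]
  pos_zone <- data.table::fifelse(is.na(pos_hit$zone_pos), 0L,
                                  data.table::fifelse(pos_hit$zone_pos == 3L, 3L, 2L))

  muts[, category := 7L]
  muts[is_snv & !is_null, category := data.table::fifelse(
    is.na(hit$cat_hit[is_snv & !is_null]), 7L, hit$cat_hit[is_snv & !is_null])]
  # category for unmapped-position SNVs will not matter (zone excluded), but
  # compute indel vs snv correctly: SNVs keep their table category when found.
  muts[, zone := 0L]
  snv_zone <- data.table::fifelse(is.na(hit$zone_hit), 0L, hit$zone_hit)
  muts[is_snv & !is_null, zone := snv_zone[is_snv & !is_null]]
  muts[!(is_snv & !is_null), zone := pos_zone[!(is_snv & !is_null)]]
  # adopt the gene that owns the position (robust to synonym drift in MAFs)
  owner <- data.table::fifelse(is.na(hit$gene_hit), pos_hit$gene_pos, hit$gene_hit)
  muts[!is.na(owner), gene_id := owner[!is.na(owner)]]
  muts[!is.na(owner), unmapped := FALSE]
  muts[]
}

#' Remove hypermutator patients
#'
#' Patients whose total mutation count (all rows, every type) exceeds the
#' threshold are removed. The count deliberately includes all mutation types;
#' the source convention does not specify SNV-only counting, and the choice
#' is logged in the report.
#'
#' @param manifest data.frame with columns patient_id, cohort.
#' @param mutations mutation records (one row per mutation).
#' @param threshold exclusion threshold; a patient is removed iff
#'   count > threshold (strictly greater). Default 50000.
#' @return list with `manifest` (retained patients) and `report` (data.table
#'   patient_id, n_mutations, excluded).
#' @export
filter_hypermutators <- function(manifest, mutations, threshold = 50000L) {
  manifest <- as.data.table(manifest)
  counts <- as_dt(mutations)[, .(n_mutations = .N), by = patient_id]
  report <- merge(manifest[, .(patient_id)], counts, by = "patient_id",
                  all.x = TRUE)
  report[is.na(n_mutations), n_mutations := 0L]
  report[, excluded := n_mutations > threshold]
  list(manifest = manifest[!patient_id %in% report[excluded == TRUE, patient_id]],
       report = report[])
}

#' Drop mutations outside transcribed regions
#'
#' Mutations in intergenic, promoter, or up-/downstream regions (any position
#' absent from every gene's coding/intron/UTR territory, `zone == 0`) are
#' removed, as are records flagged `unmapped`. Intronic and UTR mutations are
#' retained as noncoding.
#'
#' @param mutations annotated records from [annotate_mutations()].
#' @return filtered data.table with attribute `n_excluded`.
#' @export
filter_nontranscribed <- function(mutations) {
  muts <- as_dt(mutations)
  drop <- muts$zone == 0L | muts$unmapped
  out <- muts[!drop]
  data.table::setattr(out, "n_excluded", sum(drop))
  out[]
}

#' Aggregate mutation records into a count tensor
#'
#' @param mutations annotated, filtered mutation records.
#' @param gene_ids character vector defining the gene axis.
#' @param patients character vector defining the patient axis.
#' @return 4-d integer array `[gene, category(1..7, total), patient, zone]`
#'   with the total slot equal to the sum over categories 1-7.
#' @export
build_count_tensor <- function(mutations, gene_ids, patients) {
  muts <- as_dt(mutations)
  muts <- muts[zone %in% 1:3 & gene_id %in% gene_ids & patient_id %in% patients]
  tensor <- array(0L, dim = c(length(gene_ids), 8L, length(patients), 3L),
                  dimnames = list(gene_ids, CATEGORY_LEVELS, patients, ZONES))
  if (nrow(muts) > 0L) {
    agg <- muts[, .N, by = .(gene_id, category, patient_id, zone)]
    tensor[cbind(match(agg$gene_id, gene_ids), agg$category,
                 match(agg$patient_id, patients), agg$zone)] <- agg$N
  }
  tensor[, 8L, , ] <- apply(tensor[, 1:7, , , drop = FALSE], c(1, 3, 4), sum)
  class(tensor) <- c("count_tensor", class(tensor))
  tensor
}
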