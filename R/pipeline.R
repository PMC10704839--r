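# End-to-end per-cohort pipeline:
# annotation -> mutations -> coverage -> background -> significance -> FDR.

#' Pipeline run configuration
#'
#' @param maf,annotation,genome,covariates,expression,manifest input paths
#'   (see the reader functions for formats).
#' @param principal optional principal-transcript mapping TSV.
#' @param synonyms optional covariate synonym mapping TSV.
#' @param wig_dir optional directory of per-patient `<patient>.wig` masks;
#'   patients without a file get full coverage.
#' @param mode target zone: `"synonymous"` (default) or `"nonsynonymous"`
#'   (quality-control mode; swaps the target zone and defaults the FDR method
#'   to Benjamini-Hochberg).
#' @param fdr_method `"bayes"` or `"bh"`; defaults to bayes in synonymous
#'   mode, bh in nonsynonymous mode.
#' @param cohort optional cohort label to select from the manifest (default:
#'   all patients).
#' @param hypermutator_threshold patient exclusion threshold (default 50000).
#' @param p_cutoff evaluate Fdr only for p below this (default 0.05).
#' @param fdr_threshold candidate threshold (default 1e-2).
#' @param p0 prior null probability for the Bayesian FDR (default 0.99).
#' @param bagel_max_neighbors,bagel_threshold,bagel_max_coverage bagel
#'   construction knobs.
#' @param bin_width,score_cap score discretization knobs.
#' @param exclude overlap-exclusion gene list applied to candidates.
#' @param null_min_genes minimum size of the FDR null gene class (default 30).
#' @param out_dir optional output directory for result TSVs.
#' @param seed seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(maf, annotation, genome, covariates, expression,
                       manifest, principal = NULL, synonyms = NULL,
                       wig_dir = NULL,
                       mode = c("synonymous", "nonsynonymous"),
                       fdr_method = NULL, cohort = NULL,
                       hypermutator_threshold = 50000L,
                       p_cutoff = 0.05, fdr_threshold = 1e-2, p0 = 0.99,
                       bagel_max_neighbors = 50L, bagel_threshold = 0.05,
                       bagel_max_coverage = Inf,
                       bin_width = 0.1, score_cap = 250,
                       exclude = character(), null_min_genes = 30L,
                       out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(fdr_method)) {
    fdr_method <- if (mode == "synonymous") "bayes" else "bh"
  }
  fdr_method <- match.arg(fdr_method, c("bayes", "bh"))
  paths <- list(maf = maf, annotation = annotation, genome = genome,
                covariates = covariates, expression = expression,
                manifest = manifest)
  for (nm in names(paths)) {
    if (!is.character(paths[[nm]]) || !file.exists(paths[[nm]])) {
      stop_synsig("run_config: input '%s' does not exist: %s", nm,
                  paths[[nm]], class = "synsig_config_error")
    }
  }
  cfg <- as.list(environment())
  cfg$paths <- NULL
  class(cfg) <- "run_config"
  cfg
}

# align a covariate table to the analyzed gene axis, mean-imputing genes the
# table does not cover
align_covariates <- function(covariates, gene_ids) {
  cov <- as.data.table(covariates)
  num_cols <- setdiff(names(cov)[vapply(cov, is.numeric, TRUE)], "imputed")
  out <- data.table(gene_id = gene_ids)
  cov <- cov[match(gene_ids, cov[[1L]])]
  for (cc in num_cols) {
    v <- cov[[cc]]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    out[[cc]] <- v
  }
  out
}

#' Core cohort analysis on in-memory objects
#'
#' The computational heart of [run_cohort()]: takes already-loaded inputs and
#' produces per-gene results and candidates. Exposed so that simulation
#' studies can re-analyze replicates without file round-trips.
#'
#' @param mutations data.table of mutation records (as from [read_maf()]).
#' @param site_effects table from [enumerate_site_effects()].
#' @param manifest data.table(patient_id, cohort).
#' @param covariates covariate table (gene + numeric columns).
#' @param expression expression table (gene, cohort, fpkm; or wide).
#' @param masks named list of coverage masks or `NULL`.
#' @param mode,fdr_method,params see [run_config()]; `params` is a named list
#'   overriding the defaults (hypermutator_threshold, p_cutoff,
#'   fdr_threshold, p0, bagel_max_neighbors, bagel_threshold,
#'   bagel_max_coverage, bin_width, score_cap, exclude, null_min_genes).
#' @return list(results, candidates, marginals, backgrounds, hypermutators,
#'   n_excluded_nontranscribed).
#' @export
analyze_cohort <- function(mutations, site_effects, manifest, covariates,
                           expression, masks = NULL,
                           mode = c("synonymous", "nonsynonymous"),
                           fdr_method = c("bayes", "bh"), params = list()) {
  mode <- match.arg(mode)
  fdr_method <- match.arg(fdr_method)
  prm <- utils::modifyList(list(
    hypermutator_threshold = 50000L, p_cutoff = 0.05, fdr_threshold = 1e-2,
    p0 = 0.99, bagel_max_neighbors = 50L, bagel_threshold = 0.05,
    bagel_max_coverage = Inf, bin_width = 0.1, score_cap = 250,
    exclude = character(), null_min_genes = 30L, F0_hat = NULL), params)

  gene_ids <- attr(site_effects, "gene_ids", exact = TRUE) %||%
    sort(unique(site_effects$gene_id))
  # annotate_mutations copies its input and defaults missing columns
  muts <- annotate_mutations(mutations, site_effects)

  hf <- filter_hypermutators(manifest, muts, prm$hypermutator_threshold)
  patients <- hf$manifest$patient_id
  muts <- muts[patient_id %in% patients]
  muts <- filter_nontranscribed(muts)
  n_excl <- attr(muts, "n_excluded")

  counts <- build_count_tensor(muts, gene_ids, patients)
  coverage <- build_coverage_tensor(site_effects, masks, patients, gene_ids)

  marginals <- compute_marginals(counts, coverage)
  backgrounds <- raw_background_table(counts, coverage)
  distances <- covariate_distance_matrix(align_covariates(covariates, gene_ids))
  bagels <- build_all_bagels(distances, backgrounds,
                             max_neighbors = prm$bagel_max_neighbors,
                             threshold = prm$bagel_threshold,
                             max_coverage = prm$bagel_max_coverage)

  results <- run_significance(counts, coverage, bagels, marginals,
                              mode = mode, bin_width = prm$bin_width,
                              score_cap = prm$score_cap)

  if (fdr_method == "bayes") {
    # F0 may be supplied prefit (e.g. pooled across cohorts, the stated
    # estimation design); otherwise it is fit on this cohort's null class.
    F0 <- prm$F0_hat
    if (is.null(F0)) {
      nulls <- select_null_genes(expression, gene_ids)
      null_p <- results[gene_id %in% nulls, p_value]
      F0 <- kernel_cdf(null_p, min_n = prm$null_min_genes)
    }
    Fm <- kernel_cdf(results$p_value, min_n = prm$null_min_genes)
    results <- bayes_fdr(results, F0, Fm, p0 = prm$p0,
                         p_cutoff = prm$p_cutoff)
  } else {
    results[, fdr := benjamini_hochberg(p_value)]
  }
  candidates <- call_candidates(results, prm$fdr_threshold, prm$exclude)

  list(results = results, candidates = candidates, marginals = marginals,
       backgrounds = backgrounds, bagels = bagels,
       hypermutators = hf$report[excluded == TRUE],
       n_excluded_nontranscribed = n_excl)
}

#' Run the full pipeline for one cohort from input files
#'
#' Executes annotation loading, mutation reading/filtering, coverage,
#' background model, significance, and FDR in order; deterministic given the
#' configuration. When `out_dir` is set, writes `results.tsv` and
#' `candidates.tsv` with a provenance header (package version, config hash).
#'
#' @param config a [run_config()].
#' @return as [analyze_cohort()], plus `$config`.
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genes <- load_gene_models(config$annotation, config$principal)
  if (length(genes) == 0L) stop_synsig("no analyzable genes in the annotation")
  genome <- load_genome(config$genome)
  se <- enumerate_site_effects(genes, genome)

  manifest <- read_tsv(config$manifest)
  setnames(manifest, names(manifest)[1:2], c("patient_id", "cohort"))
  if (!is.null(config$cohort)) manifest <- manifest[cohort == config$cohort]
  if (nrow(manifest) == 0L) stop_synsig("no patients selected from the manifest")

  muts <- read_maf(config$maf, gene_ids = names(genes))
  muts <- muts[patient_id %in% manifest$patient_id]

  masks <- NULL
  if (!is.null(config$wig_dir) && dir.exists(config$wig_dir)) {
    wigs <- list.files(config$wig_dir, pattern = "\\.wig$", full.names = TRUE)
    masks <- lapply(wigs, parse_wig)
    names(masks) <- sub("\\.wig$", "", basename(wigs))
  }

  covariates <- read_covariates(config$covariates, config$synonyms)
  expression <- read_tsv(config$expression)

  out <- analyze_cohort(
    muts, se, manifest, covariates, expression, masks,
    mode = config$mode, fdr_method = config$fdr_method,
    params = config[c("hypermutator_threshold", "p_cutoff", "fdr_threshold",
                      "p0", "bagel_max_neighbors", "bagel_threshold",
                      "bagel_max_coverage", "bin_width", "score_cap",
                      "exclude", "null_min_genes")])
  out$config <- config

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- sprintf("mode=%s fdr=%s seed=%d config_hash=%s",
                    config$mode, config$fdr_method, config$seed,
                    config_hash(unclass(config)))
    write_tsv_provenance(out$results,
                         file.path(config$out_dir, "results.tsv"), prov)
    write_tsv_provenance(out$candidates,
                         file.path(config$out_dir, "candidates.tsv"), prov)
  }
  out
}
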