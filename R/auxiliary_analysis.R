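# Cohort heterogeneity descriptives: per-patient synonymous rates, category
# composition, and sliding-window chromosome mutation profiles.

#' Megabases of covered synonymous sites per patient
#'
#' Each (position, alternate allele) pair whose consequence is synonymous
#' counts 1/3 bp when covered. Computed from the site-effect table and the
#' patients' coverage masks (independently of the coverage tensor).
#'
#' @param site_effects table from [enumerate_site_effects()].
#' @param masks named list (patient -> `coverage_mask`), entries may be
#'   missing/`NULL` for fully covered patients.
#' @param patients character vector of patient ids.
#' @return named numeric vector of synonymous megabases per patient.
#' @export
synonymous_sites_mbp <- function(site_effects, masks = NULL, patients) {
  se <- as_dt(site_effects)[zone == 1L]
  full <- sum(se$weight)
  out <- stats::setNames(rep(full, length(patients)), patients)
  for (p in patients) {
    mask <- masks[[p]]
    if (is.null(mask)) next
    unc <- uncovered_positions(mask)
    if (length(unc) == 0L) next
    drop <- se[data.table::rbindlist(lapply(names(unc), function(ch) {
      data.table(chrom = ch, pos = unc[[ch]])
    })), on = c("chrom", "pos"), nomatch = NULL]
    out[p] <- full - sum(drop$weight)
  }
  out / 1e6
}

#' Per-patient synonymous mutation rate
#'
#' Rate = count / Mbp of covered synonymous sites; patients with zero
#' synonymous mutations are assigned 0.01 per Mbp (so the log10-transformed
#' rate is -2).
#'
#' @param count synonymous mutation count (vectorized).
#' @param mbp synonymous site megabases (vectorized; must be > 0).
#' @return rate per Mbp.
#' @export
patient_synonymous_rate <- function(count, mbp) {
  if (any(mbp <= 0)) {
    stop_synsig("synonymous rate undefined: zero synonymous site coverage")
  }
  rate <- count / mbp
  rate[count == 0] <- 0.01
  rate
}

#' Per-patient category composition of synonymous mutations
#'
#' @param mutations annotated mutation records (synonymous-zone rows are
#'   selected internally).
#' @param patients patient axis.
#' @return matrix (patients x categories 1-6) of fractions summing to 1 per
#'   patient; all-NA rows for patients with no synonymous mutations.
#' @export
category_fractions <- function(mutations, patients) {
  muts <- as_dt(mutations)[zone == 1L & category %in% 1:6 &
                                     patient_id %in% patients]
  out <- matrix(NA_real_, length(patients), 6L,
                dimnames = list(patients, as.character(1:6)))
  if (nrow(muts) > 0L) {
    agg <- muts[, .N, by = .(patient_id, category)]
    out[unique(agg$patient_id), ] <- 0
    out[cbind(match(agg$patient_id, patients), agg$category)] <- agg$N
    rs <- rowSums(out)
    nz <- !is.na(rs) & rs > 0
    out[nz, ] <- out[nz, , drop = FALSE] / rs[nz]
  }
  out
}

#' Sliding 1-Mbp window mutation profile along a chromosome
#'
#' For each base-pair window start s, the number of cohort mutations in
#' `[s, s + window)` divided by the cohort size. Implemented with prefix sums
#' (linear in chromosome length + mutations); window reported at its start.
#'
#' @param mutations data.frame with columns chrom, pos.
#' @param chrom chromosome to profile.
#' @param chrom_length chromosome length in bp.
#' @param window window width in bp (default 1e6).
#' @param n_patients cohort size used for averaging.
#' @return numeric vector of length `chrom_length` (window starts 1..L;
#'   windows are clipped at the chromosome end).
#' @export
sliding_window_profile <- function(mutations, chrom, chrom_length,
                                   window = 1e6, n_patients = 1L) {
  muts <- as_dt(mutations)
  pos <- muts[norm_chrom(muts$chrom) == norm_chrom(chrom), pos]
  pos <- pos[pos >= 1L & pos <= chrom_length]
  counts <- tabulate(pos, nbins = chrom_length)
  cs <- c(0, cumsum(counts))
  starts <- seq_len(chrom_length)
  ends <- pmin(starts + window - 1, chrom_length)
  (cs[ends + 1] - cs[starts]) / n_patients
}
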