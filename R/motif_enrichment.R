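# Permutation test for clustering of a gene's mutations within annotated
# protein motifs (e.g. the BH4 domain of an anti-apoptotic regulator).
#
# Each permutation places every mutation independently and uniformly (with
# replacement) over the gene's CDS positions and records the in-motif count.
# The p-value is the fraction of permutations with count strictly greater
# than observed, with no pseudocount -- exactly the source convention, even
# though it can return p = 0; interpret small values accordingly.

#' Read a motif annotation table
#'
#' @param path TSV with columns gene, motif, start, end, where start/end are
#'   0-based half-open nucleotide offsets within the CDS (external
#'   convention; converted to 1-based internally), or an equivalent
#'   data.frame.
#' @return data.table (gene, motif, start, end) with 1-based closed
#'   coordinates.
#' @export
read_motifs <- function(path) {
  mt <- if (is.character(path)) read_tsv(path) else as.data.table(path)
  setnames(mt, names(mt)[1:4], c("gene", "motif", "start", "end"))
  mt[, `:=`(start = as.integer(start) + 1L, end = as.integer(end))]
  mt[]
}

#' Permutation test for mutation enrichment in a motif
#'
#' @param n_mutations number of mutations to place per permutation.
#' @param cds_length CDS length in nucleotides (> 0).
#' @param motif motif intervals within the CDS: data.frame with 1-based
#'   closed `start`/`end` columns (as from [read_motifs()]) or an
#'   [IRanges::IRanges].
#' @param observed_count observed in-motif mutation count.
#' @param n_perm number of permutations (default 10000).
#' @param seed mandatory RNG seed (the caller's RNG state is restored).
#' @return `perm_result`: list(observed, perm_counts, p_value, n_perm, seed);
#'   p_value = #(perm count > observed) / n_perm.
#' @export
motif_permutation_test <- function(n_mutations, cds_length, motif,
                                   observed_count, n_perm = 10000L, seed) {
  if (missing(seed)) stop_synsig("motif_permutation_test: seed is mandatory")
  if (cds_length <= 0) stop_synsig("cds_length must be > 0")
  if (n_perm < 1) stop_synsig("n_perm must be >= 1")
  iv <- if (inherits(motif, "IRanges")) {
    data.table(start = IRanges::start(motif), end = IRanges::end(motif))
  } else {
    as.data.table(motif)[, .(start, end)]
  }
  if (any(iv$start < 1L) || any(iv$end > cds_length) || any(iv$end < iv$start)) {
    stop_synsig("motif intervals fall outside the CDS [1, %d]", cds_length)
  }
  in_motif <- logical(cds_length)
  for (i in seq_len(nrow(iv))) in_motif[iv$start[i]:iv$end[i]] <- TRUE

  counts <- with_seed(seed, {
    draws <- sample.int(cds_length, n_perm * n_mutations, replace = TRUE)
    hits <- in_motif[draws]
    as.integer(rowSums(matrix(hits, nrow = n_perm, byrow = TRUE)))
  })
  structure(list(observed = observed_count,
                 perm_counts = counts,
                 p_value = mean(counts > observed_count),
                 n_perm = as.integer(n_perm),
                 seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> observed = %d, %d permutations, p = %.4g (strict >, no pseudocount)\n",
              x$observed, x$n_perm, x$p_value))
  invisible(x)
}
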