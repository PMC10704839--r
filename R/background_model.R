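# Non-coding background model.
#
# Each gene's raw background is its non-coding mutation count and coverage
# summed over patients (total category slot). Genes with similar covariates
# (expression, replication timing, chromatin compartment) are pooled into a
# "bagel": neighbours are visited in increasing standardized-Euclidean
# covariate distance and added while a beta-binomial predictive test finds
# their non-coding rate compatible with the target's, stopping at the first
# disqualification or a size cap. Cohort marginal factors rho_c (category)
# and rho_p (patient) then distribute the bagel rate over categories and
# patients, and a beta-binomial predictive with +1 pseudocounts yields the
# probability of observing 0, 1, or 2+ target-zone mutations per
# (gene, category, patient).

#' Read a gene covariate table, applying a synonym mapping
#'
#' @param path TSV with columns gene and three numeric covariates
#'   (expression, replication timing, chromatin compartment), or an
#'   equivalent data.frame.
#' @param synonyms optional synonym mapping: TSV path or data.frame with
#'   columns old_name, new_name; covariate rows are renamed before use.
#' @return data.table keyed by gene with numeric covariate columns; missing
#'   values are imputed to the covariate mean and flagged in the `imputed`
#'   column.
#' @export
read_covariates <- function(path, synonyms = NULL) {
  cov <- if (is.character(path)) read_tsv(path) else as.data.table(path)
  setnames(cov, names(cov)[1L], "gene_id")
  cov[, gene_id := as.character(gene_id)]
  if (!is.null(synonyms)) {
    syn <- if (is.character(synonyms)) read_tsv(synonyms) else as.data.table(synonyms)
    map <- stats::setNames(as.character(syn[[2L]]), as.character(syn[[1L]]))
    hit <- cov$gene_id %in% names(map)
    cov[hit, gene_id := unname(map[gene_id])]
  }
  num_cols <- names(cov)[vapply(cov, is.numeric, TRUE)]
  if (length(num_cols) == 0L) {
    stop_synsig("covariate table has no numeric covariate columns",
                class = "synsig_config_error")
  }
  cov[, imputed := FALSE]
  for (cc in num_cols) {
    miss <- is.na(cov[[cc]])
    if (all(miss)) {
      stop_synsig("covariate column '%s' is entirely missing", cc,
                  class = "synsig_config_error")
    }
    if (any(miss)) {
      data.table::set(cov, which(miss), cc, mean(cov[[cc]], na.rm = TRUE))
      cov[miss, imputed := TRUE]
    }
  }
  cov[]
}

#' Pairwise covariate distances between genes
#'
#' Euclidean distance on per-covariate standardized (zero mean, unit
#' variance) values, so unequal covariate scales do not dominate.
#'
#' @param covariates data.table/data.frame with a gene id column and numeric
#'   covariate columns (as from [read_covariates()]).
#' @return symmetric distance matrix with gene dimnames.
#' @export
covariate_distance_matrix <- function(covariates) {
  cov <- as.data.table(covariates)
  genes <- as.character(cov[[1L]])
  if (length(genes) < 2L) {
    stop_synsig("need at least 2 genes for a distance matrix")
  }
  num_cols <- setdiff(names(cov)[vapply(cov, is.numeric, TRUE)], "imputed")
  m <- as.matrix(cov[, num_cols, with = FALSE])
  sds <- apply(m, 2L, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  m <- sweep(sweep(m, 2L, colMeans(m)), 2L, sds, "/")
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(genes, genes)
  d
}

#' Raw non-coding background for one gene
#'
#' Sums the total-category non-coding mutation count and coverage over all
#' patients.
#'
#' @param counts count tensor from [build_count_tensor()].
#' @param coverage coverage tensor from [build_coverage_tensor()].
#' @param gene gene id.
#' @return list with `n_bkgd` and `N_bkgd`.
#' @export
raw_background <- function(counts, coverage, gene) {
  if (!gene %in% dimnames(counts)[[1L]] || !gene %in% dimnames(coverage)[[1L]]) {
    stop_synsig("gene '%s' absent from the cohort tensors", gene)
  }
  list(n_bkgd = sum(counts[gene, "total", , "noncoding"]),
       N_bkgd = sum(coverage[gene, "total", , "noncoding"]))
}

raw_background_table <- function(counts, coverage) {
  genes <- dimnames(counts)[[1L]]
  data.table(
    gene_id = genes,
    n_bkgd = apply(counts[, "total", , "noncoding", drop = FALSE], 1L, sum),
    N_bkgd = apply(coverage[, "total", , "noncoding", drop = FALSE], 1L, sum)
  )
}

# Beta-binomial predictive pmf/cdf helpers (log-space, +1 pseudocounts come
# from the caller through a/b).
dbetabinom_ab <- function(k, n, a, b, log = FALSE) {
  out <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  out[k < 0 | k > n] <- -Inf
  if (log) out else exp(out)
}

pbetabinom_lower <- function(k, n, a, b) {
  if (k < 0) return(0)
  k <- min(k, n)
  if (k <= n - k) {
    sum(dbetabinom_ab(0:k, n, a, b))
  } else {
    1 - sum(dbetabinom_ab(seq.int(k + 1L, n), n, a, b))
  }
}

#' Beta-binomial bagel qualification test
#'
#' Tests whether a candidate neighbour's non-coding mutation count is
#' compatible with the target gene's background rate: the neighbour count is
#' referred to the predictive distribution BetaBinomial(N_neighbour,
#' n_target + 1, N_target - n_target + 1) and qualifies iff the two-sided
#' tail probability (2 * min(lower, upper), capped at 1) is at least
#' `threshold`.
#'
#' @param target,neighbor numeric length-2 vectors or lists `(n, N)`.
#' @param threshold qualification threshold, default 0.05.
#' @return logical scalar.
#' @export
qualify_neighbor <- function(target, neighbor, threshold = 0.05) {
  tn <- unlist(target)[1:2]; nb <- unlist(neighbor)[1:2]
  if (nb[2L] <= 0 || tn[2L] <= 0) return(FALSE)
  a <- tn[1L] + 1
  b <- tn[2L] - tn[1L] + 1
  n <- round(nb[2L])
  k <- round(nb[1L])
  lower <- pbetabinom_lower(k, n, a, b)
  upper <- 1 - (if (k >= 1) pbetabinom_lower(k - 1L, n, a, b) else 0)
  min(1, 2 * min(lower, upper)) >= threshold
}

#' Build a gene's covariate bagel and aggregated background
#'
#' Neighbours are visited in increasing covariate distance; each qualifying
#' neighbour is added until the first disqualification, the neighbour cap, or
#' the coverage cap. The aggregated background is the sum of the target's and
#' all bagel members' raw non-coding counts/coverage.
#'
#' @param gene target gene id.
#' @param distances distance matrix from [covariate_distance_matrix()].
#' @param backgrounds data.table (gene_id, n_bkgd, N_bkgd) of raw backgrounds.
#' @param max_neighbors neighbour cap (default 50).
#' @param threshold qualification threshold (default 0.05).
#' @param max_coverage optional cap on aggregated coverage X (default Inf).
#' @return `gene_background`: list(gene_id, n_bkgd, N_bkgd, bagel, x, X).
#' @export
build_bagel <- function(gene, distances, backgrounds, max_neighbors = 50L,
                        threshold = 0.05, max_coverage = Inf) {
  bg <- as.data.table(backgrounds)
  self <- bg[gene_id == gene]
  if (nrow(self) != 1L) stop_synsig("gene '%s' absent from backgrounds", gene)
  n0 <- self$n_bkgd; N0 <- self$N_bkgd
  x <- n0; X <- N0
  bagel <- character()
  if (gene %in% rownames(distances)) {
    dvec <- distances[gene, ]
    cand <- names(sort(dvec[names(dvec) != gene]))
    cand <- cand[cand %in% bg$gene_id]
    bgm <- bg[match(cand, gene_id)]
    for (i in seq_along(cand)) {
      if (length(bagel) >= max_neighbors) break
      nb <- c(bgm$n_bkgd[i], bgm$N_bkgd[i])
      if (!qualify_neighbor(c(n0, N0), nb, threshold)) break
      if (X + nb[2L] > max_coverage) break
      bagel <- c(bagel, cand[i])
      x <- x + nb[1L]
      X <- X + nb[2L]
    }
  }
  structure(list(gene_id = gene, n_bkgd = n0, N_bkgd = N0,
                 bagel = bagel, x = x, X = X),
            class = "gene_background")
}

build_all_bagels <- function(distances, backgrounds, max_neighbors = 50L,
                             threshold = 0.05, max_coverage = Inf) {
  # vectorized equivalent of lapply(genes, build_bagel, ...): plain named
  # vectors instead of per-gene data.table subsets
  bg <- as.data.table(backgrounds)
  n_vec <- stats::setNames(bg$n_bkgd, bg$gene_id)
  N_vec <- stats::setNames(bg$N_bkgd, bg$gene_id)
  out <- vector("list", nrow(bg))
  names(out) <- bg$gene_id
  for (g in bg$gene_id) {
    n0 <- n_vec[[g]]; N0 <- N_vec[[g]]
    x <- n0; X <- N0
    bagel <- character()
    if (g %in% rownames(distances)) {
      dvec <- distances[g, ]
      cand <- names(dvec)[order(dvec)]
      cand <- cand[cand != g & cand %in% bg$gene_id]
      for (nb in cand) {
        if (length(bagel) >= max_neighbors) break
        if (!qualify_neighbor(c(n0, N0), c(n_vec[[nb]], N_vec[[nb]]),
                              threshold)) break
        if (X + N_vec[[nb]] > max_coverage) break
        bagel <- c(bagel, nb)
        x <- x + n_vec[[nb]]
        X <- X + N_vec[[nb]]
      }
    }
    out[[g]] <- structure(list(gene_id = g, n_bkgd = n0, N_bkgd = N0,
                               bagel = bagel, x = x, X = X),
                          class = "gene_background")
  }
  out
}

#' Cohort marginal relative mutation rates
#'
#' Per-category and per-patient relative rate factors computed from all
#' mutations (synonymous, non-synonymous, and non-coding) and all-zone
#' coverage within one histology cohort: rho = (count/coverage in the slice)
#' divided by (total count / total coverage). The SNV-coverage-weighted mean
#' of rho_c over categories 1-6 and the coverage-weighted mean of rho_p are 1
#' by construction.
#'
#' @param counts count tensor.
#' @param coverage coverage tensor.
#' @return list(rho_c (length 7, names "1".."7"), rho_p (named by patient)).
#' @export
compute_marginals <- function(counts, coverage) {
  # SNV categories (1-6) are referenced to SNV coverage only. The category-7
  # coverage bin equals the whole-gene territory (sum of categories 1-6), so
  # summing it together with categories 1-6 would double-count every site and
  # halve all rates; it is kept out of the denominators and category 7 gets
  # its own rate relative to the same SNV-average baseline.
  n_c <- vapply(1:7, function(c) sum(counts[, c, , ]), 0)
  N_c <- vapply(1:7, function(c) sum(coverage[, c, , ]), 0)
  if (sum(N_c[1:6]) <= 0) stop_synsig("zero total coverage; cannot compute marginals")
  overall_c <- sum(n_c[1:6]) / sum(N_c[1:6])
  rho_c <- if (overall_c > 0) {
    (n_c / pmax(N_c, .Machine$double.xmin)) / overall_c
  } else {
    rep(0, 7)
  }
  rho_c[N_c == 0] <- 0

  n_p <- apply(counts[, "total", , , drop = FALSE], 3L, sum)
  N_p <- apply(coverage[, "total", , , drop = FALSE], 3L, sum)
  overall_p <- sum(n_p) / sum(N_p)
  rho_p <- if (overall_p > 0) {
    (n_p / pmax(N_p, .Machine$double.xmin)) / overall_p
  } else {
    rep(0, length(n_p))
  }
  names(rho_c) <- as.character(1:7)
  names(rho_p) <- dimnames(counts)[[3L]]
  list(rho_c = rho_c, rho_p = rho_p)
}

#' Per-(category, patient) effective background for a gene
#'
#' Distributes a gene's bagel-aggregated background over categories and
#' patients with the cohort marginal factors: x_gcp = x_g * rho_c * rho_p
#' clamped to `[0, X_g]`; X_gcp = X_g.
#'
#' @param bg a `gene_background` from [build_bagel()].
#' @param marginals from [compute_marginals()].
#' @return list with matrix `x` (7 x patients) and scalar `X`.
#' @export
gcp_background <- function(bg, marginals) {
  x <- outer(marginals$rho_c, marginals$rho_p) * bg$x
  x <- pmin(pmax(x, 0), bg$X)
  list(x = x, X = bg$X)
}

#' Beta-binomial predictive probability mass function
#'
#' `H(k, N, x, X)`: probability of `k` mutations among `N` target sites when
#' the background produced `x` mutations over `X` sites, with +1
#' pseudocounts: `choose(N, k) * B(k + x + 1, N - k + X - x + 1) /
#' B(x + 1, X - x + 1)`, computed in log space. `N` is rounded to the nearest
#' integer to define the support (coverage is fractional in thirds).
#'
#' @param k observed count (vectorized).
#' @param N target-zone coverage.
#' @param x background count, `0 <= x <= X`.
#' @param X background coverage.
#' @return probability (vectorized over the longest argument).
#' @export
beta_binomial_pmf <- function(k, N, x, X) {
  if (any(k < 0) || any(N < 0) || any(x < 0) || any(X < x)) {
    stop_synsig("beta_binomial_pmf: arguments must satisfy k,N,x >= 0 and X >= x")
  }
  N <- round(N)
  dbetabinom_ab(k, N, x + 1, X - x + 1)
}

#' Per-(gene, category, patient) prior probabilities of 0/1/2+ mutations
#'
#' @param gcp from [gcp_background()].
#' @param target_coverage matrix (7 x patients) of target-zone coverage
#'   `N_{g,c,p}` (fractional sites; rounded internally).
#' @return list of matrices `P0`, `P1`, `P2plus`, each 7 x patients; the
#'   triplet sums to 1 (P2plus floored at 0).
#' @export
site_probabilities <- function(gcp, target_coverage) {
  # round fractional thirds to integer support, but never round positive
  # coverage down to zero sites: a bin holding a single 1/3-weight site must
  # still be able to carry an observed mutation (otherwise P(1) = 0 and one
  # real mutation yields an unbounded score)
  N <- round(target_coverage)
  N[target_coverage > 0 & N == 0] <- 1
  x <- gcp$x
  X <- gcp$X
  lb0 <- lbeta(x + 1, X - x + 1)
  P0 <- exp(lbeta(x + 1, N + X - x + 1) - lb0)
  P1 <- ifelse(N >= 1,
               exp(log(pmax(N, 1)) + lbeta(x + 2, N - 1 + X - x + 1) - lb0),
               0)
  P0 <- pmin(pmax(P0, 0), 1)
  P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmax(1 - P0 - P1, 0)  # first arg keeps the matrix dims
  list(P0 = P0, P1 = P1, P2plus = P2)
}
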