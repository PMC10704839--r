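# Projection-convolution significance.
#
# For one gene: per (category, patient) priors (P0, P1, P2+) are reduced to a
# per-patient distribution over 2D projected outcomes (d1, d2) -- the
# priority ranks of the two most extreme mutations, d = 0 meaning none.
# Categories are ranked per patient by mutation-proneness (P1 + P2+,
# descending; ties by ascending category index), so a larger rank d is a less
# mutation-prone, more surprising category. Outcome scores are
# -log10(outcome probability) with the no-mutation outcome fixed at score 0
# (the "null score boost" is 0). Per-patient score distributions are binned
# and convolved into the cohort null; the gene p-value is the null mass at
# bins >= the observed score's bin (inclusive, hence conservative).

#' Rank mutation categories by mutation-proneness for one patient
#'
#' @param priors list of matrices `P0`, `P1`, `P2plus` (category x patient)
#'   from [site_probabilities()], or vectors for a single patient.
#' @param patient column index or name (ignored for vector input).
#' @return integer vector of category indices, most mutation-prone first;
#'   ties broken by ascending category index.
#' @export
rank_categories <- function(priors, patient = 1L) {
  p1 <- priors$P1; p2 <- priors$P2plus
  if (is.matrix(p1)) { p1 <- p1[, patient]; p2 <- p2[, patient] }
  prone <- p1 + p2
  order(-prone, seq_along(prone))
}

# Fixed outcome layout for K ranked categories:
# row 1: (0,0); rows 2..K+1: (d,0); rows K+2..2K+1: (d,d);
# then (d1,d2) for d1 = 2..K, d2 = 1..(d1-1).
outcome_layout <- function(K) {
  d1 <- c(0L, seq_len(K), seq_len(K))
  d2 <- c(0L, rep.int(0L, K), seq_len(K))
  for (a in seq_len(K)[-1L]) {
    d1 <- c(d1, rep.int(a, a - 1L))
    d2 <- c(d2, seq_len(a - 1L))
  }
  list(d1 = d1, d2 = d2)
}

TINY <- 1e-300

# Vectorized projection over patients. S0, S1, S2: K x np matrices already
# sorted per patient so that row K is the most extreme (least prone) rank.
project_sorted <- function(S0, S1, S2) {
  K <- nrow(S0); np <- ncol(S0)
  S0c <- pmax(S0, TINY)
  suf <- if (K == 1L) S0c else {
    apply(S0c[K:1, , drop = FALSE], 2L, cumprod)[K:1, , drop = FALSE]
  }
  suf1 <- function(i) if (i <= K) suf[i, , drop = TRUE] else rep(1, np)
  lay <- outcome_layout(K)
  n_out <- length(lay$d1)
  P <- matrix(0, n_out, np)
  P[1L, ] <- suf[1L, ]
  for (d in seq_len(K)) {
    P[1L + d, ] <- S1[d, ] * suf[1L, ] / S0c[d, ]
    P[1L + K + d, ] <- S2[d, ] * suf1(d + 1L)
  }
  r <- 1L + 2L * K
  for (a in seq_len(K)[-1L]) {
    for (b in seq_len(a - 1L)) {
      r <- r + 1L
      # one mutation at rank a, none above, >=1 at rank b, none between
      P[r, ] <- S1[a, ] * suf1(a + 1L) * (1 - S0[b, ]) * (suf1(b + 1L) / suf[a, ])
    }
  }
  P
}

#' Project per-category priors into the 2D outcome distribution
#'
#' @param P0,P1,P2plus numeric vectors (one patient, one value per category).
#' @param priority category priority order from [rank_categories()] (most
#'   mutation-prone first); defaults to ranking the given priors.
#' @param score_cap per-patient score cap in -log10 units (default 250).
#' @return data.table with columns d1, d2 (priority ranks, 0 = no mutation),
#'   prob, score. Probabilities sum to 1; the (0,0) outcome has score 0.
#' @export
project_2d <- function(P0, P1, P2plus,
                       priority = order(-(P1 + P2plus), seq_along(P0)),
                       score_cap = 250) {
  K <- length(P0)
  # rank 1 = most prone = least extreme; row K = most extreme
  S0 <- matrix(P0[priority], K, 1L)
  S1 <- matrix(P1[priority], K, 1L)
  S2 <- matrix(P2plus[priority], K, 1L)
  P <- project_sorted(S0, S1, S2)[, 1L]
  lay <- outcome_layout(K)
  score <- pmin(-log10(pmax(P, TINY)), score_cap)
  score[1L] <- 0
  data.table(d1 = lay$d1, d2 = lay$d2, prob = P, score = score)
}

# convolve a binned distribution (bins 0..nb, overflow lumped at nb) with a
# set of outcome (bin, prob) pairs
conv_cap <- function(vec, bins, probs, nb) {
  new <- numeric(nb + 1L)
  for (j in seq_along(bins)) {
    q <- probs[j]
    if (q <= 0) next
    b <- bins[j]
    if (b == 0L) {
      new <- new + q * vec
    } else {
      len <- nb + 1L - b
      new[(b + 1L):(nb + 1L)] <- new[(b + 1L):(nb + 1L)] + q * vec[seq_len(len)]
      if (len < nb + 1L) {
        new[nb + 1L] <- new[nb + 1L] + q * sum(vec[(len + 1L):(nb + 1L)])
      }
    }
  }
  new
}

#' Convolve per-patient score distributions into the null score distribution
#'
#' Scores are binned at `bin_width` (bin b covers `[b*bw, (b+1)*bw)`) and
#' capped at `score_cap`; overflow mass is lumped at the cap bin. Mass is
#' conserved.
#'
#' @param patient_dists list of per-patient data.frames with columns `score`
#'   and `prob` (e.g. from [project_2d()]).
#' @param bin_width score bin width in -log10 units (default 0.1).
#' @param score_cap total score cap (default 250 * number of patients).
#' @return `null_score_distribution`: list(bin_width, mass (bins 0..nb),
#'   score = bin start values).
#' @export
convolve_null <- function(patient_dists, bin_width = 0.1,
                          score_cap = 250 * length(patient_dists)) {
  nb <- as.integer(ceiling(score_cap / bin_width))
  vec <- c(1, numeric(nb))
  for (pd in patient_dists) {
    bins <- pmin(as.integer(floor(pd$score / bin_width + 1e-9)), nb)
    vec <- conv_cap(vec, bins, pd$prob, nb)
  }
  structure(list(bin_width = bin_width, mass = vec,
                 score = bin_width * (0:nb)),
            class = "null_score_distribution")
}

#' Gene p-value from observed per-patient scores and a null distribution
#'
#' @param observed_scores numeric vector of per-patient observed outcome
#'   scores (0 for patients with no target-zone mutation), or a single total.
#' @param null a `null_score_distribution` from [convolve_null()].
#' @return list(score = total observed score, p_value = null mass at bins
#'   >= the observed bin, inclusive).
#' @export
gene_pvalue <- function(observed_scores, null) {
  total <- sum(observed_scores)
  nb <- length(null$mass) - 1L
  b <- min(as.integer(floor(total / null$bin_width + 1e-9)), nb)
  list(score = total, p_value = min(1, sum(null$mass[(b + 1L):(nb + 1L)])))
}

# Observed outcome row index for one patient given counts sorted in priority
# order (row K most extreme). Returns 1 (the (0,0) row) when no mutation.
observed_outcome_row <- function(ksort, K) {
  mutated <- which(ksort > 0L)
  if (length(mutated) == 0L) return(1L)
  d1 <- max(mutated)
  if (ksort[d1] >= 2L) return(1L + K + d1)             # (d1, d1)
  rest <- mutated[mutated < d1]
  if (length(rest) == 0L) return(1L + d1)              # (d1, 0)
  d2 <- max(rest)
  # pairs start after 1 + 2K, ordered by d1 = 2..K then d2 = 1..d1-1
  1L + 2L * K + (d1 - 1L) * (d1 - 2L) %/% 2L + d2
}

# Full significance computation for one gene. P0/P1/P2: K x np priors;
# kobs: K x np observed target-zone counts.
significance_one_gene <- function(P0, P1, P2, kobs, bin_width = 0.1,
                                  score_cap = 250) {
  K <- nrow(P0); np <- ncol(P0)
  ordmat <- vapply(seq_len(np), function(p) {
    order(-(P1[, p] + P2[, p]), seq_len(K))
  }, integer(K))
  idx <- cbind(as.vector(ordmat), rep(seq_len(np), each = K))
  S0 <- matrix(P0[idx], K, np); S1 <- matrix(P1[idx], K, np)
  S2 <- matrix(P2[idx], K, np)
  P <- project_sorted(S0, S1, S2)
  Sc <- pmin(-log10(pmax(P, TINY)), score_cap)
  Sc[1L, ] <- 0

  ksort <- matrix(kobs[idx], K, np)
  rows <- vapply(seq_len(np), function(p) observed_outcome_row(ksort[, p], K),
                 integer(1L))
  obs_scores <- Sc[cbind(rows, seq_len(np))]
  total <- sum(obs_scores)
  if (total <= 0) {
    return(list(score = 0, p_value = 1, n_target = sum(kobs)))
  }
  nb <- as.integer(floor(total / bin_width + 1e-9))
  vec <- c(1, numeric(nb))
  for (p in seq_len(np)) {
    bins <- pmin(as.integer(floor(Sc[, p] / bin_width + 1e-9)), nb)
    vec <- conv_cap(vec, bins, P[, p], nb)
  }
  list(score = total, p_value = min(1, vec[nb + 1L]), n_target = sum(kobs))
}

#' Per-gene significance for a cohort
#'
#' Runs the full background -> priors -> projection -> convolution chain for
#' every gene and returns observed scores and p-values. In synonymous mode
#' category 7 (indel/null) is excluded from the target projection (synonymous
#' events are substitutions); it still informs the marginal rates.
#'
#' @param counts count tensor.
#' @param coverage coverage tensor.
#' @param bagels named list of `gene_background` from [build_bagel()].
#' @param marginals from [compute_marginals()].
#' @param mode `"synonymous"` or `"nonsynonymous"`.
#' @param bin_width score bin width (default 0.1).
#' @param score_cap per-patient score cap (default 250).
#' @return data.table(gene_id, n_target, score, p_value).
#' @export
run_significance <- function(counts, coverage, bagels, marginals,
                             mode = c("synonymous", "nonsynonymous"),
                             bin_width = 0.1, score_cap = 250) {
  mode <- match.arg(mode)
  zone <- if (mode == "synonymous") "synonymous" else "nonsynonymous"
  cats <- if (mode == "synonymous") 1:6 else 1:7
  genes <- dimnames(counts)[[1L]]
  np <- dim(counts)[3L]
  res <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    bg <- bagels[[g]]
    if (is.null(bg)) stop_synsig("no bagel/background for gene '%s'", g)
    gcp <- gcp_background(bg, marginals)
    Ntar <- matrix(coverage[g, cats, , zone], length(cats), np)
    pri <- site_probabilities(list(x = matrix(gcp$x[cats, ], length(cats), np),
                                   X = gcp$X), Ntar)
    kobs <- matrix(counts[g, cats, , zone], length(cats), np)
    one <- significance_one_gene(pri$P0, pri$P1, pri$P2plus, kobs,
                                 bin_width = bin_width, score_cap = score_cap)
    res[[gi]] <- data.table(gene_id = g, n_target = one$n_target,
                            score = one$score, p_value = one$p_value)
  }
  rbindlist(res)
}

#' Deliberately naive per-gene enrichment p-values (comparator)
#'
#' Assumes one constant genome-wide per-site mutation rate: no patient or
#' category marginals, no covariate bagels. Each gene's target-zone count is
#' referred to a Binomial(N_g, lambda) upper tail where lambda is the pooled
#' cohort rate. This is the uncorrected baseline that the background model is
#' designed to replace; on heterogeneous cohorts it is badly miscalibrated.
#'
#' @param counts count tensor.
#' @param coverage coverage tensor.
#' @param mode `"synonymous"` or `"nonsynonymous"`.
#' @return data.table(gene_id, n_target, p_value).
#' @export
naive_gene_pvalues <- function(counts, coverage,
                               mode = c("synonymous", "nonsynonymous")) {
  mode <- match.arg(mode)
  zone <- if (mode == "synonymous") "synonymous" else "nonsynonymous"
  k <- apply(counts[, "total", , zone, drop = FALSE], 1L, sum)
  N <- round(apply(coverage[, "total", , zone, drop = FALSE], 1L, sum))
  lambda <- sum(k) / sum(N)
  p <- stats::pbinom(pmax(k - 1, 0), N, lambda, lower.tail = FALSE)
  p[k == 0] <- 1
  data.table(gene_id = dimnames(counts)[[1L]], n_target = k, p_value = p)
}
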