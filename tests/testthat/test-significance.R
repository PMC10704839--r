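# Category ranking, 2D projection, convolution, gene p-values.

test_that("rank_categories orders by mutation-proneness with index tie-break", {
  pri <- list(P1 = c(0.01, 0.5, 0.01), P2plus = c(0, 0, 0))
  expect_equal(rank_categories(pri), c(2L, 1L, 3L))
  # all identical: ascending category index
  tie <- list(P1 = rep(0.1, 7), P2plus = rep(0, 7))
  expect_equal(rank_categories(tie), 1:7)
  # determinism under permuted construction: same priors, same order
  expect_equal(rank_categories(pri), rank_categories(pri))
})

test_that("project_2d reproduces the single-active-category outcome space", {
  # one category with (P0, P1, P2+) = (0.9, 0.09, 0.01), the rest certain-zero
  P0 <- c(0.9, 1, 1); P1 <- c(0.09, 0, 0); P2 <- c(0.01, 0, 0)
  d <- project_2d(P0, P1, P2)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(d[d$d1 == 0 & d$d2 == 0, prob], 0.9)
  # the active category ranks most-prone (d = 1)
  expect_equal(d[d$d1 == 1 & d$d2 == 0, prob], 0.09)
  expect_equal(d[d$d1 == 1 & d$d2 == 1, prob], 0.01)
  expect_equal(d[d$d1 == 1 & d$d2 == 1, score], 2)     # -log10(0.01)
  expect_equal(d[d$d1 == 0 & d$d2 == 0, score], 0)     # null outcome scores 0
  # degenerate: everything certain-zero -> all mass on (0,0)
  dd <- project_2d(c(1, 1), c(0, 0), c(0, 0))
  expect_equal(dd[d1 == 0, prob], 1)
  expect_equal(sum(dd$prob), 1)
})

test_that("projected outcome probabilities always sum to one", {
  set.seed(5)
  for (i in 1:50) {
    K <- sample(2:7, 1)
    P1 <- runif(K, 0, 0.4); P2 <- runif(K, 0, 0.2)
    P0 <- 1 - P1 - P2
    d <- project_2d(P0, P1, P2)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    expect_true(all(d$score >= 0))
  }
})

test_that("convolution arithmetic and mass conservation", {
  two <- data.frame(score = c(0, 1), prob = c(0.5, 0.5))
  # single patient: the null equals that patient's binned distribution
  n1 <- convolve_null(list(two), bin_width = 1, score_cap = 10)
  expect_equal(n1$mass[1:2], c(0.5, 0.5))
  # two independent patients
  n2 <- convolve_null(list(two, two), bin_width = 1, score_cap = 10)
  expect_equal(n2$mass[1:3], c(0.25, 0.5, 0.25))
  # conservation across many patients
  n100 <- convolve_null(rep(list(two), 100), bin_width = 1, score_cap = 20)
  expect_equal(sum(n100$mass), 1, tolerance = 1e-9)
  # cap lumps overflow into the top bin
  ncap <- convolve_null(list(two, two), bin_width = 1, score_cap = 1)
  expect_equal(ncap$mass, c(0.25, 0.75))
})

test_that("gene_pvalue: no mutations means p = 1; inclusive tail", {
  two <- data.frame(score = c(0, 1), prob = c(0.5, 0.5))
  null <- convolve_null(list(two, two), bin_width = 1, score_cap = 10)
  expect_equal(gene_pvalue(c(0, 0), null)$p_value, 1)
  expect_equal(gene_pvalue(c(1, 0), null)$p_value, 0.75)  # P(score >= 1)
  expect_equal(gene_pvalue(c(1, 1), null)$p_value, 0.25)
})

test_that("higher observed counts do not raise p in the rare-mutation regime", {
  # priors typical of the data the caller sees: P0 close to 1
  K <- 6
  P0 <- rep(0.97, K); P1 <- rep(0.025, K); P2 <- rep(0.005, K)
  mk <- function(k1, k2) {
    kobs <- matrix(0L, K, 2)
    kobs[1, 1] <- k1; kobs[2, 1] <- k2
    significance_one_gene(matrix(P0, K, 2), matrix(P1, K, 2),
                          matrix(P2, K, 2), kobs)$p_value
  }
  p0 <- mk(0L, 0L); p1 <- mk(1L, 0L); p2 <- mk(1L, 1L); p3 <- mk(2L, 1L)
  expect_true(p1 <= p0 && p2 <= p1 && p3 <= p2)
})

# exhaustive joint-outcome oracle for small cohorts
exhaustive_pvalue <- function(dists, obs_rows, bin_width) {
  combos <- do.call(expand.grid, lapply(dists, function(d) seq_len(nrow(d))))
  tot <- apply(combos, 1, function(idx) {
    sum(vapply(seq_along(dists), function(p) dists[[p]]$score[idx[p]], 0))
  })
  pr <- apply(combos, 1, function(idx) {
    prod(vapply(seq_along(dists), function(p) dists[[p]]$prob[idx[p]], 0))
  })
  obs <- sum(vapply(seq_along(dists), function(p) dists[[p]]$score[obs_rows[p]], 0))
  # binned-tail target and the one-bin mass tolerance around the boundary
  obs_bin <- floor(obs / bin_width + 1e-9)
  list(p = sum(pr[floor(tot / bin_width + 1e-9) >= obs_bin]),
       slack = sum(pr[abs(tot - obs) <= bin_width + 1e-9]))
}

test_that("convolution p-value matches exhaustive enumeration on small cohorts", {
  set.seed(31)
  for (rep in 1:8) {
    np <- sample(2:4, 1); K <- sample(2:3, 1)
    P1 <- matrix(runif(K * np, 0, 0.3), K, np)
    P2 <- matrix(runif(K * np, 0, 0.15), K, np)
    P0 <- 1 - P1 - P2
    kobs <- matrix(rbinom(K * np, 1, 0.3) + rbinom(K * np, 1, 0.1), K, np)
    got <- significance_one_gene(P0, P1, P2, kobs, bin_width = 0.1,
                                 score_cap = 250)
    # per-patient projected outcome tables and observed rows, via project_2d
    dists <- lapply(seq_len(np), function(p) project_2d(P0[, p], P1[, p], P2[, p]))
    obs_rows <- vapply(seq_len(np), function(p) {
      ord <- rank_categories(list(P1 = P1[, p], P2plus = P2[, p]))
      ks <- kobs[ord, p]
      synsig:::observed_outcome_row(ks, K)
    }, integer(1))
    ex <- exhaustive_pvalue(dists, obs_rows, 0.1)
    expect_lt(abs(got$p_value - ex$p), ex$slack + 1e-9)
  }
})

test_that("p-values are super-uniform when data are drawn from the model", {
  set.seed(77)
  n_genes <- 400L; np <- 10L; K <- 6L
  hits <- 0L
  for (g in seq_len(n_genes)) {
    P1 <- matrix(runif(K * np, 0, 0.08), K, np)
    P2 <- matrix(runif(K * np, 0, 0.02), K, np)
    P0 <- 1 - P1 - P2
    u <- matrix(runif(K * np), K, np)
    kobs <- matrix(0L, K, np)
    kobs[u > P0] <- 1L
    kobs[u > P0 + P1] <- 2L
    p <- significance_one_gene(P0, P1, P2, kobs)$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_genes)
  expect_lte(hits / n_genes, bound)
})

test_that("naive scorer is a plain pooled-rate binomial tail", {
  cnt <- array(0L, dim = c(2, 8, 2, 3),
               dimnames = list(c("g1", "g2"), c(as.character(1:7), "total"),
                               c("P1", "P2"),
                               c("synonymous", "nonsynonymous", "noncoding")))
  cov <- cnt + 0
  cov[, 8, , "synonymous"] <- 500
  cnt["g1", 8, "P1", "synonymous"] <- 4L
  res <- naive_gene_pvalues(cnt, cov)
  lambda <- 4 / 2000
  expect_equal(res[res$gene_id == "g1", ]$p_value,
               pbinom(3, 1000, lambda, lower.tail = FALSE))
  expect_equal(res[res$gene_id == "g2", ]$p_value, 1)
})
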