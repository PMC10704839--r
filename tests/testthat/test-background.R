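# Covariate distances, bagels, marginals, beta-binomial machinery.

test_that("covariate distances are standardized Euclidean", {
  cov <- data.frame(gene_id = c("a", "b", "c"),
                    x = c(-1, 0, 1),      # sample sd exactly 1
                    y = c(2, 2, 2))       # constant, contributes nothing
  d <- covariate_distance_matrix(cov)
  expect_equal(d["a", "b"], 1)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # identical covariate rows -> distance 0
  cov2 <- data.frame(gene_id = c("a", "b"), x = c(1, 1), y = c(2, 2))
  expect_equal(covariate_distance_matrix(cov2)["a", "b"], 0)
})

make_tensors <- function(counts_nc, coverage_nc) {
  # two-patient, one-gene tensors with given noncoding totals per patient
  genes <- "G"; patients <- paste0("P", seq_along(counts_nc))
  cnt <- array(0L, dim = c(1, 8, length(patients), 3),
               dimnames = list(genes, c(as.character(1:7), "total"), patients,
                               c("synonymous", "nonsynonymous", "noncoding")))
  cov <- cnt + 0
  for (i in seq_along(patients)) {
    cnt[1, 3, i, 3] <- counts_nc[i]
    cnt[1, 8, i, 3] <- counts_nc[i]
    cov[1, 1:6, i, 3] <- coverage_nc[i] / 6
    cov[1, 7, i, 3] <- coverage_nc[i]
    cov[1, 8, i, 3] <- coverage_nc[i]
  }
  list(counts = cnt, coverage = cov)
}

test_that("raw_background sums total-slot noncoding counts over patients", {
  tn <- make_tensors(c(3L, 4L), c(100, 100))
  bg <- raw_background(tn$counts, tn$coverage, "G")
  expect_equal(bg$n_bkgd, 7)
  expect_equal(bg$N_bkgd, 200)
  # zero-mutation cohort
  tz <- make_tensors(c(0L, 0L), c(100, 100))
  expect_equal(raw_background(tz$counts, tz$coverage, "G")$n_bkgd, 0)
  expect_gt(raw_background(tz$counts, tz$coverage, "G")$N_bkgd, 0)
  expect_error(raw_background(tn$counts, tn$coverage, "NOPE"), "absent")
})

test_that("beta-binomial qualification accepts like rates, rejects outliers", {
  expect_true(qualify_neighbor(c(5, 1000), c(5, 1000)))
  expect_false(qualify_neighbor(c(5, 1000), c(100, 0)))   # no coverage
  # target (0, 1000) vs neighbour (100, 1000): Monte-Carlo oracle for the
  # upper predictive tail (rate ~ Beta(1, 1001)) shows it is far below 0.05
  expect_false(qualify_neighbor(c(0, 1000), c(100, 1000)))
  mc <- local({
    set.seed(1234)
    rate <- rbeta(2e5, 1, 1001)
    mean(rbinom(2e5, 1000, rate) >= 100)
  })
  expect_lt(2 * mc, 0.001)
})

test_that("build_bagel walks neighbours nearest-first with caps", {
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  bg <- data.frame(gene_id = c("g1", "g2", "g3"),
                   n_bkgd = c(5, 5, 500), N_bkgd = c(1000, 1000, 1000))
  b <- build_bagel("g1", d, bg)
  # g2 (identical rate) qualifies; g3 (100x rate) stops the walk
  expect_equal(b$bagel, "g2")
  expect_equal(b$x, 10)
  expect_equal(b$X, 2000)
  # no qualifying neighbour: empty bagel, x = own counts
  b2 <- build_bagel("g3", d, bg)
  expect_length(b2$bagel, 0L)
  expect_equal(b2$x, 500)
  # neighbour cap: nearest only
  bg3 <- data.frame(gene_id = c("g1", "g2", "g3"),
                    n_bkgd = c(5, 5, 5), N_bkgd = c(1000, 1000, 1000))
  b3 <- build_bagel("g1", d, bg3, max_neighbors = 1L)
  expect_equal(b3$bagel, "g2")
})

test_that("cohort marginals are ratio-of-rates with unit weighted means", {
  # patient 2 has twice the burden at equal coverage
  tn <- make_tensors(c(10L, 20L), c(1000, 1000))
  m <- compute_marginals(tn$counts, tn$coverage)
  expect_equal(unname(m$rho_p["P2"] / m$rho_p["P1"]), 2)
  # coverage-weighted mean of rho_p is 1
  N_p <- apply(tn$coverage[, 8, , , drop = FALSE], 3, sum)
  expect_equal(sum(m$rho_p * N_p / sum(N_p)), 1)
  # SNV-coverage-weighted mean of rho_c over categories 1-6 is 1
  N_c <- vapply(1:6, function(c) sum(tn$coverage[, c, , ]), 0)
  expect_equal(sum(m$rho_c[1:6] * N_c / sum(N_c)), 1)
  expect_error(compute_marginals(tn$counts, tn$coverage * 0), "coverage")
})

test_that("gcp background distributes the bagel rate and clamps", {
  bg <- structure(list(gene_id = "G", n_bkgd = 5, N_bkgd = 100,
                       bagel = character(), x = 5, X = 100),
                  class = "gene_background")
  unity <- list(rho_c = setNames(rep(1, 7), 1:7), rho_p = c(P1 = 1, P2 = 1))
  g1 <- gcp_background(bg, unity)
  expect_true(all(g1$x == 5))
  expect_equal(g1$X, 100)
  zero <- unity; zero$rho_c["3"] <- 0
  expect_true(all(gcp_background(bg, zero)$x["3", ] == 0))
  big <- unity; big$rho_c[] <- 50; big$rho_p[] <- 2
  expect_true(all(gcp_background(bg, big)$x <= 100))   # clamped at X
})

test_that("beta_binomial_pmf normalizes, handles N=0, matches MC and binomial limit", {
  set.seed(7)
  for (i in 1:20) {
    N <- sample(0:30, 1); x <- runif(1, 0, 20); X <- x + runif(1, 1, 50)
    expect_equal(sum(beta_binomial_pmf(0:N, N, x, X)), 1, tolerance = 1e-10)
  }
  expect_equal(beta_binomial_pmf(0, 0, 3, 10), 1)
  expect_error(beta_binomial_pmf(1, 2, 5, 3), "X >= x")

  # H(1, 2, 1, 10) against the stated Monte-Carlo oracle
  set.seed(42)
  rate <- rbeta(1e6, 2, 10)
  k <- rbinom(1e6, 2, rate)
  mc <- mean(k == 1)
  se <- sd(k == 1) / sqrt(1e6)
  expect_lt(abs(beta_binomial_pmf(1, 2, 1, 10) - mc), 3 * se)

  # binomial limit as X -> Inf with x/X fixed
  p <- 0.3; X <- 1e7
  expect_equal(beta_binomial_pmf(0:10, 10, p * X, X),
               dbinom(0:10, 10, p), tolerance = 1e-4)
})

test_that("site probabilities form a proper 0/1/2+ triplet", {
  set.seed(11)
  for (i in 1:1000) {
    N <- matrix(runif(1, 0, 50), 1, 1)
    x <- runif(1, 0, 10); X <- x + runif(1, 1, 100)
    pr <- site_probabilities(list(x = matrix(x, 1, 1), X = X), N)
    expect_equal(pr$P0 + pr$P1 + pr$P2plus, matrix(1, 1, 1), tolerance = 1e-12)
    expect_true(all(c(pr$P0, pr$P1, pr$P2plus) >= 0 &
                      c(pr$P0, pr$P1, pr$P2plus) <= 1))
  }
  # N = 0: certainty of zero mutations
  pr0 <- site_probabilities(list(x = matrix(2, 1, 1), X = 10), matrix(0, 1, 1))
  expect_equal(c(pr0$P0, pr0$P1, pr0$P2plus), c(1, 0, 0))
  # x = 0 formula against brute-force summation of the pmf
  N <- 12; X <- 400
  pr <- site_probabilities(list(x = matrix(0, 1, 1), X = X), matrix(N, 1, 1))
  pmf <- beta_binomial_pmf(0:N, N, 0, X)
  expect_equal(pr$P0[1, 1], pmf[1], tolerance = 1e-12)
  expect_equal(pr$P1[1, 1], pmf[2], tolerance = 1e-12)
  expect_equal(pr$P2plus[1, 1], sum(pmf[-(1:2)]), tolerance = 1e-10)
})

test_that("covariate table reading maps synonyms and imputes missing values", {
  cov <- data.frame(gene = c("OLD1", "g2"), expr = c(1, NA), rt = c(0.5, 0.2))
  syn <- data.frame(old_name = "OLD1", new_name = "g1")
  out <- read_covariates(cov, syn)
  expect_setequal(out$gene_id, c("g1", "g2"))
  expect_equal(out$expr[2], 1)          # imputed to the column mean
  expect_true(out$imputed[2])
  bad <- data.frame(gene = "g1", expr = NA_real_)
  expect_error(read_covariates(bad), class = "synsig_config_error")
})

test_that("background rate is recovered on a synthetic cohort", {
  # genes with >= 1000 covered noncoding site-patients recover the known rate
  w <- tiny_world()
  cfg <- w$config
  ann <- annotate_mutations(w$mutations, w$site_effects)
  counts <- build_count_tensor(ann, w$gene_ids, w$patients)
  coverage <- build_coverage_tensor(w$site_effects, NULL, w$patients, w$gene_ids)
  for (g in w$gene_ids[1:6]) {
    bg <- raw_background(counts, coverage, g)
    mu <- cfg$base_rate * w$gene_factors[g]   # per site-patient, rho-mean 1
    expect_gt(bg$N_bkgd, 1000)
    se3 <- 3 * sqrt(mu / bg$N_bkgd)
    expect_lt(abs(bg$n_bkgd / bg$N_bkgd - mu), se3 + 1e-9)
  }
})
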