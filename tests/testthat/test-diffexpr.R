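mkStudy <- function(values, ecotypes = NULL, angles = NULL) {
  n <- ncol(values)
  if (is.null(ecotypes)) ecotypes <- rep("WS", n)
  if (is.null(angles)) angles <- rep(c(90, 135), each = n / 2)
  colnames(values) <- sprintf("s%02d", seq_len(n))
  rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  ExpressionStudy(values, data.frame(ecotype = ecotypes, angle_gp = angles,
                                     replicate = seq_len(n)))
}

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(quantileNormalize(m), m)
  m2 <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantileNormalize(m2)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  set.seed(8)
  m3 <- matrix(rnorm(300), 50, 6)
  qn <- quantileNormalize(m3)
  expect_equal(max(colMeans(qn)) - min(colMeans(qn)), 0, tolerance = 1e-9)
  expect_equal(apply(qn, 2, sort), matrix(rep(sort(qn[, 1]), 6), ncol = 6),
               ignore_attr = TRUE, tolerance = 1e-12)
  skip_if_not_installed("limma")
  expect_equal(qn, limma::normalizeQuantiles(m3), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(quantileNormalize(cbind(c(1, NA), c(1, 2))), "finite")
})

test_that("BH q-values implement the step-up rule", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    q <- bhFdr(p)
    expect_equal(q, oracleBH(p), tolerance = 1e-12)
    expect_true(all(diff(sort(q)) >= -1e-12) && all(q <= 1))
  }
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhFdr(numeric(0)), "empty")
})

test_that("with moderation off the statistic is the ordinary pooled t", {
  set.seed(10)
  v <- matrix(rnorm(40 * 6, 8, 0.4), 40, 6)
  st <- mkStudy(v)
  cr <- contrastStats(st, paste0("s0", 4:6), paste0("s0", 1:3),
                      moderated = FALSE)
  o <- oraclePooledT(v[, 4:6], v[, 1:3])
  expect_equal(unname(resultTable(cr)$t), unname(o$t), tolerance = 1e-12)
  expect_equal(unname(resultTable(cr)$p), unname(o$p), tolerance = 1e-12)
  expect_equal(unname(resultTable(cr)$log2fc), unname(o$delta),
               tolerance = 1e-12)
  expect_identical(moderationParams(cr)$d0, 0)
})

test_that("shared gene variance drives the moderated t to the pooled t", {
  # all genes have exactly equal sample variance: the moment estimator
  # finds zero excess dispersion, d0 -> Inf and s~^2 -> that variance
  set.seed(11)
  base <- rnorm(6)
  v <- t(vapply(1:30, function(i) i / 10 + base, numeric(6)))
  st <- mkStudy(v)
  cr <- contrastStats(st, paste0("s0", 4:6), paste0("s0", 1:3))
  expect_true(is.infinite(moderationParams(cr)$d0))
  o <- oraclePooledT(v[, 4:6], v[, 1:3])
  expect_equal(moderationParams(cr)$s0_sq, unname(o$s2[1]), tolerance = 1e-9)
  # with df = Inf the statistic is z-like, using s0^2 for every gene
  expect_equal(unname(resultTable(cr)$t), unname(o$t), tolerance = 1e-9)
  expect_equal(unname(resultTable(cr)$p),
               unname(2 * pnorm(abs(o$t), lower.tail = FALSE)),
               tolerance = 1e-9)
})

test_that("moment-matched prior and moderated t agree with a numeric oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n_genes <- 20
    sd_g <- sqrt(1 / rgamma(n_genes, shape = 3, rate = 0.3))
    v <- matrix(rnorm(n_genes * 6, 8, rep(sd_g, 6)), n_genes, 6)
    st <- mkStudy(v)
    cr <- contrastStats(st, paste0("s0", 4:6), paste0("s0", 1:3))
    o <- oraclePooledT(v[, 4:6], v[, 1:3])
    prior <- oracleVariancePrior(o$s2, df = 4)
    mod <- moderationParams(cr)
    expect_equal(mod$d0, prior$d0, tolerance = 1e-8)
    expect_equal(mod$s0_sq, prior$s0_sq, tolerance = 1e-8)
    s2_tilde <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(o$s2))
      else (prior$d0 * prior$s0_sq + 4 * o$s2) / (prior$d0 + 4)
    t_tilde <- o$delta / sqrt(s2_tilde * (2 / 3))
    expect_equal(unname(resultTable(cr)$t), unname(t_tilde),
                 tolerance = 1e-8)
    expect_equal(unname(resultTable(cr)$p),
                 unname(2 * pt(abs(t_tilde), prior$d0 + 4,
                               lower.tail = FALSE)), tolerance = 1e-8)
  }
})

test_that("the shrunken variances agree with limma's empirical Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(33)
  sd_g <- sqrt(1 / rgamma(200, shape = 4, rate = 0.4))
  v <- matrix(rnorm(200 * 6, 8, rep(sd_g, 6)), 200, 6)
  st <- mkStudy(v)
  cr <- contrastStats(st, paste0("s0", 4:6), paste0("s0", 1:3))
  o <- oraclePooledT(v[, 4:6], v[, 1:3])
  sq <- limma::squeezeVar(o$s2, df = 4)
  mod <- moderationParams(cr)
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, sq$var.prior, tolerance = 1e-6)
})

test_that("contrasts are invariant to column order and antisymmetric", {
  set.seed(12)
  v <- matrix(rnorm(25 * 6, 8, 0.3), 25, 6)
  st <- mkStudy(v)
  cr1 <- contrastStats(st, paste0("s0", 4:6), paste0("s0", 1:3))
  st2 <- mkStudy(v[, c(3, 1, 6, 2, 5, 4)])
  # same samples, shuffled columns: map the ids through the permutation
  perm <- c(3, 1, 6, 2, 5, 4)
  ids <- sprintf("s%02d", order(perm))
  cr2 <- contrastStats(st2, ids[4:6], ids[1:3])
  expect_equal(resultTable(cr1)$t, resultTable(cr2)$t, tolerance = 1e-12)
  swapped <- contrastStats(st, paste0("s0", 1:3), paste0("s0", 4:6))
  expect_equal(resultTable(swapped)$log2fc, -resultTable(cr1)$log2fc,
               tolerance = 1e-12)
  expect_equal(resultTable(swapped)$p, resultTable(cr1)$p, tolerance = 1e-12)
})

test_that("null simulations keep the type-I error near its nominal level", {
  set.seed(13)
  v <- matrix(rnorm(2000 * 6, 8, 0.25), 2000, 6)
  st <- mkStudy(v)
  for (moderated in c(FALSE, TRUE)) {
    cr <- contrastStats(st, paste0("s0", 4:6), paste0("s0", 1:3),
                        moderated = moderated)
    rate <- mean(resultTable(cr)$p < 0.05)
    expect_gte(rate, 0.03); expect_lte(rate, 0.07)
  }
})

test_that("significance calls use strict cutoffs on both axes", {
  st <- S4Vectors::DataFrame(
    log2fc = c(1.0, 2.08, 2.0, -1.5), t = c(5, 5, 5, -5),
    p = c(0.001, 0.01, 0.06, 0.002), q = c(0.01, 0.04, 0.2, 0.01),
    sig = c(FALSE, TRUE, FALSE, TRUE),
    sig_fdr = c(FALSE, TRUE, FALSE, TRUE),
    direction = c("up", "up", "up", "down"),
    row.names = c("exactly1", "asn1_like", "p_fails", "down_gene"))
  cr <- new("ContrastResult", contrastId = "x", testGroup = "a",
            refGroup = "b", nTest = 3L, nRef = 3L,
            moderation = list(moderated = FALSE, d0 = 0, s0_sq = NA_real_,
                              df = 4), stats = st)
  de <- callDE(cr)
  expect_false("exactly1" %in% de$gene_id)   # |log2FC| must exceed 1
  expect_true("asn1_like" %in% de$gene_id)
  expect_false("p_fails" %in% de$gene_id)
  expect_equal(de$direction[de$gene_id == "down_gene"], "down")
  expect_error(callDE(cr, fc_cut = 0), "positive")
})

test_that("group lookups and zero-variance genes are handled explicitly", {
  v <- matrix(c(rep(1, 6), rep(c(1, 2), each = 3)), 2, 6, byrow = TRUE)
  st <- mkStudy(v + 0)
  expect_error(contrastStats(st, c("s01", "nope"), c("s02", "s03")),
               "unknown samples")
  expect_error(contrastStats(st, "s01", c("s02", "s03")), ">= 2 replicates")
  cr <- contrastStats(st, paste0("s0", 4:6), paste0("s0", 1:3),
                      moderated = FALSE)
  tab <- resultTable(cr)
  expect_equal(unname(tab["g001", "p"]), 1)  # no change, no variance
  expect_equal(unname(tab["g002", "p"]), 0)  # change with zero variance
})
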