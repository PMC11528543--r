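test_that("RPKM arithmetic, zero counts and scale invariance", {
  expect_equal(rpkm(10, 2000, 1e6)[1], 5.0)
  expect_equal(rpkm(0, 2000, 1e6)[1], 0.0)
  expect_equal(rpkm(20, 2000, 2e6)[1], 5.0)  # doubling both cancels
  m <- matrix(c(10, 100, 20, 200), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  r <- rpkm(m, c(1000, 2000))
  expect_equal(dim(r), dim(m))
  expect_error(rpkm(10, 0, 1e6), "positive")
  expect_error(rpkm(10, 100, 0), "positive")
})

test_that("size factors recover library scaling on clean data", {
  set.seed(21)
  mu <- exp(rnorm(300, log(100), 1))
  base <- matrix(rpois(300 * 4, mu), nrow = 300)
  scaled <- sweep(base, 2, c(1, 2, 0.5, 1), "*")
  sf <- size_factors(scaled)
  expect_equal(sf / sf[1], c(1, 2, 0.5, 1), tolerance = 0.1)
})

test_that("identical groups give zero fold change and all-zero genes are inert", {
  set.seed(22)
  cts <- matrix(rnbinom(100 * 3, mu = 50, size = 10), nrow = 100)
  cts[1, ] <- 0
  dt <- diff_test(cbind(cts, cts)[, 1:3], cbind(cts, cts)[, 4:6])
  expect_equal(dt$log2fc, rep(0, 100))
  expect_equal(dt$p[1], 1)
  expect_equal(dt$log2fc[1], 0)
  expect_error(diff_test(cts[, 1, drop = FALSE], cts[, 2:3]), "2 samples")
})

test_that("planted four-fold genes are recovered near log2fc = 2", {
  set.seed(23)
  ng <- 1200
  mu <- exp(rnorm(ng, log(80), 1))
  planted <- sample(ng, 60)
  mu[planted] <- pmax(mu[planted], 100)
  mu1 <- mu; mu1[planted] <- mu[planted] * 4
  g1 <- matrix(rnbinom(ng * 4, mu = mu1, size = 20), nrow = ng)
  g2 <- matrix(rnbinom(ng * 4, mu = mu, size = 20), nrow = ng)
  dt <- diff_test(g1, g2)
  expect_equal(mean(dt$log2fc[planted]), 2, tolerance = 0.15)
  expect_lt(mean(abs(dt$log2fc[-planted])), 0.25)
})

test_that("null simulation keeps the p <= 0.05 fraction near nominal", {
  set.seed(24)
  ng <- 2000
  mu <- exp(rnorm(ng, log(80), 1))
  cts <- matrix(rnbinom(ng * 8, mu = mu, size = 1 / 0.05), nrow = ng)
  dt <- diff_test(cts[, 1:4], cts[, 5:8])
  expect_gte(mean(dt$p <= 0.05), 0.03)
  expect_lte(mean(dt$p <= 0.05), 0.07)
})

test_that("DEG gates apply biotype-specific RPKM floors and strict fold gate", {
  st <- data.frame(gene_id = c("c1", "l1", "c2", "c3"),
                   log2fc = c(0.6, 0.6, 0.5, -0.8),
                   p = c(0.001, 0.001, 0.001, 0.001))
  degs <- call_degs(st, mean_rpkm = c(0.8, 0.8, 5, 5),
                    biotype = c("coding", "lncRNA", "coding", "coding"))
  expect_equal(degs$status, c("ns", "up", "ns", "down"))
  # q column is BH over the supplied universe
  expect_equal(degs$q, bh_fdr(st$p))
})

test_that("cis pairs honour correlation, distance and direction gates", {
  set.seed(25)
  genes <- data.frame(
    gene_id = c("lncA", "codA", "codFar", "lncB", "codB"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(1000L, 20000L, 500000L, 1000L, 5000L),
    end = c(3000L, 25000L, 505000L, 2000L, 9000L),
    strand = "+", biotype = c("lncRNA", "coding", "coding", "lncRNA",
                              "coding"),
    tss = c(1000, 20000, 500000, 1000, 5000),
    tes = c(3000, 25000, 505000, 2000, 9000),
    length_bp = c(2000L, 5000L, 5000L, 1000L, 4000L),
    stringsAsFactors = FALSE)
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expr <- rbind(lncA = x, codA = x + rnorm(8, 0, 1e-3),
                codFar = x, lncB = x, codB = rev(x))
  degs <- data.frame(gene_id = rownames(expr),
                     status = c("up", "up", "up", "up", "up"),
                     biotype = genes$biotype, stringsAsFactors = FALSE)
  cp <- cis_pairs(degs, expr, genes)
  # lncA-codA kept (distance 17 kb, r ~ 1); codFar beyond 100 kb dropped;
  # lncB-codB anti-correlated dropped
  expect_equal(cp$lnc_id, "lncA")
  expect_equal(cp$coding_id, "codA")
  expect_equal(cp$distance_bp, 17000L)
  expect_gt(cp$r, 0.99)
  # opposite-direction pairs are never tested
  degs2 <- degs; degs2$status[degs2$gene_id == "codA"] <- "down"
  expect_equal(nrow(cis_pairs(degs2, expr, genes)), 0L)
  # overlapping spans have distance zero
  genes3 <- genes; genes3$start[2] <- 2500L; genes3$end[2] <- 7500L
  cp3 <- cis_pairs(degs, expr, genes3)
  expect_equal(cp3$distance_bp, 0L)
})

test_that("isoform ratio divides per sample and flags zero denominators", {
  expect_equal(isoform_ratio(c(100, 30), c(50, 30)), c(2, 1))
  expect_warning(r <- isoform_ratio(c(1, 2), c(1, 0)), "zero denominator")
  expect_equal(r, c(1, NA))
  # unchanged by a common library rescale
  expect_equal(isoform_ratio(2 * c(100, 30), 2 * c(50, 30)),
               isoform_ratio(c(100, 30), c(50, 30)))
})

test_that("fetal program is the direction-wise DEG intersection", {
  dd <- data.frame(gene_id = c("a", "b", "c", "d"),
                   status = c("up", "up", "down", "down"))
  df <- data.frame(gene_id = c("a", "x", "c", "y"),
                   status = c("up", "up", "down", "down"))
  prog <- fetal_program(dd, df)
  expect_equal(prog$co_up, "a")
  expect_equal(prog$co_down, "c")
  expect_length(intersect(prog$co_up, prog$co_down), 0)
  # disjoint DEG sets: empty program
  empty <- fetal_program(dd, data.frame(gene_id = "z", status = "up"))
  expect_length(empty$co_up, 0)
})

test_that("reversal fractions count genes reversed in both treated groups", {
  prog <- list(co_up = paste0("u", 1:10), co_down = paste0("d", 1:4))
  degA <- data.frame(gene_id = c(paste0("u", 1:7), "d1", "d2"),
                     status = c(rep("down", 7), "up", "up"))
  degB <- data.frame(gene_id = c(paste0("u", 1:6), "d1", "d3"),
                     status = c(rep("down", 6), "up", "up"))
  rv <- reversal_fraction(prog, degA, degB)
  expect_equal(rv$reversed_up, paste0("u", 1:6))  # in both A and B
  expect_equal(rv$reversed_down, "d1")
  expect_equal(rv$pct_up, 60)
  expect_equal(rv$pct_down, 25)
  # empty side flagged
  expect_warning(
    rv0 <- reversal_fraction(list(co_up = character(), co_down = "d1"),
                             degA, degB), "empty")
  expect_true(is.na(rv0$pct_up))
})
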