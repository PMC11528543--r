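test_that("300-bp tiling covers a contig with a short terminal window", {
  w <- tile_300bp(c(ctg = 1000))
  expect_equal(w$start, c(0L, 300L, 600L, 900L))
  expect_equal(w$end, c(300L, 600L, 900L, 1000L))
  expect_equal(nrow(w), ceiling(1000 / 300))
})

test_that("window values require three covered sites per sample", {
  w <- data.frame(chrom = "chr1", start = 0L, end = 300L)
  a <- uniform_sites(c(10, 20, 30), 0, total = 10)
  a$meth <- c(1L, 2L, 3L)  # mean level 0.2
  b <- a[1:2, ]
  v <- window_values(list(s1 = a, s2 = b), w)
  expect_equal(unname(v[1, "s1"]), 0.2)
  expect_true(is.na(v[1, "s2"]))
})

test_that("row t-tests match stats::t.test including NA handling", {
  set.seed(41)
  m <- matrix(runif(40 * 8), nrow = 40)
  m[sample(length(m), 30)] <- NA
  res <- test_windows(m, 1:4, 5:8)
  for (i in seq_len(nrow(m))) {
    x <- m[i, 1:4]; y <- m[i, 5:8]
    if (sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2 &&
        stats::sd(c(x, y), na.rm = TRUE) > 0) {
      tt <- t.test(x, y, var.equal = TRUE)
      expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
      expect_equal(res$delta[i], unname(diff(rev(tt$estimate))),
                   tolerance = 1e-12)
    }
  }
  # Welch variant
  resw <- test_windows(m, 1:4, 5:8, var_equal = FALSE)
  i <- which(rowSums(!is.na(m[, 1:4])) >= 2 &
             rowSums(!is.na(m[, 5:8])) >= 2)[1]
  expect_equal(resw$p[i],
               t.test(m[i, 1:4], m[i, 5:8])$p.value, tolerance = 1e-12)
})

test_that("t-test agrees with a hand-computed df = 4 example and is symmetric", {
  g1 <- c(0.9, 0.92, 0.88); g2 <- c(0.5, 0.52, 0.48)
  res <- test_windows(rbind(c(g1, g2)), 1:3, 4:6)
  sp2 <- (2 * var(g1) + 2 * var(g2)) / 4
  tstat <- (mean(g1) - mean(g2)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$p, 2 * pt(-abs(tstat), df = 4), tolerance = 1e-12)
  expect_equal(res$delta, 0.4, tolerance = 1e-12)
  # swapping groups negates delta, preserves p
  swap <- test_windows(rbind(c(g1, g2)), 4:6, 1:3)
  expect_equal(swap$delta, -res$delta)
  expect_equal(swap$p, res$p)
  # identical groups: no evidence
  same <- test_windows(rbind(c(g1, g1)), 1:3, 4:6)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
})

test_that("BH adjustment matches the step-up oracle and handles NA universe", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (k in 1:5) {
    p <- runif(sample(2:10, 1))
    expect_equal(bh_fdr(p), bh_by_hand(p), tolerance = 1e-12)
  }
  # NA entries stay NA and do not inflate the universe
  p <- c(0.01, NA, 0.02, 0.03)
  expect_equal(bh_fdr(p), c(0.03, NA, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMW gates are strict on delta and require both p and FDR", {
  w <- data.frame(chrom = "chr1", start = c(0L, 300L, 600L, 900L),
                  end = c(300L, 600L, 900L, 1200L))
  tests <- data.frame(mean_g1 = c(0.9, 0.9, 0.9, 0.5),
                      mean_g2 = c(0.71, 0.65, 0.65, 0.5),
                      delta = c(0.19, 0.25, 0.25, 0),
                      n1 = 3, n2 = 3,
                      p = c(1e-6, 0.04, 0.01, 0.9))
  # rig q by supplying p vectors whose BH outcome is known:
  # q = bh_fdr(p) = c(4e-6, 0.053, 0.02, 0.9)
  dmw <- call_dmws(w, tests)
  expect_equal(dmw$start, 600L)  # |delta|>0.2 & p<=0.05 & q<=0.05
  expect_equal(dmw$direction, "hyper")
})

test_that("DMRs merge same-direction windows within 300 bp only", {
  dmw <- data.frame(chrom = "chr1", start = c(0L, 600L, 1300L),
                    end = c(300L, 900L, 1600L),
                    mean_g1 = 0.9, mean_g2 = 0.6, delta = c(0.3, 0.3, 0.26),
                    p = 0.01, q = 0.01,
                    direction = "hyper", stringsAsFactors = FALSE)
  dmr <- merge_dmrs(dmw)
  # gap 300 merges; gap 400 does not
  expect_equal(dmr$start, c(0L, 1300L))
  expect_equal(dmr$end, c(900L, 1600L))
  expect_equal(dmr$n_windows, c(2L, 1L))
  expect_equal(dmr$delta, c(0.3, 0.26))
  # opposite directions never merge even when adjacent
  dmw2 <- dmw[1:2, ]
  dmw2$direction <- c("hyper", "hypo")
  expect_equal(nrow(merge_dmrs(dmw2)), 2L)
  # idempotence: re-merging the merged regions changes nothing
  dmr2 <- merge_dmrs(transform(dmr, p = 0.01, q = 0.01,
                               mean_g1 = 0.9, mean_g2 = 0.6))
  expect_equal(dmr2[c("chrom", "start", "end", "direction")],
               dmr[c("chrom", "start", "end", "direction")])
})

test_that("DMRs are disjoint within each direction", {
  cfg <- sim_config(seed = 13, genome_length = 2e5, n_ndr = 0, n_dmr = 8,
                    depth = 10, n_per_group = 4)
  g <- simulate_genome(cfg)
  calls <- simulate_calls(cfg, g)
  res <- call_dmrs(calls$samples$group1, calls$samples$group2,
                   c(chrS = cfg$genome_length))
  for (dir in c("hyper", "hypo")) {
    d <- res$dmrs[res$dmrs$direction == dir, ]
    if (nrow(d) > 1) {
      d <- d[order(d$start), ]
      expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    }
  }
})
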