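test_that("simulated genome hits the configured GC fraction and is seed-stable", {
  cfg <- sim_config(seed = 5, genome_length = 1e6, n_ndr = 10, n_dmr = 10)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  b <- table(strsplit(as.character(g1$genome[[1]]), "")[[1]])
  gc <- (b[["C"]] + b[["G"]]) / sum(b)
  expect_lt(abs(gc - cfg$gc_fraction), 0.02)
})

test_that("pattern-derived contexts agree with the neighbour-rule classifier", {
  cfg <- sim_config(seed = 6, genome_length = 5e4, n_ndr = 2, n_dmr = 2)
  g <- simulate_genome(cfg)
  ctx <- classify_contexts(g$genome)
  ctx <- ctx[ctx$context != "OTHER", ]
  rownames(ctx) <- NULL
  expect_equal(g$contexts[c("chrom", "start", "strand", "context")],
               ctx[c("chrom", "start", "strand", "context")])
})

test_that("planted features shift simulated levels as configured", {
  cfg <- sim_config(seed = 8, genome_length = 3e5, n_ndr = 5,
                    ndr_length = c(400, 500), n_dmr = 5, depth = 200,
                    n_per_group = 2)
  g <- simulate_genome(cfg)
  calls <- simulate_calls(cfg, g)
  s <- calls$samples$group1[[1]]
  gch <- filter_sites(s, "GCH", min_depth = 50)
  inside <- region_level(gch, calls$truth$ndrs, min_sites = 1)
  # law of large numbers at depth 200: observed level approaches the plant
  expect_equal(mean(inside$level), cfg$ndr_gch_level, tolerance = 0.02)
  expect_equal(global_level(gch), cfg$gch_background, tolerance = 0.02)
  # group WCG means differ by about dmr_delta inside planted DMRs
  w1 <- region_level(filter_sites(calls$samples$group1[[1]], "WCG"),
                     calls$truth$dmrs)
  w2 <- region_level(filter_sites(calls$samples$group2[[1]], "WCG"),
                     calls$truth$dmrs)
  sign <- ifelse(calls$truth$dmrs$direction == "hyper", 1, -1)
  realized <- pmin(0.99, pmax(0.01, cfg$wcg_background + sign * cfg$dmr_delta)) -
    cfg$wcg_background
  expect_equal(w1$level - w2$level, realized, tolerance = 0.05)
})

test_that("zero planted features yield empty truth tables", {
  cfg <- sim_config(seed = 9, genome_length = 5e4, n_ndr = 0, n_dmr = 0,
                    n_per_group = 1)
  calls <- simulate_calls(cfg, simulate_genome(cfg))
  expect_equal(nrow(calls$truth$ndrs), 0L)
  expect_equal(nrow(calls$truth$dmrs), 0L)
})

test_that("expression simulator plants program, reversal and cis structure", {
  cfg <- sim_config(seed = 10, n_genes = 1500, program_up = 30,
                    program_down = 50, n_de_extra = 20, n_cis_pairs = 5,
                    reversal_up = 0.8, reversal_down = 0.75)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  expect_length(tr$program$co_up, 30)
  expect_length(tr$program$co_down, 50)
  expect_length(tr$reversed_up, 24)    # round(0.8 * 30)
  expect_length(tr$reversed_down, 38)  # round_half_up(0.75 * 50) = 38
  expect_length(intersect(tr$program$co_up, tr$program$co_down), 0)
  # cis pairs are placed within 100 kb and strongly correlated
  r <- rpkm(sim$counts, sim$genes$length_bp)
  for (k in seq_len(nrow(tr$cis_pairs))) {
    gl <- sim$genes[sim$genes$gene_id == tr$cis_pairs$lnc_id[k], ]
    gc_ <- sim$genes[sim$genes$gene_id == tr$cis_pairs$coding_id[k], ]
    gap <- max(0, max(gl$start, gc_$start) - min(gl$end, gc_$end))
    expect_lte(gap, 1e5)
    expect_gt(cor(r[gl$gene_id, ], r[gc_$gene_id, ]), 0.5)
  }
  # planted program genes move in the configured direction in disease
  dis <- sim$groups == "disease"
  ctl <- sim$groups == "control"
  lfc <- log2(rowMeans(sim$counts[, dis] + 1) /
              rowMeans(sim$counts[, ctl] + 1))
  expect_gt(min(lfc[tr$program$co_up]), 0.5)
  expect_lt(max(lfc[tr$program$co_down]), -0.5)
})

test_that("simulator file outputs are byte-identical under one seed", {
  cfg <- sim_config(seed = 12, genome_length = 2e4, n_ndr = 1, n_dmr = 1,
                    n_per_group = 1, n_genes = 300, program_up = 5,
                    program_down = 8, n_de_extra = 3, n_cis_pairs = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- simulate_genome(cfg, dir = d1)
  g2 <- simulate_genome(cfg, dir = d2)
  simulate_calls(cfg, g1, dir = d1)
  simulate_calls(cfg, g2, dir = d2)
  simulate_expression(cfg, dir = d1)
  simulate_expression(cfg, dir = d2)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = paste("bytes of", f))
  # written sample tables round-trip through the cytosine-report reader
  s <- read_cytosine_report(file.path(d1, "g1_s1.cytosine_report.tsv"),
                            "cytosine_report")
  expect_gt(nrow(s), 0)
  expect_true(all(s$context %in% c("WCG", "GCH", "GCG", "CCG")))
})
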