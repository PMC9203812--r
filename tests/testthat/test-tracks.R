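flat_track <- function(v, len = 10000L, bin = 50L) {
  coverage_track(list(chr1 = rep(v, ceiling(len / bin))), bin)
}

test_that("per-N-reads normalization scales by denominator/mapped and refuses re-entry", {
  tr <- flat_track(10)
  out <- normalize_per_reads(tr, 5e7)
  expect_equal(out$values$chr1, rep(20, 200)) # 50M reads -> factor 2
  expect_equal(out$normalization, "per100M")
  ident <- normalize_per_reads(flat_track(10), 1e8)
  expect_equal(ident$values$chr1, rep(10, 200))
  expect_error(normalize_per_reads(out, 5e7), "already normalized")
  expect_error(normalize_per_reads(flat_track(1), 0), "> 0")
})

test_that("spike-in factor follows the ratio-of-ratios formula and its invariances", {
  s <- spike_in_stats(h_chip = 8e7, s_chip = 2e7, h_input = 8e7, s_input = 2e7)
  expect_equal(chiprx_factor(s), 1.25) # ratio term 1, 1e8/8e7
  # doubling ChIP depth halves the factor, leaving the normalized track unchanged
  s2 <- spike_in_stats(h_chip = 1.6e8, s_chip = 4e7, h_input = 8e7, s_input = 2e7)
  expect_equal(chiprx_factor(s2), chiprx_factor(s) / 2)
  tr <- flat_track(10)
  n1 <- normalize_chiprx(tr, s)
  tr2 <- flat_track(20) # doubled depth doubles raw coverage
  n2 <- normalize_chiprx(tr2, s2)
  expect_equal(n1$values$chr1, n2$values$chr1)
  expect_error(spike_in_stats(0, 1, 1, 1), "> 0")
})

test_that("track scaling is linear through metagene profiles", {
  set.seed(4)
  v <- runif(400, 0, 50)
  tr <- coverage_track(list(chr1 = v), 50)
  tr3 <- coverage_track(list(chr1 = 3 * v), 50)
  genes <- gr("chr1", c(5000, 9000), c(7000, 12000), strand = c("+", "-"))
  genes$name <- c("a", "b")
  p1 <- metagene_profile(tr, genes, flank = 1000)
  p3 <- metagene_profile(tr3, genes, flank = 1000)
  expect_equal(p3$mean_signal, 3 * p1$mean_signal)
})

test_that("expression strata partition the universe in both modes", {
  expr <- data.frame(gene_id = paste0("g", 1:6),
                     expr_a = c(5, 0, 3, 0, 9, 2),
                     expr_b = c(4, 6, 0, 0, 1, 3))
  st <- stratify_by_expression(expr, "status4", threshold = 1)
  expect_equal(sort(unlist(st, use.names = FALSE)), sort(expr$gene_id))
  expect_equal(sort(st$both_expressed), c("g1", "g5", "g6"))
  expect_equal(st$cellA_only, "g3")
  expect_equal(st$cellB_only, "g2")
  expect_equal(st$repressed, "g4")

  all_on <- stratify_by_expression(
    data.frame(gene_id = c("x", "y"), expr_a = c(2, 3), expr_b = c(2, 3)),
    "status4", threshold = 1)
  expect_equal(length(all_on$both_expressed), 2L)
  expect_equal(lengths(all_on)[-1], c(cellA_only = 0L, cellB_only = 0L,
                                      repressed = 0L))

  qexpr <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      expr_a = sample(1:1000, 100))
  qs <- stratify_by_expression(qexpr, "quantiles", q = 4, threshold = 0)
  expect_equal(unname(lengths(qs)), rep(25L, 4))
  # ties broken by stable gene-id order: duplicate values, deterministic split
  tie <- data.frame(gene_id = sprintf("g%02d", 1:10), expr_a = rep(c(1, 2), each = 5))
  t1 <- stratify_by_expression(tie, "quantiles", q = 2, threshold = 0)
  t2 <- stratify_by_expression(tie[sample.int(10), ], "quantiles", q = 2,
                               threshold = 0)
  expect_identical(t1, t2)
  expect_error(stratify_by_expression(
    data.frame(gene_id = "a", expr_a = NA_real_), "quantiles"), "NA expression")
  expect_error(stratify_by_expression(expr, "status4", universe = c("g1", "zz")),
               "zz")
})

test_that("metagene profiles: constant track is flat; TSS impulse peaks centrally", {
  gm_genes <- gr("chr1", c(2000, 6000, 11000), c(4000, 8000, 14000),
                 strand = c("+", "-", "+"))
  gm_genes$name <- c("a", "b", "c")
  tr <- flat_track(7, len = 20000)
  for (mode in c("tss_centered", "scaled_body")) {
    p <- metagene_profile(tr, gm_genes, mode = mode, flank = 500, body_bins = 20)
    expect_true(all(abs(p$mean_signal - 7) < 1e-12))
  }
  # unit impulse at each TSS
  v <- rep(0, 400)
  for (g in seq_along(gm_genes)) {
    tss <- if (as.character(GenomicRanges::strand(gm_genes))[g] == "-")
      GenomicRanges::end(gm_genes)[g] else GenomicRanges::start(gm_genes)[g]
    v[(tss - 1) %/% 50 + 1] <- 1
  }
  p <- metagene_profile(coverage_track(list(chr1 = v), 50), gm_genes,
                        mode = "tss_centered", flank = 500)
  expect_equal(p$position[which.max(p$mean_signal)], 0)
})

test_that("strand-flip symmetry: mirrored minus-strand genes give identical profiles", {
  ## plus-strand genes with an asymmetric signal (higher downstream of TSS),
  ## and their mirror images on the minus strand of a reflected genome
  len <- 20000L; bin <- 50L
  gplus <- gr("chr1", c(3000, 9000), c(5000, 11000), strand = "+")
  gplus$name <- c("p1", "p2")
  v <- rep(1, len / bin)
  for (i in seq_along(gplus)) {
    tssbin <- (GenomicRanges::start(gplus)[i] - 1) %/% bin + 1
    v[(tssbin + 1):(tssbin + 10)] <- 5 # downstream elevation
  }
  # mirror: position x -> len - x + 1
  gminus <- gr("chr1", len - GenomicRanges::end(gplus) + 1,
               len - GenomicRanges::start(gplus) + 1, strand = "-")
  gminus$name <- c("m1", "m2")
  vm <- rev(v)
  pp <- metagene_profile(coverage_track(list(chr1 = v), bin), gplus,
                         mode = "tss_centered", flank = 1000)
  pm <- metagene_profile(coverage_track(list(chr1 = vm), bin), gminus,
                         mode = "tss_centered", flank = 1000)
  expect_equal(pp$mean_signal, pm$mean_signal)
  ps <- metagene_profile(coverage_track(list(chr1 = v), bin), gplus,
                         mode = "scaled_body", flank = 1000, body_bins = 30)
  ms <- metagene_profile(coverage_track(list(chr1 = vm), bin), gminus,
                         mode = "scaled_body", flank = 1000, body_bins = 30)
  expect_equal(ps$mean_signal, ms$mean_signal)
})

test_that("overall metagene mean equals the gene-count-weighted mean of strata", {
  set.seed(12)
  v <- runif(400, 0, 10)
  tr <- coverage_track(list(chr1 = v), 50)
  st <- seq(2000, by = 1500, length.out = 8)
  genes <- gr("chr1", st, st + 900, strand = sample(c("+", "-"), 8, TRUE))
  genes$name <- paste0("g", 1:8)
  strata <- list(lo = genes$name[1:3], hi = genes$name[4:8])
  p <- metagene_profile(tr, genes, flank = 500, strata = strata)
  pall <- metagene_profile(tr, genes, flank = 500)
  lo <- p[p$stratum == "lo", ]; hi <- p[p$stratum == "hi", ]
  w <- (lo$mean_signal * lo$n_genes + hi$mean_signal * hi$n_genes) /
    (lo$n_genes + hi$n_genes)
  expect_equal(pall$mean_signal, w)
  expect_error(metagene_profile(tr, genes, flank = 500,
                                strata = list(none = "absent_gene")),
               "no usable genes")
})

test_that("bedGraph round trip preserves binned values; track_mean is bp-weighted", {
  gm <- genome_model(c(chr1 = 10000L, chr2 = 4000L))
  set.seed(3)
  tr <- coverage_track(list(chr1 = round(runif(200, 0, 9)),
                            chr2 = round(runif(80, 0, 9))), 50, genome = gm)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, gm, bin_size = 50)
  expect_equal(back$values, tr$values)
  tm <- track_mean(coverage_track(list(chr1 = c(2, 4)), 10), gr("chr1", 6, 15))
  expect_equal(tm, 3) # 5 bp at 2, 5 bp at 4
})
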