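test_that("identical seeds give bit-identical genomes, peaks and cells", {
  s <- tiny_spec()
  g1 <- make_genome(s); g2 <- make_genome(s)
  expect_identical(as.character(g1$genome$sequence), as.character(g2$genome$sequence))
  expect_identical(g1$truth$pqs, g2$truth$pqs)
  p1 <- make_peak_replicates(g1$genome, s)
  p2 <- make_peak_replicates(g2$genome, s)
  expect_identical(lapply(p1$samples, GenomicRanges::granges),
                   lapply(p2$samples, GenomicRanges::granges))
  sc_s <- synthetic_spec(sc_params = list(n_cells = 300L))
  e1 <- make_sc_experiment(sc_s, modalities = "atac")
  e2 <- make_sc_experiment(sc_s, modalities = "atac")
  expect_identical(e1$atac$counts, e2$atac$counts)
  # a different seed changes the data
  g3 <- make_genome(tiny_spec(seed = 2))
  expect_false(identical(as.character(g1$genome$sequence),
                         as.character(g3$genome$sequence)))
})

test_that("spec validation rejects unknown keys and out-of-range fractions", {
  expect_error(synthetic_spec(nonsense = 1), "unknown spec field")
  expect_error(synthetic_spec(peak_params = list(oops = 2)), "unknown peak_params")
  expect_error(synthetic_spec(peak_params = list(reproducibility = 1.4)),
               "fractions")
})

test_that("planted PQS motifs are all recovered by the scanner", {
  g <- make_genome(tiny_spec())
  hits <- scan_pqs_genome(g$genome)
  expect_gte(length(hits), length(g$truth$pqs))
  expect_equal(sum(IRanges::overlapsAny(g$truth$pqs, hits, ignore.strand = TRUE)),
               length(g$truth$pqs))
})

test_that("a genome without genes labels every peak intergenic", {
  g <- make_genome(tiny_spec(n_genes = 0L, peak_params = list(tss_fraction = 0)))
  pk <- make_peak_replicates(g$genome, tiny_spec(n_genes = 0L,
                                                 peak_params = list(tss_fraction = 0)))
  labs <- classify_location(pk$truth$latent, g$genome)
  expect_true(all(labs == "intergenic"))
})

test_that("perfect reproducibility copies the latent set; r = 0 empties the consensus", {
  g <- make_genome(tiny_spec())
  s1 <- tiny_spec(peak_params = list(reproducibility = 1, spurious_rate = 0))
  pk <- make_peak_replicates(g$genome, s1)
  for (sm in pk$samples) {
    expect_equal(GenomicRanges::granges(sm),
                 GenomicRanges::sort(GenomicRanges::granges(pk$truth$latent)))
  }
  s0 <- tiny_spec(peak_params = list(reproducibility = 0, spurious_rate = 0))
  pk0 <- make_peak_replicates(g$genome, s0)
  expect_equal(length(consensus_filter(pk0$samples, consensus_config(2))), 0L)
})

test_that("generated files parse cleanly back through the package readers", {
  g <- make_genome(tiny_spec())
  dir <- withr::local_tempdir()
  write_intervals(g$genome$genes, file.path(dir, "genes.bed"))
  back <- read_intervals(file.path(dir, "genes.bed"))
  expect_equal(GenomicRanges::ranges(back), GenomicRanges::ranges(g$genome$genes))
  Biostrings::writeXStringSet(g$genome$sequence, file.path(dir, "genome.fa"))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(fa), as.character(g$genome$sequence))
  sc <- make_sc_experiment(synthetic_spec(sc_params = list(n_cells = 50L)),
                           modalities = "atac")
  write_cell_matrix(sc$atac$counts, dir, "m")
  m2 <- read_cell_matrix(dir, "m")
  expect_equal(unname(as.matrix(m2)), unname(sc$atac$counts))
  expect_equal(rownames(m2), rownames(sc$atac$counts))
})

test_that("silencing with effect 0 zeroes target counts; e >= 1 warns", {
  sp <- synthetic_spec(sc_params = list(n_cells = 400L, effect_size = 0))
  sc <- make_sc_experiment(sp, modalities = "atac")
  sil <- sc$truth$atac_silenced
  expect_gt(length(sil), 0)
  expect_true(all(sc$atac$counts["HBA", sil] == 0))
  expect_true(all(sc$atac$counts["HBM", sil] == 0))
  expect_true(any(sc$atac$counts["HBB", sil] > 0))
  expect_warning(
    make_sc_experiment(synthetic_spec(sc_params = list(n_cells = 50L,
                                                       effect_size = 1.2)),
                       modalities = "atac"),
    "no detectable effect")
})

test_that("without silencing, case and control locus ratios are indistinguishable", {
  ## two-sample rank test on the HBA:HBB ratio, median p over repeated seeds
  ps <- vapply(1:7, function(s) {
    sp <- synthetic_spec(seed = s,
                         sc_params = list(n_cells = 800L, silenced_fraction = 0))
    sc <- make_sc_experiment(sp, modalities = "atac")
    act <- normalize_atac_activity(sc$atac$counts)
    ann <- relative_activity(act, sc$atac$annotation, anchor = "HBB",
                             targets = "HBA", modality = "atac")
    ok <- ann$ratio_defined
    stats::wilcox.test(ann$HBA_ratio[ok & ann$group == "case"],
                       ann$HBA_ratio[ok & ann$group == "control"])$p.value
  }, 0)
  expect_gt(median(ps), 0.01)
})

test_that("spike-in experiment reports positive counts at the configured cell ratio", {
  g <- make_genome(tiny_spec())
  rx <- make_chiprx_experiment(g$genome, tiny_spec())
  expect_equal(length(rx$tracks), 2L)
  for (s in rx$stats) {
    expect_true(all(unlist(s) > 0))
    expect_equal(s$s_chip / s$h_chip, 0.25, tolerance = 0.01)
  }
})
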