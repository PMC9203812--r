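mk_counts <- function(ids, n_feat = 5L) {
  m <- matrix(rpois(n_feat * length(ids), 5), n_feat, length(ids),
              dimnames = list(paste0("f", seq_len(n_feat)), ids))
  m
}

test_that("QC boundaries are bit-exact to the stated rules", {
  set.seed(1)
  ids <- sprintf("c%02d", 1:8)
  ann <- data.frame(cell_id = ids, sample_id = "s1",
                    passed_filters = c(499, 500, 501, 502, 600, 700, 800, 900))
  m <- mk_counts(ids)
  out <- qc_and_subsample(m, ann, sc_config(atac_cells_per_sample = 6), "atac")
  expect_false(any(c("c01", "c02") %in% out$annotation$cell_id)) # 500 dropped
  expect_equal(nrow(out$annotation), 6L)
  expect_equal(ncol(out$counts), 6L)

  ann_rna <- data.frame(
    cell_id = ids, sample_id = "s1",
    pct_mito = c(7.4, 7.5, 7.6, 1, 1, 1, 1, 1),
    n_features = c(2000, 2000, 2000, 799, 800, 4000, 4001, 1500))
  keep <- qc_and_subsample(m, ann_rna, sc_config(rna_cells_per_sample = 5), "rna")
  kept <- keep$annotation$cell_id
  expect_true(all(c("c01", "c02", "c05", "c06", "c08") %in% kept)) # boundaries kept
  expect_false(any(c("c03", "c04", "c07") %in% kept))
  expect_error(qc_and_subsample(m, ann_rna, sc_config(rna_cells_per_sample = 7),
                                "rna"),
               "5 cells after QC but 7 requested")
})

test_that("subsampling is deterministic under seed and invariant to row order", {
  set.seed(2)
  ids <- sprintf("c%03d", 1:60)
  ann <- data.frame(cell_id = ids, sample_id = rep(c("s1", "s2"), each = 30),
                    passed_filters = 1000)
  m <- mk_counts(ids)
  cfg <- sc_config(atac_cells_per_sample = 20, seed = 42)
  o1 <- qc_and_subsample(m, ann, cfg, "atac")
  o2 <- qc_and_subsample(m, ann, cfg, "atac")
  perm <- sample.int(60)
  o3 <- qc_and_subsample(m[, perm], ann[perm, ], cfg, "atac")
  expect_identical(o1$annotation$cell_id, o2$annotation$cell_id)
  expect_identical(sort(o1$annotation$cell_id), sort(o3$annotation$cell_id))
  expect_equal(table(o1$annotation$sample_id),
               table(c(rep("s1", 20), rep("s2", 20))))
  o4 <- qc_and_subsample(m, ann, sc_config(atac_cells_per_sample = 20, seed = 43),
                         "atac")
  expect_false(identical(o1$annotation$cell_id, o4$annotation$cell_id))
})

test_that("gene activity counts fragments in strand-aware extended gene bodies", {
  genes <- gr("chr1", c(5000, 20000), c(6000, 21000), strand = c("+", "-"))
  genes$name <- c("gp", "gm")
  cfg <- sc_config(gene_upstream_extension = 2000)
  frag <- function(start0, end0, cell) {
    data.frame(chrom = "chr1", start = start0, end = end0, cell_id = cell)
  }
  # 1 bp upstream of plus-strand TSS (BED end 4999 = base 4999, within 2 kb ext)
  f1 <- frag(4990, 4999, "A")
  # 2001 bp upstream: BED end 2999 -> base 2999 < 3000 boundary, excluded
  f2 <- frag(2990, 2999, "A")
  # boundary inclusion: extension reaches 1-based 3000 (BED start 2999)
  f3 <- frag(2999, 3005, "B")
  # minus-strand gene: upstream is rightward
  f4 <- frag(22900, 22999, "B")
  f5 <- frag(23010, 23100, "B")
  fr <- rbind(f1, f2, f3, f4, f5)
  act <- gene_activity(fr, genes, cfg)
  expect_equal(act["gp", "A"], 1)
  expect_equal(act["gp", "B"], 1)
  expect_equal(act["gm", "B"], 1)
  expect_equal(act["gm", "A"], 0)
  # zero-fragment cell yields a zero column
  act2 <- gene_activity(fr, genes, cfg, cell_ids = c("A", "B", "empty"))
  expect_equal(sum(act2[, "empty"]), 0)
  expect_error(gene_activity(fr, gr("chr1", 1, 10, name = "x"), cfg),
               "unstranded")
})

test_that("gene activity equals the brute-force fragment assignment oracle", {
  set.seed(33)
  n_frag <- 400L
  cells <- sprintf("c%02d", 1:20)
  fr <- data.frame(chrom = "chr1",
                   start = s0 <- sample.int(50000, n_frag),
                   end = s0 + sample.int(500, n_frag, TRUE),
                   cell_id = sample(cells, n_frag, TRUE))
  gs <- sample.int(45000, 12)
  genes <- gr("chr1", gs, gs + 2000, strand = sample(c("+", "-"), 12, TRUE))
  genes$name <- paste0("g", 1:12)
  cfg <- sc_config(gene_upstream_extension = 1000)
  act <- as.matrix(gene_activity(fr, genes, cfg, cell_ids = cells))
  brute <- matrix(0, 12, 20, dimnames = list(genes$name, cells))
  for (i in seq_len(n_frag)) {
    fs <- fr$start[i] + 1L; fe <- fr$end[i]
    for (j in 1:12) {
      minus <- as.character(GenomicRanges::strand(genes))[j] == "-"
      gs1 <- GenomicRanges::start(genes)[j] - if (minus) 0L else 1000L
      ge1 <- GenomicRanges::end(genes)[j] + if (minus) 1000L else 0L
      if (fs <= ge1 && gs1 <= fe) {
        brute[j, fr$cell_id[i]] <- brute[j, fr$cell_id[i]] + 1
      }
    }
  }
  expect_equal(act, brute)
})

test_that("log-normalization matches hand-computed values and preserves rank order", {
  counts <- matrix(c(0, 10, 90,
                     5, 5, 0,
                     1, 2, 3), nrow = 3, byrow = TRUE,
                   dimnames = list(c("HBB", "HBA1", "HBA2"),
                                   c("c1", "c2", "c3")))
  cfg <- sc_config(rna_scale_factor = 10000)
  out <- normalize_rna(counts, cfg)
  totals <- colSums(counts)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(out[i, j], log1p(counts[i, j] * 10000 / unname(totals[j])))
  }
  expect_equal(out["HBB", "c1"], 0) # count 0 -> 0
  expect_equal(out["sumHBA", ], out["HBA1", ] + out["HBA2", ])
  # cell_total equal to the scale factor gives ln(1 + count)
  c2 <- matrix(c(9999, 1), 2, dimnames = list(c("a", "b"), "x"))
  expect_equal(normalize_rna(c2, cfg)[1, 1], log1p(9999))
  # within-cell rank order preserved
  set.seed(6)
  cm <- matrix(rpois(200, 20), 20, 10,
               dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  no <- normalize_rna(cm, cfg)
  for (j in 1:10) expect_equal(order(no[, j]), order(cm[, j]))
  cm0 <- cm; cm0[, 3] <- 0
  expect_error(normalize_rna(cm0, cfg), "zero total")
})

test_that("relative activity: proportional cells give constant ratios; zero anchors flagged", {
  lvl <- matrix(log1p(c(100, 50, 200, 100, 400, 200, 0, 30)), nrow = 2,
                dimnames = list(c("HBB", "HBA"), paste0("c", 1:4)))
  ann <- data.frame(cell_id = paste0("c", 1:4), sample_id = "s",
                    group = c("control", "control", "case", "case"))
  ra <- relative_activity(lvl, ann, anchor = "HBB", targets = "HBA",
                          modality = "atac")
  expect_equal(ra$HBA_ratio[1:3], rep(0.5, 3))
  expect_true(is.na(ra$HBA_ratio[4]))
  expect_false(ra$ratio_defined[4])
  expect_error(relative_activity(lvl, ann, anchor = "HBZ", targets = "HBA"),
               "HBZ")
})

test_that("planted silencing drives silenced ratios far below the unsilenced median", {
  sp <- synthetic_spec(sc_params = list(n_cells = 1500L))
  sc <- make_sc_experiment(sp, modalities = "atac")
  act <- normalize_atac_activity(sc$atac$counts)
  ann <- relative_activity(act, sc$atac$annotation, anchor = "HBB",
                           targets = c("HBA", "HBM"), modality = "atac")
  sil <- ann$cell_id %in% sc$truth$atac_silenced
  med_sil <- median(ann$HBA_ratio[sil], na.rm = TRUE)
  med_not <- median(ann$HBA_ratio[!sil], na.rm = TRUE)
  expect_lt(med_sil, 0.5 * med_not)
})

test_that("subpopulation enrichment handles degenerate group structure", {
  lvl <- matrix(log1p(rep(c(100, 20), 6)), nrow = 2,
                dimnames = list(c("HBB", "HBA"), paste0("c", 1:6)))
  ann <- data.frame(cell_id = paste0("c", 1:6), sample_id = "s",
                    group = "case")
  ra <- relative_activity(lvl, ann, anchor = "HBB", targets = "HBA",
                          modality = "atac")
  expect_error(subpopulation_enrichment(ra), "control")
  # all flagged cells in the case group -> infinite odds ratio
  sp <- synthetic_spec(sc_params = list(n_cells = 600L, effect_size = 0.05))
  sc <- make_sc_experiment(sp, modalities = "atac")
  act <- normalize_atac_activity(sc$atac$counts)
  ann2 <- relative_activity(act, sc$atac$annotation, anchor = "HBB",
                            targets = c("HBA", "HBM"), modality = "atac")
  ## force an extreme cutoff so only truly silenced cells can fall below it
  sub <- subpopulation_enrichment(ann2, sc_config(ratio_cutoff_quantile = 0.001))
  if (sum(sub$result$table[3]) == 0 && sub$result$table[1] > 0) {
    expect_identical(sub$result$odds_ratio, Inf)
  }
  expect_true(all(c("result", "flagged", "cutoffs", "per_sample") %in%
                    names(sub)))
})

test_that("RNA modality mirrors the ratio structure with sumHBA", {
  sp <- synthetic_spec(sc_params = list(n_cells = 300L),
                       rna_params = list(n_cells = 1200L))
  sc <- make_sc_experiment(sp, modalities = "rna")
  cfg <- sc_config(rna_cells_per_sample = 900)
  qc <- qc_and_subsample(sc$rna$counts, sc$rna$annotation, cfg, "rna")
  norm <- normalize_rna(qc$counts, cfg)
  expect_true("sumHBA" %in% rownames(norm))
  ann <- relative_activity(norm, qc$annotation, anchor = "HBB",
                           targets = c("sumHBA", "HBM"), cfg, modality = "rna")
  ## anchor-high means relative expression above 8 on the log scale
  expect_true(all(ann$anchor_level[ann$anchor_high] > 8))
  ## unsilenced control cells keep a roughly constant sumHBA:HBB relationship
  ctl <- ann$group == "control" & ann$anchor_high & ann$ratio_defined
  if (sum(ctl) > 20) {
    expect_lt(stats::sd(log(ann$sumHBA_ratio[ctl])), 1)
  }
})
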