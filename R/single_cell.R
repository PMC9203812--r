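## single_cell: scATAC QC/subsampling and gene-activity scoring, per-cell
## relative accessibility/expression statistics, subpopulation flagging
## with case/control exact enrichment, and the scRNA ratio analysis.

#' Single-cell analysis configuration
#'
#' Defaults follow the study conditions: ATAC cells kept when
#' passed_filters > 500 and subsampled to 4000 per sample; RNA cells kept
#' when pct_mito <= 7.5 and 800 <= n_features <= 4000 and subsampled to
#' 4400 per sample; log-normalization with scale factor 10,000; gene
#' bodies extended 2000 bp upstream for activity scoring; cells called
#' anchor-high when the anchor's relative expression exceeds 8 (RNA) or
#' falls in the top anchor quartile (ATAC); the ratio cutoff is the 35th
#' percentile of the control group's target:anchor ratio among anchor-high
#' cells (wide enough that the null case/control odds ratio is stably
#' estimable at thousands of cells per sample; see the methods vignette).
#'
#' @param atac_min_passed_filters,atac_cells_per_sample ATAC QC.
#' @param rna_max_pct_mito,rna_min_features,rna_max_features,rna_cells_per_sample RNA QC.
#' @param rna_scale_factor Log-normalization scale factor.
#' @param gene_upstream_extension bp added upstream of each gene for
#'   activity scoring.
#' @param hbb_high_threshold Anchor-high cutoff on the RNA log-normalized
#'   scale.
#' @param anchor_high_quantile ATAC anchor-high quantile (top quartile).
#' @param ratio_cutoff_quantile Control-group ratio percentile defining
#'   "target-low".
#' @param seed RNG seed for subsampling.
#' @return An object of class \code{ScConfig}.
#' @export
sc_config <- function(atac_min_passed_filters = 500L,
                      atac_cells_per_sample = 4000L,
                      rna_max_pct_mito = 7.5,
                      rna_min_features = 800L,
                      rna_max_features = 4000L,
                      rna_cells_per_sample = 4400L,
                      rna_scale_factor = 10000,
                      gene_upstream_extension = 2000L,
                      hbb_high_threshold = 8,
                      anchor_high_quantile = 0.75,
                      ratio_cutoff_quantile = 0.35,
                      seed = 1L) {
  stopifnot(rna_min_features < rna_max_features,
            atac_min_passed_filters >= 0, rna_max_pct_mito > 0,
            atac_cells_per_sample > 0, rna_cells_per_sample > 0,
            rna_scale_factor > 0, gene_upstream_extension >= 0,
            anchor_high_quantile > 0, anchor_high_quantile < 1,
            ratio_cutoff_quantile > 0, ratio_cutoff_quantile < 1)
  structure(as.list(environment()), class = "ScConfig")
}

#' QC filtering and seeded subsampling of cells
#'
#' ATAC: keep cells with passed_filters strictly greater than the
#' threshold, then subsample each sample to exactly
#' \code{atac_cells_per_sample} cells. RNA: drop cells with
#' pct_mito > 7.5 or n_features outside [800, 4000], then subsample to
#' \code{rna_cells_per_sample}. Subsampling is deterministic under the
#' config seed and invariant to input row order (cells are ordered by id
#' before drawing). If fewer cells survive QC than requested, an error
#' reports the counts.
#'
#' @param counts Features-by-cells count matrix (column names are cell
#'   ids).
#' @param ann data.frame with \code{cell_id}, \code{sample_id} and the
#'   modality's QC fields (\code{passed_filters}, or \code{pct_mito} and
#'   \code{n_features}).
#' @param cfg A \code{\link{sc_config}}.
#' @param modality \code{"atac"} or \code{"rna"}.
#' @return List with the subset \code{counts} and \code{annotation}.
#' @export
qc_and_subsample <- function(counts, ann, cfg = sc_config(),
                             modality = c("atac", "rna")) {
  modality <- match.arg(modality)
  stopifnot(is(cfg, "ScConfig"), all(ann$cell_id %in% colnames(counts)))
  if (modality == "atac") {
    stopifnot(!is.null(ann$passed_filters))
    keep <- ann$passed_filters > cfg$atac_min_passed_filters
    target <- cfg$atac_cells_per_sample
  } else {
    stopifnot(!is.null(ann$pct_mito), !is.null(ann$n_features))
    keep <- ann$pct_mito <= cfg$rna_max_pct_mito &
      ann$n_features >= cfg$rna_min_features &
      ann$n_features <= cfg$rna_max_features
    target <- cfg$rna_cells_per_sample
  }
  ann <- ann[keep, , drop = FALSE]
  picked <- lapply(split(ann$cell_id, ann$sample_id), function(ids) {
    ids <- sort(ids)
    if (length(ids) < target) {
      stop_fmt("sample has %d cells after QC but %d requested",
               length(ids), target)
    }
    s <- with_rng_seed(derive_seed(cfg$seed, paste0("subsample_", ids[1L])),
                       sort(sample.int(length(ids), target)))
    ids[s]
  })
  ids <- unlist(picked, use.names = FALSE)
  ann <- ann[match(ids, ann$cell_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(counts = counts[, ids, drop = FALSE], annotation = ann)
}

#' Per-cell gene-activity scores from ATAC fragments
#'
#' Counts, per cell and per gene, the fragments overlapping the gene body
#' extended upstream (strand-aware) by
#' \code{cfg$gene_upstream_extension} bp. One fragment counts at most once
#' per gene.
#'
#' @param fragments Either a \code{GRanges} with a \code{cell_id} column,
#'   or a data.frame with columns chrom/start/end (BED 0-based half-open)
#'   and cell_id.
#' @param genes Stranded \code{GRanges} with a \code{name} column.
#' @param cfg A \code{\link{sc_config}}.
#' @param cell_ids Optional cell universe (columns of the result); by
#'   default the cells present in \code{fragments}.
#' @return A sparse genes-by-cells count matrix.
#' @export
gene_activity <- function(fragments, genes, cfg = sc_config(),
                          cell_ids = NULL) {
  stopifnot(is(genes, "GRanges"), !is.null(genes$name))
  if (is.data.frame(fragments)) {
    fragments <- GenomicRanges::GRanges(
      fragments$chrom,
      IRanges::IRanges(fragments$start + 1L, fragments$end),
      cell_id = fragments$cell_id)
  }
  stopifnot(is(fragments, "GRanges"), !is.null(fragments$cell_id))
  ext <- cfg$gene_upstream_extension
  str <- as.character(GenomicRanges::strand(genes))
  if (ext > 0L && any(str == "*")) {
    stop_fmt("unstranded gene with upstream extension > 0")
  }
  st <- GenomicRanges::start(genes); en <- GenomicRanges::end(genes)
  st2 <- ifelse(str == "-", st, pmax(st - ext, 1L))
  en2 <- ifelse(str == "-", en + ext, en)
  extended <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                     IRanges::IRanges(st2, en2))
  cells <- cell_ids %||% sort(unique(fragments$cell_id))
  hits <- GenomicRanges::findOverlaps(fragments, extended, ignore.strand = TRUE)
  ci <- match(fragments$cell_id[S4Vectors::queryHits(hits)], cells)
  gi <- S4Vectors::subjectHits(hits)
  ok <- !is.na(ci)
  Matrix::sparseMatrix(i = gi[ok], j = ci[ok], x = 1,
                       dims = c(length(genes), length(cells)),
                       dimnames = list(genes$name, cells))
}

## ln(1 + count * scale / cell_total), columns are cells
lognorm_cp <- function(counts, scale_factor) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop_fmt("%d cell(s) with zero total counts", sum(totals == 0))
  m <- as.matrix(counts)
  log1p(sweep(m, 2L, scale_factor / totals, "*"))
}

#' Log-normalize RNA UMI counts
#'
#' value = ln(1 + count x scale_factor / cell_total). If rows HBA1 and
#' HBA2 are present their normalized values are added as a \code{sumHBA}
#' row.
#'
#' @param counts Genes-by-cells UMI matrix.
#' @param cfg A \code{\link{sc_config}} (scale factor, default 10,000).
#' @return A dense genes-by-cells matrix of normalized values.
#' @export
normalize_rna <- function(counts, cfg = sc_config()) {
  out <- lognorm_cp(counts, cfg$rna_scale_factor)
  if (all(c("HBA1", "HBA2") %in% rownames(out))) {
    out <- rbind(out, sumHBA = out["HBA1", ] + out["HBA2", ])
  }
  out
}

#' Depth-normalize ATAC gene-activity scores
#'
#' Counts per 10,000 fragments per cell, log1p-transformed; the per-cell
#' normalization applied before relative-activity ratios.
#'
#' @param counts Loci-by-cells activity count matrix.
#' @param scale_factor Scale (default 1e4).
#' @return A dense matrix of normalized activities.
#' @export
normalize_atac_activity <- function(counts, scale_factor = 1e4) {
  lognorm_cp(counts, scale_factor)
}

#' Per-cell relative activity of target loci versus an anchor locus
#'
#' Stores, per cell, the anchor level, each target level, and the
#' target:anchor ratio on the linear normalized scale
#' (\code{expm1(level)} ratios; cells with anchor 0 get an undefined
#' ratio and are excluded from ratio summaries). Cells are partitioned
#' into anchor-high versus anchor-low: on the RNA modality by the fixed
#' threshold \code{hbb_high_threshold} on the log-normalized anchor; on
#' ATAC by the pooled anchor quantile \code{anchor_high_quantile}.
#'
#' @param activity Normalized loci-by-cells matrix (from
#'   \code{\link{normalize_rna}} or \code{\link{normalize_atac_activity}}).
#' @param ann Cell annotation data.frame (\code{cell_id}, \code{group}).
#' @param anchor Anchor locus id (HBB-like).
#' @param targets Target locus ids (HBA-like, HBM-like).
#' @param cfg A \code{\link{sc_config}}.
#' @param modality \code{"atac"} or \code{"rna"}.
#' @return \code{ann} with derived columns \code{anchor_level},
#'   \code{<target>_level}, \code{<target>_ratio}, \code{ratio_defined},
#'   \code{anchor_high}.
#' @export
relative_activity <- function(activity, ann, anchor = "HBB",
                              targets = c("HBA", "HBM"), cfg = sc_config(),
                              modality = c("atac", "rna")) {
  modality <- match.arg(modality)
  missing <- setdiff(c(anchor, targets), rownames(activity))
  if (length(missing)) stop_fmt("locus missing from activity matrix: %s",
                                paste(missing, collapse = ", "))
  stopifnot(all(ann$cell_id %in% colnames(activity)))
  act <- activity[, ann$cell_id, drop = FALSE]
  a <- act[anchor, ]
  ann$anchor_level <- a
  ann$ratio_defined <- a > 0
  for (t in targets) {
    tl <- act[t, ]
    ann[[paste0(t, "_level")]] <- tl
    ann[[paste0(t, "_ratio")]] <- ifelse(a > 0, expm1(tl) / expm1(a), NA_real_)
  }
  ann$anchor_high <- if (modality == "rna") {
    a > cfg$hbb_high_threshold
  } else {
    a >= quantile(a, cfg$anchor_high_quantile, names = FALSE)
  }
  attr(ann, "targets") <- targets
  attr(ann, "anchor") <- anchor
  ann
}

#' Flag the silenced subpopulation and test its case/control enrichment
#'
#' Flags cells that are anchor-high and whose target:anchor ratio falls
#' below the cutoff for every target (the silenced phenotype is a
#' coordinated loss at all target loci), where each target's cutoff
#' is the \code{ratio_cutoff_quantile} percentile (default 35th) of the
#' control group's ratios among anchor-high cells. The case/control x
#' flagged/not 2x2 table is tested with the exact test; per-sample tables
#' (each case sample versus all controls) are also reported.
#'
#' @param ann Output of \code{\link{relative_activity}}.
#' @param cfg A \code{\link{sc_config}}.
#' @param control_group,case_group Group labels (defaults "control",
#'   "case").
#' @return A list with \code{result} (\code{EnrichmentResult}),
#'   \code{flagged} (cell ids), \code{cutoffs}, and \code{per_sample}
#'   (list of \code{EnrichmentResult} per case sample).
#' @export
subpopulation_enrichment <- function(ann, cfg = sc_config(),
                                     control_group = "control",
                                     case_group = "case") {
  targets <- attr(ann, "targets") %||% stop_fmt(
    "annotation lacks relative_activity columns")
  groups <- unique(ann$group)
  if (!all(c(control_group, case_group) %in% groups)) {
    stop_fmt("need both '%s' and '%s' groups with cells", control_group, case_group)
  }
  is_ctl <- ann$group == control_group
  is_case <- ann$group == case_group
  if (sum(is_ctl) == 0L || sum(is_case) == 0L) {
    stop_fmt("a group has zero cells")
  }
  cutoffs <- vapply(targets, function(t) {
    r <- ann[[paste0(t, "_ratio")]][is_ctl & ann$anchor_high & ann$ratio_defined]
    if (length(r) == 0L) stop_fmt("no anchor-high control cells for cutoff")
    quantile(r, cfg$ratio_cutoff_quantile, names = FALSE)
  }, 0)
  below <- Reduce(`&`, lapply(targets, function(t) {
    r <- ann[[paste0(t, "_ratio")]]
    !is.na(r) & r < cutoffs[[t]]
  }))
  flagged <- ann$anchor_high & ann$ratio_defined & below
  test_pair <- function(case_mask) {
    tab <- contingency_table(sum(case_mask & flagged), sum(case_mask & !flagged),
                             sum(is_ctl & flagged), sum(is_ctl & !flagged))
    ft <- fisher_exact(tab)
    structure(list(table = tab, p_value = ft$p_value,
                   odds_ratio = ft$odds_ratio,
                   odds_ratio_raw = ft$odds_ratio_raw,
                   or_undefined = ft$or_undefined,
                   null_description = list(cutoffs = cutoffs)),
              class = "EnrichmentResult")
  }
  per_sample <- lapply(split(seq_len(nrow(ann))[is_case],
                             ann$sample_id[is_case]), function(idx) {
    mask <- rep(FALSE, nrow(ann)); mask[idx] <- TRUE
    test_pair(mask)
  })
  list(result = test_pair(is_case),
       flagged = ann$cell_id[flagged],
       cutoffs = cutoffs,
       per_sample = per_sample)
}

#' Write a sparse count matrix as MatrixMarket + cells/features TSV
#'
#' @param counts Features-by-cells matrix.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The directory, invisibly.
#' @export
write_cell_matrix <- function(counts, dir, prefix = "matrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, paste0(prefix, ".mtx")))
  writeLines(rownames(counts), file.path(dir, paste0(prefix, "_features.tsv")))
  writeLines(colnames(counts), file.path(dir, paste0(prefix, "_cells.tsv")))
  invisible(dir)
}

#' Read a MatrixMarket matrix with cells/features TSV back
#'
#' @param dir Directory written by \code{\link{write_cell_matrix}}.
#' @param prefix File name prefix.
#' @return A sparse features-by-cells matrix with dimnames.
#' @export
read_cell_matrix <- function(dir, prefix = "matrix") {
  m <- Matrix::readMM(file.path(dir, paste0(prefix, ".mtx")))
  rownames(m) <- readLines(file.path(dir, paste0(prefix, "_features.tsv")))
  colnames(m) <- readLines(file.path(dir, paste0(prefix, "_cells.tsv")))
  m
}
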