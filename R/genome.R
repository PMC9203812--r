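## genome_io: coordinate model, interval algebra, readers/writers.
##
## The in-memory currency for regions is GRanges (1-based, closed), the
## native Bioconductor convention. BED on disk is 0-based half-open and is
## converted at the reader/writer boundary, so "overlap" always means >= 1
## shared base and abutting BED intervals never overlap.

#' Construct an interval set
#'
#' Wraps a \code{GRanges} with the provenance fields used throughout the
#' package (a label, a sample id and an antibody), sorts it, and flags
#' duplicated records.
#'
#' @param gr A \code{GRanges}.
#' @param label,sample_id,antibody Optional provenance strings.
#' @return A sorted \code{GRanges}; provenance is stored in
#'   \code{S4Vectors::metadata}, and the number of duplicated records in
#'   \code{metadata(x)$n_duplicates}.
#' @export
interval_set <- function(gr, label = NULL, sample_id = NULL, antibody = NULL) {
  stopifnot(is(gr, "GRanges"))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  md <- S4Vectors::metadata(gr)
  md$label <- label
  md$sample_id <- sample_id
  md$antibody <- antibody
  md$n_duplicates <- sum(duplicated(gr))
  S4Vectors::metadata(gr) <- md
  gr
}

parse_interval_table <- function(lines, path, one_based = FALSE) {
  keep <- !grepl("^(#|track |browser )", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_fmt("malformed line (fewer than 3 tab-separated columns) at line %d of %s",
             lineno[which(nf < 3L)[1L]], path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end < 0 |
                 start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop_fmt("malformed coordinates at line %d of %s", lineno[bad[1L]], path)
  }
  if (!one_based) {
    ge <- which(start >= end)
    if (length(ge)) stop_fmt("start >= end at line %d of %s", lineno[ge[1L]], path)
    start <- start + 1 # BED 0-based half-open -> 1-based closed
  } else {
    ge <- which(start > end)
    if (length(ge)) stop_fmt("start > end at line %d of %s", lineno[ge[1L]], path)
  }
  nm <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  sc <- suppressWarnings(as.numeric(
    ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""), NA_character_)))
  st <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  st[!st %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = st)
  gr$name <- nm
  gr$score <- sc
  gr
}

#' Read genomic intervals from BED or TSV
#'
#' BED coordinates are interpreted verbatim as 0-based half-open; a TSV in a
#' 1-based closed dialect can be converted at this boundary with
#' \code{one_based = TRUE}. Malformed lines and \code{start >= end} raise an
#' error naming the offending line.
#'
#' @param path File path; plain text, tab-separated, columns
#'   chrom/start/end and optionally name/score/strand.
#' @param format \code{"BED"} (default) or \code{"TSV"}.
#' @param one_based Interpret coordinates as 1-based closed (TSV dialects).
#' @param label,sample_id,antibody Provenance passed to
#'   \code{\link{interval_set}}.
#' @return A sorted \code{GRanges} with \code{name} and \code{score}
#'   metadata columns.
#' @export
read_intervals <- function(path, format = c("BED", "TSV"), one_based = FALSE,
                           label = NULL, sample_id = NULL, antibody = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  gr <- parse_interval_table(readLines(path), path, one_based = one_based)
  interval_set(gr, label = label %||% basename(path),
               sample_id = sample_id, antibody = antibody)
}

#' Write genomic intervals as BED
#'
#' Emits BED3/BED6 (0-based half-open), tab-separated, newline-terminated,
#' with no header unless \code{header = TRUE}.
#'
#' @param x A \code{GRanges}.
#' @param path Output path.
#' @param header Write a commented column header line.
#' @return \code{path}, invisibly.
#' @export
write_intervals <- function(x, path, header = FALSE) {
  stopifnot(is(x, "GRanges"))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = if (!is.null(x$name)) ifelse(is.na(x$name), ".", x$name) else ".",
    score = if (!is.null(x$score)) ifelse(is.na(x$score), 0, x$score) else 0,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(x))),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes TSV
#'
#' @param path TSV with columns chromosome name and length in bp.
#' @return A named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_fmt("chromosome sizes file needs 2 columns: %s", path)
  sz <- as.integer(df[[2L]])
  if (anyNA(sz) || any(sz <= 0)) stop_fmt("non-positive chromosome size in %s", path)
  setNames(sz, as.character(df[[1L]]))
}

#' Assemble a genome model
#'
#' Bundles chromosome sizes with the annotation layers the analyses consume
#' (genes with strand, CpG islands, blacklist, per-factor TFBS, open
#' chromatin) and an optional genome sequence. Every layer interval is
#' checked to lie within its chromosome.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param genes Stranded \code{GRanges} of gene bodies (TSS is the stranded
#'   5' end; for a minus-strand gene that is its \code{end} coordinate).
#' @param cpg_islands,blacklist,open_chromatin Optional \code{GRanges} layers.
#' @param tfbs Optional named list of \code{GRanges}, one per factor.
#' @param sequence Optional \code{Biostrings::DNAStringSet} named by
#'   chromosome.
#' @return An object of class \code{GenomeModel}.
#' @export
genome_model <- function(chrom_sizes, genes = NULL, cpg_islands = NULL,
                         blacklist = NULL, tfbs = NULL,
                         open_chromatin = NULL, sequence = NULL) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0))
  chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  check_layer <- function(gr, what) {
    if (is.null(gr)) return(GenomicRanges::GRanges())
    stopifnot(is(gr, "GRanges"))
    chr <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(chr), names(chrom_sizes))
    if (length(unknown)) {
      stop_fmt("%s layer uses unknown chromosome '%s'", what, unknown[1L])
    }
    if (any(GenomicRanges::end(gr) > chrom_sizes[chr]) ||
        any(GenomicRanges::start(gr) < 1L)) {
      stop_fmt("%s layer has intervals outside chromosome bounds", what)
    }
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  }
  if (!is.null(sequence)) {
    stopifnot(is(sequence, "DNAStringSet"))
    if (!all(names(chrom_sizes) %in% names(sequence)) ||
        !all(Biostrings::width(sequence[names(chrom_sizes)]) == chrom_sizes)) {
      stop_fmt("sequence lengths disagree with chrom_sizes")
    }
  }
  obj <- list(
    chrom_sizes = chrom_sizes,
    layers_present = c(genes = !is.null(genes),
                       cpg_islands = !is.null(cpg_islands),
                       blacklist = !is.null(blacklist),
                       open_chromatin = !is.null(open_chromatin)),
    genes = check_layer(genes, "genes"),
    cpg_islands = check_layer(cpg_islands, "cpg_islands"),
    blacklist = check_layer(blacklist, "blacklist"),
    tfbs = lapply(tfbs %||% list(), check_layer, what = "tfbs"),
    open_chromatin = check_layer(open_chromatin, "open_chromatin"),
    sequence = sequence
  )
  class(obj) <- "GenomeModel"
  obj
}

#' @exportS3Method base::print
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosome(s), %s bp total\n",
              length(x$chrom_sizes),
              format(sum(as.numeric(x$chrom_sizes)), big.mark = ",")))
  cat(sprintf("  genes: %d  cpg_islands: %d  blacklist: %d  open_chromatin: %d  tfbs factors: %d\n",
              length(x$genes), length(x$cpg_islands), length(x$blacklist),
              length(x$open_chromatin), length(x$tfbs)))
  cat(sprintf("  sequence: %s\n", if (is.null(x$sequence)) "absent" else "attached"))
  invisible(x)
}

#' Whole-genome GRanges of a genome model
#' @param genome A \code{GenomeModel}.
#' @return A \code{GRanges} with one range per chromosome.
#' @export
genome_ranges <- function(genome) {
  stopifnot(is(genome, "GenomeModel"))
  GenomicRanges::GRanges(names(genome$chrom_sizes),
                         IRanges::IRanges(1L, unname(genome$chrom_sizes)))
}

#' Transcription start sites of stranded genes
#'
#' @param genes Stranded \code{GRanges}.
#' @return Width-1 \code{GRanges} at the stranded 5' end of each gene.
#' @export
tss_of <- function(genes) {
  stopifnot(is(genes, "GRanges"))
  if (any(GenomicRanges::strand(genes) == "*")) {
    stop_fmt("TSS undefined for unstranded genes")
  }
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' All overlapping pairs between two interval sets
#'
#' A pair is emitted iff the two intervals share at least one base
#' (half-open BED abutment does not overlap).
#'
#' @param a,b \code{GRanges}.
#' @return A data.frame with the indices and coordinates of each
#'   overlapping (a, b) pair.
#' @export
overlap_pairs <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.frame(
    a_index = qi, b_index = si,
    a_chrom = as.character(GenomicRanges::seqnames(a))[qi],
    a_start = GenomicRanges::start(a)[qi], a_end = GenomicRanges::end(a)[qi],
    b_chrom = as.character(GenomicRanges::seqnames(b))[si],
    b_start = GenomicRanges::start(b)[si], b_end = GenomicRanges::end(b)[si],
    stringsAsFactors = FALSE
  )
}

#' Classify peaks as promoter, gene body or intergenic
#'
#' The promoter window is \code{[TSS - promoter_up, TSS + promoter_down)}
#' oriented by gene strand; precedence is promoter > gene_body > intergenic,
#' so every peak receives exactly one label.
#'
#' @param peaks \code{GRanges}.
#' @param genome A \code{GenomeModel} with a genes layer.
#' @param promoter_up,promoter_down Promoter window extent in bp upstream /
#'   downstream of the TSS (defaults 1000 / 500).
#' @return A factor of labels (promoter, gene_body, intergenic), one per
#'   peak, in input order.
#' @export
classify_location <- function(peaks, genome, promoter_up = 1000L,
                              promoter_down = 500L) {
  stopifnot(is(peaks, "GRanges"), is(genome, "GenomeModel"))
  if (!isTRUE(genome$layers_present[["genes"]])) {
    stop_fmt("genome model has no genes layer")
  }
  if (length(genome$genes) == 0L) { # genes layer supplied but empty
    return(factor(rep("intergenic", length(peaks)),
                  levels = c("promoter", "gene_body", "intergenic")))
  }
  prom <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(genome$genes, upstream = promoter_up,
                             downstream = promoter_down)))
  in_prom <- IRanges::overlapsAny(peaks, prom, ignore.strand = TRUE)
  in_body <- IRanges::overlapsAny(peaks, genome$genes, ignore.strand = TRUE)
  lab <- ifelse(in_prom, "promoter", ifelse(in_body, "gene_body", "intergenic"))
  factor(lab, levels = c("promoter", "gene_body", "intergenic"))
}
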