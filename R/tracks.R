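## signal_tracks: binned coverage, per-100M and ChIP-Rx normalization,
## expression strata, metagene/TSS profiles.

#' Construct a binned coverage track
#'
#' @param values Named list (one numeric vector per chromosome) of
#'   non-negative bin values.
#' @param bin_size Bin width in bp.
#' @param genome Optional \code{GenomeModel}; if supplied, vector lengths
#'   are checked against \code{ceiling(chrom_len / bin_size)}.
#' @param normalization One of raw, per100M, chiprx.
#' @param factor Normalization factor already applied (> 0).
#' @param sample_id Provenance string.
#' @return An object of class \code{CoverageTrack}.
#' @export
coverage_track <- function(values, bin_size, genome = NULL,
                           normalization = c("raw", "per100M", "chiprx"),
                           factor = 1, sample_id = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(is.list(values), !is.null(names(values)), bin_size >= 1, factor > 0)
  if (any(vapply(values, function(v) any(!is.finite(v)) || any(v < 0), TRUE))) {
    stop_fmt("coverage values must be finite and non-negative")
  }
  if (!is.null(genome)) {
    expected <- ceiling(genome$chrom_sizes / bin_size)
    if (!all(names(values) %in% names(expected)) ||
        !all(lengths(values) == expected[names(values)])) {
      stop_fmt("bin vector lengths disagree with ceiling(chrom_len / bin_size)")
    }
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 normalization = normalization, factor = factor,
                 sample_id = sample_id),
            class = "CoverageTrack")
}

#' @exportS3Method base::print
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack (%s, factor %.4g): %d chromosome(s), bin %d bp\n",
              x$normalization, x$factor, length(x$values), x$bin_size))
  invisible(x)
}

scale_track <- function(track, factor, normalization) {
  track$values <- lapply(track$values, `*`, factor)
  track$factor <- track$factor * factor
  track$normalization <- normalization
  track
}

#' Normalize a coverage track per N mapped reads
#'
#' Scales every bin by \code{denominator / mapped_reads} (default: per 100
#' million mapped reads). Re-normalizing an already normalized track is
#' rejected.
#'
#' @param track A raw \code{CoverageTrack}.
#' @param mapped_reads Mapped read count (> 0); by convention computed
#'   after duplicate removal, either genome-wide or restricted to peak
#'   regions -- the caller chooses which count to supply.
#' @param denominator Reference read count (default 1e8).
#' @return The scaled \code{CoverageTrack}.
#' @export
normalize_per_reads <- function(track, mapped_reads, denominator = 1e8) {
  stopifnot(is(track, "CoverageTrack"))
  if (track$normalization != "raw") {
    stop_fmt("track is already normalized (%s)", track$normalization)
  }
  if (!is.numeric(mapped_reads) || mapped_reads <= 0) {
    stop_fmt("mapped_reads must be > 0")
  }
  scale_track(track, denominator / mapped_reads, "per100M")
}

#' Spike-in read-count summary
#'
#' @param h_chip,s_chip Mapped target-genome and spike-genome reads in the
#'   ChIP sample.
#' @param h_input,s_input The same counts in the matched input.
#' @return An object of class \code{SpikeInStats}.
#' @export
spike_in_stats <- function(h_chip, s_chip, h_input, s_input) {
  x <- c(h_chip = h_chip, s_chip = s_chip, h_input = h_input, s_input = s_input)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_fmt("all spike-in read counts must be > 0")
  }
  structure(as.list(x), class = "SpikeInStats")
}

#' ChIP-Rx (spike-in) normalization factor
#'
#' The per-100M factor adjusted by the ratio of spike:target mapped reads
#' in ChIP versus input:
#' \deqn{\gamma = \frac{s_{input}/h_{input}}{s_{chip}/h_{chip}} \times
#'       \frac{10^8}{h_{chip}}}
#' Tracks scaled by \eqn{\gamma} are quantitatively comparable across
#' samples sharing the same true spike:target cell ratio.
#'
#' @param s A \code{\link{spike_in_stats}}.
#' @param denominator Reference read count (default 1e8).
#' @return A positive scale factor.
#' @export
chiprx_factor <- function(s, denominator = 1e8) {
  stopifnot(is(s, "SpikeInStats"))
  (s$s_input / s$h_input) / (s$s_chip / s$h_chip) * (denominator / s$h_chip)
}

#' Apply ChIP-Rx normalization to a raw track
#'
#' @param track A raw \code{CoverageTrack}.
#' @param s A \code{\link{spike_in_stats}}.
#' @param denominator Reference read count (default 1e8).
#' @return The scaled \code{CoverageTrack}.
#' @export
normalize_chiprx <- function(track, s, denominator = 1e8) {
  stopifnot(is(track, "CoverageTrack"))
  if (track$normalization != "raw") {
    stop_fmt("track is already normalized (%s)", track$normalization)
  }
  scale_track(track, chiprx_factor(s, denominator), "chiprx")
}

#' Mean track signal over intervals
#'
#' Base-pair-weighted mean of bin values across each interval.
#'
#' @param track A \code{CoverageTrack}.
#' @param gr A \code{GRanges}.
#' @return Numeric vector, one mean per range (NA for chromosomes absent
#'   from the track).
#' @export
track_mean <- function(track, gr) {
  stopifnot(is(track, "CoverageTrack"), is(gr, "GRanges"))
  b <- track$bin_size
  chr <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  vapply(seq_along(gr), function(i) {
    v <- track$values[[chr[i]]]
    if (is.null(v)) return(NA_real_)
    i0 <- (st[i] - 1L) %/% b + 1L
    i1 <- min((en[i] - 1L) %/% b + 1L, length(v))
    if (i0 > length(v)) return(NA_real_)
    idx <- i0:i1
    lo <- pmax((idx - 1L) * b + 1L, st[i])
    hi <- pmin(idx * b, en[i])
    w <- hi - lo + 1L
    sum(v[idx] * w) / sum(w)
  }, 0)
}

#' Read a bedGraph into a binned coverage track
#'
#' @param path bedGraph path (0-based half-open, 4 columns).
#' @param genome A \code{GenomeModel} (defines chromosome lengths).
#' @param bin_size Bin width in bp.
#' @param sample_id Provenance string.
#' @return A raw \code{CoverageTrack}; each bin holds the positional mean
#'   of the bedGraph signal over the bin (uncovered positions count as 0).
#' @export
read_bedgraph <- function(path, genome, bin_size = 50L, sample_id = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "integer", "integer", "numeric"))
  values <- lapply(names(genome$chrom_sizes), function(chr) {
    len <- genome$chrom_sizes[[chr]]
    nb <- ceiling(len / bin_size)
    v <- numeric(nb)
    sub <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(sub)) {
      full <- numeric(len)
      for (j in seq_len(nrow(sub))) {
        full[(sub$start[j] + 1L):min(sub$end[j], len)] <- sub$value[j]
      }
      cs <- c(0, cumsum(full))
      starts <- seq.int(1L, by = bin_size, length.out = nb)
      ends <- pmin(starts + bin_size - 1L, len)
      v <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
    }
    v
  })
  names(values) <- names(genome$chrom_sizes)
  coverage_track(values, bin_size, genome = genome, sample_id = sample_id)
}

#' Write a coverage track as bedGraph
#'
#' Consecutive equal-valued bins are merged into single records; zero bins
#' are omitted.
#'
#' @param track A \code{CoverageTrack}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  b <- track$bin_size
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    df <- data.frame(chr, (starts_bin[keep] - 1L) * b,
                     ends_bin[keep] * b, r$values[keep])
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Partition genes into expression strata
#'
#' \code{status4} yields the four classes expressed-in-both, A-only,
#' B-only, repressed (detection: value >= \code{threshold});
#' \code{quantiles} yields \code{q} equal-count bins of the genes expressed
#' in cell type A, ordered by level with ties broken by gene id so the
#' partition is deterministic.
#'
#' @param expr data.frame with columns \code{gene_id}, \code{expr_a} and
#'   (for status4) \code{expr_b}.
#' @param mode \code{"status4"} or \code{"quantiles"}.
#' @param q Number of quantile bins.
#' @param threshold Detection threshold (same units as the expression
#'   values).
#' @param universe Optional character vector of gene ids that must all be
#'   present; missing genes raise an error listing them.
#' @return Named list of character vectors of gene ids; strata are
#'   disjoint and exhaustive over their universe.
#' @export
stratify_by_expression <- function(expr, mode = c("status4", "quantiles"),
                                   q = 5L, threshold = 1,
                                   universe = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr),
            "expr_a" %in% names(expr))
  if (!is.null(universe)) {
    missing <- setdiff(universe, expr$gene_id)
    if (length(missing)) {
      stop_fmt("expression values missing for gene(s): %s",
               paste(head(missing, 10L), collapse = ", "))
    }
  }
  if (anyNA(expr$expr_a) || (mode == "status4" && anyNA(expr$expr_b))) {
    bad <- expr$gene_id[!stats::complete.cases(
      expr[, intersect(c("expr_a", "expr_b"), names(expr))])]
    stop_fmt("NA expression for gene(s): %s",
             paste(head(bad, 10L), collapse = ", "))
  }
  if (mode == "status4") {
    stopifnot("expr_b" %in% names(expr))
    on_a <- expr$expr_a >= threshold
    on_b <- expr$expr_b >= threshold
    list(both_expressed = expr$gene_id[on_a & on_b],
         cellA_only = expr$gene_id[on_a & !on_b],
         cellB_only = expr$gene_id[!on_a & on_b],
         repressed = expr$gene_id[!on_a & !on_b])
  } else {
    stopifnot(q >= 1L)
    keep <- expr$expr_a >= threshold
    sub <- expr[keep, , drop = FALSE]
    ord <- order(sub$expr_a, sub$gene_id)
    ids <- sub$gene_id[ord]
    n <- length(ids)
    if (n == 0L) stop_fmt("no expressed genes above threshold")
    bin <- ceiling(seq_len(n) * q / n)
    setNames(split(ids, bin), paste0("q", sort(unique(bin))))
  }
}

#' Metagene / TSS signal profile, optionally stratified
#'
#' Averages track signal over genes on a common axis: either TSS-centered
#' (+/- \code{flank} bp) or length-scaled gene bodies (\code{body_bins}
#' interpolated bins with \code{flank}-bp flanks). Minus-strand genes are
#' coordinate-reversed so the axis always reads 5' to 3'. Genes whose
#' window is truncated by a chromosome end (or, in scaled mode, shorter
#' than \code{body_bins} bases) are dropped and counted.
#'
#' @param track A \code{CoverageTrack}.
#' @param genes Stranded \code{GRanges} with a \code{name} column.
#' @param mode \code{"tss_centered"} or \code{"scaled_body"}.
#' @param flank Flank in bp; must be a multiple of the track bin size.
#' @param body_bins Number of interpolated body bins (scaled mode).
#' @param strata Optional named list of gene-id vectors (from
#'   \code{\link{stratify_by_expression}}); default a single "all" stratum.
#' @return A data.frame with columns \code{position} (bp offset from TSS,
#'   or bin index with body bins 1..body_bins), \code{zone},
#'   \code{mean_signal}, \code{stratum}, \code{n_genes}; attribute
#'   \code{n_dropped} counts unusable genes per stratum.
#' @export
metagene_profile <- function(track, genes, mode = c("tss_centered", "scaled_body"),
                             flank = 2000L, body_bins = 100L, strata = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(track, "CoverageTrack"), is(genes, "GRanges"), flank >= 0L)
  if (any(GenomicRanges::strand(genes) == "*")) {
    stop_fmt("metagene profiling requires stranded genes")
  }
  b <- track$bin_size
  if (flank %% b != 0L) stop_fmt("flank must be a multiple of bin_size (%d)", b)
  fb <- flank %/% b
  gene_vector <- function(i) {
    chr <- as.character(GenomicRanges::seqnames(genes))[i]
    v <- track$values[[chr]]
    if (is.null(v)) return(NULL)
    st <- GenomicRanges::start(genes)[i]; en <- GenomicRanges::end(genes)[i]
    minus <- as.character(GenomicRanges::strand(genes))[i] == "-"
    if (mode == "tss_centered") {
      tss <- if (minus) en else st
      ti <- (tss - 1L) %/% b + 1L
      idx <- (ti - fb):(ti + fb)
      if (idx[1L] < 1L || idx[length(idx)] > length(v)) return(NULL)
      out <- v[idx]
    } else {
      if (en - st + 1L < body_bins) return(NULL)
      i0 <- (st - 1L) %/% b + 1L
      i1 <- (en - 1L) %/% b + 1L
      if (i0 - fb < 1L || i1 + fb > length(v)) return(NULL)
      body <- v[i0:i1]
      body <- if (length(body) == 1L) rep(body, body_bins) else
        approx(seq_along(body), body, n = body_bins)$y
      out <- if (fb == 0L) body else
        c(v[(i0 - fb):(i0 - 1L)], body, v[(i1 + 1L):(i1 + fb)])
    }
    if (minus) rev(out) else out
  }
  if (is.null(genes$name)) genes$name <- paste0("gene_", seq_along(genes))
  if (is.null(strata)) strata <- list(all = genes$name)
  npos <- if (mode == "tss_centered") 2L * fb + 1L else body_bins + 2L * fb
  position <- if (mode == "tss_centered") seq(-fb, fb) * b else
    seq(1L - fb, body_bins + fb)
  zone <- if (mode == "tss_centered") rep("tss_flank", npos) else
    c(rep("upstream", fb), rep("body", body_bins), rep("downstream", fb))
  vecs <- lapply(seq_along(genes), gene_vector)
  names(vecs) <- genes$name
  res <- lapply(names(strata), function(lab) {
    vs <- vecs[names(vecs) %in% strata[[lab]]]
    vs <- vs[!vapply(vs, is.null, TRUE)]
    if (length(vs) == 0L) stop_fmt("stratum '%s' has no usable genes", lab)
    mat <- do.call(rbind, vs)
    data.frame(position = position, zone = zone,
               mean_signal = colMeans(mat), stratum = lab,
               n_genes = length(vs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  dropped <- vapply(names(strata), function(lab) {
    sum(vapply(vecs[names(vecs) %in% strata[[lab]]], is.null, TRUE))
  }, 0L)
  attr(out, "n_dropped") <- dropped
  out
}
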