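## pqs_scan: putative G-quadruplex-forming sequence (PQS) detection.
##
## The motif rule is the canonical Quadparser pattern: n_runs runs of at
## least min_run guanines separated by loops of loop_min..loop_max
## non-N bases, plus its reverse-complement (C-run) mirror on the minus
## strand. Matching is leftmost-greedy and non-overlapping per strand;
## N never matches and soft-masked lowercase only matches when
## match_lowercase = TRUE.

pqs_pattern <- function(min_run, loop_min, loop_max, n_runs) {
  sprintf("G{%d,}(?:[ACGT]{%d,%d}G{%d,}){%d}",
          min_run, loop_min, loop_max, min_run, n_runs - 1L)
}

## Anchored greedy decomposition of a matched PQS substring into G-run and
## loop lengths (longest-first, mirroring the scanner's greediness).
decompose_pqs <- function(s, min_run, loop_min, loop_max, n_runs) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  g_prefix <- function(from) {
    i <- from
    while (i <= n && ch[i] == "G") i <- i + 1L
    i - from
  }
  rec <- function(pos, runs_left, runs, loops) {
    if (runs_left == 0L) {
      if (pos == n + 1L) return(list(runs = runs, loops = loops))
      return(NULL)
    }
    gmax <- g_prefix(pos)
    if (gmax < min_run) return(NULL)
    for (g in seq(gmax, min_run)) {
      after <- pos + g
      if (runs_left == 1L) {
        res <- rec(after, 0L, c(runs, g), loops)
        if (!is.null(res)) return(res)
      } else {
        upper <- min(loop_max, n - after + 1L)
        if (upper >= loop_min) {
          for (l in seq(upper, loop_min)) {
            res <- rec(after + l, runs_left - 1L, c(runs, g), c(loops, l))
            if (!is.null(res)) return(res)
          }
        }
      }
    }
    NULL
  }
  rec(1L, n_runs, integer(0), integer(0))
}

scan_one_strand <- function(seq_chr, pattern) {
  m <- gregexpr(pattern, seq_chr, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), len = integer(0)))
  }
  data.frame(start = as.integer(m), len = attr(m, "match.length"))
}

#' Scan a sequence for putative G-quadruplex motifs (PQS)
#'
#' Detects, on both strands, runs-and-loops quadruplex motifs
#' (default: four runs of >= 3 G separated by loops of 1-7 nt). Plus-strand
#' hits match the G-pattern; minus-strand hits are G-pattern matches on the
#' reverse complement, reported in plus-strand coordinates. Hits are
#' maximal, leftmost-greedy and non-overlapping within each strand.
#'
#' @param sequence A character string or \code{Biostrings::DNAString} over
#'   A/C/G/T/N (lowercase permitted; see \code{match_lowercase}).
#' @param chrom Chromosome name for the returned coordinates.
#' @param min_run Minimum G-run length (default 3).
#' @param loop_min,loop_max Loop length bounds in nt (defaults 1 and 7).
#' @param n_runs Number of G runs (default 4).
#' @param match_lowercase If \code{TRUE}, soft-masked lowercase bases match
#'   as their uppercase equivalents; by default they never match.
#' @return A stranded \code{GRanges} of hits with metadata columns
#'   \code{matched_sequence} (on the G-rich strand), \code{g_run_lengths}
#'   and \code{loop_lengths} (comma-joined), and \code{score} (hit width).
#' @export
scan_pqs <- function(sequence, chrom = "seq", min_run = 3L, loop_min = 1L,
                     loop_max = 7L, n_runs = 4L, match_lowercase = FALSE) {
  stopifnot(min_run >= 1L, loop_min >= 1L, loop_min <= loop_max, n_runs >= 2L)
  seq_chr <- as.character(sequence)
  stopifnot(length(seq_chr) == 1L)
  bad <- regexpr("[^ACGTNacgtn]", seq_chr)
  if (bad != -1L) {
    stop_fmt("invalid alphabet symbol '%s' at offset %d",
             substr(seq_chr, bad, bad), as.integer(bad) - 1L)
  }
  if (match_lowercase) seq_chr <- toupper(seq_chr)
  pat <- pqs_pattern(min_run, loop_min, loop_max, n_runs)
  L <- nchar(seq_chr)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    chartr("acgtn", "ACGTN", seq_chr)))) # rc needs uppercase; mask lowercase after
  if (!match_lowercase) {
    ## positions soft-masked on the forward strand stay non-matching on the
    ## reverse complement: re-lower them there
    low <- gregexpr("[acgtn]", as.character(sequence))[[1L]]
    if (low[1L] != -1L) {
      pos_rc <- L - as.integer(low) + 1L
      rc_ch <- strsplit(rc, "", fixed = TRUE)[[1L]]
      rc_ch[pos_rc] <- tolower(rc_ch[pos_rc])
      rc <- paste(rc_ch, collapse = "")
    }
  }
  plus <- scan_one_strand(seq_chr, pat)
  minus <- scan_one_strand(rc, pat)
  hit_gr <- function(df, strand, src) {
    if (nrow(df) == 0L) return(GenomicRanges::GRanges())
    if (strand == "+") {
      start <- df$start
    } else {
      start <- L - (df$start + df$len - 1L) + 1L
    }
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = df$len),
                                 strand = strand)
    gr$matched_sequence <- substring(src, df$start, df$start + df$len - 1L)
    dec <- lapply(gr$matched_sequence, decompose_pqs, min_run = min_run,
                  loop_min = loop_min, loop_max = loop_max, n_runs = n_runs)
    gr$g_run_lengths <- vapply(dec, function(d) paste(d$runs, collapse = ","), "")
    gr$loop_lengths <- vapply(dec, function(d) paste(d$loops, collapse = ","), "")
    gr$score <- df$len
    gr
  }
  out <- c(hit_gr(plus, "+", seq_chr), hit_gr(minus, "-", rc))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Scan every chromosome of a genome model for PQS
#'
#' @param genome A \code{GenomeModel} with an attached sequence.
#' @param ... Passed to \code{\link{scan_pqs}}.
#' @return A \code{GRanges} of hits across all chromosomes.
#' @export
scan_pqs_genome <- function(genome, ...) {
  stopifnot(is(genome, "GenomeModel"))
  if (is.null(genome$sequence)) stop_fmt("genome model has no sequence")
  hits <- lapply(names(genome$chrom_sizes), function(chr) {
    scan_pqs(genome$sequence[[chr]], chrom = chr, ...)
  })
  out <- suppressWarnings(do.call(c, hits))
  GenomeInfoDb::seqlevels(out) <- names(genome$chrom_sizes)
  GenomeInfoDb::seqlengths(out) <- unname(genome$chrom_sizes)
  out
}

#' Fraction of peaks overlapping at least one PQS hit
#'
#' Strand-blind; PQS hits are merged first so nested or overlapping hits
#' count once.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param pqs \code{GRanges} of PQS hits (from \code{\link{scan_pqs}}).
#' @return A fraction in [0, 1].
#' @export
pqs_overlap_fraction <- function(peaks, pqs) {
  stopifnot(is(peaks, "GRanges"), is(pqs, "GRanges"))
  if (length(peaks) == 0L) return(NaN)
  if (length(pqs) == 0L) return(0)
  merged <- GenomicRanges::reduce(pqs, ignore.strand = TRUE, min.gapwidth = 0L)
  mean(IRanges::overlapsAny(peaks, merged, ignore.strand = TRUE))
}
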