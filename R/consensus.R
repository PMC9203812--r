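## peak_consensus: cross-sample consensus peak retention with antibody
## independence, blacklist exclusion and high-background exclusion.
##
## "Present in N samples" is formalized at component level: peaks from all
## samples are pooled and chained into connected components by >= 1 bp
## overlap; a component is retained iff it carries peaks from at least
## min_samples distinct samples (and, when required, from at least two
## distinct antibodies). The reported footprint is the component union.

#' Consensus filter configuration
#'
#' @param min_samples Minimum number of distinct supporting samples.
#' @param require_antibody_agreement Require support from >= 2 distinct
#'   antibody labels.
#' @param blacklist Optional \code{GRanges}; retained components touching
#'   it by >= 1 bp are removed.
#' @param background_track Optional \code{CoverageTrack} of input/gDNA
#'   signal.
#' @param background_threshold Signal threshold above which a component's
#'   mean background disqualifies it. If \code{NULL} and a background
#'   track is given, defaults to mean + 3 SD over the track's bins.
#' @return An object of class \code{ConsensusConfig}.
#' @export
consensus_config <- function(min_samples = 3L,
                             require_antibody_agreement = FALSE,
                             blacklist = NULL,
                             background_track = NULL,
                             background_threshold = NULL) {
  stopifnot(min_samples >= 1L)
  if (!is.null(background_track)) {
    stopifnot(is(background_track, "CoverageTrack"))
    if (is.null(background_threshold)) {
      allv <- unlist(background_track$values, use.names = FALSE)
      background_threshold <- mean(allv) + 3 * stats::sd(allv)
    }
  }
  if (!is.null(background_threshold)) stopifnot(background_threshold >= 0)
  structure(list(min_samples = as.integer(min_samples),
                 require_antibody_agreement = require_antibody_agreement,
                 blacklist = blacklist,
                 background_track = background_track,
                 background_threshold = background_threshold),
            class = "ConsensusConfig")
}

pool_samples <- function(per_sample) {
  stopifnot(is.list(per_sample), length(per_sample) >= 1L)
  ids <- vapply(seq_along(per_sample), function(i) {
    S4Vectors::metadata(per_sample[[i]])$sample_id %||%
      names(per_sample)[i] %||% paste0("sample_", i)
  }, "")
  if (anyDuplicated(ids)) stop_fmt("sample_ids must be unique")
  abs <- vapply(seq_along(per_sample), function(i) {
    S4Vectors::metadata(per_sample[[i]])$antibody %||% NA_character_
  }, "")
  pooled <- lapply(seq_along(per_sample), function(i) {
    g <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(per_sample[[i]]),
      IRanges::ranges(per_sample[[i]]))
    g$sample_id <- rep(ids[i], length(g))
    g$antibody <- rep(abs[i], length(g))
    g
  })
  suppressWarnings(do.call(c, pooled))
}

consensus_components <- function(pool) {
  comps <- GenomicRanges::reduce(pool, ignore.strand = TRUE, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(comps, pool, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  comps$supporting_samples <- unname(vapply(
    split(pool$sample_id[si], factor(qi, seq_along(comps))),
    function(s) paste(sort(unique(s)), collapse = ","), ""))
  comps$n_samples <- lengths(strsplit(comps$supporting_samples, ","))
  comps$antibodies_supporting <- unname(vapply(
    split(pool$antibody[si], factor(qi, seq_along(comps))),
    function(s) paste(sort(unique(s[!is.na(s)])), collapse = ","), ""))
  comps$n_antibodies <- ifelse(nzchar(comps$antibodies_supporting),
                               lengths(strsplit(comps$antibodies_supporting, ",")),
                               0L)
  comps
}

#' Cross-sample consensus peak filter
#'
#' Pools per-sample peak calls, chains them into >= 1 bp overlap
#' components, and retains a component iff it is supported by at least
#' \code{min_samples} distinct samples (and >= 2 antibodies when
#' required). Retained components overlapping the blacklist by >= 1 bp,
#' or whose mean background signal exceeds the configured threshold, are
#' then removed.
#'
#' @param per_sample List of \code{GRanges}, one per sample; sample id and
#'   antibody are read from each element's \code{metadata} (see
#'   \code{\link{interval_set}}) or the list names.
#' @param cfg A \code{\link{consensus_config}}.
#' @return A sorted \code{GRanges} of consensus footprints with metadata
#'   columns \code{supporting_samples}, \code{n_samples},
#'   \code{antibodies_supporting}.
#' @export
consensus_filter <- function(per_sample, cfg = consensus_config()) {
  stopifnot(is(cfg, "ConsensusConfig"))
  pool <- pool_samples(per_sample)
  if (length(pool) == 0L) return(GenomicRanges::GRanges())
  if (cfg$require_antibody_agreement &&
      length(unique(pool$antibody[!is.na(pool$antibody)])) < 2L) {
    stop_fmt("antibody agreement required but fewer than 2 antibody labels present")
  }
  comps <- consensus_components(pool)
  keep <- comps$n_samples >= cfg$min_samples
  if (cfg$require_antibody_agreement) keep <- keep & comps$n_antibodies >= 2L
  comps <- comps[keep]
  if (!is.null(cfg$blacklist) && length(cfg$blacklist) > 0L) {
    comps <- comps[!IRanges::overlapsAny(comps, cfg$blacklist,
                                               ignore.strand = TRUE)]
  }
  if (!is.null(cfg$background_track)) {
    mu <- track_mean(cfg$background_track, comps)
    comps <- comps[is.na(mu) | mu <= cfg$background_threshold]
  }
  GenomicRanges::sort(comps, ignore.strand = TRUE)
}

#' Retained consensus counts as min_samples varies
#'
#' QC report: the number of retained components for each support cutoff
#' from 1 to the number of samples. Counts are non-increasing in the
#' cutoff by construction.
#'
#' @param per_sample As in \code{\link{consensus_filter}}.
#' @param cfg A \code{\link{consensus_config}} (its \code{min_samples} is
#'   ignored; all cutoffs are reported).
#' @return Named integer vector \code{counts[k]} for k = 1..n_samples.
#' @export
consensus_monotonicity_report <- function(per_sample, cfg = consensus_config()) {
  ks <- seq_len(length(per_sample))
  counts <- vapply(ks, function(k) {
    cfg$min_samples <- k
    length(consensus_filter(per_sample, cfg))
  }, 0L)
  setNames(counts, paste0("min_samples_", ks))
}
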