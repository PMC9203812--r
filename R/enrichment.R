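## enrichment_null: matched-size random-fragment null and exact Fisher
## enrichment testing.
##
## The two-sided p-value is the exact probability-mass-ordering rule on the
## central hypergeometric distribution (all tables with the observed
## margins whose probability is <= that of the observed table, with a
## 1e-7 relative tolerance for ties), and the odds ratio is the conditional
## maximum-likelihood estimate of the noncentral hypergeometric odds
## parameter -- both authored here and cross-checked against independent
## oracles in the test suite.

#' Construct a 2x2 contingency table
#'
#' @param a,b Observed intervals overlapping / not overlapping the feature.
#' @param c,d Null intervals overlapping / not overlapping.
#' @return A named integer vector of class \code{ContingencyTable}.
#' @export
contingency_table <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop_fmt("contingency table entries must be non-negative integers")
  }
  structure(as.integer(x), names = names(x), class = "ContingencyTable")
}

## E[X] of Fisher's noncentral hypergeometric at log-odds t, support k,
## log central weights lw (= lchoose(m,k) + lchoose(n,K-k)).
nchg_mean <- function(t, k, lw) {
  w <- lw + k * t
  w <- exp(w - max(w))
  sum(k * w) / sum(w)
}

cmle_odds_ratio <- function(a, k, lw) {
  if (a == min(k)) return(0)
  if (a == max(k)) return(Inf)
  f <- function(t) nchg_mean(t, k, lw) - a
  lohi <- c(-1, 1)
  while (f(lohi[1L]) > 0) lohi[1L] <- lohi[1L] * 2
  while (f(lohi[2L]) < 0) lohi[2L] <- lohi[2L] * 2
  exp(stats::uniroot(f, lohi, tol = 1e-12)$root)
}

#' Two-sided exact test on a 2x2 table with conditional-MLE odds ratio
#'
#' Conditions on both margins. The p-value sums the central hypergeometric
#' probabilities of every table at least as extreme (probability-mass
#' ordering, relative tie tolerance \code{tie_tol}); the odds ratio is the
#' value of the noncentral hypergeometric odds parameter maximizing the
#' conditional likelihood of the observed count. If any margin is zero the
#' p-value is 1 and the odds ratio is flagged undefined.
#'
#' @param table A \code{\link{contingency_table}} or numeric vector
#'   (a, b, c, d).
#' @param tie_tol Relative tolerance for probability ties (default 1e-7).
#' @param or Compute the conditional-MLE odds ratio (set \code{FALSE} to
#'   return only the p-value, e.g. in large simulation loops).
#' @return A list with \code{p_value}, \code{odds_ratio} (CMLE; may be 0 or
#'   \code{Inf}), \code{odds_ratio_raw} (the sample cross-product ratio)
#'   and \code{or_undefined}.
#' @export
fisher_exact <- function(table, tie_tol = 1e-7, or = TRUE) {
  x <- as.integer(table)
  stopifnot(length(x) == 4L, all(x >= 0))
  a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]
  m <- a + b; n2 <- cc + d; K <- a + cc
  if (m == 0L || n2 == 0L || K == 0L || (b + d) == 0L) {
    return(list(p_value = 1, odds_ratio = NA_real_,
                odds_ratio_raw = NA_real_, or_undefined = TRUE))
  }
  k <- seq.int(max(0L, K - n2), min(K, m))
  dh <- stats::dhyper(k, m, n2, K)
  d_obs <- dh[match(a, k)]
  p <- min(1, sum(dh[dh <= d_obs * (1 + tie_tol)]))
  est <- NA_real_
  if (or) {
    lw <- lchoose(m, k) + lchoose(n2, K - k)
    est <- cmle_odds_ratio(a, k, lw)
  }
  list(p_value = p, odds_ratio = est, odds_ratio_raw = (a * d) / (b * cc),
       or_undefined = FALSE)
}

## Placement geometry: gaps left open by `exclude`, and the number of
## eligible start positions each gap offers a fragment of length L.
allowed_gaps <- function(genome, exclude = NULL) {
  gg <- genome_ranges(genome)
  if (is.null(exclude) || length(exclude) == 0L) return(gg)
  ## strip seqinfo/mcols so set operations need no seqlevel reconciliation
  ex <- GenomicRanges::GRanges(GenomicRanges::seqnames(exclude),
                               IRanges::ranges(exclude))
  ex <- GenomicRanges::reduce(ex, ignore.strand = TRUE)
  suppressWarnings(GenomicRanges::setdiff(gg, ex, ignore.strand = TRUE))
}

eligible_starts <- function(gaps, L) {
  pmax(GenomicRanges::width(gaps) - L + 1L, 0L)
}

#' Matched-size random fragments
#'
#' Draws one random interval per observed interval so that the multiset of
#' fragment lengths exactly equals the observed multiset. Each fragment is
#' placed uniformly over every genome position where it fits entirely
#' outside \code{exclude}; chromosomes are therefore hit with probability
#' proportional to their eligible placement count.
#'
#' @param observed \code{GRanges} of observed intervals.
#' @param genome A \code{GenomeModel}.
#' @param exclude Optional \code{GRanges} of forbidden regions (e.g. the
#'   blacklist).
#' @param seed RNG seed for a deterministic draw.
#' @return A sorted \code{GRanges} of \code{length(observed)} fragments.
#' @export
matched_random_fragments <- function(observed, genome, exclude = NULL,
                                     seed = NULL) {
  stopifnot(is(observed, "GRanges"), is(genome, "GenomeModel"))
  if (length(observed) == 0L) return(GenomicRanges::GRanges())
  gaps <- allowed_gaps(genome, exclude)
  widths <- GenomicRanges::width(observed)
  with_rng_seed(seed, {
    parts <- lapply(split(seq_along(widths), widths), function(idx) {
      L <- widths[idx[1L]]
      elig <- eligible_starts(gaps, L)
      tot <- sum(as.numeric(elig))
      if (tot == 0) {
        stop_fmt("no eligible placement for a fragment of length %d", L)
      }
      gi <- sample.int(length(gaps), length(idx), replace = TRUE, prob = elig)
      off <- floor(runif(length(idx)) * elig[gi])
      GenomicRanges::GRanges(
        GenomicRanges::seqnames(gaps)[gi],
        IRanges::IRanges(GenomicRanges::start(gaps)[gi] + off, width = L))
    })
    out <- GenomicRanges::sort(do.call(c, unname(parts)), ignore.strand = TRUE)
    S4Vectors::metadata(out) <- list(n_fragments = length(out), seed = seed)
    out
  })
}

#' Expected probability that a matched random fragment overlaps a feature
#'
#' Exact placement-geometry computation (no simulation): for each observed
#' fragment length the fraction of eligible placements that intersect the
#' feature set, averaged over the observed length multiset. Used as the
#' analytic reference for enrichment power checks.
#'
#' @param observed \code{GRanges} whose length multiset defines the null.
#' @param feature \code{GRanges} feature layer.
#' @param genome A \code{GenomeModel}.
#' @param exclude Optional \code{GRanges} excluded from placement.
#' @return Probability in [0, 1].
#' @export
expected_null_overlap <- function(observed, feature, genome, exclude = NULL) {
  gaps_ex <- allowed_gaps(genome, exclude)
  strip <- function(g) GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                              IRanges::ranges(g))
  both <- if (is.null(exclude)) strip(feature) else
    c(strip(exclude), strip(feature))
  gaps_exf <- allowed_gaps(genome, both)
  widths <- GenomicRanges::width(observed)
  tab <- table(widths)
  Ls <- as.integer(names(tab))
  q <- vapply(Ls, function(L) {
    tot <- sum(as.numeric(eligible_starts(gaps_ex, L)))
    avoid <- sum(as.numeric(eligible_starts(gaps_exf, L)))
    if (tot == 0) return(NA_real_)
    1 - avoid / tot
  }, 0)
  sum(q * as.numeric(tab)) / sum(tab)
}

#' Feature-overlap enrichment against a matched random-fragment null
#'
#' Counts observed intervals overlapping the feature (>= 1 bp), draws one
#' matched-size random-fragment null set, counts again, and applies the
#' exact test. With \code{n_draws > 1} the 2x2 table still uses the first
#' draw, and an empirical permutation p-value across draws is reported in
#' addition.
#'
#' @param observed,feature \code{GRanges}.
#' @param genome A \code{GenomeModel}.
#' @param exclude Optional \code{GRanges} excluded from null placement.
#' @param seed RNG seed.
#' @param n_draws Number of null draws (default 1).
#' @return An \code{EnrichmentResult}: the table, exact p-value, CMLE and
#'   raw odds ratios, null provenance, and \code{perm_p} when
#'   \code{n_draws > 1}.
#' @export
feature_enrichment <- function(observed, feature, genome, exclude = NULL,
                               seed = NULL, n_draws = 1L) {
  stopifnot(length(observed) > 0L, n_draws >= 1L)
  n <- length(observed)
  a <- sum(IRanges::overlapsAny(observed, feature, ignore.strand = TRUE))
  draws <- vapply(seq_len(n_draws), function(i) {
    nul <- matched_random_fragments(
      observed, genome, exclude,
      seed = if (is.null(seed)) NULL else derive_seed(seed, paste0("draw", i)))
    sum(IRanges::overlapsAny(nul, feature, ignore.strand = TRUE))
  }, 0L)
  tab <- contingency_table(a, n - a, draws[1L], n - draws[1L])
  ft <- fisher_exact(tab)
  res <- list(
    table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio,
    odds_ratio_raw = ft$odds_ratio_raw, or_undefined = ft$or_undefined,
    null_description = list(n_fragments = n, seed = seed, n_draws = n_draws,
                            excluded = length(exclude %||% GenomicRanges::GRanges()))
  )
  if (n_draws > 1L) {
    res$perm_p <- (1 + sum(draws >= a)) / (1 + n_draws)
  }
  structure(res, class = "EnrichmentResult")
}

#' @exportS3Method base::print
print.EnrichmentResult <- function(x, ...) {
  t <- x$table
  cat(sprintf("EnrichmentResult: table (a=%d b=%d c=%d d=%d)\n",
              t[1L], t[2L], t[3L], t[4L]))
  cat(sprintf("  odds ratio (CMLE) = %s, p = %.4g\n",
              if (isTRUE(x$or_undefined)) "undefined" else format(x$odds_ratio, digits = 4),
              x$p_value))
  if (!is.null(x$perm_p)) cat(sprintf("  permutation p = %.4g\n", x$perm_p))
  invisible(x)
}

#' Gene-set vs peak proximity association within a window
#'
#' A gene "has a peak" iff any peak overlaps the gene body extended by
#' \code{window} bp on both sides (\code{window = 0} is the intragenic
#' rule). The 2x2 table is gene-set membership against peak possession over
#' the background gene universe.
#'
#' @param gene_set \code{GRanges} of selected genes (e.g. DEGs) with a
#'   \code{name} column; must be a subset of \code{background_genes}.
#' @param background_genes \code{GRanges} gene universe with \code{name}.
#' @param peaks \code{GRanges}.
#' @param window Extension in bp (>= 0).
#' @return An \code{EnrichmentResult} (no null draw is involved; the table
#'   is observed directly).
#' @export
window_association <- function(gene_set, background_genes, peaks, window = 0L) {
  stopifnot(window >= 0L, !is.null(background_genes$name), !is.null(gene_set$name))
  missing <- setdiff(gene_set$name, background_genes$name)
  if (length(missing)) {
    stop_fmt("gene(s) not in background universe: %s",
             paste(head(missing, 5L), collapse = ", "))
  }
  ext <- suppressWarnings(GenomicRanges::trim(background_genes + window))
  has_peak <- IRanges::overlapsAny(ext, peaks, ignore.strand = TRUE)
  is_set <- background_genes$name %in% gene_set$name
  tab <- contingency_table(sum(is_set & has_peak), sum(is_set & !has_peak),
                           sum(!is_set & has_peak), sum(!is_set & !has_peak))
  ft <- fisher_exact(tab)
  structure(list(table = tab, p_value = ft$p_value,
                 odds_ratio = ft$odds_ratio,
                 odds_ratio_raw = ft$odds_ratio_raw,
                 or_undefined = ft$or_undefined,
                 null_description = list(window = window)),
            class = "EnrichmentResult")
}
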