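## Independent oracles used across the suite. Each deliberately takes a
## different computational route from the implementation it checks.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Quadratic brute-force overlap enumeration (oracle for overlap_pairs).
brute_overlap_pairs <- function(a, b) {
  ac <- as.character(seqnames(a)); as_ <- start(a); ae <- end(a)
  bc <- as.character(seqnames(b)); bs <- start(b); be <- end(b)
  out <- NULL
  for (i in seq_along(a)) {
    hit <- which(ac[i] == bc & as_[i] <= be & bs <= ae[i])
    if (length(hit)) out <- rbind(out, cbind(i, hit))
  }
  out
}

## Per-peak exhaustive location labels (oracle for classify_location).
brute_classify <- function(peaks, genes, up, down) {
  pc <- as.character(seqnames(peaks)); ps <- start(peaks); pe <- end(peaks)
  gc <- as.character(seqnames(genes)); gs <- start(genes); ge <- end(genes)
  minus <- as.character(strand(genes)) == "-"
  tss <- ifelse(minus, ge, gs)
  ws <- ifelse(minus, tss - down + 1, tss - up)
  we <- ifelse(minus, tss + up, tss + down - 1)
  lab <- character(length(peaks))
  for (i in seq_along(peaks)) {
    same <- gc == pc[i]
    in_prom <- any(same & ps[i] <= we & ws <= pe[i])
    in_body <- any(same & ps[i] <= ge & gs <= pe[i])
    lab[i] <- if (in_prom) "promoter" else if (in_body) "gene_body" else "intergenic"
  }
  lab
}

## Leftmost-greedy backtracking PQS matcher mirroring the greediness of a
## backtracking regex engine on G{r,}([ACGT]{lmin,lmax}G{r,}){n-1}:
## quantifiers try their longest extent first; scanning restarts after each
## match. Returns 1-based [start, end] spans on the scanned strand.
pqs_oracle_scan <- function(seq_chr, min_run = 3L, loop_min = 1L,
                            loop_max = 7L, n_runs = 4L) {
  ch <- strsplit(seq_chr, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  is_g <- ch == "G"
  is_acgt <- ch %in% c("A", "C", "G", "T")
  g_run_at <- integer(n) # length of G run starting at each position
  run <- 0L
  for (i in rev(seq_len(n))) {
    run <- if (is_g[i]) run + 1L else 0L
    g_run_at[i] <- run
  }
  match_from <- function(pos) {
    ## returns end index of the greedy match starting exactly at pos, or NA
    rec <- function(p, runs_left) {
      if (p > n) return(NA_integer_)
      gmax <- g_run_at[p]
      if (gmax < min_run) return(NA_integer_)
      if (runs_left == 1L) return(p + gmax - 1L) # greedy: final run maximal
      for (g in seq(gmax, min_run)) {
        after <- p + g
        upper <- min(loop_max, n - after + 1L)
        if (upper >= loop_min) {
          for (l in seq(upper, loop_min)) {
            if (!all(is_acgt[after:(after + l - 1L)])) next
            res <- rec(after + l, runs_left - 1L)
            if (!is.na(res)) return(res)
          }
        }
      }
      NA_integer_
    }
    rec(pos, n_runs)
  }
  spans <- NULL
  i <- 1L
  while (i <= n) {
    if (g_run_at[i] >= min_run) {
      e <- match_from(i)
      if (!is.na(e)) {
        spans <- rbind(spans, c(i, e))
        i <- e + 1L
        next
      }
    }
    i <- i + 1L
  }
  spans
}

## Both-strand PQS spans in plus coordinates (oracle for scan_pqs spans).
pqs_oracle_both <- function(seq_chr, ...) {
  L <- nchar(seq_chr)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
  plus <- pqs_oracle_scan(seq_chr, ...)
  minus <- pqs_oracle_scan(rc, ...)
  out <- NULL
  if (!is.null(plus)) out <- cbind(plus, strand = 1L)
  if (!is.null(minus)) {
    refl <- cbind(L - minus[, 2L] + 1L, L - minus[, 1L] + 1L, strand = 2L)
    out <- rbind(out, refl)
  }
  if (is.null(out)) return(NULL)
  out[order(out[, 1L], out[, 2L], out[, 3L]), , drop = FALSE]
}

## Hypergeometric pmf from first principles (no dhyper): oracle for the
## exact two-sided p-value by full fixed-margin enumeration.
fisher_p_oracle <- function(a, b, c, d, tie_tol = 1e-7) {
  m <- a + b; n2 <- c + d; K <- a + c
  if (m == 0 || n2 == 0 || K == 0 || b + d == 0) return(1)
  lo <- max(0, K - n2); hi <- min(K, m)
  ks <- lo:hi
  lp <- lgamma(m + 1) - lgamma(ks + 1) - lgamma(m - ks + 1) +
    lgamma(n2 + 1) - lgamma(K - ks + 1) - lgamma(n2 - K + ks + 1) -
    (lgamma(m + n2 + 1) - lgamma(K + 1) - lgamma(m + n2 - K + 1))
  p <- exp(lp)
  min(1, sum(p[p <= p[ks == a] * (1 + tie_tol)]))
}

## Conditional log-likelihood of a 2x2 table at odds parameter psi.
cond_loglik <- function(psi, a, b, c, d) {
  m <- a + b; n2 <- c + d; K <- a + c
  ks <- max(0, K - n2):min(K, m)
  lw <- lchoose(m, ks) + lchoose(n2, K - ks)
  lt <- lw + ks * log(psi)
  lw[ks == a] + a * log(psi) - (max(lt) + log(sum(exp(lt - max(lt)))))
}

## TRUE iff the supplied estimate attains at least the maximum conditional
## likelihood over a log-spaced grid (oracle maximization).
cmle_beats_grid <- function(or_hat, a, b, c, d, n_grid = 1e4) {
  if (!is.finite(or_hat) || or_hat <= 0) return(TRUE) # boundary cases checked separately
  grid <- exp(seq(log(1e-8), log(1e8), length.out = n_grid))
  m <- a + b; n2 <- c + d; K <- a + c
  ks <- max(0, K - n2):min(K, m)
  lw <- lchoose(m, ks) + lchoose(n2, K - ks)
  ia <- which(ks == a)
  ll <- vapply(grid, function(psi) {
    lt <- lw + ks * log(psi)
    lw[ia] + a * log(psi) - (max(lt) + log(sum(exp(lt - max(lt)))))
  }, 0)
  cond_loglik(or_hat, a, b, c, d) >= max(ll) - 1e-9
}

## Small genome model without sequence, for placement/consensus tests.
toy_genome <- function(sizes = c(chr1 = 100000L, chr2 = 50000L), ...) {
  genome_model(sizes, ...)
}

gr <- function(chrom, start, end, strand = "*", ...) {
  GRanges(chrom, IRanges(start, end), strand = strand, ...)
}

## Small-footprint synthetic spec for unit tests.
tiny_spec <- function(...) {
  base <- list(n_chroms = 2L, chrom_len = 2e5, n_genes = 40L, n_cpg = 20L,
               n_blacklist = 5L, pqs_planted = 10L,
               peak_params = list(n_peaks = 300L, n_samples = 4L))
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% names(base) && is.list(base[[nm]]) && is.list(ov[[nm]])) {
      base[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      base[[nm]] <- ov[[nm]]
    }
  }
  do.call(synthetic_spec, base)
}

random_seq <- function(n, p_g = 0.25) {
  p <- c(A = (1 - p_g) / 3, C = (1 - p_g) / 3, G = p_g, T = (1 - p_g) / 3)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
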