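## synthetic_data: generates every input the pipeline consumes, with
## planted ground truth. Fully deterministic under the spec seed; each
## generator stage derives its own seed so stages are independently
## reproducible.

default_spec <- function() {
  list(
    seed = 1L,
    n_chroms = 2L,
    chrom_len = 2e6,
    n_genes = 200L,
    n_cpg = 100L,
    n_blacklist = 20L,
    pqs_planted = 50L,
    peak_params = list(
      n_peaks = 2000L,          # latent true peaks
      len_meanlog = log(300),   # peak length ~ lognormal, typical ChIP widths
      len_sdlog = 0.35,
      min_len = 100L,
      tss_fraction = 0.5,       # fraction of latent peaks centered on a TSS
      reproducibility = 0.9,    # per-sample detection probability r
      n_samples = 6L,
      antibodies = c("abA", "abB"),
      spurious_rate = 0.05      # spurious peaks per sample ~ Pois(rate * n_peaks)
    ),
    spikein_params = list(
      n_samples = 2L,
      human_chip_reads = c(6e7, 1.8e8), # 3x depth difference
      human_input_reads = c(8e7, 8e7),
      spike_cell_ratio = 0.25,  # spike-in cells at 1:4
      bin_size = 200L
    ),
    sc_params = list(
      n_cells = 4000L,            # cells per sample (two samples: control, case)
      silenced_fraction = 0.2,    # f_s, case sample only
      effect_size = 0.2,          # e, multiplier on HBA/HBM-like rates
      n_background_loci = 400L,
      depth_meanlog = log(5000),
      depth_sdlog = 0.5,
      globin_base_weight = 5,     # anchor locus weight, relative to bg weight 1
      target_weight_mult = 2,     # HBA/HBM-like loci span wider regulatory regions
      globin_maturity_gain = 9,   # globin weight scales as base*(1 + gain*maturity)
      silencing_rank_power = 6    # silencing prob ~ depth_rank^power
    ),
    rna_params = list(
      n_cells = 5200L,            # pre-QC cells per sample
      ratio_mu = 1,               # HBA:HBB expression ratio in unsilenced cells
      n_background_genes = 300L,
      hbb_base = 0.02,            # w_HBB = B*(hbb_base + hbb_gain*maturity^2)
      hbb_gain = 1.5,
      hbm_fraction = 0.05,        # w_HBM relative to w_HBB
      depth_meanlog = log(8000),
      depth_sdlog = 0.4
    )
  )
}

#' Specification for the synthetic-data generators
#'
#' Returns the study-condition defaults, overridden by any supplied
#' values. Overrides are validated: fractions must lie in [0, 1] and
#' unknown keys are rejected.
#'
#' @param ... Top-level fields to override; \code{peak_params},
#'   \code{spikein_params}, \code{sc_params} and \code{rna_params} are
#'   merged element-wise.
#' @return A list of class \code{SyntheticSpec}.
#' @export
synthetic_spec <- function(...) {
  spec <- default_spec()
  ov <- list(...)
  if (anyDuplicated(names(ov))) {
    stop_fmt("duplicated spec field(s): %s",
             paste(unique(names(ov)[duplicated(names(ov))]), collapse = ", "))
  }
  unknown <- setdiff(names(ov), names(spec))
  if (length(unknown)) stop_fmt("unknown spec field(s): %s",
                                paste(unknown, collapse = ", "))
  for (nm in names(ov)) {
    if (is.list(spec[[nm]]) && is.list(ov[[nm]])) {
      bad <- setdiff(names(ov[[nm]]), names(spec[[nm]]))
      if (length(bad)) stop_fmt("unknown %s field(s): %s", nm,
                                paste(bad, collapse = ", "))
      spec[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      spec[[nm]] <- ov[[nm]]
    }
  }
  fr <- c(spec$peak_params$tss_fraction, spec$peak_params$reproducibility,
          spec$sc_params$silenced_fraction, spec$spikein_params$spike_cell_ratio)
  if (any(fr < 0 | fr > 1)) stop_fmt("fractions must lie in [0, 1]")
  structure(spec, class = c("SyntheticSpec", "list"))
}

## Place n non-overlapping intervals of the given widths uniformly across
## the genome, avoiding `avoid` and previously placed intervals.
place_nonoverlapping <- function(widths, chrom_sizes, avoid = NULL,
                                 max_rounds = 60L) {
  n <- length(widths)
  if (n == 0L) return(GenomicRanges::GRanges())
  placed <- GenomicRanges::GRanges()
  taken <- if (is.null(avoid) || length(avoid) == 0L) GenomicRanges::GRanges() else
    GenomicRanges::reduce(GenomicRanges::GRanges(
      GenomicRanges::seqnames(avoid), IRanges::ranges(avoid)))
  todo <- order(widths, decreasing = TRUE)
  for (round in seq_len(max_rounds)) {
    if (length(todo) == 0L) break
    w <- widths[todo]
    chr_i <- sample.int(length(chrom_sizes), length(todo), replace = TRUE,
                        prob = chrom_sizes)
    max_start <- chrom_sizes[chr_i] - w + 1
    ok <- max_start >= 1
    if (!any(ok)) next
    st <- floor(runif(sum(ok)) * max_start[ok]) + 1
    cand <- GenomicRanges::GRanges(names(chrom_sizes)[chr_i[ok]],
                                   IRanges::IRanges(st, width = w[ok]))
    free <- !IRanges::overlapsAny(cand, taken, ignore.strand = TRUE)
    ## also reject candidates overlapping each other within this round
    self <- GenomicRanges::countOverlaps(cand, cand, ignore.strand = TRUE) > 1L
    accept <- free & !self
    if (any(accept)) {
      newly <- cand[accept]
      placed <- c(placed, newly)
      taken <- GenomicRanges::reduce(c(taken, newly))
      done <- rep(FALSE, length(todo))
      done[which(ok)[accept]] <- TRUE
      todo <- todo[!done]
    }
  }
  if (length(todo) > 0L) {
    stop_fmt("could not place %d of %d requested features (genome too small or too crowded)",
             length(todo), n)
  }
  GenomicRanges::sort(placed, ignore.strand = TRUE)
}

random_dna <- function(len, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  intToUtf8(utf8ToInt(paste(names(p), collapse = ""))[
    sample.int(length(p), len, replace = TRUE, prob = p)])
}

## One synthetic quadruplex motif: runs of min_run G separated by random
## loops of 1..loop_max bases drawn from {A, C, T} (no G, so planted runs
## never fuse with loop bases).
random_pqs_motif <- function(min_run = 3L, loop_max = 7L, n_runs = 4L) {
  loops <- vapply(seq_len(n_runs - 1L), function(i) {
    paste(sample(c("A", "C", "T"), sample.int(loop_max, 1L), replace = TRUE),
          collapse = "")
  }, "")
  run <- strrep("G", min_run)
  paste0(run, paste0(loops, run, collapse = ""))
}

#' Generate a synthetic genome with planted annotation and motifs
#'
#' Random nucleotide sequence per chromosome with \code{pqs_planted}
#' quadruplex motifs inserted at recorded positions on random strands;
#' non-overlapping genes (strand and TSS defined), CpG islands and
#' blacklist regions placed without overlapping each other.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A list with \code{genome} (a \code{GenomeModel} with sequence)
#'   and \code{truth} (planted PQS coordinates and layer copies).
#' @export
make_genome <- function(spec = synthetic_spec()) {
  stopifnot(is(spec, "SyntheticSpec"))
  with_rng_seed(derive_seed(spec$seed, "genome"), {
    sizes <- setNames(rep(as.integer(spec$chrom_len), spec$n_chroms),
                      paste0("chr", seq_len(spec$n_chroms)))
    seqs <- lapply(sizes, random_dna)

    motifs <- if (spec$pqs_planted > 0L) {
      vapply(seq_len(spec$pqs_planted), function(i) random_pqs_motif(), "")
    } else character(0)
    pqs_truth <- GenomicRanges::GRanges()
    if (length(motifs)) {
      pqs_truth <- place_nonoverlapping(nchar(motifs), sizes)
      strand_pick <- sample(c("+", "-"), length(pqs_truth), replace = TRUE)
      GenomicRanges::strand(pqs_truth) <- strand_pick
      ## placement sorts by position; re-pair each interval with an unused
      ## motif of the same width
      pool <- split(seq_along(motifs), nchar(motifs))
      assigned <- integer(length(pqs_truth))
      for (i in seq_along(pqs_truth)) {
        key <- as.character(GenomicRanges::width(pqs_truth)[i])
        assigned[i] <- pool[[key]][1L]
        pool[[key]] <- pool[[key]][-1L]
      }
      motifs <- motifs[assigned]
      for (i in seq_along(pqs_truth)) {
        chr <- as.character(GenomicRanges::seqnames(pqs_truth))[i]
        ins <- if (strand_pick[i] == "+") motifs[i] else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(motifs[i])))
        substr(seqs[[chr]], GenomicRanges::start(pqs_truth)[i],
               GenomicRanges::end(pqs_truth)[i]) <- ins
      }
    }

    genes <- GenomicRanges::GRanges()
    if (spec$n_genes > 0L) {
      gw <- pmin(pmax(round(rlnorm(spec$n_genes, log(4000), 0.5)), 1000), 20000)
      genes <- place_nonoverlapping(gw, sizes, avoid = NULL)
      GenomicRanges::strand(genes) <- sample(c("+", "-"), length(genes),
                                             replace = TRUE)
      genes$name <- paste0("gene_", seq_along(genes))
    }
    cpg <- GenomicRanges::GRanges()
    if (spec$n_cpg > 0L) {
      cw <- round(runif(spec$n_cpg, 500, 2000))
      cpg <- place_nonoverlapping(cw, sizes)
      cpg$name <- paste0("cpg_", seq_along(cpg))
    }
    bl <- GenomicRanges::GRanges()
    if (spec$n_blacklist > 0L) {
      bw <- round(runif(spec$n_blacklist, 1000, 5000))
      bl <- place_nonoverlapping(bw, sizes, avoid = cpg)
      bl$name <- paste0("blacklist_", seq_along(bl))
    }
    genome <- genome_model(
      sizes, genes = genes, cpg_islands = cpg, blacklist = bl,
      sequence = Biostrings::DNAStringSet(unlist(seqs)))
    list(genome = genome,
         truth = list(pqs = pqs_truth, genes = genes, cpg_islands = cpg,
                      blacklist = bl))
  })
}

#' Generate per-sample replicate peak sets with a latent truth
#'
#' A latent true peak set is drawn (fraction \code{tss_fraction} centered
#' on TSSs, the rest uniform outside the blacklist and non-overlapping);
#' each sample independently observes each latent peak with probability
#' \code{reproducibility} and adds Poisson-distributed spurious peaks.
#' Antibody labels are assigned round-robin across samples.
#'
#' @param genome A \code{GenomeModel}.
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A list with \code{samples} (list of \code{GRanges} with
#'   sample/antibody metadata), and \code{truth} (latent peaks, TSS flag,
#'   and the sample-by-peak presence matrix).
#' @export
make_peak_replicates <- function(genome, spec = synthetic_spec()) {
  pp <- spec$peak_params
  with_rng_seed(derive_seed(spec$seed, "peaks"), {
    sizes <- genome$chrom_sizes
    n <- pp$n_peaks
    widths <- pmax(round(rlnorm(n, pp$len_meanlog, pp$len_sdlog)), pp$min_len)
    at_tss <- runif(n) < pp$tss_fraction
    if (length(genome$genes) == 0L) at_tss[] <- FALSE
    latent <- GenomicRanges::GRanges()
    if (any(at_tss)) {
      tss <- tss_of(genome$genes)
      pick <- if (sum(at_tss) <= length(tss)) {
        sample.int(length(tss), sum(at_tss))
      } else {
        sample.int(length(tss), sum(at_tss), replace = TRUE)
      }
      w <- widths[at_tss]
      pos <- GenomicRanges::start(tss)[pick]
      st <- pmax(pos - w %/% 2L, 1L)
      chr <- as.character(GenomicRanges::seqnames(tss))[pick]
      en <- pmin(st + w - 1L, sizes[chr])
      latent <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en))
    }
    if (any(!at_tss)) {
      uni <- place_nonoverlapping(widths[!at_tss], sizes,
                                  avoid = c(GenomicRanges::granges(genome$blacklist),
                                            GenomicRanges::granges(latent)))
      latent <- c(latent, uni)
    }
    latent$at_tss <- c(rep(TRUE, sum(at_tss)), rep(FALSE, sum(!at_tss)))
    latent$name <- paste0("latent_", seq_along(latent))

    presence <- matrix(FALSE, length(latent), pp$n_samples,
                       dimnames = list(latent$name, NULL))
    samples <- vector("list", pp$n_samples)
    for (s in seq_len(pp$n_samples)) {
      seen <- runif(length(latent)) < pp$reproducibility
      presence[, s] <- seen
      n_sp <- rpois(1L, pp$spurious_rate * n)
      spur <- if (n_sp > 0L) {
        sw <- pmax(round(rlnorm(n_sp, pp$len_meanlog, pp$len_sdlog)), pp$min_len)
        place_nonoverlapping(sw, sizes, avoid = genome$blacklist)
      } else GenomicRanges::GRanges()
      obs <- c(GenomicRanges::granges(latent[seen]), spur)
      sid <- sprintf("sample_%02d", s)
      samples[[s]] <- interval_set(
        obs, label = sid, sample_id = sid,
        antibody = pp$antibodies[(s - 1L) %% length(pp$antibodies) + 1L])
    }
    names(samples) <- sprintf("sample_%02d", seq_len(pp$n_samples))
    colnames(presence) <- names(samples)
    list(samples = samples,
         truth = list(latent = latent, presence = presence))
  })
}

#' Generate a spike-in (ChIP-Rx) experiment with shared biology
#'
#' All samples share one latent binding-intensity profile; each sample's
#' binned read counts are Poisson draws at its own sequencing depth, and
#' spike-in read counts follow the configured spike:target cell ratio.
#'
#' @param genome A \code{GenomeModel}.
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A list with \code{tracks} (raw \code{CoverageTrack}s),
#'   \code{stats} (\code{\link{spike_in_stats}} per sample) and
#'   \code{truth} (the shared intensity profile and true spike factor).
#' @export
make_chiprx_experiment <- function(genome, spec = synthetic_spec()) {
  sp <- spec$spikein_params
  with_rng_seed(derive_seed(spec$seed, "chiprx"), {
    b <- sp$bin_size
    nb <- ceiling(genome$chrom_sizes / b)
    intensity <- lapply(nb, function(k) stats::rgamma(k, shape = 2, rate = 2))
    tot_int <- sum(vapply(intensity, sum, 0))
    tracks <- vector("list", sp$n_samples)
    stats_l <- vector("list", sp$n_samples)
    for (j in seq_len(sp$n_samples)) {
      H <- sp$human_chip_reads[j]
      values <- lapply(intensity, function(v) {
        as.numeric(rpois(length(v), v / tot_int * H))
      })
      h_chip <- sum(vapply(values, sum, 0))
      s_chip <- rpois(1L, h_chip * sp$spike_cell_ratio)
      h_input <- sp$human_input_reads[j]
      s_input <- rpois(1L, h_input * sp$spike_cell_ratio)
      tracks[[j]] <- coverage_track(values, b, genome = genome,
                                    sample_id = sprintf("rx_%d", j))
      stats_l[[j]] <- spike_in_stats(h_chip, s_chip, h_input, s_input)
    }
    list(tracks = tracks, stats = stats_l,
         truth = list(intensity = intensity,
                      spike_cell_ratio = sp$spike_cell_ratio))
  })
}

sc_locus_weights <- function(maturity, params, silenced) {
  K <- params$n_background_loci
  n <- length(maturity)
  gw <- params$globin_base_weight * (1 + params$globin_maturity_gain * maturity)
  eff <- ifelse(silenced, params$effect_size, 1)
  tm <- params$target_weight_mult
  rbind(
    HBB = gw,
    HBA = tm * gw * eff,
    HBM = tm * gw * eff,
    matrix(1, K, n, dimnames = list(paste0("bg_", seq_len(K)), NULL))
  )
}

#' Generate a two-sample single-cell experiment with a planted silenced
#' subpopulation
#'
#' Two samples (control, case). Per cell, total depth is lognormal and
#' per-locus counts are Poisson with rate locus_weight/sum(weights) x
#' depth. Globin-like loci (HBB/HBA/HBM) gain weight with the cell's
#' maturity (its depth rank), emulating late erythroid differentiation. In
#' the case sample a fraction \code{silenced_fraction} of cells -- drawn
#' with probability proportional to depth rank^\code{silencing_rank_power},
#' i.e. concentrated in the most mature cells -- has the HBA-like and
#' HBM-like rates multiplied by \code{effect_size} while HBB is untouched.
#' The RNA modality mirrors this with HBA proportional to
#' \code{ratio_mu} x HBB except in silenced cells.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param modalities Subset of \code{c("atac", "rna")} to generate.
#' @return A list with \code{atac}/\code{rna} (each: \code{counts}
#'   features-by-cells, \code{annotation} data.frame) and \code{truth}
#'   (silenced cell ids per modality).
#' @export
make_sc_experiment <- function(spec = synthetic_spec(),
                               modalities = c("atac", "rna")) {
  sc <- spec$sc_params
  if (sc$silenced_fraction > 0 && sc$effect_size >= 1) {
    warning("effect_size >= 1 with silenced_fraction > 0: no detectable effect")
  }
  out <- list(truth = list())
  if ("atac" %in% modalities) {
    out_atac <- with_rng_seed(derive_seed(spec$seed, "sc_atac"), {
      gen_sample <- function(group) {
        n <- sc$n_cells
        depth <- rlnorm(n, sc$depth_meanlog, sc$depth_sdlog)
        maturity <- rank(depth, ties.method = "first") / n
        sil <- rep(FALSE, n)
        if (group == "case" && sc$silenced_fraction > 0) {
          k <- round(sc$silenced_fraction * n)
          sil[sample.int(n, k, prob = maturity^sc$silencing_rank_power)] <- TRUE
        }
        w <- sc_locus_weights(maturity, sc, sil)
        p <- sweep(w, 2L, colSums(w), "/")
        counts <- matrix(rpois(length(p), p * rep(depth, each = nrow(p))),
                         nrow(p), n, dimnames = dimnames(p))
        ann <- data.frame(
          cell_id = sprintf("%s_cell_%04d", group, seq_len(n)),
          sample_id = group, group = group,
          passed_filters = round(depth),
          stringsAsFactors = FALSE)
        colnames(counts) <- ann$cell_id
        list(counts = counts, ann = ann, silenced = ann$cell_id[sil])
      }
      ctl <- gen_sample("control"); cas <- gen_sample("case")
      list(counts = cbind(ctl$counts, cas$counts),
           annotation = rbind(ctl$ann, cas$ann),
           silenced = c(ctl$silenced, cas$silenced))
    })
    out$atac <- list(counts = out_atac$counts, annotation = out_atac$annotation)
    out$truth$atac_silenced <- out_atac$silenced
  }
  if ("rna" %in% modalities) {
    rp <- spec$rna_params
    out_rna <- with_rng_seed(derive_seed(spec$seed, "sc_rna"), {
      gen_sample <- function(group) {
        n <- rp$n_cells
        depth <- rlnorm(n, rp$depth_meanlog, rp$depth_sdlog)
        maturity <- rank(depth, ties.method = "first") / n
        sil <- rep(FALSE, n)
        if (group == "case" && sc$silenced_fraction > 0) {
          k <- round(sc$silenced_fraction * n)
          sil[sample.int(n, k, prob = maturity^sc$silencing_rank_power)] <- TRUE
        }
        B <- rp$n_background_genes
        w_hbb <- B * (rp$hbb_base + rp$hbb_gain * maturity^2)
        eff <- ifelse(sil, sc$effect_size, 1)
        w <- rbind(
          HBB = w_hbb,
          HBA1 = rp$ratio_mu * w_hbb / 2 * eff,
          HBA2 = rp$ratio_mu * w_hbb / 2 * eff,
          HBM = rp$hbm_fraction * w_hbb * eff,
          matrix(1, B, n, dimnames = list(paste0("bg_", seq_len(B)), NULL)))
        p <- sweep(w, 2L, colSums(w), "/")
        counts <- matrix(rpois(length(p), p * rep(depth, each = nrow(p))),
                         nrow(p), n, dimnames = dimnames(p))
        ## QC metadata emulates upstream pipeline fields (computed, in real
        ## data, on the full transcriptome; here synthetic per-cell draws)
        ann <- data.frame(
          cell_id = sprintf("%s_rna_%04d", group, seq_len(n)),
          sample_id = group, group = group,
          pct_mito = round(stats::rbeta(n, 2, 60) * 100, 3),
          n_features = pmax(round(stats::rnorm(n, 2200, 700)), 0L),
          stringsAsFactors = FALSE)
        colnames(counts) <- ann$cell_id
        list(counts = counts, ann = ann, silenced = ann$cell_id[sil])
      }
      ctl <- gen_sample("control"); cas <- gen_sample("case")
      list(counts = cbind(ctl$counts, cas$counts),
           annotation = rbind(ctl$ann, cas$ann),
           silenced = c(ctl$silenced, cas$silenced))
    })
    out$rna <- list(counts = out_rna$counts, annotation = out_rna$annotation)
    out$truth$rna_silenced <- out_rna$silenced
  }
  out
}
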