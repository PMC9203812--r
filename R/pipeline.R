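## pipeline_cli: config-driven orchestration of the synthetic demonstration
## run. Every stage derives its seed from the single global seed, outputs
## are plain text, and a machine-readable manifest records files, hashes
## and seeds so identical configs reproduce identical outputs.

default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "chromenrich_run",
    stages = c("simulate", "pqs", "consensus", "enrich", "chiprx",
               "metagene", "sc_atac", "sc_rna"),
    spec = list(),        # synthetic_spec overrides
    pqs = list(min_run = 3L, loop_min = 1L, loop_max = 7L, n_runs = 4L),
    consensus = list(min_samples = 3L, require_antibody_agreement = TRUE),
    enrich = list(features = c("tss", "cpg_islands"), n_draws = 1L),
    metagene = list(mode = "tss_centered", flank = 2000L, body_bins = 100L,
                    bin_size = 200L),
    sc = list()           # sc_config overrides
  )
}

merge_config <- function(defaults, user, path = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop_fmt("unknown %s key(s): %s", path, paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, "$", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

pipe_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the end-to-end synthetic demonstration pipeline
#'
#' Executes the requested stages in dependency order on a synthetic
#' dataset with planted ground truth: simulate (genome, replicate peaks,
#' spike-in tracks, single-cell matrices), pqs, consensus, enrich,
#' chiprx, metagene, sc_atac, sc_rna. All outputs are plain text under
#' \code{outdir}; a JSON manifest records every file with its MD5 hash and
#' the per-stage seeds. Rerunning with an identical config reproduces
#' byte-identical outputs. Unknown config keys are rejected by name; a
#' stage failure aborts with the stage named and leaves a
#' \code{FAILED_<stage>} marker beside any partial outputs.
#'
#' @param config A nested list of overrides to the defaults, or a path to
#'   a YAML file of the same shape.
#' @param verbose Log stage progress to stderr.
#' @return The manifest, invisibly (also written to
#'   \code{outdir/manifest.json}).
#' @export
run_pipeline <- function(config = list(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config_echo.yaml"))
  spec <- do.call(synthetic_spec, c(cfg$spec, list(seed = cfg$seed)))
  manifest <- list(seed = cfg$seed, stages = list(), files = list())
  state <- new.env(parent = emptyenv())

  add_file <- function(path) {
    manifest$files[[basename(path)]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    pipe_log(verbose, "[chromenrich] stage %s (seed %d)", name,
             derive_seed(cfg$seed, name))
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      marker <- file.path(cfg$outdir, paste0("FAILED_", name))
      writeLines(conditionMessage(e), marker)
      stop_fmt("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(seed = derive_seed(cfg$seed, name))
  }
  out <- function(...) file.path(cfg$outdir, ...)

  run_stage("simulate", function() {
    g <- make_genome(spec)
    state$genome <- g$genome; state$truth <- g$truth
    Biostrings::writeXStringSet(g$genome$sequence, out("genome.fa"))
    write_intervals(g$genome$genes, out("genes.bed"))
    write_intervals(g$genome$cpg_islands, out("cpg_islands.bed"))
    write_intervals(g$genome$blacklist, out("blacklist.bed"))
    write_intervals(g$truth$pqs, out("truth_pqs.bed"))
    sizes <- data.frame(names(g$genome$chrom_sizes),
                        unname(g$genome$chrom_sizes))
    write.table(sizes, out("chrom.sizes"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    pk <- make_peak_replicates(g$genome, spec)
    state$peaks <- pk
    mani <- data.frame(
      sample_id = names(pk$samples),
      antibody = vapply(pk$samples, function(x)
        S4Vectors::metadata(x)$antibody, ""),
      path = paste0("peaks_", names(pk$samples), ".bed"))
    for (i in seq_along(pk$samples)) {
      write_intervals(pk$samples[[i]], out(mani$path[i]))
      add_file(out(mani$path[i]))
    }
    write.table(mani, out("samples_manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_intervals(pk$truth$latent, out("truth_latent_peaks.bed"))
    for (f in c("genome.fa", "genes.bed", "cpg_islands.bed", "blacklist.bed",
                "truth_pqs.bed", "chrom.sizes", "samples_manifest.tsv",
                "truth_latent_peaks.bed")) add_file(out(f))
  })

  run_stage("pqs", function() {
    hits <- do.call(scan_pqs_genome, c(list(state$genome), cfg$pqs))
    state$pqs <- hits
    bed <- hits
    bed$name <- "G4"
    write_intervals(bed, out("pqs.bed"))
    add_file(out("pqs.bed"))
  })

  run_stage("consensus", function() {
    ccfg <- consensus_config(
      min_samples = cfg$consensus$min_samples,
      require_antibody_agreement = cfg$consensus$require_antibody_agreement,
      blacklist = state$genome$blacklist)
    cons <- consensus_filter(state$peaks$samples, ccfg)
    state$consensus <- cons
    write_intervals(cons, out("consensus.bed"))
    supp <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(cons)),
      start = GenomicRanges::start(cons) - 1L,
      end = GenomicRanges::end(cons),
      n_samples = cons$n_samples,
      supporting_samples = cons$supporting_samples,
      antibodies = cons$antibodies_supporting)
    write.table(supp, out("consensus_support.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(state$pqs)) {
      frac <- pqs_overlap_fraction(cons, state$pqs)
      writeLines(sprintf("pqs_overlap_fraction\t%.6f", frac),
                 out("consensus_pqs_overlap.tsv"))
      add_file(out("consensus_pqs_overlap.tsv"))
    }
    add_file(out("consensus.bed")); add_file(out("consensus_support.tsv"))
  })

  run_stage("enrich", function() {
    feats <- list(
      tss = tss_of(state$genome$genes),
      cpg_islands = state$genome$cpg_islands,
      pqs = if (!is.null(state$pqs)) state$pqs else NULL)
    rows <- lapply(cfg$enrich$features, function(fn) {
      f <- feats[[fn]]
      if (is.null(f)) stop_fmt("unknown enrichment feature '%s'", fn)
      er <- feature_enrichment(state$consensus, f, state$genome,
                               exclude = state$genome$blacklist,
                               seed = derive_seed(cfg$seed, paste0("enrich_", fn)),
                               n_draws = cfg$enrich$n_draws)
      data.frame(feature = fn, a = er$table[1L], b = er$table[2L],
                 c = er$table[3L], d = er$table[4L],
                 odds_ratio = er$odds_ratio, p_value = er$p_value,
                 seed = er$null_description$seed)
    })
    df <- do.call(rbind, rows)
    write.table(df, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_file(out("enrichment.tsv"))
  })

  run_stage("chiprx", function() {
    rx <- make_chiprx_experiment(state$genome, spec)
    state$chiprx <- rx
    facs <- vapply(rx$stats, chiprx_factor, 0)
    norm <- Map(normalize_chiprx, rx$tracks, rx$stats)
    state$chiprx_norm <- norm
    for (j in seq_along(norm)) {
      write_bedgraph(norm[[j]], out(sprintf("chiprx_norm_%d.bedgraph", j)))
      add_file(out(sprintf("chiprx_norm_%d.bedgraph", j)))
    }
    df <- data.frame(sample = seq_along(facs), factor = facs,
                     h_chip = vapply(rx$stats, `[[`, 0, "h_chip"),
                     s_chip = vapply(rx$stats, `[[`, 0, "s_chip"))
    write.table(df, out("chiprx_factors.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_file(out("chiprx_factors.tsv"))
  })

  run_stage("metagene", function() {
    if (is.null(state$chiprx_norm)) stop_fmt("metagene needs the chiprx stage")
    track <- state$chiprx_norm[[1L]]
    prof <- metagene_profile(track, state$genome$genes,
                             mode = cfg$metagene$mode,
                             flank = cfg$metagene$flank,
                             body_bins = cfg$metagene$body_bins)
    write.table(prof, out("metagene_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add_file(out("metagene_profile.tsv"))
  })

  run_stage("sc_atac", function() {
    sc <- make_sc_experiment(spec, modalities = "atac")
    scc <- do.call(sc_config, c(cfg$sc, list(seed = derive_seed(cfg$seed, "sc"))))
    act <- normalize_atac_activity(sc$atac$counts)
    ann <- relative_activity(act, sc$atac$annotation, cfg = scc,
                             modality = "atac")
    sub <- subpopulation_enrichment(ann, scc)
    write_cell_matrix(sc$atac$counts, cfg$outdir, "sc_atac")
    write.table(ann, out("sc_atac_cells.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(sub$flagged, out("sc_atac_flagged_cells.txt"))
    er <- sub$result
    df <- data.frame(a = er$table[1L], b = er$table[2L], c = er$table[3L],
                     d = er$table[4L], odds_ratio = er$odds_ratio,
                     p_value = er$p_value)
    write.table(df, out("sc_atac_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(sc$truth$atac_silenced, out("truth_silenced_cells.txt"))
    for (f in c("sc_atac_cells.tsv", "sc_atac_flagged_cells.txt",
                "sc_atac_enrichment.tsv", "truth_silenced_cells.txt",
                "sc_atac.mtx")) add_file(out(f))
  })

  run_stage("sc_rna", function() {
    sc <- make_sc_experiment(spec, modalities = "rna")
    scc <- do.call(sc_config, c(cfg$sc, list(seed = derive_seed(cfg$seed, "sc"))))
    qc <- qc_and_subsample(sc$rna$counts, sc$rna$annotation, scc,
                           modality = "rna")
    norm <- normalize_rna(qc$counts, scc)
    ann <- relative_activity(norm, qc$annotation, anchor = "HBB",
                             targets = c("sumHBA", "HBM"), cfg = scc,
                             modality = "rna")
    write.table(ann, out("sc_rna_cells.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_file(out("sc_rna_cells.tsv"))
  })

  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  pipe_log(verbose, "[chromenrich] manifest written to %s", manifest_path)
  invisible(manifest)
}
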