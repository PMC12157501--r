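#' Run configuration for the end-to-end pipeline
#'
#' @param genome path to the genome FASTA.
#' @param loci path to the locus GFF3.
#' @param counts path to the count TSV (spike rows included), or `NULL`.
#' @param reads named character vector of collapsed-read FASTA paths
#'   (names = sample ids), or `NULL` to skip the tailing stage.
#' @param peaks optional Pol III ChIP peak BED path.
#' @param structures optional dot-bracket file path; loci without supplied
#'   structures are folded internally.
#' @param contrasts named list of length-2 `(treat, ctrl)` condition
#'   vectors; recognised names `MP_1`, `MP_2`, `Dicer`, `PolIII`.
#' @param thresholds classification thresholds ([classify_thresholds()]).
#' @param scan Pol III scan parameters ([polIII_config()]).
#' @param hairpin_threshold short-hairpin cutoff in base pairs.
#' @param base_mean_min `baseMean` flagging threshold for results tables.
#' @param spike_prefix spike-in feature-id prefix in the count TSV.
#' @param seed seed for the (few) stochastic steps downstream of input
#'   generation.
#' @param outdir output directory; created if missing.
#' @return validated `run_config` list.
#' @export
run_config <- function(genome, loci, counts = NULL, reads = NULL,
                       peaks = NULL, structures = NULL,
                       contrasts = list(MP_1 = c("MP_depleted", "control"),
                                        Dicer = c("Dicer_depleted", "control"),
                                        PolIII = c("PolIII_depleted",
                                                   "control")),
                       thresholds = classify_thresholds(),
                       scan = polIII_config(),
                       hairpin_threshold = 32L,
                       base_mean_min = 10,
                       spike_prefix = "spike_",
                       seed = 1L, outdir = tempfile("noncanomir_run")) {
  .check(length(contrasts) >= 1, "at least one contrast required")
  for (p in c(genome, loci, counts, reads, peaks, structures)) {
    .check(file.exists(p), "input path does not exist: %s", p)
  }
  structure(list(genome = genome, loci = loci, counts = counts,
                 reads = reads, peaks = peaks, structures = structures,
                 contrasts = contrasts, thresholds = thresholds,
                 scan = scan, hairpin_threshold = hairpin_threshold,
                 base_mean_min = base_mean_min, spike_prefix = spike_prefix,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

.write_tsv <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.provenance <- function(config) {
  hashable <- config[setdiff(names(config), "outdir")]
  sprintf("# noncanomiR %s | seed=%d | config=%s",
          as.character(packageVersion("noncanomiR")), config$seed,
          .config_hash(hashable))
}

#' Run the whole classification pipeline from files to labels
#'
#' Stage order: input parsing, tailing (when reads are supplied),
#' differential abundance per contrast, hairpin structure, Pol III
#' promoter scan, evidence assembly and classification. Every output
#' table is written to `config$outdir` with a provenance header (package
#' version, seed, config hash); reruns with an identical config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `evidence`, `labels`, `diff` (per
#'   contrast), `hairpins`, `polIII`, `tail_profile`, `isoforms`.
#' @export
run_all <- function(config) {
  stage <- "io"
  res <- tryCatch({
    prov <- .provenance(config)
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    genome <- read_fasta(config$genome)
    loci <- read_loci_gff3(config$loci)

    stage <- "tailing"
    calls <- NULL
    profile <- NULL
    if (!is.null(config$reads)) {
      idx <- arm_index(loci, genome)
      reads <- do.call(rbind, lapply(names(config$reads), function(sid) {
        read_collapsed_fasta(config$reads[[sid]], sid)
      }))
      calls <- call_tails(assign_reads(reads, idx), idx)
      profile <- tailing_profile(calls)
      .write_tsv(profile$profile, file.path(config$outdir,
                                            "tail_profile.tsv"), prov)
      .write_tsv(profile$isoforms, file.path(config$outdir,
                                             "tail_isoforms.tsv"), prov)
    }

    stage <- "diffabund"
    diffs <- NULL
    if (!is.null(config$counts)) {
      cm <- read_counts_tsv(config$counts, config$spike_prefix)
      diffs <- lapply(config$contrasts, function(ct) {
        diff_table(cm, ct, base_mean_min = config$base_mean_min)
      })
      for (nm in names(diffs)) {
        .write_tsv(diffs[[nm]],
                   file.path(config$outdir, sprintf("diff_%s.tsv", nm)), prov)
      }
    }
    .check(!is.null(diffs), "no count matrix supplied; cannot classify")

    stage <- "hairpin"
    structures <- if (!is.null(config$structures)) {
      read_dotbracket(config$structures)
    } else NULL
    hairpins <- hairpin_report_all(loci, genome, structures,
                                   threshold = config$hairpin_threshold)
    .write_tsv(hairpins, file.path(config$outdir, "hairpin.tsv"), prov)

    stage <- "polIII_scan"
    pol <- polIII_report_all(loci, genome, config$scan)
    .write_tsv(pol, file.path(config$outdir, "polIII.tsv"), prov)

    stage <- "classify"
    chip <- if (!is.null(config$peaks)) {
      chip_overlap(loci, read_bed(config$peaks))
    } else NULL
    evidence <- build_evidence(loci, genome, diffs, hairpins, pol,
                               chip = chip, calls = calls)
    labels <- classify_loci(evidence, config$thresholds)
    .write_tsv(evidence, file.path(config$outdir, "evidence.tsv"), prov)
    .write_tsv(labels, file.path(config$outdir, "labels.tsv"), prov)

    list(evidence = evidence, labels = labels, diff = diffs,
         hairpins = hairpins, polIII = pol,
         tail_profile = if (!is.null(profile)) profile$profile else NULL,
         isoforms = if (!is.null(profile)) profile$isoforms else NULL)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Write the default synthetic study bundle to disk
#'
#' Emits genome FASTA, locus GFF3, spike-in-bearing count TSV, per-sample
#' collapsed-read FASTA, synthetic ChIP peaks and the ground-truth
#' manifest for the default six-class study, ready for [run_all()].
#'
#' @param seed generator seed.
#' @param outdir output directory; created if missing.
#' @param config optional [sim_config()] overriding the defaults (its seed
#'   wins over `seed`).
#' @return list with all file `paths`, the `config`, the truth `manifest`
#'   and a ready-made [run_config()].
#' @export
make_demo <- function(seed = 42L, outdir = tempfile("noncanomir_demo"),
                      config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- build_genome_and_loci(config)
  cm <- simulate_counts(config, sim$manifest)
  reads <- simulate_reads(config, sim$manifest)
  peaks <- simulate_chip_peaks(sim$loci, sim$manifest)

  paths <- list(genome = file.path(outdir, "genome.fa"),
                loci = file.path(outdir, "loci.gff3"),
                counts = file.path(outdir, "counts.tsv"),
                peaks = file.path(outdir, "chip_peaks.bed"),
                truth = file.path(outdir, "truth_loci.tsv"),
                truth_arms = file.path(outdir, "truth_arms.tsv"))
  write_fasta(sim$genome, paths$genome)
  write_loci_gff3(sim$loci, paths$loci)
  write_counts_tsv(cm, paths$counts)
  write_bed(peaks, paths$peaks)
  utils::write.table(sim$manifest$loci, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$manifest$arms, paths$truth_arms, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  read_paths <- character(0)
  for (sid in unique(reads$sample_id)) {
    p <- file.path(outdir, sprintf("reads_%s.fa", sid))
    write_collapsed_fasta(reads[reads$sample_id == sid, , drop = FALSE], p)
    read_paths[sid] <- p
  }
  paths$reads <- read_paths
  rc <- run_config(genome = paths$genome, loci = paths$loci,
                   counts = paths$counts, reads = paths$reads,
                   peaks = paths$peaks, seed = config$seed,
                   outdir = file.path(outdir, "results"))
  list(paths = paths, config = config, manifest = sim$manifest,
       run_config = rc, counts = cm, reads = reads)
}
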