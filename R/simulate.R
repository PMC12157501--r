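SIM_CLASSES <- c("canonical", "mirtron_like", "polIII_noncanonical",
                 "mp_dicer_independent", "piRNA_like", "siRNA26G_like")
SIM_CONDITIONS <- c("control", "MP_depleted", "Dicer_depleted",
                    "PolIII_depleted")

# classes carrying a planted type-II Pol III promoter/terminator architecture
.POLIII_CLASSES <- c("polIII_noncanonical", "mp_dicer_independent")

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

.default_lfc <- function() {
  m <- matrix(0, length(SIM_CLASSES), length(SIM_CONDITIONS),
              dimnames = list(SIM_CLASSES, SIM_CONDITIONS))
  m["canonical", c("MP_depleted", "Dicer_depleted")] <- c(-2.5, -2.5)
  m["mirtron_like", c("MP_depleted", "Dicer_depleted")] <- c(0.3, -2.5)
  m["polIII_noncanonical",
    c("MP_depleted", "Dicer_depleted", "PolIII_depleted")] <- c(0.3, -2.5, -3)
  m["mp_dicer_independent",
    c("MP_depleted", "PolIII_depleted")] <- c(0.3, -3)
  m["siRNA26G_like", "Dicer_depleted"] <- -2
  m
}

.default_tail_model <- function() {
  zero <- c(A = 0, U = 0, C = 0, G = 0)
  tm <- lapply(SIM_CLASSES, function(cl) {
    list(`5p` = zero,
         `3p` = if (cl == "polIII_noncanonical") c(A = 0.1, U = 0, C = 0,
                                                   G = 0) else zero)
  })
  names(tm) <- SIM_CLASSES
  tm
}

#' Simulation configuration for the synthetic small-RNA study
#'
#' Defines a multi-condition depletion study (control, Microprocessor,
#' Dicer and Pol III depletion) over loci of six biogenesis classes, with
#' negative-binomial count noise, spike-ins, 3' trimming isoforms and
#' class-specific untemplated tailing. The defaults encode the qualitative
#' depletion-response matrix the classifier targets: e.g. Pol III
#' noncanonical loci are Microprocessor-insensitive (slightly up-regulated
#' under MP loss), strongly Dicer- and Pol III-dependent, and carry planted
#' Box A/Box B/terminator geometry and 3p-arm A-tailing.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_loci_per_class loci per class.
#' @param classes subset of the six supported classes.
#' @param depth_mean expected reads per expressed arm (5p) in control.
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param n_replicates replicates per condition.
#' @param conditions condition labels (control must be present).
#' @param planted_lfc class x condition log2 fold-change matrix vs control.
#' @param tail_model per-class, per-arm untemplated tail rates for A/U/C/G.
#' @param trim_model probability over 3' trimming offsets 0..-3.
#' @param tail_len_probs probabilities of tail lengths 1..3.
#' @param tail_on_minus1_prob probability that a tailed read sits on the
#'   1-nt-shorter trimming isoform (precursor-tailing signature).
#' @param reads_per_arm reads simulated per arm per read-bearing sample.
#' @param read_conditions conditions for which raw reads are simulated.
#' @param spike_mean Poisson mean of per-sample spike-in totals.
#' @param arm_scalar relative abundance of 5p/3p arms.
#' @param stem_pairs planted stem base pairs per hairpin class.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 42L,
                       n_loci_per_class = 10L,
                       classes = SIM_CLASSES,
                       depth_mean = 2000,
                       nb_dispersion = 0.1,
                       n_replicates = 3L,
                       conditions = SIM_CONDITIONS,
                       planted_lfc = .default_lfc(),
                       tail_model = .default_tail_model(),
                       trim_model = c(`0` = 0.6, `-1` = 0.25, `-2` = 0.1,
                                      `-3` = 0.05),
                       tail_len_probs = c(0.7, 0.2, 0.1),
                       tail_on_minus1_prob = 0.7,
                       reads_per_arm = 2000L,
                       read_conditions = "control",
                       spike_mean = 5000,
                       arm_scalar = c(`5p` = 1, `3p` = 0.6),
                       stem_pairs = c(canonical = 35L, mirtron_like = 22L,
                                      polIII_noncanonical = 22L,
                                      mp_dicer_independent = 22L)) {
  .check(all(classes %in% SIM_CLASSES), "unknown class in config")
  .check("control" %in% conditions, "conditions must include control")
  .check(abs(sum(trim_model) - 1) < 1e-9, "trim_model must sum to 1")
  .check(abs(sum(tail_len_probs) - 1) < 1e-9, "tail_len_probs must sum to 1")
  for (cl in names(tail_model)) {
    for (arm in names(tail_model[[cl]])) {
      r <- tail_model[[cl]][[arm]]
      .check(all(r >= 0 & r <= 1) && sum(r) <= 1,
             "tail rates for %s/%s must lie in [0,1] and sum to <= 1", cl, arm)
    }
  }
  .check(depth_mean > 0 && nb_dispersion >= 0 && spike_mean > 0 &&
           n_replicates >= 1, "invalid config scalars")
  structure(list(seed = as.integer(seed),
                 n_loci_per_class = as.integer(n_loci_per_class),
                 classes = classes, depth_mean = depth_mean,
                 nb_dispersion = nb_dispersion,
                 n_replicates = as.integer(n_replicates),
                 conditions = conditions, planted_lfc = planted_lfc,
                 tail_model = tail_model, trim_model = trim_model,
                 tail_len_probs = tail_len_probs,
                 tail_on_minus1_prob = tail_on_minus1_prob,
                 reads_per_arm = as.integer(reads_per_arm),
                 read_conditions = read_conditions,
                 spike_mean = spike_mean, arm_scalar = arm_scalar,
                 stem_pairs = stem_pairs),
            class = "sim_config")
}

.rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# concrete instance of an IUPAC consensus
.iupac_instance <- function(iupac) {
  paste(vapply(strsplit(iupac, "")[[1]],
               function(code) sample(IUPAC_SETS[[code]], 1), character(1)),
        collapse = "")
}

# Build the sense-orientation region of one locus:
#   upstream flank | precursor | downstream flank
# Returns the region string plus transcript-relative annotation offsets.
.build_locus_region <- function(class, stem_pairs_cfg, scan_cfg) {
  up_len <- 150L
  down_len <- 100L
  truth <- list(boxA_offset = NA_integer_, boxB_offset = NA_integer_,
                tss_offset = NA_integer_, term_proximal_offset = NA_integer_,
                term_distal_offset = NA_integer_, stem_pairs = NA_integer_)
  is_polIII <- class %in% .POLIII_CLASSES

  if (class %in% c("piRNA_like", "siRNA26G_like")) {
    pre_len <- 40L
    arm_len <- if (class == "piRNA_like") 21L else 26L
    first <- if (class == "piRNA_like") "T" else "G"
    pre <- paste0(first, .rand_dna(pre_len - 1L))
    arm5p <- c(0L, arm_len)
    arm3p <- NULL
    spacer <- 0L
  } else {
    P <- stem_pairs_cfg[[class]]
    arm_len <- 22L
    loop <- .rand_dna(6L)
    spacer <- if (is_polIII) sample(3:4, 1) else 0L
    # Constrain stem5 start so that, after reverse complementation into the
    # 3p stem, the bases at and upstream of the 3p-arm 3' end cannot absorb
    # planted A-tails into the templated extension (and, for Pol III loci,
    # cannot extend the terminator T-run leftward).
    head_spacer <- if (spacer > 0) .rand_dna(spacer, c("C", "G")) else ""
    head_ctx <- .rand_dna(3L, c("A", "C", "G"))
    stem5 <- paste0(head_spacer, head_ctx,
                    .rand_dna(P - spacer - 3L))
    pre <- paste0(stem5, loop, revcomp(stem5))
    pre_len <- nchar(pre)
    arm5p <- c(0L, arm_len)
    arm3p <- c(pre_len - spacer - arm_len, pre_len - spacer)
    truth$stem_pairs <- as.integer(P)
  }

  downstream <- if (is_polIII) {
    gap <- sample(5:15, 1)
    distal_run <- sample(4:5, 1)
    core <- paste0(strrep("T", 5L), .rand_dna(gap, c("A", "C", "G")),
                   strrep("T", distal_run), .rand_dna(1L, c("A", "C", "G")))
    paste0(core, .rand_dna(down_len - nchar(core)))
  } else {
    # keep the base adjacent to the 3p end out of the A-tail context
    paste0(.rand_dna(1L, c("C", "G", "T")), .rand_dna(down_len - 1L))
  }

  if (is_polIII) {
    boxA_off <- sample(79:87, 1)
    boxB_off <- sample(35:42, 1)
    truth$tss_offset <- -sample(101:103, 1)
    boxA_seq <- .iupac_instance(scan_cfg$boxA$iupac)
    boxB_seq <- .iupac_instance(scan_cfg$boxB$iupac)
    for (try in 1:100) {
      up <- .rand_dna(up_len)
      substr(up, up_len - boxA_off + 1L,
             up_len - boxA_off + nchar(boxA_seq)) <- boxA_seq
      substr(up, up_len - boxB_off + 1L,
             up_len - boxB_off + nchar(boxB_seq)) <- boxB_seq
      # accept only if the planted instances are the unique best hits, so
      # reported offsets are exactly the planted geometry
      ok <- TRUE
      for (box in list(list(m = scan_cfg$boxA, off = boxA_off),
                       list(m = scan_cfg$boxB, off = boxB_off))) {
        w <- box$m$window
        seg <- substr(up, up_len + w[1] + 1L, up_len + w[2] + nchar(box$m$iupac))
        hits <- scan_iupac(seg, box$m, center = (w[2] - w[1]) / 2 + 1)
        zero <- hits[hits$mismatches == 0, , drop = FALSE]
        if (nrow(zero) != 1L || w[1] + zero$offset[1] - 1L != -box$off) {
          ok <- FALSE
          break
        }
      }
      if (ok) break
    }
    truth$boxA_offset <- -boxA_off
    truth$boxB_offset <- -boxB_off
    truth$term_proximal_offset <- spacer
    truth$term_distal_offset <- spacer + 5L + gap
  } else {
    up <- .rand_dna(up_len)
  }

  list(region = paste0(up, pre, downstream),
       up_len = up_len, pre_len = pre_len,
       arm5p = arm5p, arm3p = arm3p, truth = truth)
}

#' Build a synthetic genome, locus annotations and truth manifest
#'
#' Each locus gets its own contig (alternating `+`/`-` strands) consisting
#' of an upstream flank, the precursor and a downstream flank, in sense
#' orientation before strand placement. Pol III-class loci carry a planted
#' Box A (79-87 nt upstream of the precursor start), Box B (35-42 nt
#' upstream), a recorded TSS marker (101-103 nt upstream), a 5-T terminator
#' starting 3-4 nt downstream of the 3p-arm 3' end and a distal 4-5-T run
#' further downstream. Hairpin precursors are perfect reverse-complement
#' stems of the configured pair count around a 6-nt loop; piRNA-like loci
#' yield 21-nt reads with 5' U, 26G-like loci 26-nt reads with 5' G.
#'
#' @param config a [sim_config()].
#' @param scan_cfg Pol III scan configuration used to verify that planted
#'   motifs are the unique best in-window hits.
#' @return list with `genome` (named character vector), `loci` (locus
#'   table) and `manifest` (truth tables: `loci`, `arms`, `planted_lfc`).
#' @export
build_genome_and_loci <- function(config, scan_cfg = polIII_config()) {
  set.seed(config$seed)
  loci_rows <- list()
  arm_rows <- list()
  genome <- character(0)
  truth_rows <- list()
  idx <- 0L
  for (class in config$classes) {
    for (k in seq_len(config$n_loci_per_class)) {
      idx <- idx + 1L
      locus_id <- sprintf("sim-%s-%02d", class, k)
      contig_id <- paste0("ctg_", locus_id)
      strand <- if (idx %% 2L == 1L) "+" else "-"
      reg <- .build_locus_region(class, config$stem_pairs, scan_cfg)
      region_len <- nchar(reg$region)
      if (strand == "+") {
        contig_seq <- reg$region
        pre_start <- reg$up_len
        pre_end <- reg$up_len + reg$pre_len
        to_genomic <- function(iv) pre_start + iv
      } else {
        contig_seq <- revcomp(reg$region)
        pre_end <- region_len - reg$up_len
        pre_start <- pre_end - reg$pre_len
        to_genomic <- function(iv) c(pre_end - iv[2], pre_end - iv[1])
      }
      a5 <- to_genomic(reg$arm5p)
      a3 <- if (!is.null(reg$arm3p)) to_genomic(reg$arm3p) else
        c(NA_integer_, NA_integer_)
      host <- if (class %in% c("mirtron_like", .POLIII_CLASSES)) {
        paste0("host_", locus_id)
      } else NA_character_
      genome[contig_id] <- contig_seq
      loci_rows[[idx]] <- data.frame(
        locus_id = locus_id, contig_id = contig_id, strand = strand,
        pre_start = pre_start, pre_end = pre_end,
        arm5p_start = a5[1], arm5p_end = a5[2],
        arm3p_start = a3[1], arm3p_end = a3[2],
        host_gene_id = host, stringsAsFactors = FALSE)
      truth_rows[[idx]] <- data.frame(
        locus_id = locus_id, class = class, strand = strand,
        stem_pairs = reg$truth$stem_pairs,
        boxA_offset = reg$truth$boxA_offset,
        boxB_offset = reg$truth$boxB_offset,
        tss_offset = reg$truth$tss_offset,
        term_proximal_offset = reg$truth$term_proximal_offset,
        term_distal_offset = reg$truth$term_distal_offset,
        host_gene_id = host, stringsAsFactors = FALSE)
      arms_here <- c("5p", if (!is.null(reg$arm3p)) "3p")
      for (arm in arms_here) {
        iv <- if (arm == "5p") reg$arm5p else reg$arm3p
        arm_seq <- substr(reg$region, reg$up_len + iv[1] + 1L,
                          reg$up_len + iv[2])
        rates <- config$tail_model[[class]][[arm]] %||%
          c(A = 0, U = 0, C = 0, G = 0)
        arm_rows[[length(arm_rows) + 1L]] <- data.frame(
          feature_id = paste0(locus_id, "-", arm), locus_id = locus_id,
          arm = arm, class = class, arm_seq = arm_seq,
          arm_scalar = unname(config$arm_scalar[[arm]]),
          tail_rate_A = rates[["A"]], tail_rate_U = rates[["U"]],
          tail_rate_C = rates[["C"]], tail_rate_G = rates[["G"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  loci <- loci_frame(do.call(rbind, loci_rows))
  manifest <- list(loci = do.call(rbind, truth_rows),
                   arms = do.call(rbind, arm_rows),
                   planted_lfc = config$planted_lfc)
  list(genome = genome, loci = loci, manifest = manifest)
}

#' Simulate a spike-in-bearing count matrix from planted fold changes
#'
#' Per arm and sample, counts are drawn from a negative binomial with mean
#' `depth_mean * 2^lfc(class, condition) * arm_scalar` and dispersion
#' `nb_dispersion` (Var = mu + alpha mu^2; the Poisson limit is used when
#' alpha is 0). Spike-in totals are Poisson around `spike_mean`,
#' independent of condition, as expected for exogenous spikes added at
#' fixed amounts.
#'
#' @param config a [sim_config()].
#' @param manifest truth manifest from [build_genome_and_loci()].
#' @return a `count_matrix`.
#' @export
simulate_counts <- function(config, manifest) {
  set.seed(config$seed + 1L)
  arms <- manifest$arms
  samples <- as.vector(t(outer(config$conditions, seq_len(config$n_replicates),
                               function(cond, r) sprintf("%s_%d", cond, r))))
  condition <- rep(config$conditions, each = config$n_replicates)
  mu <- outer(seq_len(nrow(arms)), seq_along(samples),
              function(i, j) {
                lfc <- config$planted_lfc[cbind(arms$class[i], condition[j])]
                config$depth_mean * 2^lfc * arms$arm_scalar[i]
              })
  draw <- function(m) {
    if (config$nb_dispersion < 1e-12) rpois(length(m), m)
    else rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
  }
  counts <- matrix(draw(mu), nrow = nrow(arms),
                   dimnames = list(arms$feature_id, samples))
  spike <- rpois(length(samples), config$spike_mean)
  spike[spike == 0] <- 1   # spike totals must be positive for size factors
  count_matrix(counts, spike, condition)
}

#' Simulate collapsed reads with trimming isoforms and untemplated tails
#'
#' Each read is the arm reference trimmed at its 3' end by an offset drawn
#' from `trim_model`, optionally extended by a mononucleotide untemplated
#' tail of length 1-3 per the class/arm tail rates. Tailed reads sit on the
#' 1-nt-shorter isoform with probability `tail_on_minus1_prob`, emulating
#' tailing of a trimmed precursor 3' end prior to Dicer processing. Isoform
#' category counts are drawn multinomially per arm and sample, so the
#' marginal tailed fraction is binomial around the planted rate.
#'
#' @param config a [sim_config()].
#' @param manifest truth manifest from [build_genome_and_loci()].
#' @return data.frame of collapsed reads with truth columns: `read`,
#'   `count`, `sample_id`, `feature_id`, `trim`, `tail`.
#' @export
simulate_reads <- function(config, manifest) {
  set.seed(config$seed + 2L)
  arms <- manifest$arms
  trims <- as.integer(names(config$trim_model))
  p_trim <- unname(config$trim_model)
  p_trim_tailed <- config$tail_on_minus1_prob * (trims == -1L) +
    (1 - config$tail_on_minus1_prob) * p_trim
  p_trim_tailed <- p_trim_tailed / sum(p_trim_tailed)
  samples <- as.vector(t(outer(
    intersect(config$read_conditions, config$conditions),
    seq_len(config$n_replicates),
    function(cond, r) sprintf("%s_%d", cond, r))))
  out <- list()
  for (sample_id in samples) {
    for (i in seq_len(nrow(arms))) {
      rates <- c(A = arms$tail_rate_A[i], U = arms$tail_rate_U[i],
                 C = arms$tail_rate_C[i], G = arms$tail_rate_G[i])
      # category table: untailed x trim, tailed x (nt, len 1..3) x trim
      cat_p <- (1 - sum(rates)) * p_trim
      cat_df <- data.frame(trim = trims, nt = "", len = 0L,
                           stringsAsFactors = FALSE)
      for (nt in names(rates)) {
        if (rates[[nt]] <= 0) next
        for (len in 1:3) {
          cat_p <- c(cat_p, rates[[nt]] * config$tail_len_probs[len] *
                       p_trim_tailed)
          cat_df <- rbind(cat_df, data.frame(trim = trims, nt = nt,
                                             len = len))
        }
      }
      n_cat <- stats::rmultinom(1, config$reads_per_arm, cat_p)[, 1]
      keep <- n_cat > 0
      if (!any(keep)) next
      cd <- cat_df[keep, , drop = FALSE]
      arm_seq <- arms$arm_seq[i]
      tail_chr <- ifelse(cd$len > 0,
                         strrep(chartr("U", "T", cd$nt), cd$len), "")
      body <- substring(arm_seq, 1L, nchar(arm_seq) + cd$trim)
      out[[length(out) + 1L]] <- data.frame(
        read = paste0(body, tail_chr), count = n_cat[keep],
        sample_id = sample_id, feature_id = arms$feature_id[i],
        trim = cd$trim, tail = tail_chr, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic Pol III ChIP peaks over architecture-bearing loci
#'
#' Emits one peak per Pol III-class locus spanning the precursor with a
#' margin, mimicking polymerase occupancy calls at independently
#' transcribed small-RNA units.
#'
#' @param loci locus table.
#' @param manifest truth manifest.
#' @param margin peak extension beyond the precursor, nt.
#' @return BED-style data.frame (see [read_bed()]).
#' @export
simulate_chip_peaks <- function(loci, manifest, margin = 20L) {
  pol <- manifest$loci$locus_id[manifest$loci$class %in% .POLIII_CLASSES]
  sel <- loci[loci$locus_id %in% pol, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(contig_id = sel$contig_id,
             start = pmax(0L, sel$pre_start - margin),
             end = sel$pre_end + margin,
             name = paste0("peak_", sel$locus_id),
             score = 100, strand = ".", stringsAsFactors = FALSE)
}
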