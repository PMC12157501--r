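#' Default Pol III type-II promoter scan configuration
#'
#' Box A and Box B are internal promoter elements of type-II RNA Pol III
#' genes (tRNA-type promoters). The default consensus strings are the
#' standard eukaryotic tRNA-derived consensi and are deliberately
#' user-replaceable: organism-specific consensi should be supplied when
#' available. Windows are offsets of the motif start relative to the
#' precursor start in transcript orientation (negative = upstream); the
#' defaults bracket the ~79-87 bp (Box A) and ~35-42 bp (Box B) upstream
#' placement characteristic of small-RNA loci carried by independent
#' type-II Pol III units.
#'
#' @param boxA_iupac,boxB_iupac IUPAC consensus strings.
#' @param boxA_window,boxB_window integer length-2 vectors of start offsets
#'   searched (inclusive).
#' @param max_mismatches mismatches tolerated per motif.
#' @param term_min_run minimum T-run length reported as a terminator.
#' @param term_strong_run run length flagged as a strong terminator.
#' @param term_prox_max_offset proximal terminator must start within this
#'   many nt downstream of the 3p-arm 3' end.
#' @param term_distal_max_offset distal terminator searched within this many
#'   nt beyond the proximal run.
#' @return list of scan parameters.
#' @export
polIII_config <- function(boxA_iupac = "TRGCNNARYNNG",
                          boxB_iupac = "GWTCRANNC",
                          boxA_window = c(-95L, -70L),
                          boxB_window = c(-50L, -28L),
                          max_mismatches = 1L,
                          term_min_run = 4L,
                          term_strong_run = 5L,
                          term_prox_max_offset = 10L,
                          term_distal_max_offset = 60L) {
  .check(boxA_window[1] < boxA_window[2] && boxB_window[1] < boxB_window[2],
         "motif window bounds must be ordered")
  list(boxA = list(name = "BoxA", iupac = boxA_iupac, window = boxA_window,
                   max_mismatches = max_mismatches),
       boxB = list(name = "BoxB", iupac = boxB_iupac, window = boxB_window,
                   max_mismatches = max_mismatches),
       term_min_run = term_min_run, term_strong_run = term_strong_run,
       term_prox_max_offset = term_prox_max_offset,
       term_distal_max_offset = term_distal_max_offset)
}

#' Scan a sequence for an IUPAC motif with mismatches
#'
#' Degenerate matching is delegated to Biostrings (`fixed = "subject"`, so
#' IUPAC codes in the pattern are expanded while subject bases are literal).
#'
#' @param seq sense-strand sequence of the scan window.
#' @param motif list with `iupac` and `max_mismatches` (see
#'   [polIII_config()]).
#' @param center optional offset (1-based position within `seq`) used to
#'   order equally good hits by proximity; defaults to the window midpoint.
#' @return data.frame with columns `offset` (1-based start within `seq`),
#'   `match` (matched subsequence) and `mismatches`, sorted by
#'   `(mismatches, |offset - center|)`.
#' @export
scan_iupac <- function(seq, motif, center = NULL) {
  m <- nchar(motif$iupac)
  .check(m <= nchar(seq), "motif longer than scan window")
  subject <- Biostrings::DNAString(chartr("U", "T", toupper(seq)))
  pattern <- Biostrings::DNAString(toupper(motif$iupac))
  hits <- Biostrings::matchPattern(pattern, subject,
                                   max.mismatch = motif$max_mismatches,
                                   with.indels = FALSE, fixed = "subject")
  # drop hits overhanging the window edge (allowed when mismatches fall
  # outside the subject)
  hits <- hits[IRanges::start(hits) >= 1L &
                 IRanges::end(hits) <= length(subject)]
  if (length(hits) == 0) {
    return(data.frame(offset = integer(0), match = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  starts <- IRanges::start(hits)
  mm <- Biostrings::neditStartingAt(pattern, subject, starting.at = starts,
                                    with.indels = FALSE, fixed = "subject")
  if (is.null(center)) center <- (nchar(seq) - m) / 2 + 1
  ord <- order(mm, abs(starts - center), starts)
  data.frame(offset = starts[ord],
             match = as.character(Biostrings::Views(subject, hits[ord])),
             mismatches = as.integer(mm[ord]),
             stringsAsFactors = FALSE)
}

#' Find maximal poly-T runs (Pol III terminators)
#'
#' Type-II Pol III genes terminate at runs of >= 4-5 T on the sense strand.
#'
#' @param seq sense-strand downstream sequence.
#' @param min_len minimum run length reported.
#' @return data.frame with columns `offset` (0-based distance from the start
#'   of `seq` to the run start) and `run_length`, left to right.
#' @export
find_t_runs <- function(seq, min_len = 4L) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  r <- rle(chars == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(offset = starts[keep] - 1L, run_length = r$lengths[keep])
}

#' Pol III type-II promoter architecture report for one locus
#'
#' Searches the upstream region (transcript orientation) for Box A and
#' Box B within their configured offset windows, and the region downstream
#' of the 3p-arm 3' end for poly-T terminators: the proximal terminator is
#' the first run of >= `term_min_run` T starting within
#' `term_prox_max_offset` nt of the arm end, the distal terminator the next
#' run within `term_distal_max_offset` nt. A locus has
#' `polIII_architecture = TRUE` when Box A, Box B and a proximal terminator
#' are all present. The TSS estimate (Box A offset minus 15) is a crude
#' heuristic, reported for orientation only.
#'
#' @param locus one row of a locus table.
#' @param genome named character vector of contig sequences.
#' @param config scan parameters from [polIII_config()].
#' @return one-row data.frame with hit offsets (transcript-relative;
#'   upstream offsets negative, terminator offsets = nt downstream of the
#'   3p-arm 3' end), matched sequences, mismatch counts, terminator run
#'   lengths and the `polIII_architecture` flag. Absent features are `NA`.
#' @export
polIII_report <- function(locus, genome, config = polIII_config()) {
  .check(!is.null(genome[[locus$contig_id]]), "unknown contig %s",
         locus$contig_id)
  contig_len <- nchar(genome[[locus$contig_id]])
  up_need <- -min(config$boxA$window[1], config$boxB$window[1])
  down_need <- config$term_prox_max_offset + config$term_distal_max_offset +
    config$term_strong_run + 5L
  # transcript-relative extraction bounds in genomic coordinates
  if (locus$strand == "+") {
    ok <- locus$pre_start - up_need >= 0 &&
      locus$pre_end + down_need <= contig_len
  } else {
    ok <- locus$pre_end + up_need <= contig_len &&
      locus$pre_start - down_need >= 0
  }
  .check(ok, "locus %s too close to contig edge for scan margins",
         locus$locus_id)

  scan_box <- function(motif) {
    w <- motif$window
    m <- nchar(motif$iupac)
    # window of motif START offsets [w1, w2]; need sequence covering
    # offsets w1 .. w2+m-1 upstream of precursor start
    if (locus$strand == "+") {
      seg <- sense_seq(genome, locus$contig_id, locus$pre_start + w[1],
                       locus$pre_start + w[2] + m, "+")
    } else {
      seg <- sense_seq(genome, locus$contig_id, locus$pre_end - (w[2] + m),
                       locus$pre_end - w[1], "-")
    }
    hits <- scan_iupac(seg, motif, center = (w[2] - w[1]) / 2 + 1)
    if (nrow(hits) == 0) return(NULL)
    best <- hits[1, ]
    best$offset <- w[1] + best$offset - 1L   # back to transcript-relative
    best
  }
  boxA <- scan_box(config$boxA)
  boxB <- scan_box(config$boxB)

  # downstream of the 3p-arm 3' end (fall back to precursor end when no arm)
  arm_end <- if (!is.na(locus$arm3p_start)) {
    if (locus$strand == "+") locus$arm3p_end else locus$arm3p_start
  } else {
    if (locus$strand == "+") locus$pre_end else locus$pre_start
  }
  down_len <- down_need
  if (locus$strand == "+") {
    down <- sense_seq(genome, locus$contig_id, arm_end, arm_end + down_len,
                      "+")
  } else {
    down <- sense_seq(genome, locus$contig_id, arm_end - down_len, arm_end,
                      "-")
  }
  runs <- find_t_runs(down, min_len = config$term_min_run)
  prox <- runs[runs$offset <= config$term_prox_max_offset, , drop = FALSE]
  prox <- if (nrow(prox)) prox[1, ] else NULL
  dist <- NULL
  if (!is.null(prox)) {
    after <- prox$offset + prox$run_length
    cand <- runs[runs$offset > after &
                   runs$offset <= after + config$term_distal_max_offset, ,
                 drop = FALSE]
    if (nrow(cand)) dist <- cand[1, ]
  }

  data.frame(
    locus_id = locus$locus_id,
    boxA_offset = if (!is.null(boxA)) boxA$offset else NA_integer_,
    boxA_match = if (!is.null(boxA)) boxA$match else NA_character_,
    boxA_mismatches = if (!is.null(boxA)) boxA$mismatches else NA_integer_,
    boxB_offset = if (!is.null(boxB)) boxB$offset else NA_integer_,
    boxB_match = if (!is.null(boxB)) boxB$match else NA_character_,
    boxB_mismatches = if (!is.null(boxB)) boxB$mismatches else NA_integer_,
    term_proximal_offset = if (!is.null(prox)) prox$offset else NA_integer_,
    term_proximal_run = if (!is.null(prox)) prox$run_length else NA_integer_,
    term_proximal_strong = if (!is.null(prox))
      prox$run_length >= config$term_strong_run else NA,
    term_distal_offset = if (!is.null(dist)) dist$offset else NA_integer_,
    term_distal_run = if (!is.null(dist)) dist$run_length else NA_integer_,
    tss_estimate = if (!is.null(boxA)) boxA$offset - 15L else NA_integer_,
    tss_is_heuristic = TRUE,
    polIII_architecture = !is.null(boxA) && !is.null(boxB) && !is.null(prox),
    stringsAsFactors = FALSE
  )
}

#' Pol III architecture reports for all loci
#'
#' @inheritParams polIII_report
#' @param loci locus table.
#' @return data.frame, one row per locus (see [polIII_report()]).
#' @export
polIII_report_all <- function(loci, genome, config = polIII_config()) {
  do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    polIII_report(loci[i, ], genome, config)
  }))
}
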