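#' Build the arm reference index used for read assignment and tail calling
#'
#' For every annotated arm this precomputes the sense-strand reference
#' sequence extended `max_shift` nt upstream of the arm 5' end and
#' `down_ext` nt downstream of the arm 3' end (so that genome-templated 3'
#' extensions are visible to the tail caller), plus an anchor dictionary
#' mapping every `anchor_len`-mer that starts within `max_shift` nt of an
#' arm 5' end to the arms it belongs to.
#'
#' @param loci locus table (see [loci_frame()]).
#' @param genome named character vector of contig sequences.
#' @param anchor_len anchor prefix length used for assignment.
#' @param max_shift allowed offset of the read start from the annotated arm
#'   5' end.
#' @param down_ext downstream extension of the reference, nt.
#' @return an `arm_index` list with elements `arms` (data.frame) and
#'   `anchors` (environment).
#' @export
arm_index <- function(loci, genome, anchor_len = 16L, max_shift = 2L,
                      down_ext = 10L) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    r <- loci[i, ]
    for (arm in c("5p", "3p")) {
      s <- r[[paste0("arm", arm, "_start")]]
      e <- r[[paste0("arm", arm, "_end")]]
      if (is.na(s)) next
      contig_len <- nchar(genome[[r$contig_id]])
      if (r$strand == "+") {
        ext_start <- max(0L, s - max_shift)
        ext_end <- min(contig_len, e + down_ext)
        ext <- sense_seq(genome, r$contig_id, ext_start, ext_end, "+")
        lead <- s - ext_start
      } else {
        ext_start <- max(0L, s - down_ext)
        ext_end <- min(contig_len, e + max_shift)
        ext <- sense_seq(genome, r$contig_id, ext_start, ext_end, "-")
        lead <- ext_end - e
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0(r$locus_id, "-", arm), locus_id = r$locus_id,
        arm = arm, arm_len = e - s, ext = ext, lead = lead,
        stringsAsFactors = FALSE)
    }
  }
  arms <- do.call(rbind, rows)
  anchors <- new.env(parent = emptyenv(), size = nrow(arms) * 5L)
  for (i in seq_len(nrow(arms))) {
    for (shift in -max_shift:max_shift) {
      at <- arms$lead[i] + shift
      key <- substr(arms$ext[i], at + 1L, at + anchor_len)
      if (nchar(key) < anchor_len || at < 0) next
      hit <- list(row = i, shift = shift)
      cur <- anchors[[key]]
      if (is.null(cur)) {
        anchors[[key]] <- list(hit)
      } else if (!any(vapply(cur, function(h) h$row == i, logical(1)))) {
        # keep the smallest-|shift| anchor per arm
        anchors[[key]] <- c(cur, list(hit))
      }
    }
  }
  structure(list(arms = arms, anchors = anchors, anchor_len = anchor_len,
                 max_shift = max_shift, down_ext = down_ext),
            class = "arm_index")
}

#' Assign collapsed reads to arms by anchored prefix match
#'
#' A read is assigned to an arm when its first `anchor_len` nucleotides
#' match the arm's sense reference starting within `max_shift` nt of the
#' annotated arm 5' end. Reads matching k arms (e.g. identical-sequence
#' paralogs) receive fractional weight 1/k per arm, the "nonunique
#' fraction" convention of union-mode counting. Unassigned reads are
#' dropped (a normal outcome, reported via the `n_unassigned` attribute).
#'
#' @param reads data.frame with columns `read`, `count`, `sample_id`.
#' @param index an [arm_index()].
#' @return data.frame with one row per (read, arm) assignment: `read`,
#'   `count`, `sample_id`, `feature_id`, `shift`, `weight`.
#' @export
assign_reads <- function(reads, index) {
  keys <- substr(reads$read, 1L, index$anchor_len)
  out <- vector("list", nrow(reads))
  n_unassigned <- 0L
  for (i in seq_len(nrow(reads))) {
    hits <- index$anchors[[keys[i]]]
    if (is.null(hits)) {
      n_unassigned <- n_unassigned + 1L
      next
    }
    k <- length(hits)
    out[[i]] <- data.frame(
      read = reads$read[i], count = reads$count[i],
      sample_id = reads$sample_id[i],
      feature_id = index$arms$feature_id[vapply(hits, `[[`, 0L, "row")],
      shift = vapply(hits, `[[`, 0L, "shift"),
      weight = 1 / k, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(read = character(0), count = numeric(0),
                      sample_id = character(0), feature_id = character(0),
                      shift = integer(0), weight = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "n_unassigned") <- n_unassigned
  res
}

.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1] - 1L
}

#' Decompose assigned reads into templated body and untemplated 3' tail
#'
#' The templated length is the longest read prefix matching the genomic
#' sense sequence extended past the annotated arm 3' end, so a 3' addition
#' identical to the downstream genomic base is treated as templated, never
#' as a tail (conservative: tails that mimic the genome are undercounted;
#' without molecular barcodes the two cases are indistinguishable). The
#' trim offset is the templated 3' end relative to the annotated arm 3'
#' end (0 = reference-length, negative = trimmed isoform); templated
#' extensions are capped at `+3`. The tail class is the single repeated
#' nucleotide (T reported as U) or `other` for mixed tails.
#'
#' @param assignments output of [assign_reads()].
#' @param index the [arm_index()] used for assignment.
#' @param max_tail tails longer than this are flagged low-confidence.
#' @param max_ext cap on reported templated 3' extension.
#' @return `assignments` with added columns `templated_length`,
#'   `trim_offset`, `tail`, `tail_class`, `low_conf`.
#' @export
call_tails <- function(assignments, index, max_tail = 5L, max_ext = 3L) {
  n <- nrow(assignments)
  templated <- integer(n)
  tail <- character(n)
  arm_row <- match(assignments$feature_id, index$arms$feature_id)
  for (i in seq_len(n)) {
    j <- arm_row[i]
    at <- index$arms$lead[j] + assignments$shift[i]
    ref <- substr(index$arms$ext[j], at + 1L, nchar(index$arms$ext[j]))
    tl <- .common_prefix_len(assignments$read[i], ref)
    .check(tl >= index$anchor_len,
           "inconsistent assignment: templated prefix %d < anchor %d for %s",
           tl, index$anchor_len, assignments$feature_id[i])
    templated[i] <- tl
    tail[i] <- substr(assignments$read[i], tl + 1L,
                      nchar(assignments$read[i]))
  }
  trim <- assignments$shift + templated - index$arms$arm_len[arm_row]
  assignments$templated_length <- templated
  assignments$trim_offset <- pmin(trim, max_ext)
  assignments$tail <- tail
  assignments$tail_class <- vapply(tail, function(t) {
    if (nchar(t) == 0L) return("none")
    ch <- unique(strsplit(t, "")[[1]])
    if (length(ch) > 1L) return("other")
    c(A = "A", C = "C", G = "G", T = "U")[[ch]]
  }, character(1), USE.NAMES = FALSE)
  assignments$low_conf <- nchar(tail) > max_tail
  assignments
}

#' Per-arm tailing percentages, abundance and trimming-isoform tables
#'
#' Profiles are computed per sample (weighted by assignment fraction and
#' collapse count) and averaged across samples with equal weight. Arms
#' whose mean abundance falls below `min_rpm` reads per million assigned
#' reads are excluded from reporting. The isoform table keeps the `top_k`
#' (trim offset, tail class) species per arm by pooled weighted count.
#'
#' @param calls output of [call_tails()].
#' @param min_rpm reporting threshold on mean RPM.
#' @param top_k isoforms retained per arm.
#' @return list with `profile` (per-arm data.frame: `feature_id`, `arm`,
#'   `mean_rpm`, `total_reads`, `pct_A`, `pct_U`, `pct_C`, `pct_G`,
#'   `pct_other`, `pct_untailed`) and `isoforms` (per-arm top-k table).
#' @export
tailing_profile <- function(calls, min_rpm = 1.0, top_k = 6L) {
  if (nrow(calls) == 0L) {
    return(list(profile = data.frame(), isoforms = data.frame()))
  }
  calls$w <- calls$weight * calls$count
  sample_tot <- tapply(calls$w, calls$sample_id, sum)
  calls$rpm_w <- calls$w / as.numeric(sample_tot[calls$sample_id]) * 1e6

  key <- interaction(calls$feature_id, calls$sample_id, drop = TRUE)
  per_as <- data.frame(
    feature_id = tapply(calls$feature_id, key, `[`, 1),
    sample_id = tapply(calls$sample_id, key, `[`, 1),
    n = as.numeric(tapply(calls$w, key, sum)),
    rpm = as.numeric(tapply(calls$rpm_w, key, sum)),
    stringsAsFactors = FALSE)
  for (cls in c("A", "U", "C", "G", "other", "none")) {
    wcls <- calls$w * (calls$tail_class == cls)
    per_as[[paste0("pct_", cls)]] <-
      as.numeric(tapply(wcls, key, sum)) / per_as$n * 100
  }
  prof <- do.call(rbind, lapply(split(per_as, per_as$feature_id), function(d) {
    data.frame(feature_id = d$feature_id[1],
               mean_rpm = mean(d$rpm), total_reads = sum(d$n),
               pct_A = mean(d$pct_A), pct_U = mean(d$pct_U),
               pct_C = mean(d$pct_C), pct_G = mean(d$pct_G),
               pct_other = mean(d$pct_other),
               pct_untailed = mean(d$pct_none),
               stringsAsFactors = FALSE)
  }))
  prof$arm <- sub("^.*-", "", prof$feature_id)
  prof <- prof[prof$mean_rpm >= min_rpm, , drop = FALSE]
  rownames(prof) <- NULL

  iso_key <- interaction(calls$feature_id, calls$trim_offset,
                         calls$tail_class, drop = TRUE)
  iso <- data.frame(
    feature_id = tapply(calls$feature_id, iso_key, `[`, 1),
    trim_offset = as.integer(tapply(calls$trim_offset, iso_key, `[`, 1)),
    tail_class = tapply(calls$tail_class, iso_key, `[`, 1),
    count = as.numeric(tapply(calls$w, iso_key, sum)),
    stringsAsFactors = FALSE)
  iso <- do.call(rbind, lapply(split(iso, iso$feature_id), function(d) {
    d <- d[order(-d$count, d$trim_offset), , drop = FALSE]
    utils::head(d, top_k)
  }))
  rownames(iso) <- NULL
  list(profile = prof, isoforms = iso)
}

#' Permutation test for 3p-vs-5p tailing asymmetry
#'
#' Tailing that is skewed toward 3p-derived strands is the signature of an
#' enzyme acting on the precursor 3' end (exposed before Dicer cleavage,
#' unlike 5p 3' ends). The statistic is the difference in mean percent
#' tailing between 3p and 5p arms for the chosen nucleotide; significance
#' comes from permuting arm labels, with add-one correction.
#'
#' @param profile per-arm profile from [tailing_profile()].
#' @param nucleotide tail class tested (`A`, `U`, `C` or `G`).
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutation draw.
#' @return list with `delta` (mean 3p minus mean 5p percent tailing) and
#'   `p` (permutation p-value, `>= 1/(n_perm+1)`).
#' @export
asymmetry_test <- function(profile, nucleotide = "A", n_perm = 10000L,
                           seed = 1L) {
  .check(nucleotide %in% c("A", "U", "C", "G"), "invalid nucleotide")
  x <- profile[[paste0("pct_", nucleotide)]]
  is3p <- profile$arm == "3p"
  .check(sum(is3p) >= 2 && sum(!is3p) >= 2,
         "need at least 2 arms per strand class (have %d x 3p, %d x 5p)",
         sum(is3p), sum(!is3p))
  delta <- mean(x[is3p]) - mean(x[!is3p])
  set.seed(seed)
  n3 <- sum(is3p)
  n <- length(x)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n3)
    d <- mean(x[idx]) - mean(x[-idx])
    if (abs(d) >= abs(delta) - 1e-12) exceed <- exceed + 1L
  }
  list(delta = delta, p = (exceed + 1) / (n_perm + 1))
}
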