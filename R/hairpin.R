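#' Parse a dot-bracket string into base-pair index pairs
#'
#' Standard stack matching over `(`, `)` and `.`. Returned indices are
#' 1-based positions within the structure string, sorted by opening index.
#'
#' @param struct dot-bracket string.
#' @return integer matrix with columns `i` (opening) and `j` (closing);
#'   zero rows for an unpaired structure.
#' @export
parse_dotbracket <- function(struct) {
  chars <- strsplit(struct, "")[[1]]
  .check(all(chars %in% c("(", ")", ".")),
         "invalid structure character at position %d",
         which(!chars %in% c("(", ")", "."))[1])
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  out <- vector("list", length(chars))
  n_out <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      .check(length(stack) > 0, "unbalanced ')' at position %d", k)
      n_out <- n_out + 1L
      out[[n_out]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  .check(length(stack) == 0, "unbalanced '(' at end-of-string (position %d)",
         if (length(stack)) stack[length(stack)] else nchar(struct))
  if (n_out > 0) {
    pairs <- do.call(rbind, out[seq_len(n_out)])
    colnames(pairs) <- c("i", "j")
    pairs <- pairs[order(pairs[, "i"]), , drop = FALSE]
  }
  pairs
}

# Watson-Crick + GU wobble pairing table (T treated as U)
.can_pair <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "AU", "UA", "GC", "CG", "GT", "TG", "GU", "UG")
}

#' Fold a sequence by base-pair maximization
#'
#' Nussinov-style dynamic program returning a nested structure with the
#' maximum number of Watson-Crick plus GU pairs, subject to a minimum
#' hairpin-loop length. This is a deliberately simple, fully verifiable
#' folder used when no externally predicted structures are supplied; it does
#' not model stacking energies (see the package vignette for the rationale
#' and limitations).
#'
#' Ties in the dynamic program are broken deterministically by preferring a
#' pair with the smaller opening index.
#'
#' @param seq RNA/DNA sequence over `{A,C,G,U,T}`.
#' @param min_loop minimum number of unpaired bases enclosed by a pair.
#' @return dot-bracket string of the same length as `seq`.
#' @export
fold_maxpair <- function(seq, min_loop = 3L) {
  .check(min_loop >= 3, "min_loop must be >= 3")
  s <- strsplit(toupper(seq), "")[[1]]
  .check(all(s %in% c("A", "C", "G", "U", "T", "N")),
         "invalid sequence character")
  n <- length(s)
  if (n == 0) return("")
  # pairable[i,j]: complementary and loop constraint satisfied
  M <- matrix(0L, n, n)
  if (n > min_loop + 1) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1L]               # j unpaired
        ks <- i:(j - min_loop - 1L)
        ks <- ks[.can_pair(s[ks], s[j])]
        if (length(ks)) {
          # left part is M[i, k-1] (0 when k == i)
          left <- integer(length(ks))
          sel <- ks > i
          if (any(sel)) left[sel] <- M[cbind(i, ks[sel] - 1L)]
          inner <- M[cbind(ks + 1L, j - 1L)]
          cand <- left + 1L + inner
          best <- max(best, max(cand))
        }
        M[i, j] <- best
      }
    }
  }
  struct <- rep(".", n)
  # Pairing j with the smallest k that still achieves the optimum is always
  # preferred over leaving j unpaired (deterministic tie-break).
  traceback <- function(i, j) {
    while (i < j) {
      paired <- FALSE
      if (j - i > min_loop) {
        for (k in i:(j - min_loop - 1L)) {
          if (.can_pair(s[k], s[j])) {
            left <- if (k > i) M[i, k - 1L] else 0L
            if (left + 1L + M[k + 1L, j - 1L] == M[i, j]) {
              struct[k] <<- "("
              struct[j] <<- ")"
              if (k > i) traceback(i, k - 1L)
              i <- k + 1L
              j <- j - 1L
              paired <- TRUE
              break
            }
          }
        }
      }
      if (!paired) j <- j - 1L
    }
  }
  if (n > 1) traceback(1L, n)
  paste(struct, collapse = "")
}

#' Hairpin stem report with short-hairpin classification
#'
#' Counts the base pairs of a predicted secondary structure that lie fully
#' inside the precursor span and applies the short-hairpin rule: precursors
#' whose structure carries fewer than `threshold` internal base pairs
#' (default 32, the duplex-pair criterion used for MirGeneDB-style hairpin
#' annotation) are flagged `short_hairpin`, a hallmark of Microprocessor-
#' independent substrates such as mirtrons. Unpaired flank lengths are the
#' contiguous runs of unpaired bases at the precursor 5' and 3' termini.
#'
#' @param locus one row of a locus table (or any list with `locus_id`,
#'   `pre_start`, `pre_end`).
#' @param struct dot-bracket string covering exactly the precursor span
#'   (transcript orientation).
#' @param threshold short-hairpin cutoff in base pairs.
#' @return one-row data.frame: `locus_id`, `stem_pairs`, `short_hairpin`,
#'   `unpaired_5p_flank`, `unpaired_3p_flank`, `structure`.
#' @export
hairpin_report <- function(locus, struct, threshold = 32L) {
  pre_len <- locus$pre_end - locus$pre_start
  .check(nchar(struct) == pre_len,
         "structure length %d != precursor length %d for locus %s",
         nchar(struct), pre_len, locus$locus_id)
  pairs <- parse_dotbracket(struct)
  stem_pairs <- nrow(pairs)
  chars <- strsplit(struct, "")[[1]]
  unp <- chars == "."
  run5 <- if (all(unp)) length(unp) else which(!unp)[1] - 1L
  run3 <- if (all(unp)) length(unp) else length(unp) - max(which(!unp))
  data.frame(locus_id = locus$locus_id,
             stem_pairs = stem_pairs,
             short_hairpin = stem_pairs < threshold,
             unpaired_5p_flank = run5,
             unpaired_3p_flank = run3,
             structure = struct,
             stringsAsFactors = FALSE)
}

#' Fold or look up structures and build hairpin reports for all loci
#'
#' @param loci locus table.
#' @param genome named character vector of contig sequences.
#' @param structures optional data.frame from [read_dotbracket()] keyed by
#'   locus id; loci without a supplied structure are folded with
#'   [fold_maxpair()].
#' @param threshold short-hairpin cutoff in base pairs.
#' @param min_loop minimum hairpin loop length for the built-in folder.
#' @return data.frame of per-locus hairpin reports.
#' @export
hairpin_report_all <- function(loci, genome, structures = NULL,
                               threshold = 32L, min_loop = 3L) {
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    r <- loci[i, ]
    struct <- NULL
    if (!is.null(structures)) {
      hit <- match(r$locus_id, structures$id)
      if (!is.na(hit)) struct <- structures$structure[hit]
    }
    if (is.null(struct)) {
      pre_seq <- sense_seq(genome, r$contig_id, r$pre_start, r$pre_end,
                           r$strand)
      struct <- fold_maxpair(pre_seq, min_loop = min_loop)
    }
    out[[i]] <- hairpin_report(r, struct, threshold = threshold)
  }
  do.call(rbind, out)
}
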