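#' @importFrom stats rnbinom rpois runif setNames rbinom p.adjust pnorm var
#'   aggregate
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse-complement a DNA string
#'
#' Vectorised over its input. `N` maps to `N`; case is preserved as upper.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Validate a DNA sequence, returning the offending character and position,
# or NULL when clean.
.bad_dna_char <- function(seq, alphabet = DNA_ALPHABET) {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) == 0L) return(NULL)
  list(char = chars[bad[1]], pos = bad[1])
}

#' Extract a sense-strand sequence from the genome
#'
#' Returns the transcript-orientation sequence of a 0-based half-open
#' genomic interval: minus-strand intervals are reverse-complemented, so
#' downstream code always works in transcript orientation.
#'
#' @param genome named character vector of contig sequences.
#' @param contig_id contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return character scalar.
#' @export
sense_seq <- function(genome, contig_id, start, end, strand = "+") {
  seq <- genome[[contig_id]]
  if (is.null(seq)) stop("unknown contig: ", contig_id)
  if (start < 0 || end > nchar(seq) || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, contig_id, nchar(seq)))
  }
  s <- substr(seq, start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

# Hash a list deterministically (provenance headers). jsonlite gives a
# canonical-enough serialization for our flat configs.
.config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  substr(.digest_string(as.character(json)), 1, 12)
}

# Small polynomial string hash; avoids a dependency for a provenance stamp.
.digest_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x%04x", h, length(bytes) %% 65536)
}

# stopifnot with sprintf-style message
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
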