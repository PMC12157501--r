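# Independent oracles used to verify the package's implementations.
# These deliberately use the most naive correct formulation available
# (exhaustive enumeration, literal definitions) and share no code with R/.

# Maximum number of nested base pairs by exhaustive enumeration over all
# nested structures: position i is unpaired, or paired with some k.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in%
    c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)                       # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (k > j) break
      if (ok(s[i], s[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  if (length(s) < 2) return(0L)
  rec(1L, length(s))
}

# Literal Benjamini-Hochberg step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force maximal-templated-prefix split of a read against an extended
# reference: tries every split point and keeps the largest templated length.
oracle_tail_split <- function(read, ext_ref) {
  best <- 0L
  for (t in 0:nchar(read)) {
    if (t > nchar(ext_ref)) break
    if (substr(read, 1, t) == substr(ext_ref, 1, t)) best <- t
  }
  list(templated = best, tail = substr(read, best + 1L, nchar(read)))
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
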