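#' Read a FASTA file with strict alphabet validation
#'
#' Parses a (multi-)FASTA file into a named character vector of uppercase
#' sequences. Unlike permissive readers, this one enforces the DNA alphabet
#' `{A,C,G,T,N}` and reports the offending line on failure, which matters
#' when genome files are assembled by hand or by other tools.
#'
#' @param path path to a FASTA file.
#' @param alphabet allowed characters after uppercasing.
#' @return named character vector; names are the first whitespace-delimited
#'   token of each header, order preserved.
#' @export
read_fasta <- function(path, alphabet = DNA_ALPHABET) {
  .check(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  ids <- character(0)
  seqs <- character(0)
  cur_id <- NULL
  cur <- character(0)
  flush <- function() {
    if (!is.null(cur_id)) {
      s <- paste(cur, collapse = "")
      .check(nchar(s) > 0, "empty sequence for record '%s'", cur_id)
      ids <<- c(ids, cur_id)
      seqs <<- c(seqs, s)
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^>", ln)) {
      flush()
      cur_id <- sub("^>\\s*", "", ln)
      cur_id <- strsplit(cur_id, "\\s+")[[1]][1]
      .check(!is.na(cur_id) && nzchar(cur_id),
             "malformed FASTA header at line %d", i)
      cur <- character(0)
    } else if (nzchar(trimws(ln))) {
      .check(!is.null(cur_id), "sequence before first header at line %d", i)
      up <- toupper(trimws(ln))
      bad <- .bad_dna_char(up, alphabet)
      if (!is.null(bad)) {
        stop(sprintf("invalid character %s at line %d", bad$char, i),
             call. = FALSE)
      }
      cur <- c(cur, up)
    }
  }
  flush()
  .check(length(ids) > 0, "no FASTA records in %s", path)
  .check(!anyDuplicated(ids), "duplicate FASTA ids in %s", path)
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct and validate a locus table
#'
#' Loci use 0-based half-open genomic coordinates throughout. Arm intervals
#' (`arm5p_*`, `arm3p_*`) may be `NA` but when present must lie within the
#' precursor, and the 5p arm must precede the 3p arm in transcript
#' orientation (i.e. in genomic order on `+` loci, reversed on `-` loci).
#'
#' @param df data.frame with columns `locus_id`, `contig_id`, `strand`,
#'   `pre_start`, `pre_end`, and optionally `arm5p_start`, `arm5p_end`,
#'   `arm3p_start`, `arm3p_end`, `host_gene_id`.
#' @param min_pre_len,max_pre_len allowed precursor length bounds.
#' @return the validated data.frame (missing optional columns added as `NA`).
#' @export
loci_frame <- function(df, min_pre_len = 40L, max_pre_len = 200L) {
  need <- c("locus_id", "contig_id", "strand", "pre_start", "pre_end")
  .check(all(need %in% names(df)), "loci table missing columns: %s",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in c("arm5p_start", "arm5p_end", "arm3p_start", "arm3p_end")) {
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  }
  if (!"host_gene_id" %in% names(df)) df$host_gene_id <- NA_character_
  .check(!anyDuplicated(df$locus_id), "duplicate locus ids")
  .check(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  len <- df$pre_end - df$pre_start
  .check(all(len > 0), "empty precursor interval")
  .check(all(len >= min_pre_len & len <= max_pre_len),
         "precursor length outside [%d,%d] for: %s", min_pre_len, max_pre_len,
         paste(df$locus_id[len < min_pre_len | len > max_pre_len],
               collapse = ", "))
  for (arm in c("arm5p", "arm3p")) {
    s <- df[[paste0(arm, "_start")]]
    e <- df[[paste0(arm, "_end")]]
    has <- !is.na(s)
    .check(all(is.na(s) == is.na(e)), "%s interval half-specified", arm)
    .check(all(e[has] > s[has]), "empty %s interval", arm)
    out <- has & (s < df$pre_start | e > df$pre_end)
    .check(!any(out), "%s outside precursor for: %s", arm,
           paste(df$locus_id[out], collapse = ", "))
  }
  both <- !is.na(df$arm5p_start) & !is.na(df$arm3p_start)
  if (any(both)) {
    plus_ok <- df$strand != "+" | !both | df$arm5p_end <= df$arm3p_start
    minus_ok <- df$strand != "-" | !both | df$arm3p_end <= df$arm5p_start
    bad <- !(plus_ok & minus_ok)
    .check(!any(bad), "arm5p does not precede arm3p in transcript order: %s",
           paste(df$locus_id[bad], collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read small-RNA loci from GFF3
#'
#' Expects `pre_miRNA` features with an `ID` attribute and child `miRNA`
#' features with `Parent` plus an `arm` attribute (`5p`/`3p`; an
#' `-5p`/`-3p` suffix on the child `ID` is accepted as a fallback).
#' GFF3 1-based closed coordinates are converted to the package's 0-based
#' half-open convention at this boundary.
#'
#' @inheritParams loci_frame
#' @param path path to a GFF3 file.
#' @return a validated locus table (see [loci_frame()]).
#' @export
read_loci_gff3 <- function(path, min_pre_len = 40L, max_pre_len = 200L) {
  .check(file.exists(path), "file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  pre <- gr[type == "pre_miRNA"]
  .check(length(pre) > 0, "no pre_miRNA features in %s", path)
  .check(all(as.character(GenomicRanges::strand(pre)) %in% c("+", "-")),
         "unknown strand on pre_miRNA feature(s) in %s", path)
  df <- data.frame(
    locus_id = as.character(pre$ID),
    contig_id = as.character(GenomicRanges::seqnames(pre)),
    strand = as.character(GenomicRanges::strand(pre)),
    pre_start = GenomicRanges::start(pre) - 1L,
    pre_end = GenomicRanges::end(pre),
    arm5p_start = NA_integer_, arm5p_end = NA_integer_,
    arm3p_start = NA_integer_, arm3p_end = NA_integer_,
    host_gene_id = if (!is.null(pre$host_gene)) as.character(pre$host_gene)
                   else NA_character_,
    stringsAsFactors = FALSE
  )
  kids <- gr[type == "miRNA"]
  if (length(kids) > 0) {
    parent <- vapply(kids$Parent, function(p) {
      .check(length(p) == 1L, "miRNA child with %d parents", length(p))
      as.character(p)
    }, character(1))
    arm <- if (!is.null(kids$arm)) as.character(kids$arm) else
      rep(NA_character_, length(kids))
    kid_id <- if (!is.null(kids$ID)) as.character(kids$ID) else
      rep(NA_character_, length(kids))
    arm[is.na(arm) & grepl("-5p$", kid_id)] <- "5p"
    arm[is.na(arm) & grepl("-3p$", kid_id)] <- "3p"
    .check(all(arm %in% c("5p", "3p")),
           "miRNA child without resolvable arm tag in %s", path)
    for (i in seq_along(kids)) {
      row <- match(parent[i], df$locus_id)
      .check(!is.na(row), "miRNA child references unknown parent '%s'",
             parent[i])
      s <- GenomicRanges::start(kids)[i] - 1L
      e <- GenomicRanges::end(kids)[i]
      .check(s >= df$pre_start[row] && e <= df$pre_end[row],
             "arm outside precursor for locus %s", df$locus_id[row])
      df[[paste0("arm", arm[i], "_start")]][row] <- s
      df[[paste0("arm", arm[i], "_end")]][row] <- e
    }
  }
  loci_frame(df, min_pre_len, max_pre_len)
}

#' Write a locus table to GFF3
#'
#' Inverse of [read_loci_gff3()]; internal 0-based half-open intervals are
#' converted back to 1-based closed GFF3 coordinates.
#'
#' @param loci a locus table (see [loci_frame()]).
#' @param path output path.
#' @export
write_loci_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    r <- loci[i, ]
    attrs <- paste0("ID=", r$locus_id)
    if (!is.na(r$host_gene_id)) {
      attrs <- paste0(attrs, ";host_gene=", r$host_gene_id)
    }
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       r$contig_id, "noncanomiR", "pre_miRNA",
                       r$pre_start + 1L, r$pre_end, r$strand, attrs), con)
    for (arm in c("5p", "3p")) {
      s <- r[[paste0("arm", arm, "_start")]]
      e <- r[[paste0("arm", arm, "_end")]]
      if (!is.na(s)) {
        writeLines(sprintf(
          "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s-%s;Parent=%s;arm=%s",
          r$contig_id, "noncanomiR", "miRNA", s + 1L, e, r$strand,
          r$locus_id, arm, r$locus_id, arm), con)
      }
    }
  }
  invisible(path)
}

#' Construct a count matrix with spike-in totals and condition labels
#'
#' @param counts numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Non-integer values are
#'   allowed (fractional multi-mapper assignment).
#' @param spike_counts numeric vector of spike-in totals, one per sample.
#' @param condition character vector of condition labels per sample; when
#'   `NULL`, inferred by stripping a trailing `_<number>` replicate suffix
#'   from sample ids.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, spike_counts, condition = NULL) {
  .check(is.matrix(counts) && !is.null(rownames(counts)) &&
           !is.null(colnames(counts)), "counts must be a named matrix")
  .check(!anyDuplicated(rownames(counts)), "duplicate feature ids")
  .check(!anyDuplicated(colnames(counts)), "duplicate sample ids")
  .check(all(counts >= 0), "negative counts")
  .check(length(spike_counts) == ncol(counts),
         "spike_counts length != number of samples")
  .check(all(spike_counts > 0),
         "sample(s) with zero spike-in total: %s; disable spike normalization",
         paste(colnames(counts)[spike_counts <= 0], collapse = ", "))
  if (is.null(condition)) condition <- sub("_[0-9]+$", "", colnames(counts))
  .check(length(condition) == ncol(counts),
         "condition length != number of samples")
  structure(list(counts = counts,
                 spike_counts = setNames(as.numeric(spike_counts),
                                         colnames(counts)),
                 condition = setNames(as.character(condition),
                                      colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix from TSV, aggregating spike-in rows
#'
#' The first column holds feature ids, the header row sample ids. Rows whose
#' id starts with `spike_prefix` are treated as spike-in features: they are
#' removed from the matrix and summed into per-sample spike-in totals used
#' for size-factor normalization.
#'
#' @param path path to a TSV file.
#' @param spike_prefix feature-id prefix identifying spike-in rows.
#' @param condition optional condition labels (see [count_matrix()]).
#' @return a `count_matrix`.
#' @export
read_counts_tsv <- function(path, spike_prefix = "spike_", condition = NULL) {
  .check(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  .check(ncol(df) >= 2, "count TSV needs a feature-id column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  .check(is.numeric(m), "non-numeric count cell in %s", path)
  .check(all(m >= 0), "negative count cell in %s", path)
  rownames(m) <- df[[1]]
  is_spike <- startsWith(rownames(m), spike_prefix)
  .check(any(is_spike),
         "no spike-in rows with prefix '%s' in %s; disable spike normalization",
         spike_prefix, path)
  spike <- colSums(m[is_spike, , drop = FALSE])
  count_matrix(m[!is_spike, , drop = FALSE], spike, condition)
}

#' Write a count matrix to TSV
#'
#' Spike-in totals are written as a single `spike_total` row so that a
#' write/read round trip reproduces both counts and spike totals exactly.
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_counts_tsv <- function(cm, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("feature_id", colnames(cm$counts)), collapse = "\t"), con)
  all <- rbind(cm$counts, spike_total = cm$spike_counts)
  for (i in seq_len(nrow(all))) {
    writeLines(paste(c(rownames(all)[i], sprintf("%.17g", all[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read collapsed small-RNA reads from FASTA
#'
#' Headers follow the `readN_xCOPY` dialect (e.g. `>read12_x53` is a read
#' observed 53 times). Read lengths outside the configured bounds are
#' rejected: collapsed small-RNA libraries are expected to be pre-filtered
#' to the mature-small-RNA size range.
#'
#' @param path path to a collapsed-read FASTA file.
#' @param sample_id sample label attached to every read.
#' @param min_len,max_len allowed read length bounds.
#' @return data.frame with columns `read`, `count`, `sample_id`.
#' @export
read_collapsed_fasta <- function(path, sample_id, min_len = 16L,
                                 max_len = 35L) {
  seqs <- read_fasta(path, alphabet = c("A", "C", "G", "T"))
  counts <- suppressWarnings(as.integer(sub("^.*_x", "", names(seqs))))
  .check(!anyNA(counts) && all(counts >= 1),
         "collapsed-read header without _xCOPY count in %s", path)
  lens <- nchar(seqs)
  .check(all(lens >= min_len & lens <= max_len),
         "read length outside [%d,%d] in %s", min_len, max_len, path)
  data.frame(read = unname(seqs), count = counts,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Write collapsed reads to FASTA
#'
#' @param reads data.frame with columns `read` and `count`.
#' @param path output path.
#' @export
write_collapsed_fasta <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(sprintf(">read%d_x%d", i, reads$count[i]), reads$read[i]),
               con)
  }
  invisible(path)
}

#' Read dot-bracket structure records
#'
#' Each record is three lines: `>id`, sequence, structure.
#'
#' @param path path to a dot-bracket text file.
#' @return data.frame with columns `id`, `seq`, `structure`.
#' @export
read_dotbracket <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  .check(length(lines) %% 3 == 0 && all(grepl("^>", lines[c(TRUE, FALSE, FALSE)])),
         "malformed dot-bracket file %s (expect >id/seq/struct triples)", path)
  ids <- sub("^>\\s*", "", lines[c(TRUE, FALSE, FALSE)])
  seqs <- toupper(lines[c(FALSE, TRUE, FALSE)])
  structs <- lines[c(FALSE, FALSE, TRUE)]
  .check(all(nchar(seqs) == nchar(structs)),
         "sequence/structure length mismatch in %s", path)
  data.frame(id = ids, seq = seqs, structure = structs,
             stringsAsFactors = FALSE)
}

#' Write dot-bracket structure records
#'
#' @param db data.frame with columns `id`, `seq`, `structure`.
#' @param path output path.
#' @export
write_dotbracket <- function(db, path) {
  writeLines(rbind(paste0(">", db$id), db$seq, db$structure), path)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' BED is natively 0-based half-open, matching the package's internal
#' convention, so coordinates pass through unchanged.
#'
#' @param path path to a BED file (3+ columns).
#' @return data.frame with columns `contig_id`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  n <- length(gr)
  data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else rep(".", n),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else rep(0, n),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write BED6 intervals
#'
#' @param bed data.frame with columns `contig_id`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(bed, path) {
  name <- bed$name %||% rep(".", nrow(bed))
  score <- bed$score %||% rep(0, nrow(bed))
  strand <- bed$strand %||% rep(".", nrow(bed))
  strand[strand == "*"] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s", bed$contig_id, bed$start,
                     bed$end, name, score, strand), path)
  invisible(path)
}
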