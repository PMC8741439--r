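#' Read a BED file of genomic intervals
#'
#' Minimal native BED3+/BED6 reader: 0-based half-open input coordinates are
#' converted to the 1-based closed convention of [GenomicRanges::GRanges].
#'
#' @param path BED file (tab-separated, no header; track/browser lines
#'   ignored).
#' @return a `GRanges` with names from column 4 when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) stop_("empty BED file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) stop_("BED record with fewer than 3 fields (line %d)", which(ncols < 3L)[1])
  chrom <- vapply(parts, `[`, character(1), 1L)
  start0 <- as.numeric(vapply(parts, `[`, character(1), 2L))
  end0 <- as.numeric(vapply(parts, `[`, character(1), 3L))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0)
  if (length(bad))
    stop_("malformed interval at BED line %d: %s", bad[1], lines[bad[1]])
  nm <- ifelse(ncols >= 4L, vapply(parts, function(p) p[4] %||% NA_character_, character(1)),
               NA_character_)
  strand <- ifelse(ncols >= 6L, vapply(parts, function(p) p[6] %||% "*", character(1)), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = strand)
  if (!all(is.na(nm))) names(gr) <- nm
  gr
}

#' Read promoter sequences from FASTA
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

as_dna_set <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) return(sequences)
  if (is.character(sequences) && length(sequences) == 1L && file.exists(sequences))
    return(read_fasta(sequences))
  if (is.character(sequences)) {
    if (is.null(names(sequences)))
      names(sequences) <- paste0("seq", seq_along(sequences))
    return(Biostrings::DNAStringSet(sequences))
  }
  stop_("sequences must be a DNAStringSet, a named character vector, or a FASTA path")
}

#' Scan sequences for an exact DNA motif
#'
#' Reports every (possibly overlapping) occurrence of the motif on the plus
#' strand and, optionally, occurrences of its reverse complement (reported on
#' the minus strand at their plus-strand coordinates). Positions are 0-based
#' offsets. The default motif is the CHR (cell-cycle genes homology region)
#' element bound by MuvB/DREAM complexes.
#'
#' @param sequences a [Biostrings::DNAStringSet], named character vector, or
#'   FASTA path; matched case-insensitively.
#' @param motif DNA motif over A/C/G/T (default `"TTTGAA"`).
#' @param both_strands also report reverse-complement occurrences.
#' @return data.frame `sequence_id, position, strand, matched` sorted by
#'   sequence, position, strand.
#' @export
scan_motif <- function(sequences, motif = "TTTGAA", both_strands = FALSE) {
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif))
    stop_("motif must be a non-empty string over A/C/G/T, got '%s'", motif)
  seqs <- as_dna_set(sequences)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))

  one_strand <- function(pattern, strand, matched) {
    hits <- lapply(seq_along(seqs), function(i) {
      m <- Biostrings::matchPattern(pattern, seqs[[i]])
      if (length(m) == 0L) return(NULL)
      data.frame(sequence_id = ids[i], position = Biostrings::start(m) - 1L,
                 strand = strand, matched = matched, stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  }
  out <- one_strand(motif, "+", motif)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    if (rc != motif) out <- rbind(out, one_strand(rc, "-", rc))
    else {
      minus <- one_strand(motif, "-", motif)   # palindromic motif
      out <- rbind(out, minus)
    }
  }
  if (is.null(out))
    return(data.frame(sequence_id = character(), position = integer(),
                      strand = character(), matched = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$sequence_id, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag genes whose TSS window contains a peak
#'
#' Windows are `[max(0, TSS - window), TSS + window)` in 0-based half-open
#' coordinates around each 1-bp transcription start site; a gene is flagged
#' when any peak on the same chromosome intersects its window (strand
#' ignored).
#'
#' @param tss `GRanges` of 1-bp TSS records (or a BED path); names are gene
#'   ids.
#' @param peaks `GRanges` of peak intervals (or a BED path).
#' @param window half-width in bp (default 5000).
#' @return data.frame `gene, hit, peaks` (semicolon-joined peak names).
#' @export
tss_window_overlap <- function(tss, peaks, window = 5000) {
  if (is.character(tss)) tss <- read_bed(tss)
  if (is.character(peaks)) peaks <- read_bed(peaks)
  if (any(GenomicRanges::width(tss) != 1L))
    stop_("TSS records must be 1-bp intervals")
  genes <- names(tss) %||% paste0("tss", seq_along(tss))
  pos0 <- GenomicRanges::start(tss) - 1L              # 0-based TSS position
  win_start0 <- pmax(0L, pos0 - window)
  win_end0 <- pos0 + window                           # half-open end
  windows <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(start = win_start0 + 1L, end = win_end0))
  ov <- GenomicRanges::findOverlaps(windows, peaks, ignore.strand = TRUE)
  pk_names <- names(peaks) %||% paste0("peak", seq_along(peaks))
  hit_peaks <- vapply(seq_along(tss), function(i) {
    j <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    paste(pk_names[j], collapse = ";")
  }, character(1))
  data.frame(gene = genes, hit = hit_peaks != "", peaks = hit_peaks,
             stringsAsFactors = FALSE)
}
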