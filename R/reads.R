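# Aligned reads and pileup-window extraction from BAM files or in-memory
# read sets.

#' Construct an aligned read
#'
#' Minimal representation of one aligned sequencing read: the reference
#' positions of its aligned bases (gaps allowed), the base calls and their
#' phred qualities, the mapping quality and the strand flag. When a CIGAR
#' string is supplied, aligned pairs are derived from it: M/=/X consume both
#' read and reference, insertions and soft clips consume the read only,
#' deletions and skips consume the reference only.
#'
#' @param qname read name (used as a stable tie-break when ordering pileups)
#' @param chrom reference sequence name
#' @param start 0-based leftmost aligned reference position
#' @param bases character vector (or single string) of base calls, including
#'   any soft-clipped bases when a CIGAR is given
#' @param quals integer phred base qualities, same length as `bases`
#' @param mapq phred-scaled mapping quality (>= 0)
#' @param is_reverse logical strand flag
#' @param cigar optional CIGAR string; `NULL` means fully aligned
#'   (`<length>M`)
#' @return object of class `aligned_read` with fields `ref_pos` (0-based
#'   reference position of each aligned base), `bases`, `quals` (aligned
#'   subset), `mapq`, `is_reverse`, `span` (half-open reference interval)
#' @export
aligned_read <- function(qname, chrom, start, bases, quals, mapq,
                         is_reverse = FALSE, cigar = NULL) {
  if (length(bases) == 1 && nchar(bases[1]) > 1)
    bases <- strsplit(bases, "")[[1]]
  bases <- toupper(bases)
  if (length(quals) != length(bases))
    stop_data("base_quals must have the same length as bases")
  if (mapq < 0) stop_data("map_qual must be >= 0")
  n <- length(bases)
  if (is.null(cigar)) {
    ref_pos <- start + seq_len(n) - 1L
    qidx <- seq_len(n)
    span_end <- start + n
  } else {
    ap <- cigar_aligned_pairs(cigar, start)
    if (ap$qlen != n)
      stop_data("CIGAR query length (", ap$qlen, ") does not match ",
                n, " bases")
    ref_pos <- ap$ref_pos
    qidx <- ap$query_idx
    span_end <- ap$span_end
  }
  structure(list(qname = as.character(qname), chrom = as.character(chrom),
                 start = as.integer(start), ref_pos = as.integer(ref_pos),
                 bases = bases[qidx], quals = as.integer(quals[qidx]),
                 mapq = as.integer(mapq), is_reverse = isTRUE(is_reverse),
                 span = c(as.integer(start), as.integer(span_end)),
                 cigar = cigar %||% paste0(n, "M")),
            class = "aligned_read")
}

# CIGAR -> (reference position, query index) pairs for aligned bases;
# positions are 0-based, query indices 1-based into the full SEQ field
cigar_aligned_pairs <- function(cigar, start) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0 || sum(nchar(toks)) != nchar(cigar))
    stop_data("malformed CIGAR: ", cigar)
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- substr(toks, nchar(toks), nchar(toks))
  ref <- start
  q <- 1L
  ref_pos <- integer(0)
  qidx <- integer(0)
  qlen <- 0L
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, ref + seq_len(len) - 1L)
      qidx <- c(qidx, q + seq_len(len) - 1L)
      ref <- ref + len; q <- q + len; qlen <- qlen + len
    } else if (op %in% c("I", "S")) {
      q <- q + len; qlen <- qlen + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    }  # H, P consume nothing in SEQ
  }
  list(ref_pos = ref_pos, query_idx = qidx, span_end = ref, qlen = qlen)
}

#' In-memory alignment source
#'
#' Wraps a list of [aligned_read()] objects so they can be queried with
#' [extract_window()] exactly like an indexed BAM file. Used by the pileup
#' simulator and in tests.
#'
#' @param reads list of aligned reads (may span several chromosomes)
#' @return object of class `read_set`
#' @export
read_set <- function(reads) {
  stopifnot(all(vapply(reads, inherits, logical(1), "aligned_read")))
  structure(list(reads = reads,
                 chroms = unique(vapply(reads, `[[`, character(1), "chrom"))),
            class = "read_set")
}

#' BAM alignment source
#'
#' @param path coordinate-sorted, indexed BAM file
#' @param index index file (defaults to `<path>.bai`)
#' @return object of class `bam_source`
#' @export
bam_source <- function(path, index = paste0(path, ".bai")) {
  if (!file.exists(path)) stop_usage("BAM not found: ", path)
  if (!file.exists(index)) stop_usage("BAM index not found: ", index)
  structure(list(path = path, index = index), class = "bam_source")
}

# half-open 0-based window bounds around a candidate site
window_bounds <- function(site, config) {
  half <- (config$d_window - 1L) %/% 2L
  pos0 <- site$pos - 1L
  list(start0 = pos0 - half, end0 = pos0 + half + 1L, half = half)
}

#' Extract the read window around a candidate site
#'
#' Returns every read whose alignment span overlaps the symmetric window of
#' `d_window` bases centred on the candidate locus, truncated to `d_reads`
#' reads. Reads are ordered the way a reviewer sorts a genome-viewer pileup
#' when inspecting a candidate: reads supporting the alternative allele
#' first, then reads with another mismatch at the locus, then
#' reference-matching reads, then reads not covering the locus; ties are
#' broken by ascending alignment start and then read name, so the order is
#' deterministic. Grouping allele support into contiguous row blocks makes
#' the allele fraction visible as a spatial extent, and guarantees that
#' truncation to `d_reads` never discards variant evidence first.
#'
#' @param source a [bam_source()] or [read_set()]
#' @param site a [candidate_site()]
#' @param config an [encoding_config()]
#' @return list of [aligned_read()] (possibly empty)
#' @export
extract_window <- function(source, site, config = encoding_config()) {
  UseMethod("extract_window")
}

# base carried by the read at the candidate locus, NA if not covered
base_at_locus <- function(read, pos0) {
  k <- match(pos0, read$ref_pos)
  if (is.na(k)) NA_character_ else read$bases[k]
}

order_and_truncate <- function(reads, site, d_reads) {
  if (length(reads) == 0) return(reads)
  pos0 <- site$pos - 1L
  at <- vapply(reads, base_at_locus, character(1), pos0 = pos0)
  group <- ifelse(is.na(at), 3L,
                  ifelse(at == site$alt_base, 0L,
                         ifelse(at == site$ref_base, 2L, 1L)))
  starts <- vapply(reads, `[[`, integer(1), "start")
  names_ <- vapply(reads, `[[`, character(1), "qname")
  reads <- reads[order(group, starts, names_, method = "radix")]
  head(reads, d_reads)
}

#' @export
extract_window.read_set <- function(source, site, config = encoding_config()) {
  if (length(source$reads) == 0) return(list())  # empty source: empty pileup
  if (!site$chrom %in% source$chroms)
    stop_data("chromosome '", site$chrom, "' not present in read set")
  wb <- window_bounds(site, config)
  keep <- vapply(source$reads, function(r) {
    r$chrom == site$chrom && r$span[1] < wb$end0 && r$span[2] > wb$start0
  }, logical(1))
  order_and_truncate(source$reads[keep], site, config$d_reads)
}

#' @export
extract_window.bam_source <- function(source, site, config = encoding_config()) {
  hdr <- Rsamtools::scanBamHeader(source$path)[[1]]$targets
  if (!site$chrom %in% names(hdr))
    stop_data("chromosome '", site$chrom, "' not present in BAM ",
              source$path)
  wb <- window_bounds(site, config)
  gr <- GenomicRanges::GRanges(site$chrom,
                               IRanges::IRanges(max(1L, wb$start0 + 1L),
                                                wb$end0))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(source$path, index = source$index,
                            param = param)[[1]]
  n <- length(res$pos)
  if (n == 0) return(list())
  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  reads <- lapply(seq_len(n), function(i) {
    aligned_read(qname = res$qname[i], chrom = site$chrom,
                 start = res$pos[i] - 1L,
                 bases = seqs[i],
                 quals = utf8ToInt(quals[i]) - 33L,
                 mapq = ifelse(is.na(res$mapq[i]), 0L, res$mapq[i]),
                 is_reverse = bitwAnd(res$flag[i], 16L) > 0L,
                 cigar = res$cigar[i])
  })
  # re-check precise overlap with the window (scanBam already queried it,
  # but deletions can make spans differ from SEQ length)
  keep <- vapply(reads, function(r) {
    r$span[1] < wb$end0 && r$span[2] > wb$start0
  }, logical(1))
  order_and_truncate(reads[keep], site, config$d_reads)
}
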