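# Interval helpers shared by all modules.
#
# Public data frames carry BED-style 0-based half-open coordinates in
# columns chrom/start/end/strand; GRanges (1-based closed) only lives
# inside these helpers.

#' Convert a BED-style data frame to a GRanges
#' @param df data frame with chrom, start, end, strand columns
#'   (0-based, half-open)
#' @return a GRanges (1-based, closed)
#' @keywords internal
#' @noRd
.as_gr <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = as.character(df$strand)
  )
}

#' Convert a GRanges back to a BED-style data frame
#' @keywords internal
#' @noRd
.as_bed_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' 5'-most genomic position of each read (0-based)
#'
#' On the plus strand this is the read start; on the minus strand the
#' last covered base, end - 1.
#' @keywords internal
#' @noRd
.five_prime_pos <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' GRanges of width-1 read 5' start positions, strand kept
#' @keywords internal
#' @noRd
.start_gr <- function(reads) {
  if (nrow(reads) == 0) {
    return(GenomicRanges::GRanges())
  }
  pos <- .five_prime_pos(reads)
  GenomicRanges::GRanges(
    seqnames = as.character(reads$chrom),
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L),
    strand = as.character(reads$strand)
  )
}

#' Basic validation of a BED-style interval data frame
#' @keywords internal
#' @noRd
.check_intervals <- function(df, what = "intervals",
                             strands = c("+", "-")) {
  req <- c("chrom", "start", "end", "strand")
  missing_cols <- req[!req %in% names(df)]
  if (length(missing_cols) > 0) {
    stop(what, ": missing columns ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 0) {
    if (any(is.na(df$start)) || any(is.na(df$end)) ||
        any(df$end <= df$start)) {
      stop(what, ": every interval must satisfy end > start")
    }
    if (!all(df$strand %in% strands)) {
      stop(what, ": strand must be one of ",
           paste(strands, collapse = "/"))
    }
  }
  invisible(df)
}

#' Per-interval read-start counts, by sample
#'
#' Counts, for every interval row, the number of same-strand read 5'
#' starts falling inside it. Intervals need not be disjoint; each read
#' start is counted in every interval containing it.
#'
#' @param reads data frame with chrom/start/end/strand/sample
#' @param intervals BED-style data frame
#' @param samples character vector of sample labels defining the count
#'   columns; defaults to the sorted labels present in `reads`
#' @param ignore_strand count starts regardless of strand
#' @return integer matrix, one row per interval, one column per sample
#' @keywords internal
#' @noRd
.start_counts <- function(reads, intervals, samples = NULL,
                          ignore_strand = FALSE) {
  if (is.null(samples)) {
    samples <- sort(unique(as.character(reads$sample)))
  }
  out <- matrix(0L, nrow = nrow(intervals), ncol = length(samples),
                dimnames = list(NULL, samples))
  if (nrow(reads) == 0 || nrow(intervals) == 0) {
    return(out)
  }
  hits <- GenomicRanges::findOverlaps(.start_gr(reads), .as_gr(intervals),
                                      ignore.strand = ignore_strand)
  if (length(hits) == 0) {
    return(out)
  }
  smp <- factor(as.character(reads$sample)[S4Vectors::queryHits(hits)],
                levels = samples)
  keep <- !is.na(smp)
  tab <- table(
    interval = factor(S4Vectors::subjectHits(hits)[keep],
                      levels = seq_len(nrow(intervals))),
    sample = smp[keep]
  )
  out[, ] <- as.integer(tab)
  out
}

#' Index of the unique interval containing each read start (NA if none)
#' @keywords internal
#' @noRd
.start_assignment <- function(reads, intervals, ignore_strand = FALSE) {
  idx <- rep(NA_integer_, nrow(reads))
  if (nrow(reads) == 0 || nrow(intervals) == 0) {
    return(idx)
  }
  hits <- GenomicRanges::findOverlaps(.start_gr(reads), .as_gr(intervals),
                                      ignore.strand = ignore_strand)
  idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  idx
}
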