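# Discovery of unannotated transcription: TAR refinement by windowed
# read-density segmentation, per-sample TAR quantification, UTR
# extension windows, and ORF scanning.

#' Refine unannotated regions into transcriptionally active regions
#'
#' Each intronic/intergenic region is tiled with non-overlapping
#' windows of width `W` anchored at the region start (the final window
#' is truncated at the region end). Windows containing at least `T`
#' pooled read 5' starts qualify; maximal runs of adjacent qualifying
#' windows are merged into one TAR whose boundaries are trimmed to the
#' outermost read starts inside the run. TARs inherit the strand and
#' kind of their parent region (inR -> inTAR, igR -> igTAR). Reads
#' should be pooled across both samples.
#'
#' @param reads pooled read data frame
#' @param regions region data frame (from
#'   [derive_nonannotated_regions()] or [apply_annotation_masks()])
#' @param W window width in nt (default 500)
#' @param T minimum read starts per window (default 30)
#' @return data frame `tar_id`, `chrom`, `start`, `end`, `strand`,
#'   `kind` ("inTAR"/"igTAR"), `parent_region_id`, `host_locus_id`,
#'   `pooled_count`
#' @export
refine_tars <- function(reads, regions, W = 500, T = 30) {
  if (W <= 0 || T <= 0) stop("W and T must be positive")
  empty <- data.frame(
    tar_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), kind = character(0),
    parent_region_id = character(0), host_locus_id = character(0),
    pooled_count = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(reads) == 0 || nrow(regions) == 0) return(empty)

  hits <- GenomicRanges::findOverlaps(.start_gr(reads), .as_gr(regions))
  if (length(hits) == 0) return(empty)
  ri <- S4Vectors::subjectHits(hits)
  pos <- .five_prime_pos(reads)[S4Vectors::queryHits(hits)]
  dt <- data.table::data.table(
    region = ri,
    win = (pos - regions$start[ri]) %/% as.integer(W),
    pos = pos
  )
  wins <- dt[, list(n = .N, lo = min(pos), hi = max(pos)),
             by = c("region", "win")]
  wins <- wins[wins$n >= T, ]
  if (nrow(wins) == 0) return(empty)
  data.table::setkey(wins, region, win)
  # run id: adjacent qualifying windows share a run
  wins[, run := cumsum(c(1L, diff(win) != 1L)), by = "region"]
  tars <- wins[, list(start = min(lo), end = max(hi) + 1L,
                      pooled_count = sum(n)),
               by = c("region", "run")]
  out <- data.frame(
    chrom = regions$chrom[tars$region],
    start = tars$start, end = tars$end,
    strand = regions$strand[tars$region],
    kind = ifelse(regions$kind[tars$region] == "inR", "inTAR", "igTAR"),
    parent_region_id = regions$region_id[tars$region],
    host_locus_id = regions$host_locus_id[tars$region],
    pooled_count = as.integer(tars$pooled_count),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$tar_id <- sprintf("TAR%06d", seq_len(nrow(out)))
  out[, c("tar_id", "chrom", "start", "end", "strand", "kind",
          "parent_region_id", "host_locus_id", "pooled_count")]
}

#' Quantify TARs per sample and flag activity
#'
#' Per-sample counts are same-strand read 5' starts inside the TAR; a
#' TAR is active in a sample when its count reaches `min_active`
#' (default 1 read). TARs active in exactly one sample are
#' sample-specific.
#'
#' @param reads per-sample read data frame
#' @param tars output of [refine_tars()]
#' @param samples length-2 sample label vector
#' @param min_active minimum per-sample count for activity
#' @return `tars` with `count_<sample>` and `active_<sample>` columns
#'   and a `status` column (`common`, `<sample>_specific`, `inactive`)
#' @export
quantify_tars <- function(reads, tars, samples = NULL, min_active = 1) {
  if (is.null(samples)) {
    samples <- sort(unique(as.character(reads$sample)))
  }
  cnt <- .start_counts(reads, tars, samples = samples)
  out <- tars
  for (s in samples) {
    out[[paste0("count_", s)]] <- cnt[, s]
    out[[paste0("active_", s)]] <- cnt[, s] >= min_active
  }
  if (length(samples) == 2) {
    a <- out[[paste0("active_", samples[1])]]
    b <- out[[paste0("active_", samples[2])]]
    out$status <- ifelse(a & b, "common",
                  ifelse(a, paste0(samples[1], "_specific"),
                  ifelse(b, paste0(samples[2], "_specific"),
                         "inactive")))
  }
  out
}

#' Detect UTR extensions in fixed windows flanking gene ends
#'
#' For each locus a 3' window of `window` nt is placed immediately
#' downstream of the annotated 3' end and a 5' window immediately
#' upstream of the annotated 5' end (strand-oriented). A call is
#' emitted per side per sample when the window contains at least
#' `min_reads` same-strand read 5' starts; calls present in both
#' samples are `common`, calls with no call on the other side are
#' sample-specific.
#'
#' @param reads per-sample read data frame
#' @param revised a `revised_annotation` (its loci supply the outermost
#'   annotated ends)
#' @param chrom_sizes optional named vector; windows beyond chromosome
#'   bounds are clipped
#' @param window window length in nt (default 150)
#' @param min_reads minimum same-strand read starts for a call
#'   (default 5)
#' @param samples length-2 sample label vector
#' @return data frame of windows with at least one call: `locus_id`,
#'   `side` ("5p"/"3p"), coordinates, `count_<sample>`,
#'   `called_<sample>`, `status`
#' @export
detect_utr_extensions <- function(reads, revised, chrom_sizes = NULL,
                                  window = 150, min_reads = 5,
                                  samples = NULL) {
  stopifnot(inherits(revised, "revised_annotation"))
  if (is.null(samples)) {
    samples <- sort(unique(as.character(reads$sample)))
  }
  loci <- revised$loci
  if (nrow(loci) == 0) {
    return(data.frame())
  }
  plus <- loci$strand == "+"
  win3 <- data.frame(
    locus_id = loci$locus_id, side = "3p", chrom = loci$chrom,
    start = ifelse(plus, loci$end, loci$start - window),
    end = ifelse(plus, loci$end + window, loci$start),
    strand = loci$strand, stringsAsFactors = FALSE
  )
  win5 <- data.frame(
    locus_id = loci$locus_id, side = "5p", chrom = loci$chrom,
    start = ifelse(plus, loci$start - window, loci$end),
    end = ifelse(plus, loci$start, loci$end + window),
    strand = loci$strand, stringsAsFactors = FALSE
  )
  win <- rbind(win3, win5)
  win$start <- pmax(win$start, 0L)
  if (!is.null(chrom_sizes)) {
    win$end <- pmin(win$end, as.integer(chrom_sizes[win$chrom]))
  }
  win <- win[win$end > win$start, , drop = FALSE]
  cnt <- .start_counts(reads, win, samples = samples)
  for (s in samples) {
    win[[paste0("count_", s)]] <- cnt[, s]
    win[[paste0("called_", s)]] <- cnt[, s] >= min_reads
  }
  called <- cnt >= min_reads
  win <- win[rowSums(called) > 0, , drop = FALSE]
  called <- called[rowSums(called) > 0, , drop = FALSE]
  if (length(samples) == 2 && nrow(win) > 0) {
    a <- called[, samples[1]]
    b <- called[, samples[2]]
    win$status <- ifelse(a & b, "common",
                  ifelse(a, paste0(samples[1], "_specific"),
                         paste0(samples[2], "_specific")))
  } else if (nrow(win) > 0) {
    win$status <- NA_character_
  }
  rownames(win) <- NULL
  win
}

#' Scan TAR sequences for open reading frames
#'
#' Reports ORFs (start codon through in-frame stop codon, length
#' counted inclusive of the stop) of at least `min_orf` nt. Intronic
#' TARs are scanned in the three frames of their host strand — an
#' intronic ORF in frame with the host coding sequence suggests an
#' unannotated alternative exon; intergenic TARs are scanned on both
#' strands (six frames).
#'
#' @param tars TAR data frame
#' @param genome named character vector or `Biostrings::DNAStringSet`
#'   of chromosome sequences
#' @param min_orf minimum ORF length in nt (default 200)
#' @param host_frames optional data frame (`locus_id`, `anchor`) giving
#'   a genomic coordinate at which a host codon starts, used to flag
#'   frame consistency of intronic ORFs
#' @return data frame `tar_id`, `strand`, `frame`, `start`, `end`
#'   (0-based half-open, relative to the TAR on the forward genomic
#'   axis), `length`, `frame_consistent_with_host`; TARs whose
#'   chromosome sequence is missing are reported in the `errors`
#'   attribute
#' @export
scan_orfs <- function(tars, genome, min_orf = 200, host_frames = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  res <- list()
  errors <- character(0)
  for (i in seq_len(nrow(tars))) {
    chrom <- tars$chrom[i]
    if (!chrom %in% names(genome)) {
      errors <- c(errors, sprintf("%s: no sequence for %s",
                                  tars$tar_id[i], chrom))
      next
    }
    seq <- substr(genome[[chrom]], tars$start[i] + 1L, tars$end[i])
    strands <- if (tars$kind[i] == "inTAR") tars$strand[i] else c("+", "-")
    for (st in strands) {
      orfs <- .find_orfs(seq, st, min_orf)
      if (nrow(orfs) == 0) next
      orfs$tar_id <- tars$tar_id[i]
      orfs$strand <- st
      orfs$frame_consistent_with_host <- NA
      if (tars$kind[i] == "inTAR" && !is.null(host_frames)) {
        anchor <- host_frames$anchor[
          match(tars$host_locus_id[i], host_frames$locus_id)]
        if (!is.na(anchor)) {
          gpos <- if (st == "+") tars$start[i] + orfs$start
                  else tars$start[i] + orfs$end
          orfs$frame_consistent_with_host <- (gpos - anchor) %% 3 == 0
        }
      }
      res[[length(res) + 1]] <- orfs
    }
  }
  out <- if (length(res) > 0) {
    do.call(rbind, res)[, c("tar_id", "strand", "frame", "start", "end",
                            "length", "frame_consistent_with_host")]
  } else {
    data.frame(tar_id = character(0), strand = character(0),
               frame = integer(0), start = integer(0), end = integer(0),
               length = integer(0),
               frame_consistent_with_host = logical(0),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

# ORFs in one strand of a sequence; coordinates returned on the forward
# axis of the input sequence, 0-based half-open
.find_orfs <- function(seq, strand, min_orf) {
  n <- nchar(seq)
  s <- toupper(seq)
  if (strand == "-") {
    s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  out <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2) next
    codons <- substring(s, frame + 3 * (seq_len(ncod) - 1) + 1,
                        frame + 3 * seq_len(ncod))
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open_at <- NA_integer_
    for (k in seq_len(ncod)) {
      if (is.na(open_at) && is_start[k]) open_at <- k
      if (!is.na(open_at) && is_stop[k]) {
        len <- (k - open_at + 1L) * 3L
        if (len >= min_orf) {
          rel_start <- frame + 3L * (open_at - 1L)
          rel_end <- frame + 3L * k
          if (strand == "-") {
            tmp <- rel_start
            rel_start <- n - rel_end
            rel_end <- n - tmp
          }
          out[[length(out) + 1]] <- data.frame(
            frame = frame, start = rel_start, end = rel_end,
            length = len, stringsAsFactors = FALSE
          )
        }
        open_at <- NA_integer_
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  }
  do.call(rbind, out)
}

#' Drop TARs overlapping a repeat mask
#'
#' Expression estimates inside repeated elements are unreliable in a
#' uniquely-assigned-read framework; this optional filter removes TARs
#' whose interval is covered by repeats at or above `max_frac`.
#'
#' @param tars TAR data frame
#' @param repeat_mask BED-style data frame of repeat intervals
#'   (strand-agnostic)
#' @param max_frac maximum tolerated repeat-covered fraction
#'   (default 0.5)
#' @return filtered TAR data frame
#' @export
filter_tars_by_repeats <- function(tars, repeat_mask, max_frac = 0.5) {
  if (nrow(tars) == 0 || is.null(repeat_mask) ||
      nrow(repeat_mask) == 0) {
    return(tars)
  }
  rm_df <- repeat_mask
  rm_df$strand <- "*"
  tg <- .as_gr(tars)
  cov <- GenomicRanges::intersect(
    tg, GenomicRanges::reduce(.as_gr(rm_df), ignore.strand = TRUE),
    ignore.strand = TRUE
  )
  hits <- GenomicRanges::findOverlaps(tg, cov, ignore.strand = TRUE)
  olap <- GenomicRanges::width(GenomicRanges::pintersect(
    tg[S4Vectors::queryHits(hits)], cov[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  frac <- rep(0, nrow(tars))
  covered <- tapply(olap, S4Vectors::queryHits(hits), sum)
  frac[as.integer(names(covered))] <- covered
  frac <- frac / (tars$end - tars$start)
  tars[frac < max_frac, , drop = FALSE]
}
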