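# Readers and writers for the pipeline's interchange formats: BED,
# GTF/BED12 gene models, chrom.sizes, TSV and bedGraph custom tracks.

#' Read a two-column chrom.sizes file
#' @param path text file: chromosome name, length
#' @return named integer vector
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$size), df$chrom)
}

#' Read a BED6 file into a 0-based data frame
#' @param path BED file (3 to 6 columns)
#' @return data frame chrom/start/end/name/score/strand
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  df <- utils::read.table(text = lines, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  if (!"strand" %in% names(df)) df$strand <- "*"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write a BED6 file (0-based, native coordinates)
#' @param df data frame with chrom/start/end and optionally
#'   name/score/strand
#' @param path output path
#' @param track_name optional custom-track name; written as a
#'   `track` header line for genome-browser loading
#' @return `path`, invisibly
#' @export
write_bed6 <- function(df, path, track_name = NULL) {
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name)) {
    writeLines(sprintf('track name="%s" type=bed', track_name), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV with a header
#' @param df data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path
#' @return data frame
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read gene models from GTF or BED12
#'
#' GTF exon records are grouped by `gene_id`/`transcript_id`; BED12
#' blocks become exons named by the BED name field. Coordinates are
#' returned 0-based half-open.
#'
#' @param path annotation file
#' @param format "gtf" or "bed12" (guessed from the extension by
#'   default)
#' @return exon data frame suitable for [revise_annotation()]
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    mc <- GenomicRanges::mcols(gr)
    tx <- if ("transcript_id" %in% names(mc)) mc$transcript_id
          else mc$gene_id
    data.frame(
      gene_id = mc$gene_id, transcript_id = tx,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    blocks <- if (!is.null(gr$blocks)) {
      GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) {
        b <- gr$blocks[[i]]
        GenomicRanges::GRanges(
          GenomicRanges::seqnames(gr)[i],
          IRanges::shift(b, GenomicRanges::start(gr)[i] - 1L),
          strand = GenomicRanges::strand(gr)[i])
      }))
    } else {
      GenomicRanges::GRangesList(as.list(GenomicRanges::split(
        gr, seq_along(gr))))
    }
    names(blocks) <- gr$name
    flat <- unlist(blocks)
    data.frame(
      gene_id = names(flat), transcript_id = names(flat),
      chrom = as.character(GenomicRanges::seqnames(flat)),
      start = GenomicRanges::start(flat) - 1L,
      end = GenomicRanges::end(flat),
      strand = as.character(GenomicRanges::strand(flat)),
      stringsAsFactors = FALSE
    )
  }
}

#' Export strand-specific bedGraph coverage tracks
#'
#' Writes one bedGraph custom track per sample and strand from the
#' full read intervals (per-base pileup), plus BED tracks for TARs,
#' UTR-extension calls and sample-specific junctions when supplied.
#' Zero-coverage runs are omitted, so an empty read set yields a valid
#' header-only bedGraph.
#'
#' @param reads read data frame
#' @param out_dir output directory (created if needed)
#' @param tars optional TAR data frame
#' @param utr_calls optional UTR call data frame
#' @param junctions optional sample-specific junction records
#' @param samples sample labels
#' @return character vector of files written, invisibly
#' @export
export_tracks <- function(reads, out_dir, tars = NULL, utr_calls = NULL,
                          junctions = NULL, samples = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(samples)) {
    samples <- sort(unique(as.character(reads$sample)))
  }
  files <- character(0)
  for (s in samples) {
    for (st in c("+", "-")) {
      sel <- reads[reads$sample == s & reads$strand == st, ,
                   drop = FALSE]
      tag <- if (st == "+") "plus" else "minus"
      path <- file.path(out_dir,
                        sprintf("coverage_%s_%s.bedGraph", s, tag))
      con <- file(path, "w")
      writeLines(sprintf(
        'track type=bedGraph name="%s %s strand coverage"', s, st), con)
      if (nrow(sel) > 0) {
        cov <- GenomicRanges::coverage(.as_gr(sel))
        for (chrom in names(cov)) {
          rle <- cov[[chrom]]
          ends <- cumsum(S4Vectors::runLength(rle))
          starts <- c(0L, ends[-length(ends)])
          vals <- S4Vectors::runValue(rle)
          keep <- vals > 0
          if (any(keep)) {
            utils::write.table(
              data.frame(chrom, starts[keep], ends[keep], vals[keep]),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
          }
        }
      }
      close(con)
      files <- c(files, path)
    }
  }
  if (!is.null(tars) && nrow(tars) > 0) {
    path <- file.path(out_dir, "tars.bed")
    write_bed6(data.frame(chrom = tars$chrom, start = tars$start,
                          end = tars$end, name = tars$tar_id,
                          score = tars$pooled_count,
                          strand = tars$strand),
               path, track_name = "TARs")
    files <- c(files, path)
  }
  if (!is.null(utr_calls) && nrow(utr_calls) > 0) {
    path <- file.path(out_dir, "utr_extensions.bed")
    write_bed6(data.frame(chrom = utr_calls$chrom,
                          start = utr_calls$start, end = utr_calls$end,
                          name = paste0(utr_calls$locus_id, "_",
                                        utr_calls$side),
                          score = 0, strand = utr_calls$strand),
               path, track_name = "UTR extensions")
    files <- c(files, path)
  }
  if (!is.null(junctions) && nrow(junctions) > 0) {
    g <- .junction_genomic(junctions$strand, junctions$donor_end,
                           junctions$acceptor_start)
    path <- file.path(out_dir, "sample_specific_junctions.bed")
    write_bed6(data.frame(chrom = junctions$chrom, start = g$left_end,
                          end = g$right_start,
                          name = junctions$junction_id, score = 0,
                          strand = junctions$strand),
               path, track_name = "sample-specific junctions")
    files <- c(files, path)
  }
  invisible(files)
}
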