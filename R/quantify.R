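# Read counting by 5' start, junction augmentation, RPKM, expression
# categories, per-chromosome dosage ratios and the snoRNA host-gene
# cross-table.

#' Count uniquely assigned reads into annotation elements
#'
#' A read is assigned to the unique same-strand element containing its
#' 5'-most genomic position (the start on the plus strand, end - 1 on
#' the minus strand). Reads whose 5' start falls in no element are
#' returned as the unassigned pool, for intronic/intergenic accounting.
#'
#' @param reads data frame with `chrom`, `start`, `end`, `strand`,
#'   `sample`
#' @param elements element data frame from [revise_annotation()]
#'   (non-overlapping per strand)
#' @param samples sample labels defining the count columns; defaults to
#'   sorted labels present in `reads`
#' @return list with `counts` (elements plus one `count_<sample>`
#'   column per sample) and `unassigned` (rows of `reads`)
#' @export
count_reads_by_start <- function(reads, elements, samples = NULL) {
  .check_intervals(reads, "reads")
  if (is.null(samples)) {
    samples <- sort(unique(as.character(reads$sample)))
  }
  cnt <- .start_counts(reads, elements, samples = samples)
  counts <- elements
  for (s in samples) {
    counts[[paste0("count_", s)]] <- cnt[, s]
  }
  idx <- .start_assignment(reads, elements)
  list(counts = counts,
       unassigned = reads[is.na(idx), , drop = FALSE])
}

#' Locus expression with junction augmentation
#'
#' Sums element read counts per locus, adds the counts of the locus's
#' junctions, computes RPKM on the gene-model length and classifies
#' expression, for each sample independently.
#'
#' @param revised a `revised_annotation`
#' @param element_counts `counts` component of [count_reads_by_start()]
#' @param junction_records junction count data frame (from
#'   [count_junctions()], or NULL for none); every junction must
#'   resolve to a library locus
#' @param library junction library from [build_junction_library()]
#' @param lib_sizes named numeric vector of per-sample library sizes
#'   (total mapped reads, genome plus junctions)
#' @param rpkm_threshold detection threshold; a locus is detected when
#'   RPKM is strictly greater than it
#' @param category_mode "decade" (fixed decade bins) or "quantile"
#' @param samples sample labels; defaults to names of `lib_sizes`
#' @return long data frame: `locus_id`, `sample`, `raw_count`,
#'   `junction_count`, `total_count`, `model_length`, `rpkm`,
#'   `detected`, `category`
#' @export
locus_expression <- function(revised, element_counts,
                             junction_records = NULL, library = NULL,
                             lib_sizes, rpkm_threshold = 0.1,
                             category_mode = c("decade", "quantile"),
                             samples = NULL) {
  stopifnot(inherits(revised, "revised_annotation"))
  category_mode <- match.arg(category_mode)
  if (is.null(samples)) samples <- names(lib_sizes)
  loci <- revised$loci
  out <- list()
  for (s in samples) {
    col <- paste0("count_", s)
    raw <- tapply(element_counts[[col]], element_counts$locus_id, sum)
    raw_count <- as.integer(raw[loci$locus_id])
    raw_count[is.na(raw_count)] <- 0L
    junction_count <- rep(0L, nrow(loci))
    if (!is.null(junction_records) && nrow(junction_records) > 0) {
      if (is.null(library)) {
        stop("junction records supplied without a junction library")
      }
      jk <- .junction_key(junction_records)
      lk <- .junction_key(library)
      m <- match(jk, lk)
      if (anyNA(m)) {
        stop("junction key not present in the junction library: ",
             jk[which(is.na(m))[1]])
      }
      jl <- library$locus_id[m]
      jc <- tapply(junction_records[[col]], jl, sum)
      hit <- match(loci$locus_id, names(jc))
      junction_count <- ifelse(is.na(hit), 0L, as.integer(jc[hit]))
    }
    total <- raw_count + junction_count
    rpkm <- compute_rpkm(total, loci$model_length, lib_sizes[[s]])
    out[[s]] <- data.frame(
      locus_id = loci$locus_id, sample = s, raw_count = raw_count,
      junction_count = junction_count, total_count = total,
      model_length = loci$model_length, rpkm = rpkm,
      stringsAsFactors = FALSE
    )
  }
  expr <- do.call(rbind, out)
  rownames(expr) <- NULL
  expr$detected <- expr$rpkm > rpkm_threshold
  expr$category <- classify_expression(expr$rpkm,
                                       threshold = rpkm_threshold,
                                       mode = category_mode)
  expr
}

#' RPKM: reads per kilobase of gene model per million mapped reads
#'
#' @param count total read count C of the feature
#' @param model_length feature model length L in nt (> 0)
#' @param lib_size library size N in mapped reads (> 0)
#' @return `1e9 * C / (L * N)`, vectorised
#' @export
compute_rpkm <- function(count, model_length, lib_size) {
  if (any(model_length <= 0)) stop("model_length must be > 0")
  if (any(lib_size <= 0)) stop("lib_size must be > 0")
  1e9 * count / (model_length * lib_size)
}

#' Classify RPKM values into five expression categories
#'
#' Loci with RPKM strictly greater than the threshold are considered
#' detected; detected loci fall into five categories. In "decade" mode
#' the bins are (threshold, 1], (1, 10], (10, 100], (100, 1000] and
#' (1000, Inf) labelled very_low .. very_high; "quantile" mode uses the
#' quintiles of the detected RPKM distribution instead.
#'
#' @param rpkm numeric vector
#' @param threshold detection threshold (default 0.1, strict >)
#' @param mode "decade" or "quantile"
#' @return ordered factor with levels `undetected`, `very_low`, `low`,
#'   `intermediate`, `high`, `very_high`
#' @export
classify_expression <- function(rpkm, threshold = 0.1,
                                mode = c("decade", "quantile")) {
  mode <- match.arg(mode)
  labels <- c("very_low", "low", "intermediate", "high", "very_high")
  breaks <- if (mode == "decade") {
    c(threshold, 1, 10, 100, 1000, Inf)
  } else {
    det <- rpkm[rpkm > threshold]
    if (length(det) == 0) {
      c(threshold, 1, 10, 100, 1000, Inf)
    } else {
      unique(c(threshold,
               stats::quantile(det, probs = seq(0.2, 0.8, by = 0.2),
                               names = FALSE), Inf))
    }
  }
  cat <- cut(rpkm, breaks = breaks,
             labels = labels[seq_len(length(breaks) - 1)],
             right = TRUE, include.lowest = FALSE)
  out <- as.character(cat)
  out[rpkm <= threshold] <- "undetected"
  factor(out, levels = c("undetected", labels), ordered = TRUE)
}

#' Per-chromosome read-count ratio between the two samples
#'
#' A quality-control mirror of the chromosome dosage check: an extra
#' chromosome copy in sample A should show up as an elevated A/B mapped
#' read ratio on that chromosome only. By default ratios are scaled so
#' that the median chromosome ratio equals 1 (median-of-ratios
#' normalisation, robust to the dosage chromosome's own excess and to
#' differential expression); "total" divides by the library-size ratio
#' instead, and "none" reports raw count ratios.
#'
#' @param reads data frame with `chrom` and `sample`
#' @param samples length-2 character vector `c(A, B)`; defaults to the
#'   sorted labels present
#' @param normalize "median", "total" or "none"
#' @return data frame `chrom`, `count_A`, `count_B`, `ratio` (NA where
#'   the B count is 0), with attributes `mean_ratio` and `sd_ratio`
#'   over chromosomes
#' @export
chromosome_read_ratio <- function(reads, samples = NULL,
                                  normalize = c("median", "total",
                                                "none")) {
  normalize <- match.arg(normalize)
  if (is.null(samples)) {
    samples <- sort(unique(as.character(reads$sample)))
  }
  stopifnot(length(samples) == 2)
  chroms <- sort(unique(as.character(reads$chrom)))
  nA <- table(factor(reads$chrom[reads$sample == samples[1]],
                     levels = chroms))
  nB <- table(factor(reads$chrom[reads$sample == samples[2]],
                     levels = chroms))
  ratio <- ifelse(nB > 0, as.numeric(nA) / as.numeric(nB), NA_real_)
  if (normalize == "total") {
    ratio <- ratio / (sum(nA) / sum(nB))
  } else if (normalize == "median") {
    med <- stats::median(ratio, na.rm = TRUE)
    if (is.finite(med) && med > 0) ratio <- ratio / med
  }
  out <- data.frame(chrom = chroms, count_A = as.integer(nA),
                    count_B = as.integer(nB), ratio = ratio,
                    stringsAsFactors = FALSE)
  attr(out, "mean_ratio") <- mean(ratio, na.rm = TRUE)
  attr(out, "sd_ratio") <- stats::sd(ratio, na.rm = TRUE)
  out
}

#' snoRNA host-gene cross-table
#'
#' A small-RNA locus is intron-hosted (SHG: its host is a snoRNA host
#' gene) when its span lies entirely within an intronic region of
#' another locus, on either strand. The cross-table relates the
#' small RNA's own expression category to its host status and the
#' host gene's category.
#'
#' @param small_rnas data frame with `id`, `chrom`, `start`, `end`,
#'   `strand` and `category` (the small RNA's expression category)
#' @param regions region data frame (only `kind == "inR"` rows are
#'   used) carrying `host_locus_id`
#' @param expression single-sample slice of [locus_expression()] output
#'   supplying the host category
#' @return list with `calls` (per small RNA: `hosted`, `host_locus_id`,
#'   `host_category`, `small_category`) and `table` (small-RNA category
#'   x SHG/nSHG counts)
#' @export
snorna_host_table <- function(small_rnas, regions, expression) {
  inr <- regions[regions$kind == "inR", , drop = FALSE]
  hosted <- rep(FALSE, nrow(small_rnas))
  host <- rep(NA_character_, nrow(small_rnas))
  if (nrow(small_rnas) > 0 && nrow(inr) > 0) {
    hits <- GenomicRanges::findOverlaps(.as_gr(small_rnas), .as_gr(inr),
                                        type = "within",
                                        ignore.strand = TRUE)
    hosted[S4Vectors::queryHits(hits)] <- TRUE
    host[S4Vectors::queryHits(hits)] <-
      inr$host_locus_id[S4Vectors::subjectHits(hits)]
  }
  host_cat <- as.character(
    expression$category[match(host, expression$locus_id)])
  calls <- data.frame(
    small_rna_id = small_rnas$id, hosted = hosted,
    host_locus_id = host, host_category = host_cat,
    small_category = as.character(small_rnas$category),
    stringsAsFactors = FALSE
  )
  tab <- table(small_category = calls$small_category,
               host_status = ifelse(calls$hosted, "SHG", "nSHG"))
  list(calls = calls, table = tab)
}

#' Partition read starts over elements, intronic and intergenic regions
#'
#' Because elements, inR and igR tile each strand, every read 5' start
#' on a known chromosome lands in exactly one of the three; reads on
#' chromosomes absent from the annotation space are `unassigned`. The
#' per-sample counts satisfy element + inR + igR + unassigned = total.
#'
#' @param reads read data frame
#' @param elements element data frame
#' @param regions region data frame from
#'   [derive_nonannotated_regions()]
#' @param samples sample labels
#' @return data frame with one row per sample and columns `element`,
#'   `inR`, `igR`, `unassigned`, `total`
#' @export
partition_read_counts <- function(reads, elements, regions,
                                  samples = NULL) {
  if (is.null(samples)) {
    samples <- sort(unique(as.character(reads$sample)))
  }
  space <- rbind(
    cbind(elements[, c("chrom", "start", "end", "strand")],
          class = "element"),
    cbind(regions[regions$kind == "inR",
                  c("chrom", "start", "end", "strand")], class = "inR"),
    cbind(regions[regions$kind == "igR",
                  c("chrom", "start", "end", "strand")], class = "igR")
  )
  idx <- .start_assignment(reads, space)
  cls <- ifelse(is.na(idx), "unassigned", space$class[idx])
  tab <- table(sample = factor(reads$sample, levels = samples),
               class = factor(cls, levels = c("element", "inR", "igR",
                                              "unassigned")))
  out <- as.data.frame.matrix(tab)
  out$total <- rowSums(out)
  cbind(sample = rownames(out), out, row.names = NULL)
}
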