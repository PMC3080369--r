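# Annotation revision: non-overlapping elements, family loci, stranded
# intronic/intergenic regions, masks, and the combinatorial junction
# library.

#' Revise gene models into a non-overlapping element/locus annotation
#'
#' Same-strand genes whose spans overlap are merged into a single family
#' locus, and exons are fragmented at every exon boundary within the
#' locus, so the resulting exonic elements never overlap and each "exon
#' or part of exon" has a well-defined read count. Antisense overlaps
#' are kept separate: strand-oriented libraries determine the
#' directionality of transcription, so the two strands are revised
#' independently.
#'
#' @param gene_models data frame with one row per exon and columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand` (0-based, half-open);
#'   an optional `transcript_id` column distinguishes isoforms when the
#'   junction library flags annotated junctions.
#' @return an object of class `revised_annotation`: a list with
#'   \describe{
#'     \item{elements}{data frame of non-overlapping exonic elements
#'       (`element_id`, `chrom`, `start`, `end`, `strand`, `locus_id`)}
#'     \item{loci}{data frame of loci (`locus_id`, `chrom`, `strand`,
#'       `start`, `end` span, `genes` comma-separated member gene ids,
#'       `n_elements`, `model_length` in nt)}
#'     \item{rejected}{malformed input rows with a `reason` column}
#'     \item{models}{the accepted input rows (used for junction
#'       annotation flags)}
#'   }
#' @export
revise_annotation <- function(gene_models) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(gene_models))) {
    stop("gene_models needs columns ", paste(req, collapse = ", "))
  }
  gm <- as.data.frame(gene_models, stringsAsFactors = FALSE)
  if (!"transcript_id" %in% names(gm)) {
    gm$transcript_id <- gm$gene_id
  }

  bad_len <- is.na(gm$start) | is.na(gm$end) | gm$end <= gm$start
  bad_strand <- !gm$strand %in% c("+", "-")
  bad <- bad_len | bad_strand
  rejected <- gm[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- ifelse(bad_len[bad], "end <= start", "bad strand")
  } else {
    rejected$reason <- character(0)
  }
  gm <- gm[!bad, , drop = FALSE]

  empty_elements <- data.frame(
    element_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    locus_id = character(0), stringsAsFactors = FALSE
  )
  empty_loci <- data.frame(
    locus_id = character(0), chrom = character(0), strand = character(0),
    start = integer(0), end = integer(0), genes = character(0),
    n_elements = integer(0), model_length = integer(0),
    stringsAsFactors = FALSE
  )
  if (nrow(gm) == 0) {
    out <- list(elements = empty_elements, loci = empty_loci,
                rejected = rejected, models = gm)
    class(out) <- "revised_annotation"
    return(out)
  }

  # gene spans per (gene, chrom, strand)
  key <- paste(gm$gene_id, gm$chrom, gm$strand, sep = "\r")
  span_start <- tapply(gm$start, key, min)
  span_end <- tapply(gm$end, key, max)
  parts <- do.call(rbind, strsplit(names(span_start), "\r", fixed = TRUE))
  spans <- data.frame(
    gene_id = parts[, 1], chrom = parts[, 2], strand = parts[, 3],
    start = as.integer(span_start), end = as.integer(span_end),
    stringsAsFactors = FALSE
  )

  # merge overlapping same-strand spans into family loci
  span_gr <- .as_gr(spans)
  merged <- GenomicRanges::reduce(span_gr, ignore.strand = FALSE)
  hits <- GenomicRanges::findOverlaps(span_gr, merged)
  cluster <- rep(NA_integer_, nrow(spans))
  cluster[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

  merged_df <- .as_bed_df(merged)
  ord <- order(merged_df$chrom, merged_df$start, merged_df$strand)
  rank <- match(seq_len(nrow(merged_df)), ord)
  locus_ids <- sprintf("LOC%05d", rank)

  loci <- merged_df
  loci$locus_id <- locus_ids
  loci$genes <- vapply(seq_len(nrow(loci)), function(i) {
    paste(sort(unique(spans$gene_id[cluster == i])), collapse = ",")
  }, character(1))

  # fragment exons at all exon boundaries (disjoin); same-strand loci
  # have disjoint spans, so a global per-strand disjoin is a per-locus one
  exon_gr <- .as_gr(gm)
  frag <- GenomicRanges::disjoin(exon_gr, ignore.strand = FALSE)
  fhits <- GenomicRanges::findOverlaps(frag, merged, type = "within")
  elements <- .as_bed_df(frag)
  elements$locus_id <- locus_ids[S4Vectors::subjectHits(fhits)[
    match(seq_along(frag), S4Vectors::queryHits(fhits))]]
  elements <- elements[order(elements$chrom, elements$start,
                             elements$strand), , drop = FALSE]
  rownames(elements) <- NULL
  idx <- stats::ave(seq_len(nrow(elements)), elements$locus_id,
                    FUN = seq_along)
  elements$element_id <- sprintf("%s_e%04d", elements$locus_id, idx)
  elements <- elements[, c("element_id", "chrom", "start", "end",
                           "strand", "locus_id")]

  len <- tapply(elements$end - elements$start, elements$locus_id, sum)
  n_el <- tapply(elements$element_id, elements$locus_id, length)
  loci$model_length <- as.integer(len[loci$locus_id])
  loci$n_elements <- as.integer(n_el[loci$locus_id])
  loci <- loci[order(loci$chrom, loci$start, loci$strand), , drop = FALSE]
  rownames(loci) <- NULL
  loci <- loci[, c("locus_id", "chrom", "strand", "start", "end",
                   "genes", "n_elements", "model_length")]

  out <- list(elements = elements, loci = loci, rejected = rejected,
              models = gm)
  class(out) <- "revised_annotation"
  out
}

#' @export
print.revised_annotation <- function(x, ...) {
  cat("revised_annotation:", nrow(x$loci), "loci,",
      nrow(x$elements), "elements,",
      nrow(x$rejected), "rejected input rows\n")
  invisible(x)
}

#' Derive stranded intronic (inR) and intergenic (igR) regions
#'
#' Per strand, intronic regions are the gaps between consecutive
#' elements inside each locus span and intergenic regions are the
#' complement of all locus spans, so that elements, inR and igR tile
#' `[0, chrom_size)` exactly on each strand.
#'
#' @param revised a `revised_annotation`
#' @param chrom_sizes named integer vector of chromosome lengths; every
#'   chromosome in the annotation must be present
#' @return data frame with `region_id`, `chrom`, `start`, `end`,
#'   `strand`, `kind` ("inR"/"igR") and `host_locus_id` (NA for igR)
#' @export
derive_nonannotated_regions <- function(revised, chrom_sizes) {
  stopifnot(inherits(revised, "revised_annotation"))
  loci <- revised$loci
  if (nrow(loci) > 0) {
    miss <- setdiff(unique(loci$chrom), names(chrom_sizes))
    if (length(miss) > 0) {
      stop("chromosome sizes missing for: ", paste(miss, collapse = ", "))
    }
    if (any(loci$end > chrom_sizes[loci$chrom])) {
      stop("locus extends beyond chromosome size")
    }
  }
  elements <- revised$elements
  res <- list()
  for (chrom in names(chrom_sizes)) {
    size <- as.integer(chrom_sizes[[chrom]])
    for (st in c("+", "-")) {
      l <- loci[loci$chrom == chrom & loci$strand == st, , drop = FALSE]
      e <- elements[elements$chrom == chrom & elements$strand == st, ,
                    drop = FALSE]
      # igR: complement of locus spans
      bounds <- sort(c(0L, rbind(l$start, l$end), size))
      ig_start <- bounds[seq(1, length(bounds), 2)]
      ig_end <- bounds[seq(2, length(bounds), 2)]
      keep <- ig_end > ig_start
      if (any(keep)) {
        res[[length(res) + 1]] <- data.frame(
          chrom = chrom, start = ig_start[keep], end = ig_end[keep],
          strand = st, kind = "igR", host_locus_id = NA_character_,
          stringsAsFactors = FALSE
        )
      }
      # inR: per locus, span minus its elements
      for (i in seq_len(nrow(l))) {
        le <- e[e$locus_id == l$locus_id[i], , drop = FALSE]
        le <- le[order(le$start), , drop = FALSE]
        gap_start <- le$end[-nrow(le)]
        gap_end <- le$start[-1]
        keep <- gap_end > gap_start
        if (any(keep)) {
          res[[length(res) + 1]] <- data.frame(
            chrom = chrom, start = gap_start[keep], end = gap_end[keep],
            strand = st, kind = "inR", host_locus_id = l$locus_id[i],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  regions <- if (length(res) > 0) {
    do.call(rbind, res)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), kind = character(0),
               host_locus_id = character(0), stringsAsFactors = FALSE)
  }
  regions <- regions[order(regions$chrom, regions$start, regions$strand), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  .enumerate_regions(regions)
}

# stable enumerated region ids, one counter per kind
.enumerate_regions <- function(regions) {
  n_in <- cumsum(regions$kind == "inR")
  n_ig <- cumsum(regions$kind == "igR")
  regions$region_id <- ifelse(regions$kind == "inR",
                              sprintf("inR%06d", n_in),
                              sprintf("igR%06d", n_ig))
  regions[, c("region_id", "chrom", "start", "end", "strand", "kind",
              "host_locus_id")]
}

#' Subtract secondary-annotation masks from a region set
#'
#' Plays the role of filtering intronic/intergenic regions with external
#' annotations (e.g. UCSC known genes, Ensembl, a repeat mask) so that
#' only truly unannotated intervals remain. Remaining pieces are
#' re-labelled and enumerated; `parent_region_id` records the original
#' region.
#'
#' @param regions region data frame from [derive_nonannotated_regions()]
#' @param masks list of BED-style data frames; a mask row whose strand
#'   is `"*"` (or a mask without a strand column) removes the interval
#'   from both strands
#' @return region data frame with an extra `parent_region_id` column
#' @export
apply_annotation_masks <- function(regions, masks = list()) {
  if (length(masks) == 0 || nrow(regions) == 0) {
    out <- regions
    out$parent_region_id <- out$region_id
    return(out)
  }
  mask_df <- do.call(rbind, lapply(masks, function(m) {
    m <- as.data.frame(m, stringsAsFactors = FALSE)
    if (!"strand" %in% names(m)) m$strand <- "*"
    m[, c("chrom", "start", "end", "strand")]
  }))
  # strand-agnostic rows removed from both strands
  star <- mask_df$strand == "*"
  mask_df <- rbind(
    transform(mask_df[star, , drop = FALSE], strand = "+"),
    transform(mask_df[star, , drop = FALSE], strand = "-"),
    mask_df[!star, , drop = FALSE]
  )
  pieces <- GenomicRanges::subtract(.as_gr(regions), .as_gr(mask_df),
                                    ignore.strand = FALSE)
  n_per <- lengths(pieces)
  flat <- .as_bed_df(unlist(pieces, use.names = FALSE))
  parent <- rep(seq_len(nrow(regions)), n_per)
  flat$kind <- regions$kind[parent]
  flat$host_locus_id <- regions$host_locus_id[parent]
  flat$parent_region_id <- regions$region_id[parent]
  flat <- flat[order(flat$chrom, flat$start, flat$strand), , drop = FALSE]
  rownames(flat) <- NULL
  out <- .enumerate_regions(flat)
  out$parent_region_id <- flat$parent_region_id[
    match(paste(out$chrom, out$start, out$strand),
          paste(flat$chrom, flat$start, flat$strand))]
  out
}

# strand-oriented donor/acceptor coordinates from genomic left/right
# boundaries: the donor is the transcriptionally upstream exon end
.orient_junction <- function(strand, left_end, right_start) {
  data.frame(
    donor_end = ifelse(strand == "+", left_end, right_start),
    acceptor_start = ifelse(strand == "+", right_start, left_end)
  )
}

# genomic left/right boundaries from strand-oriented donor/acceptor
.junction_genomic <- function(strand, donor_end, acceptor_start) {
  data.frame(
    left_end = ifelse(strand == "+", donor_end, acceptor_start),
    right_start = ifelse(strand == "+", acceptor_start, donor_end)
  )
}

.junction_key <- function(df) {
  paste(df$chrom, df$strand, df$donor_end, df$acceptor_start, sep = ":")
}

#' Build the combinatorial exon-junction library
#'
#' For every locus with k elements, all k(k-1)/2 ordered element pairs
#' (in transcription order) define one junction key, enabling
#' identification of novel combinatorial exon usage. Pairs of exons
#' that are consecutive in an input transcript model are flagged
#' `annotated_model`; all other pairs are `combinatorial`.
#'
#' @param revised a `revised_annotation`
#' @return data frame with `junction_id`, `chrom`, `strand`,
#'   `donor_end`, `acceptor_start` (strand-oriented: on the minus strand
#'   the donor coordinate is genomically to the right of the acceptor),
#'   `locus_id` and `status`
#' @export
build_junction_library <- function(revised) {
  stopifnot(inherits(revised, "revised_annotation"))
  el <- revised$elements
  res <- list()
  for (lid in revised$loci$locus_id) {
    e <- el[el$locus_id == lid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    k <- nrow(e)
    if (k < 2) next
    pairs <- utils::combn(k, 2)
    res[[length(res) + 1]] <- data.frame(
      chrom = e$chrom[1], strand = e$strand[1],
      left_end = e$end[pairs[1, ]], right_start = e$start[pairs[2, ]],
      locus_id = lid, stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0) {
    return(data.frame(
      junction_id = character(0), chrom = character(0),
      strand = character(0), donor_end = integer(0),
      acceptor_start = integer(0), locus_id = character(0),
      status = character(0), stringsAsFactors = FALSE
    ))
  }
  lib <- do.call(rbind, res)
  oriented <- .orient_junction(lib$strand, lib$left_end, lib$right_start)
  lib$donor_end <- oriented$donor_end
  lib$acceptor_start <- oriented$acceptor_start

  # consecutive-exon pairs of each input transcript -> annotated_model
  gm <- revised$models
  ann_keys <- character(0)
  if (nrow(gm) > 0) {
    sp <- split(gm, paste(gm$transcript_id, gm$chrom, gm$strand))
    ann <- lapply(sp, function(tx) {
      tx <- tx[order(tx$start), , drop = FALSE]
      if (nrow(tx) < 2) return(NULL)
      data.frame(chrom = tx$chrom[1], strand = tx$strand[1],
                 left_end = tx$end[-nrow(tx)], right_start = tx$start[-1],
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, ann)
    if (!is.null(ann) && nrow(ann) > 0) {
      ann <- ann[ann$right_start > ann$left_end, , drop = FALSE]
      o <- .orient_junction(ann$strand, ann$left_end, ann$right_start)
      ann$donor_end <- o$donor_end
      ann$acceptor_start <- o$acceptor_start
      ann_keys <- .junction_key(ann)
    }
  }
  lib$status <- ifelse(.junction_key(lib) %in% ann_keys,
                       "annotated_model", "combinatorial")
  lib <- lib[order(lib$chrom, lib$left_end, lib$right_start, lib$strand), ,
             drop = FALSE]
  rownames(lib) <- NULL
  lib$junction_id <- sprintf("J%06d", seq_len(nrow(lib)))
  lib[, c("junction_id", "chrom", "strand", "donor_end",
          "acceptor_start", "locus_id", "status")]
}
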