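# Orchestration of the full two-sample comparison: annotation ->
# quantify -> novel transcription -> splicing -> differential
# expression, with every stage's artifacts written to an output
# directory and a summary report of the counts the analysis yields.

#' Pipeline parameters
#'
#' @param ... overrides of the documented defaults; unknown keys are
#'   rejected
#' @return a `pipeline_params` list: `W`, `T` (TAR refinement window
#'   and read threshold), `T1` (junction reliability), `utr_window`,
#'   `utr_min_reads`, `min_orf`, `rpkm_threshold`, `category_mode`,
#'   `q_nb_cutoff`, `p_cutoff`, `fc_threshold`, `phi`, `pseudocount`,
#'   `tar_min_active`, `ratio_normalize`
#' @export
pipeline_params <- function(...) {
  par <- list(
    W = 500L, T = 30L, T1 = 5L,
    utr_window = 150L, utr_min_reads = 5L, min_orf = 200L,
    rpkm_threshold = 0.1, category_mode = "decade",
    q_nb_cutoff = 0.1, p_cutoff = 1e-4, fc_threshold = 1.5,
    phi = 0.1, pseudocount = 0.5, tar_min_active = 1L,
    ratio_normalize = "median"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(par))
  if (length(unknown) > 0) {
    stop("unknown pipeline parameters: ",
         paste(unknown, collapse = ", "))
  }
  par[names(overrides)] <- overrides
  stopifnot(par$W > 0, par$T > 0, par$T1 > 0, par$utr_window > 0,
            par$rpkm_threshold >= 0, par$fc_threshold >= 1,
            par$phi >= 0)
  class(par) <- "pipeline_params"
  par
}

#' Run the full two-sample whole-transcriptome comparison
#'
#' Executes annotation revision, read/junction quantification, TAR
#' refinement, UTR-extension detection, splicing analysis and
#' differential expression in order, writing every stage's artifacts
#' under `out_dir` and returning a result list with a summary report.
#' A stage failure aborts with the stage name; artifacts already
#' written are retained.
#'
#' @param gene_models exon data frame (see [revise_annotation()])
#' @param reads read data frame for both samples
#' @param junction_counts junction count data frame
#'   (chrom/strand/donor_end/acceptor_start/sample/count)
#' @param chrom_sizes named integer vector
#' @param out_dir output directory
#' @param samples length-2 sample label vector, case first
#' @param masks optional list of secondary-annotation mask data frames
#' @param small_rnas optional small-RNA locus data frame for the
#'   host-gene cross-table
#' @param genome optional named character vector of chromosome
#'   sequences enabling the ORF scan
#' @param params a [pipeline_params()] list
#' @return (invisibly) list of all stage outputs plus `report`, a
#'   named list of summary counts
#' @export
run_pipeline <- function(gene_models, reads, junction_counts,
                         chrom_sizes, out_dir, samples = NULL,
                         masks = list(), small_rnas = NULL,
                         genome = NULL, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(samples)) {
    samples <- sort(unique(as.character(reads$sample)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  revised <- stage("annotation", {
    r <- revise_annotation(gene_models)
    write_bed6(data.frame(chrom = r$elements$chrom,
                          start = r$elements$start,
                          end = r$elements$end,
                          name = r$elements$locus_id, score = 0,
                          strand = r$elements$strand),
               file.path(out_dir, "elements.bed"))
    write_tsv(r$loci, file.path(out_dir, "loci.tsv"))
    r
  })

  regions <- stage("regions", {
    reg <- derive_nonannotated_regions(revised, chrom_sizes)
    reg <- apply_annotation_masks(reg, masks)
    write_bed6(data.frame(chrom = reg$chrom, start = reg$start,
                          end = reg$end, name = reg$region_id,
                          score = 0, strand = reg$strand),
               file.path(out_dir, "regions.bed"))
    reg
  })

  library <- stage("junction_library", {
    lib <- build_junction_library(revised)
    write_tsv(lib, file.path(out_dir, "junction_library.tsv"))
    lib
  })

  quant <- stage("quantify", {
    counted <- count_reads_by_start(reads, revised$elements,
                                    samples = samples)
    jrec <- count_junctions(junction_counts, library,
                            samples = samples)
    junction_totals <- vapply(samples, function(s)
      sum(jrec[[paste0("count_", s)]]), numeric(1))
    genome_totals <- vapply(samples, function(s)
      sum(reads$sample == s &
            reads$chrom %in% names(chrom_sizes)), numeric(1))
    # empty libraries still quantify (all-zero RPKM) rather than abort
    lib_sizes <- pmax(genome_totals + junction_totals, 1)
    expr <- locus_expression(revised, counted$counts, jrec, library,
                             lib_sizes,
                             rpkm_threshold = params$rpkm_threshold,
                             category_mode = params$category_mode,
                             samples = samples)
    write_tsv(expr, file.path(out_dir, "expression.tsv"))
    ratio <- chromosome_read_ratio(reads, samples = samples,
                                   normalize = params$ratio_normalize)
    write_tsv(ratio, file.path(out_dir, "chromosome_ratio.tsv"))
    partition <- partition_read_counts(reads, revised$elements,
                                       regions, samples = samples)
    write_tsv(partition, file.path(out_dir, "read_partition.tsv"))
    list(expr = expr, jrec = jrec, lib_sizes = lib_sizes,
         ratio = ratio, partition = partition)
  })

  tars <- stage("tars", {
    t0 <- refine_tars(reads, regions, W = params$W, T = params$T)
    tq <- quantify_tars(reads, t0, samples = samples,
                        min_active = params$tar_min_active)
    write_tsv(tq, file.path(out_dir, "tars.tsv"))
    tq
  })

  utr <- stage("utr", {
    u <- detect_utr_extensions(reads, revised,
                               chrom_sizes = chrom_sizes,
                               window = params$utr_window,
                               min_reads = params$utr_min_reads,
                               samples = samples)
    write_tsv(u, file.path(out_dir, "utr_extensions.tsv"))
    u
  })

  orfs <- NULL
  if (!is.null(genome)) {
    orfs <- stage("orfs", {
      o <- scan_orfs(tars, genome, min_orf = params$min_orf)
      write_tsv(o, file.path(out_dir, "orfs.tsv"))
      o
    })
  }

  splicing <- stage("splicing", {
    jrec <- sample_specific_junctions(quant$jrec, T1 = params$T1,
                                      samples = samples)
    ase <- stats::setNames(lapply(samples, function(s)
      detect_ase(jrec, s, T1 = params$T1)), samples)
    write_tsv(jrec, file.path(out_dir, "junction_records.tsv"))
    for (s in samples) {
      write_tsv(ase[[s]], file.path(out_dir,
                                    sprintf("ase_%s.tsv", s)))
    }
    list(records = jrec, ase = ase)
  })

  de <- stage("diffexp", {
    locus_counts <- .expression_to_counts(quant$expr, samples)
    de_loci <- classify_de(
      de_test_table(locus_counts, quant$lib_sizes[[samples[1]]],
                    quant$lib_sizes[[samples[2]]], phi = params$phi,
                    pseudocount = params$pseudocount),
      q_nb_cutoff = params$q_nb_cutoff, p_cutoff = params$p_cutoff,
      fc_threshold = params$fc_threshold)
    write_tsv(de_loci, file.path(out_dir, "de_loci.tsv"))
    de_tars <- NULL
    if (nrow(tars) > 0) {
      tar_counts <- data.frame(
        feature_id = tars$tar_id,
        count_A = tars[[paste0("count_", samples[1])]],
        count_B = tars[[paste0("count_", samples[2])]],
        stringsAsFactors = FALSE
      )
      de_tars <- classify_de(
        de_test_table(tar_counts, quant$lib_sizes[[samples[1]]],
                      quant$lib_sizes[[samples[2]]],
                      phi = params$phi,
                      pseudocount = params$pseudocount),
        q_nb_cutoff = params$q_nb_cutoff, p_cutoff = params$p_cutoff,
        fc_threshold = params$fc_threshold)
      write_tsv(de_tars, file.path(out_dir, "de_tars.tsv"))
    }
    list(loci = de_loci, tars = de_tars)
  })

  snorna <- NULL
  if (!is.null(small_rnas) && nrow(small_rnas) > 0) {
    snorna <- stage("snorna", {
      sr_counts <- .start_counts(reads, small_rnas, samples = samples)
      s1 <- samples[1]
      sr <- small_rnas
      sr$rpkm <- compute_rpkm(sr_counts[, s1], sr$end - sr$start,
                              quant$lib_sizes[[s1]])
      sr$category <- classify_expression(
        sr$rpkm, threshold = params$rpkm_threshold)
      host <- snorna_host_table(
        sr, regions, quant$expr[quant$expr$sample == s1, ])
      write_tsv(host$calls, file.path(out_dir, "snorna_host.tsv"))
      host
    })
  }

  tracks <- stage("tracks", {
    export_tracks(reads, file.path(out_dir, "tracks"), tars = tars,
                  utr_calls = utr,
                  junctions = splicing$records[
                    !is.na(splicing$records$specific), , drop = FALSE],
                  samples = samples)
  })

  report <- .pipeline_report(revised, regions, quant, tars, utr,
                             splicing, de, samples)
  writeLines(paste(names(report), unlist(report), sep = "\t"),
             file.path(out_dir, "report.txt"))

  invisible(list(
    revised = revised, regions = regions, library = library,
    expression = quant$expr, lib_sizes = quant$lib_sizes,
    ratio = quant$ratio, partition = quant$partition, tars = tars,
    utr = utr, orfs = orfs, splicing = splicing, de = de,
    snorna = snorna, tracks = tracks, report = report,
    samples = samples, params = params
  ))
}

.expression_to_counts <- function(expr, samples) {
  a <- expr[expr$sample == samples[1], ]
  b <- expr[expr$sample == samples[2], ]
  b <- b[match(a$locus_id, b$locus_id), ]
  data.frame(feature_id = a$locus_id, count_A = a$total_count,
             count_B = b$total_count, stringsAsFactors = FALSE)
}

.pipeline_report <- function(revised, regions, quant, tars, utr,
                             splicing, de, samples) {
  s1 <- samples[1]; s2 <- samples[2]
  expr <- quant$expr
  rep_ <- list(
    n_loci = nrow(revised$loci),
    n_elements = nrow(revised$elements),
    n_regions_inR = sum(regions$kind == "inR"),
    n_regions_igR = sum(regions$kind == "igR")
  )
  for (s in samples) {
    e <- expr[expr$sample == s, ]
    rep_[[paste0("detected_loci_", s)]] <- sum(e$detected)
    for (lv in levels(e$category)) {
      rep_[[paste0("category_", lv, "_", s)]] <- sum(e$category == lv)
    }
  }
  rep_$n_inTARs <- sum(tars$kind == "inTAR")
  rep_$n_igTARs <- sum(tars$kind == "igTAR")
  for (s in samples) {
    rep_[[paste0("active_tars_", s)]] <-
      sum(tars[[paste0("active_", s)]])
  }
  rep_$tars_common <- sum(tars$status == "common")
  rep_[[paste0("tars_", s1, "_specific")]] <-
    sum(tars$status == paste0(s1, "_specific"))
  rep_[[paste0("tars_", s2, "_specific")]] <-
    sum(tars$status == paste0(s2, "_specific"))
  rep_$utr_calls <- nrow(utr)
  rep_$utr_common <- sum(utr$status == "common")
  rep_$ase <- sum(vapply(splicing$ase, nrow, integer(1)))
  rep_[[paste0("specific_junctions_", s1)]] <-
    sum(splicing$records$specific == s1, na.rm = TRUE)
  rep_[[paste0("specific_junctions_", s2)]] <-
    sum(splicing$records$specific == s2, na.rm = TRUE)
  for (tier in c("strong", "good", "acceptable", "weak",
                 "no_change")) {
    rep_[[paste0("de_", tier)]] <- sum(de$loci$tier == tier)
  }
  rep_
}
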