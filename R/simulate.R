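# Seeded synthetic-data generator: a toy genome with annotated genes,
# intron-hosted snoRNA-like loci, a trisomic chromosome, planted TARs,
# UTR extensions and junction profiles, plus the truth set every
# downstream stage is scored against.

#' Build a simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: two
#' strand-specific libraries of 2e5 uniquely assigned 50-nt reads, one
#' chromosome (chr21) at 1.5x read dosage in the trisomic sample,
#' lognormal gene expression scaled so the realised library size
#' matches the nominal one, a handful of planted differentially
#' expressed genes (balanced up/down so library totals stay
#' comparable), short highly expressed intron-hosted snoRNA-like loci,
#' intronic and intergenic read clusters dense enough to qualify as
#' TARs (pooled density 2T per window, width 3W), fixed-count read
#' plants in 150-bp gene flanks (UTR extensions), annotated-junction
#' counts proportional to expression, exon-skip junctions creating
#' alternative-splicing events, and sample-specific junctions.
#'
#' @param seed integer seed fixing all randomness
#' @param ... overrides of the defaults; unknown keys are rejected
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chromosomes = c(chr1 = 800000L, chr2 = 800000L, chr3 = 800000L,
                    chr21 = 400000L),
    genes_per_chromosome = c(30L, 30L, 30L, 12L),
    trisomic_chromosome = "chr21",
    dosage = 1.5,
    samples = c("trisomic", "euploid"),
    exons_per_gene = c(1L, 8L),        # uniform range
    exon_length = c(100L, 400L),       # uniform range, nt
    intron_length = c(300L, 3000L),    # uniform range, nt
    intergenic_gap = c(2000L, 6000L),  # uniform range, nt
    expression_meanlog = log(6000),    # RPKM-like scale for a toy genome
    expression_sdlog = 0.9,
    n_overlapping_pairs = 2L,
    n_small_rnas = 6L,
    small_rna_length = 150L,
    small_rna_rpkm = 2000,
    n_de_genes = 8L,                   # half up, half down in sample A
    de_fold = 4,
    n_tar_intronic = 4L,
    n_tar_intergenic = 4L,
    tar_window = 500L,                 # W used when planting density
    tar_min_reads = 30L,               # T used when planting density
    tar_width_windows = 3L,            # planted cluster width, in W
    tar_density = 2,                   # pooled starts per window, in T
    n_utr_genes = 6L,
    utr_window = 150L,
    utr_reads = 15L,                   # exact planted starts per call
    n_sample_specific_junctions = 4L,  # split between the two samples
    specific_junction_reads = 8L,
    n_ase_junctions = 4L,              # planted exon-skip junctions
    ase_junction_reads = 10L,
    junction_rate = 0.01,              # per adjacent junction, x gene mu
    background_rate = 2e-5,            # reads per bp per strand
    antisense_rate = 0,
    read_length = 50L,
    library_size = 2e5
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  if (cfg$dosage <= 0) stop("dosage must be positive")
  if (cfg$background_rate < 0 || cfg$antisense_rate < 0) {
    stop("rates must be non-negative")
  }
  class(cfg) <- "sim_config"
  cfg
}

.runif_int <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

#' Simulate gene models and small-RNA loci
#'
#' Places genes sequentially along each chromosome with random
#' intergenic gaps, sorted positive-length exons and random strands;
#' plants the configured number of same-strand overlapping gene pairs
#' (to exercise annotation revision) and intron-hosted snoRNA-like
#' small-RNA loci. Deterministic for a fixed config.
#'
#' @param config a `sim_config`
#' @return list with `genes` (exon data frame: `gene_id`,
#'   `transcript_id`, `chrom`, `start`, `end`, `strand`) and
#'   `small_rnas` (`id`, `chrom`, `start`, `end`, `strand`,
#'   `host_gene`)
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- list()
  gnum <- 0L
  for (ci in seq_along(config$chromosomes)) {
    chrom <- names(config$chromosomes)[ci]
    size <- config$chromosomes[[ci]]
    cursor <- .runif_int(1, config$intergenic_gap)
    for (g in seq_len(config$genes_per_chromosome[ci])) {
      k <- .runif_int(1, config$exons_per_gene)
      exon_len <- .runif_int(k, config$exon_length)
      intron_len <- if (k > 1) .runif_int(k - 1, config$intron_length)
                    else integer(0)
      starts <- cursor + cumsum(c(0L, exon_len[-k] + intron_len))
      ends <- starts + exon_len
      if (ends[k] + 200L > size) {
        stop("infeasible placement: genes exceed chromosome ", chrom)
      }
      gnum <- gnum + 1L
      gid <- sprintf("G%04d", gnum)
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = gid, transcript_id = gid, chrom = chrom,
        start = starts, end = ends,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE
      )
      cursor <- ends[k] + .runif_int(1, config$intergenic_gap)
    }
  }
  if (length(genes) == 0) {
    empty_genes <- data.frame(
      gene_id = character(0), transcript_id = character(0),
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), stringsAsFactors = FALSE
    )
    return(list(genes = empty_genes, small_rnas = data.frame(
      id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0),
      host_gene = character(0), stringsAsFactors = FALSE)))
  }
  genes <- do.call(rbind, genes)

  # planted same-strand overlapping pairs: a single-exon gene straddling
  # the 3'-most exon boundary of a host gene
  if (config$n_overlapping_pairs > 0) {
    multi <- unique(genes$gene_id[duplicated(genes$gene_id)])
    hosts <- utils::head(multi, config$n_overlapping_pairs)
    ov <- lapply(seq_along(hosts), function(i) {
      h <- genes[genes$gene_id == hosts[i], , drop = FALSE]
      span_end <- max(h$end)
      data.frame(
        gene_id = sprintf("GOV%02d", i),
        transcript_id = sprintf("GOV%02d", i),
        chrom = h$chrom[1], start = span_end - 100L,
        end = span_end + 200L, strand = h$strand[1],
        stringsAsFactors = FALSE
      )
    })
    genes <- rbind(genes, do.call(rbind, ov))
  }

  # intron-hosted snoRNA-like loci, centred in a sufficiently long
  # intron of a multi-exon host
  small <- list()
  if (config$n_small_rnas > 0) {
    need <- config$small_rna_length + 40L
    for (gid in unique(genes$gene_id)) {
      if (length(small) >= config$n_small_rnas) break
      ex <- genes[genes$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) < 2) next
      gap_start <- ex$end[-nrow(ex)]
      gap_end <- ex$start[-1]
      ok <- which(gap_end - gap_start >= need)
      if (length(ok) == 0) next
      i <- ok[1]
      mid <- (gap_start[i] + gap_end[i]) %/% 2L
      small[[length(small) + 1]] <- data.frame(
        id = sprintf("SNO%02d", length(small) + 1L),
        chrom = ex$chrom[1],
        start = mid - config$small_rna_length %/% 2L,
        end = mid - config$small_rna_length %/% 2L +
          config$small_rna_length,
        strand = ex$strand[1], host_gene = gid,
        stringsAsFactors = FALSE
      )
    }
  }
  small_rnas <- if (length(small) > 0) {
    do.call(rbind, small)
  } else {
    data.frame(id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), host_gene = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL
  list(genes = genes, small_rnas = small_rnas)
}

#' Assign the planted truth for a simulated annotation
#'
#' Draws per-gene base expression, chooses the differentially expressed
#' genes and their fold changes (applied to sample A), plants TAR
#' intervals in introns and intergenic gaps, UTR-extension windows with
#' their intended status, exon-skip (alternative splicing) junctions and
#' sample-specific junctions.
#'
#' @param annotation output of [simulate_annotation()]
#' @param config a `sim_config`
#' @return a `truth` list (serializable with [write_truth()])
#' @export
simulate_truth <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  genes <- annotation$genes
  gene_ids <- unique(genes$gene_id)
  W <- config$tar_window
  Tmin <- config$tar_min_reads

  expr <- data.frame(
    gene_id = gene_ids,
    base_rpkm = stats::rlnorm(length(gene_ids),
                              config$expression_meanlog,
                              config$expression_sdlog),
    fold_A = 1, de = FALSE, stringsAsFactors = FALSE
  )
  # rescale so the expected gene-derived read total equals the nominal
  # library size (sum of expr * length = 1e9): expression values are
  # compositional, and this keeps empirical RPKM calibrated to truth
  model_len <- tapply(genes$end - genes$start, genes$gene_id, sum)
  mass <- sum(expr$base_rpkm * as.numeric(model_len[expr$gene_id]))
  if (is.finite(mass) && mass > 0) {
    expr$base_rpkm <- expr$base_rpkm * 1e9 / mass
  }

  # gene spans per chromosome, for placement bookkeeping
  span <- do.call(rbind, lapply(split(genes, genes$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = min(e$start), end = max(e$end),
               strand = e$strand[1], stringsAsFactors = FALSE)
  }))

  # read-mass-balanced planted DE, off the dosage chromosome: each
  # up-regulated gene (fold f) is paired with a same-chromosome
  # down-regulated partner of roughly f-times its base expression, so
  # the expected extra reads (f-1)*mu_up cancel the removed reads
  # (1-1/f)*mu_down and chromosome totals stay dosage-dominated (in a
  # toy genome of ~100 genes unbalanced 4-fold plants would swamp the
  # per-chromosome dosage signal the generator emulates)
  f <- config$de_fold
  gene_mu <- expr$base_rpkm * as.numeric(model_len[expr$gene_id])
  n_pairs <- min(config$n_de_genes, length(gene_ids)) %/% 2
  chroms <- setdiff(names(config$chromosomes),
                    config$trisomic_chromosome)
  pair_chrom <- rep(chroms, length.out = n_pairs)
  up <- character(0); down <- character(0)
  for (ch in pair_chrom) {
    cand <- setdiff(span$gene_id[span$chrom == ch], c(up, down))
    mu <- gene_mu[match(cand, expr$gene_id)]
    lo <- cand[mu <= stats::median(mu)]
    if (length(lo) < 1 || length(cand) < 2) next
    u <- sample(lo, 1)
    mu_u <- gene_mu[expr$gene_id == u]
    rest <- setdiff(cand, u)
    mu_r <- gene_mu[match(rest, expr$gene_id)]
    d <- rest[which.min(abs(log(mu_r) - log(f * mu_u)))]
    up <- c(up, u); down <- c(down, d)
  }
  expr$fold_A[expr$gene_id %in% up] <- f
  expr$fold_A[expr$gene_id %in% down] <- 1 / f
  expr$de <- expr$gene_id %in% c(up, down)

  tar_width <- config$tar_width_windows * W
  tars <- list()
  # intergenic plants: inside gaps between consecutive spans, with a
  # margin keeping clear of gene flanks and UTR windows
  margin <- 600L
  for (chrom in names(config$chromosomes)) {
    if (length(tars) >= config$n_tar_intergenic) break
    sp <- span[span$chrom == chrom, , drop = FALSE]
    sp <- sp[order(sp$start), , drop = FALSE]
    if (nrow(sp) < 2) next
    gap_start <- sp$end[-nrow(sp)] + margin
    gap_end <- sp$start[-1] - margin
    ok <- which(gap_end - gap_start >= tar_width)
    for (i in ok) {
      if (length(tars) >= config$n_tar_intergenic) break
      tars[[length(tars) + 1]] <- data.frame(
        chrom = chrom, start = gap_start[i],
        end = gap_start[i] + tar_width,
        strand = sample(c("+", "-"), 1), kind = "igTAR",
        stringsAsFactors = FALSE
      )
    }
  }
  # intronic plants: inside long introns, margin from exon boundaries
  n_ig <- length(tars)
  for (gid in gene_ids) {
    if (length(tars) - n_ig >= config$n_tar_intronic) break
    ex <- genes[genes$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) next
    if (gid %in% annotation$small_rnas$host_gene) next
    gap_start <- ex$end[-nrow(ex)] + 100L
    gap_end <- ex$start[-1] - 100L
    ok <- which(gap_end - gap_start >= tar_width)
    if (length(ok) == 0) next
    i <- ok[length(ok)]
    tars[[length(tars) + 1]] <- data.frame(
      chrom = ex$chrom[1], start = gap_start[i],
      end = gap_start[i] + tar_width, strand = ex$strand[1],
      kind = "inTAR", stringsAsFactors = FALSE
    )
  }
  tars <- if (length(tars) > 0) {
    cbind(plant_id = sprintf("PTAR%02d", seq_along(tars)),
          do.call(rbind, tars))
  } else {
    data.frame(plant_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), kind = character(0),
               stringsAsFactors = FALSE)
  }
  tars$reads_per_window <- rep(config$tar_density * Tmin, nrow(tars))

  # UTR-extension plants on genes free of overlaps and snoRNA hosting
  plain <- span$gene_id[!span$gene_id %in%
                          c(annotation$small_rnas$host_gene,
                            grep("^GOV", span$gene_id, value = TRUE))]
  # overlapping-pair hosts are not plain either
  ov_hosts <- span$gene_id[vapply(seq_len(nrow(span)), function(i) {
    any(span$chrom == span$chrom[i] & span$strand == span$strand[i] &
        span$gene_id != span$gene_id[i] &
        span$start < span$end[i] & span$end > span$start[i])
  }, logical(1))]
  plain <- setdiff(plain, ov_hosts)
  n_utr <- min(config$n_utr_genes, length(plain))
  utr_ids <- sample(plain, n_utr)
  sides <- rep(c("3p", "5p"), length.out = n_utr)
  status <- rep("common", n_utr)
  if (n_utr >= 2) {
    status[n_utr - 1] <- paste0(config$samples[1], "_specific")
    status[n_utr] <- paste0(config$samples[2], "_specific")
  }
  utr <- do.call(rbind, lapply(seq_len(n_utr), function(i) {
    s <- span[span$gene_id == utr_ids[i], , drop = FALSE]
    plus <- s$strand == "+"
    right <- (sides[i] == "3p") == plus  # window on the right flank?
    data.frame(
      gene_id = utr_ids[i], side = sides[i], chrom = s$chrom,
      start = if (right) s$end else s$start - config$utr_window,
      end = if (right) s$end + config$utr_window else s$start,
      strand = s$strand, status = status[i], stringsAsFactors = FALSE
    )
  }))
  if (is.null(utr)) {
    utr <- data.frame(gene_id = character(0), side = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      status = character(0), stringsAsFactors = FALSE)
  }

  # planted junctions need hosts with >= 3 exons: skip junctions
  # (exon i -> exon i+2) give multiple-donor/acceptor events and,
  # separately, sample-specific junctions
  rich <- names(which(table(genes$gene_id) >= 3))
  rich <- sample(rich, min(length(rich),
                           config$n_ase_junctions +
                             config$n_sample_specific_junctions))
  skip_key <- function(gid, at) {
    ex <- genes[genes$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    o <- .orient_junction(ex$strand[1], ex$end[at], ex$start[at + 2])
    data.frame(gene_id = gid, chrom = ex$chrom[1], strand = ex$strand[1],
               donor_end = o$donor_end,
               acceptor_start = o$acceptor_start,
               stringsAsFactors = FALSE)
  }
  # the adjacent junction sharing the skip junction's donor site, so a
  # planted skip always yields a multiple-donor event
  partner_key <- function(gid, at) {
    ex <- genes[genes$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (ex$strand[1] == "+") {
      o <- .orient_junction("+", ex$end[at], ex$start[at + 1])
    } else {
      o <- .orient_junction("-", ex$end[at + 1], ex$start[at + 2])
    }
    data.frame(gene_id = gid, chrom = ex$chrom[1], strand = ex$strand[1],
               donor_end = o$donor_end,
               acceptor_start = o$acceptor_start,
               stringsAsFactors = FALSE)
  }
  n_ase <- min(config$n_ase_junctions, length(rich))
  ase <- do.call(rbind, lapply(utils::head(rich, n_ase),
                               function(g) skip_key(g, 1L)))
  ase_partners <- do.call(rbind, lapply(utils::head(rich, n_ase),
                                        function(g) partner_key(g, 1L)))
  rest <- utils::tail(rich, max(0, length(rich) - n_ase))
  n_sp <- min(config$n_sample_specific_junctions, length(rest))
  spj <- do.call(rbind, lapply(utils::head(rest, n_sp),
                               function(g) skip_key(g, 1L)))
  if (!is.null(spj) && nrow(spj) > 0) {
    spj$specific_to <- rep(config$samples, length.out = nrow(spj))
  } else {
    spj <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), donor_end = integer(0),
                      acceptor_start = integer(0),
                      specific_to = character(0),
                      stringsAsFactors = FALSE)
  }
  if (is.null(ase)) {
    ase <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), donor_end = integer(0),
                      acceptor_start = integer(0),
                      stringsAsFactors = FALSE)
    ase_partners <- ase
  }

  truth <- list(
    gene_expr = expr,
    gene_spans = span,
    tars = tars,
    utr = utr,
    ase_junctions = ase,
    ase_partner_junctions = ase_partners,
    specific_junctions = spj,
    trisomic_chromosome = config$trisomic_chromosome,
    dosage = config$dosage,
    samples = config$samples
  )
  class(truth) <- c("sim_truth", "list")
  truth
}

# expected genome read count of one gene in one sample
.gene_mu <- function(base_rpkm, fold, length_nt, lib_size) {
  base_rpkm * fold * length_nt * lib_size / 1e9
}

#' Simulate mapped reads and junction counts for both samples
#'
#' Per-gene genome read counts are Poisson with mean proportional to
#' expression x model length x library size (dosage applied to genes on
#' the trisomic chromosome in sample A, planted fold changes likewise);
#' read 5' starts are uniform over exonic positions on the gene strand
#' and reads extend `read_length` nt in the transcription direction.
#' snoRNA-like loci, planted TAR clusters, fixed-count UTR-flank
#' plants, genomic background and the junction count profiles
#' (annotated junctions proportional to expression, planted exon-skip
#' and sample-specific junctions) are added on top.
#'
#' @param annotation output of [simulate_annotation()]
#' @param truth output of [simulate_truth()]
#' @param config a `sim_config`
#' @return list with `reads` (chrom/start/end/strand/sample) and
#'   `junction_counts` (chrom/strand/donor_end/acceptor_start/sample/
#'   count)
#' @export
simulate_reads <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genes <- annotation$genes
  samples <- config$samples
  N <- config$library_size
  RL <- config$read_length
  tri <- config$trisomic_chromosome
  sizes <- config$chromosomes
  reads <- list()

  emit <- function(chrom, pos, strand, sample) {
    if (length(pos) == 0) return()
    if (strand == "+") {
      start <- pos
      end <- pmin(as.integer(sizes[[chrom]]), pos + RL)
    } else {
      start <- pmax(0L, pos - RL + 1L)
      end <- pos + 1L
    }
    reads[[length(reads) + 1]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand, sample = sample, stringsAsFactors = FALSE
    )
  }

  sample_exonic <- function(ex, n) {
    # uniform over model positions, mapped back to genomic coordinates
    len <- ex$end - ex$start
    offs <- sample.int(sum(len), n, replace = TRUE) - 1L
    cum <- cumsum(len)
    exi <- findInterval(offs, c(0L, cum), rightmost.closed = FALSE)
    ex$start[exi] + (offs - c(0L, cum)[exi])
  }

  for (s in samples) {
    is_case <- s == samples[1]
    # gene-derived reads
    for (gid in unique(genes$gene_id)) {
      ex <- genes[genes$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      row <- truth$gene_expr[truth$gene_expr$gene_id == gid, ]
      fold <- if (is_case) row$fold_A else 1
      dos <- if (is_case && ex$chrom[1] == tri) config$dosage else 1
      mu <- .gene_mu(row$base_rpkm, fold * dos, sum(ex$end - ex$start), N)
      n <- stats::rpois(1, mu)
      if (n > 0) {
        pos <- sample_exonic(ex, n)
        st <- rep(ex$strand[1], n)
        if (config$antisense_rate > 0) {
          flip <- stats::runif(n) < config$antisense_rate
          st[flip] <- ifelse(st[flip] == "+", "-", "+")
        }
        for (u in unique(st)) emit(ex$chrom[1], pos[st == u], u, s)
      }
    }
    # snoRNA-like loci
    for (i in seq_len(nrow(annotation$small_rnas))) {
      sr <- annotation$small_rnas[i, ]
      dos <- if (is_case && sr$chrom == tri) config$dosage else 1
      mu <- .gene_mu(config$small_rna_rpkm, dos, sr$end - sr$start, N)
      n <- stats::rpois(1, mu)
      if (n > 0) {
        pos <- sr$start + sample.int(sr$end - sr$start, n,
                                     replace = TRUE) - 1L
        emit(sr$chrom, pos, sr$strand, s)
      }
    }
    # planted TAR clusters: half the pooled per-window density each
    for (i in seq_len(nrow(truth$tars))) {
      ta <- truth$tars[i, ]
      mu <- ta$reads_per_window / 2 *
        (ta$end - ta$start) / config$tar_window
      n <- stats::rpois(1, mu)
      if (n > 0) {
        pos <- ta$start + sample.int(ta$end - ta$start, n,
                                     replace = TRUE) - 1L
        emit(ta$chrom, pos, ta$strand, s)
      }
    }
    # UTR-extension plants: exact counts define the truth signal
    for (i in seq_len(nrow(truth$utr))) {
      u <- truth$utr[i, ]
      wanted <- u$status == "common" ||
        u$status == paste0(s, "_specific")
      if (!wanted) next
      pos <- u$start + sample.int(u$end - u$start, config$utr_reads,
                                  replace = TRUE) - 1L
      emit(u$chrom, pos, u$strand, s)
    }
    # genomic background
    for (chrom in names(sizes)) {
      for (st in c("+", "-")) {
        n <- stats::rpois(1, config$background_rate * sizes[[chrom]])
        if (n > 0) {
          pos <- sample.int(sizes[[chrom]], n, replace = TRUE) - 1L
          emit(chrom, pos, st, s)
        }
      }
    }
  }
  reads <- if (length(reads) > 0) {
    do.call(rbind, reads)
  } else {
    data.frame(chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               sample = character(0), stringsAsFactors = FALSE)
  }
  rownames(reads) <- NULL

  # junction counts: annotated adjacent junctions ~ expression
  jc <- list()
  for (s in samples) {
    is_case <- s == samples[1]
    for (gid in unique(genes$gene_id)) {
      ex <- genes[genes$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) < 2) next
      row <- truth$gene_expr[truth$gene_expr$gene_id == gid, ]
      fold <- if (is_case) row$fold_A else 1
      dos <- if (is_case && ex$chrom[1] == tri) config$dosage else 1
      mu <- .gene_mu(row$base_rpkm, fold * dos,
                     sum(ex$end - ex$start), N) * config$junction_rate
      o <- .orient_junction(ex$strand[1], ex$end[-nrow(ex)],
                            ex$start[-1])
      cnt <- stats::rpois(nrow(o), mu)
      keep <- cnt > 0
      if (any(keep)) {
        jc[[length(jc) + 1]] <- data.frame(
          chrom = ex$chrom[1], strand = ex$strand[1],
          donor_end = o$donor_end[keep],
          acceptor_start = o$acceptor_start[keep],
          sample = s, count = cnt[keep], stringsAsFactors = FALSE
        )
      }
    }
    # planted exon-skip (ASE) junctions plus the adjacent junction
    # sharing their donor site: both samples
    planted_ase <- rbind(
      truth$ase_junctions[, c("chrom", "strand", "donor_end",
                              "acceptor_start")],
      truth$ase_partner_junctions[, c("chrom", "strand", "donor_end",
                                      "acceptor_start")]
    )
    if (nrow(planted_ase) > 0) {
      planted_ase$sample <- s
      planted_ase$count <- config$ase_junction_reads
      jc[[length(jc) + 1]] <- planted_ase
    }
    # planted sample-specific junctions: reads in one sample only
    spj <- truth$specific_junctions
    spj <- spj[spj$specific_to == s, , drop = FALSE]
    if (nrow(spj) > 0) {
      jc[[length(jc) + 1]] <- data.frame(
        chrom = spj$chrom, strand = spj$strand,
        donor_end = spj$donor_end,
        acceptor_start = spj$acceptor_start,
        sample = s, count = config$specific_junction_reads,
        stringsAsFactors = FALSE
      )
    }
  }
  junction_counts <- if (length(jc) > 0) {
    do.call(rbind, jc)
  } else {
    data.frame(chrom = character(0), strand = character(0),
               donor_end = integer(0), acceptor_start = integer(0),
               sample = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(junction_counts) <- NULL
  list(reads = reads, junction_counts = junction_counts)
}

#' Simulate a complete two-sample dataset
#'
#' Convenience wrapper: annotation, truth and reads in one call.
#'
#' @param config a `sim_config`
#' @return list with `annotation`, `truth`, `reads`,
#'   `junction_counts`, `chrom_sizes` and `config`
#' @export
simulate_dataset <- function(config = sim_config()) {
  annotation <- simulate_annotation(config)
  truth <- simulate_truth(annotation, config)
  rd <- simulate_reads(annotation, truth, config)
  list(annotation = annotation, truth = truth, reads = rd$reads,
       junction_counts = rd$junction_counts,
       chrom_sizes = config$chromosomes, config = config)
}

#' Serialize a truth set to JSON
#'
#' @param truth a `sim_truth`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  obj <- unclass(truth)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a truth set written by [write_truth()]
#' @param path JSON file path
#' @return a `sim_truth` list
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("gene_expr", "gene_spans", "tars", "utr",
               "ase_junctions", "ase_partner_junctions",
               "specific_junctions")) {
    if (!is.null(obj[[nm]])) {
      obj[[nm]] <- as.data.frame(obj[[nm]], stringsAsFactors = FALSE)
    }
  }
  class(obj) <- c("sim_truth", "list")
  obj
}
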