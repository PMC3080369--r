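# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (per-base / per-window loops)
# and share no code with the package implementation.

mk_reads <- function(chrom, start, strand, sample = "A", len = 50L) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(start + len),
             strand = rep_len(strand, n),
             sample = rep_len(sample, n), stringsAsFactors = FALSE)
}

# reads placed by their 5' position (pos is the 5'-most base)
mk_reads5 <- function(chrom, pos, strand, sample = "A", len = 50L) {
  n <- length(pos)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", pos, pos - len + 1L)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(start + len), strand = strand,
             sample = rep_len(sample, n), stringsAsFactors = FALSE)
}

mk_gene <- function(gene_id, chrom, starts, ends, strand) {
  data.frame(gene_id = gene_id, transcript_id = gene_id, chrom = chrom,
             start = as.integer(starts), end = as.integer(ends),
             strand = strand, stringsAsFactors = FALSE)
}

# Brute-force TAR refinement: explicit window loop over one region.
# pos are pooled read 5' starts on the region's strand/chromosome.
bf_refine_region <- function(pos, region_start, region_end, W, T) {
  pos <- sort(pos[pos >= region_start & pos < region_end])
  win_starts <- seq(region_start, region_end - 1, by = W)
  qual <- logical(length(win_starts))
  for (i in seq_along(win_starts)) {
    ws <- win_starts[i]
    we <- min(ws + W, region_end)
    qual[i] <- sum(pos >= ws & pos < we) >= T
  }
  out <- NULL
  i <- 1
  while (i <= length(qual)) {
    if (qual[i]) {
      j <- i
      while (j < length(qual) && qual[j + 1]) j <- j + 1
      ws <- win_starts[i]
      we <- min(win_starts[j] + W, region_end)
      inside <- pos[pos >= ws & pos < we]
      out <- rbind(out, data.frame(start = min(inside),
                                   end = max(inside) + 1L,
                                   count = length(inside)))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Brute-force Benjamini-Hochberg step-up
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  # step-up: running minimum from the largest rank down
  if (n > 1) {
    for (i in (n - 1):1) {
      q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
    }
  }
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force ASE grouping by exhaustive pair scan
bf_ase_groups <- function(junc, count_col, T1) {
  rel <- junc[junc[[count_col]] >= T1, , drop = FALSE]
  groups <- list()
  if (nrow(rel) >= 2) {
    for (site_col in c("donor_end", "acceptor_start")) {
      type <- if (site_col == "donor_end") "multiple_donor"
              else "multiple_acceptor"
      seen <- character(0)
      for (i in seq_len(nrow(rel) - 1)) {
        for (j in (i + 1):nrow(rel)) {
          if (rel$locus_id[i] == rel$locus_id[j] &&
              rel[[site_col]][i] == rel[[site_col]][j]) {
            key <- paste(rel$locus_id[i], type, rel[[site_col]][i])
            if (!key %in% seen) {
              seen <- c(seen, key)
              members <- which(rel$locus_id == rel$locus_id[i] &
                               rel[[site_col]] == rel[[site_col]][i])
              groups[[key]] <- data.frame(
                locus_id = rel$locus_id[i], type = type,
                shared_site = rel[[site_col]][i],
                n_junctions = length(members),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(groups) == 0) {
    return(data.frame(locus_id = character(0), type = character(0),
                      shared_site = integer(0),
                      n_junctions = integer(0)))
  }
  out <- do.call(rbind, groups)
  rownames(out) <- NULL
  out[order(out$locus_id, out$type, out$shared_site), , drop = FALSE]
}

# Brute-force per-base pileup of read intervals
bf_pileup <- function(reads, chrom_len) {
  cov <- integer(chrom_len)
  for (i in seq_len(nrow(reads))) {
    ix <- (reads$start[i] + 1):reads$end[i]
    cov[ix] <- cov[ix] + 1L
  }
  cov
}

# small, fast simulation config for pipeline-level tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    chromosomes = c(chr1 = 300000L, chr2 = 300000L, chr21 = 200000L),
    genes_per_chromosome = c(12L, 12L, 6L),
    n_de_genes = 4L, n_small_rnas = 3L,
    n_tar_intronic = 2L, n_tar_intergenic = 2L,
    n_utr_genes = 4L, n_ase_junctions = 2L,
    n_sample_specific_junctions = 2L,
    library_size = 5e4,
    ...
  )
}
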