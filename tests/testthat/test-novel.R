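# TAR refinement, per-sample TAR activity, UTR-extension windows and
# ORF scanning.

one_region <- function(start, end, strand = "+", kind = "igR") {
  data.frame(region_id = "igR000001", chrom = "chr1", start = start,
             end = end, strand = strand, kind = kind,
             host_locus_id = NA_character_, stringsAsFactors = FALSE)
}

test_that("TAR refinement: empty region, dense window, T boundary", {
  reg <- one_region(0, 2000)
  expect_equal(nrow(refine_tars(mk_reads("chr1", integer(0), "+"),
                                reg)), 0)
  # 40 starts uniform in [600, 900): one TAR trimmed to the reads
  set.seed(1)
  pos <- sample(600:899, 40, replace = TRUE)
  reads <- mk_reads5("chr1", pos, "+")
  tars <- refine_tars(reads, reg, W = 500, T = 30)
  expect_equal(nrow(tars), 1)
  expect_equal(tars$start, min(pos))
  expect_equal(tars$end, max(pos) + 1)
  expect_gte(tars$start, 500)
  expect_lte(tars$end, 1000)
  expect_equal(tars$kind, "igTAR")
  # exactly T starts qualify, T - 1 do not
  r30 <- mk_reads5("chr1", 100 + seq_len(30), "+")
  expect_equal(nrow(refine_tars(r30, reg, W = 500, T = 30)), 1)
  expect_equal(nrow(refine_tars(r30[1:29, ], reg, W = 500, T = 30)), 0)
  expect_error(refine_tars(r30, reg, W = 0, T = 30))
  expect_error(refine_tars(r30, reg, W = 500, T = 0))
})

test_that("TAR refinement matches the brute-force window scan", {
  set.seed(42)
  for (rep in 1:20) {
    W <- sample(100:1000, 1)
    T <- sample(5:50, 1)
    reg_len <- sample(2000:50000, 1)
    reg <- one_region(0, reg_len,
                      kind = sample(c("igR", "inR"), 1))
    n <- sample(c(0, 50, 500, 2000), 1)
    pos <- sort(sample(0:(reg_len - 1), n, replace = TRUE))
    reads <- mk_reads5("chr1", pos, "+")
    got <- refine_tars(reads, reg, W = W, T = T)
    want <- bf_refine_region(pos, 0, reg_len, W, T)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$pooled_count, want$count)
    }
  }
})

test_that("TARs stay inside their parent region and inherit kind", {
  set.seed(7)
  regions <- rbind(one_region(1000, 9000, "+", "inR"),
                   one_region(20000, 26000, "-", "igR"))
  regions$region_id <- c("inR000001", "igR000001")
  regions$host_locus_id <- c("LOC00001", NA)
  reads <- rbind(
    mk_reads5("chr1", sample(2000:2400, 80, TRUE), "+"),
    mk_reads5("chr1", sample(21000:21400, 80, TRUE), "-")
  )
  tars <- refine_tars(reads, regions, W = 500, T = 30)
  expect_equal(nrow(tars), 2)
  for (i in seq_len(nrow(tars))) {
    parent <- regions[regions$region_id == tars$parent_region_id[i], ]
    expect_gte(tars$start[i], parent$start)
    expect_lte(tars$end[i], parent$end)
    expect_equal(tars$strand[i], parent$strand)
  }
  expect_setequal(tars$kind, c("inTAR", "igTAR"))
  expect_equal(tars$host_locus_id[tars$kind == "inTAR"], "LOC00001")
})

test_that("per-sample TAR activity and specificity", {
  reg <- one_region(0, 2000)
  pos <- 600 + seq_len(40)
  reads <- rbind(mk_reads5("chr1", pos, "+", "A"),
                 mk_reads5("chr1", pos[1:2], "+", "B"))
  tars <- refine_tars(reads, reg, W = 500, T = 30)
  q <- quantify_tars(reads, tars, samples = c("A", "B"))
  expect_equal(q$count_A, 40)
  expect_equal(q$count_B, 2)
  expect_equal(q$status, "common")
  # all pooled reads from A: A-specific
  only_a <- mk_reads5("chr1", pos, "+", "A")
  t2 <- refine_tars(only_a, reg, W = 500, T = 30)
  q2 <- quantify_tars(only_a, t2, samples = c("A", "B"))
  expect_equal(q2$status, "A_specific")
})

test_that("UTR windows call planted flank signal with the strand rule", {
  rv <- revise_annotation(mk_gene("G", "chr1", 1000, 2000, "+"))
  # 10 same-strand starts in the 3' window [2000, 2150)
  reads <- rbind(mk_reads5("chr1", 2010 + seq_len(10) * 10, "+", "A"),
                 mk_reads5("chr1", 2010 + seq_len(10) * 10, "-", "B"))
  calls <- detect_utr_extensions(reads, rv, window = 150,
                                 min_reads = 5,
                                 samples = c("A", "B"))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$side, "3p")
  expect_equal(calls$start, 2000)
  expect_equal(calls$end, 2150)
  expect_equal(calls$count_A, 10)
  expect_equal(calls$count_B, 0)  # antisense reads do not count
  expect_equal(calls$status, "A_specific")
  # no reads: no call
  empty <- detect_utr_extensions(mk_reads("chr1", integer(0), "+"),
                                 rv, samples = c("A", "B"))
  expect_equal(nrow(empty), 0)
})

test_that("UTR windows are strand-oriented and clipped at bounds", {
  rv <- revise_annotation(mk_gene("G", "chr1", 100, 500, "-"))
  # minus strand: 3' window is upstream [start-150, start)
  reads <- mk_reads5("chr1", 40 + seq_len(8) * 5, "-", "A")
  calls <- detect_utr_extensions(reads, rv,
                                 chrom_sizes = c(chr1 = 10000L),
                                 min_reads = 5, samples = c("A", "B"))
  expect_equal(calls$side, "3p")
  expect_equal(calls$start, 0)   # clipped at the chromosome start
  expect_equal(calls$end, 100)
})

test_that("ORF scan honours the 200-nt boundary and both strands", {
  pad <- function(n) paste(rep("GCA", n), collapse = "")
  orf210 <- paste0("ATG", pad(68), "TAA")      # 210 nt
  orf198 <- paste0("ATG", pad(64), "TAA")      # 198 nt
  seq210 <- paste0(pad(10), orf210, pad(10))
  seq198 <- paste0(pad(10), orf198, pad(10))
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  tars <- data.frame(
    tar_id = c("T1", "T2", "T3", "T4"),
    chrom = c("c1", "c2", "c3", "c4"),
    start = 0L,
    end = nchar(c(seq210, seq198, pad(100), revcomp(seq210))),
    strand = "+",
    kind = c("inTAR", "inTAR", "inTAR", "igTAR"),
    host_locus_id = NA, stringsAsFactors = FALSE)
  genome <- c(c1 = seq210, c2 = seq198, c3 = pad(100),
              c4 = revcomp(seq210))
  hits <- scan_orfs(tars, genome, min_orf = 200)
  expect_equal(hits$tar_id, c("T1", "T4"))
  expect_equal(hits$length, c(210, 210))
  expect_equal(hits$start[1], 30)
  expect_equal(hits$end[1], 240)
  # igTAR found on the reverse strand
  expect_equal(hits$strand[2], "-")
  # missing chromosome is an error entry, others proceed
  hits2 <- scan_orfs(tars, genome[c("c1", "c2", "c3")])
  expect_equal(length(attr(hits2, "errors")), 1)
  expect_equal(hits2$tar_id, "T1")
})

test_that("repeat filter drops TARs covered at or above the cutoff", {
  tars <- data.frame(tar_id = c("T1", "T2"), chrom = "chr1",
                     start = c(0L, 1000L), end = c(100L, 1100L),
                     strand = "+", kind = "igTAR",
                     host_locus_id = NA, stringsAsFactors = FALSE)
  mask <- data.frame(chrom = "chr1", start = 0, end = 60)
  out <- filter_tars_by_repeats(tars, mask, max_frac = 0.5)
  expect_equal(out$tar_id, "T2")
})
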