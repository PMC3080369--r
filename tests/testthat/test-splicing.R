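# Junction tallies, reliability, alternative-splicing events,
# sample-specific calls and annotation status.

lib4 <- build_junction_library(revise_annotation(
  mk_gene("A", "chr1", c(100, 300, 500, 700),
          c(200, 400, 600, 800), "+")))

jread <- function(donor, acceptor, sample, count = 1L) {
  data.frame(chrom = "chr1", strand = "+", donor_end = donor,
             acceptor_start = acceptor, sample = sample,
             count = count, stringsAsFactors = FALSE)
}

test_that("junction tallies are exact and zero rows are omitted", {
  reads <- rbind(jread(200, 300, "A", 7),
                 jread(200, 500, "A", 2), jread(200, 500, "A", 1),
                 jread(400, 500, "B", 4))
  rec <- count_junctions(reads, lib4, samples = c("A", "B"))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$count_A[rec$donor_end == 200 &
                             rec$acceptor_start == 300], 7)
  expect_equal(rec$count_A[rec$donor_end == 200 &
                             rec$acceptor_start == 500], 3)
  expect_equal(rec$count_B[rec$donor_end == 400], 4)
  # no reads -> empty output
  expect_equal(nrow(count_junctions(jread(200, 300, "A", 0)[0, ],
                                    lib4, samples = c("A", "B"))), 0)
  # unresolvable records are excluded and reported
  bad <- rbind(jread(200, 300, "A", 2), jread(201, 300, "A", 5))
  expect_message(rec2 <- count_junctions(bad, lib4,
                                         samples = c("A", "B")))
  expect_equal(nrow(attr(rec2, "unresolved")), 1)
  expect_equal(sum(rec2$count_A), 2)
})

test_that("multiple donor/acceptor grouping of reliable junctions", {
  reads <- rbind(jread(200, 300, "A", 6),   # e1 -> e2
                 jread(200, 500, "A", 8),   # e1 -> e3 shares donor
                 jread(400, 500, "A", 1))   # unreliable
  rec <- count_junctions(reads, lib4, samples = c("A", "B"))
  groups <- detect_ase(rec, "A", T1 = 5)
  expect_equal(nrow(groups), 1)
  expect_equal(groups$type, "multiple_donor")
  expect_equal(groups$shared_site, 200)
  expect_equal(groups$n_junctions, 2)
  # shared acceptor
  acc <- rbind(jread(200, 500, "A", 6), jread(400, 500, "A", 9))
  ga <- detect_ase(count_junctions(acc, lib4, samples = c("A", "B")),
                   "A", T1 = 5)
  expect_equal(ga$type, "multiple_acceptor")
  # a single reliable junction yields nothing
  one <- detect_ase(count_junctions(jread(200, 300, "A", 9), lib4,
                                    samples = c("A", "B")), "A")
  expect_equal(nrow(one), 0)
})

test_that("ASE grouping matches a pairwise brute-force grouper", {
  set.seed(12)
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    donors <- sample(c(200, 400, 600), n, replace = TRUE)
    acceptors <- vapply(donors, function(d) {
      opts <- seq(d + 100, 700, by = 200)
      opts[sample.int(length(opts), 1)]
    }, numeric(1))
    reads <- do.call(rbind, lapply(seq_len(n), function(i)
      jread(donors[i], acceptors[i], "A", sample(0:9, 1))))
    rec <- count_junctions(reads, lib4, samples = c("A", "B"))
    T1 <- sample(c(3, 5), 1)
    got <- detect_ase(rec, "A", T1 = T1)
    want <- bf_ase_groups(rec, "count_A", T1)
    expect_equal(got[, c("locus_id", "type", "shared_site",
                         "n_junctions")],
                 want, ignore_attr = TRUE)
  }
})

test_that("sample-specific junctions follow the zero-hit rule", {
  reads <- rbind(jread(200, 300, "A", 7),                # A-specific
                 jread(200, 500, "A", 7), jread(200, 500, "B", 1),
                 jread(400, 500, "A", 4),                # below T1
                 jread(400, 700, "B", 6))                # B-specific
  rec <- count_junctions(reads, lib4, samples = c("A", "B"))
  out <- sample_specific_junctions(rec, T1 = 5, samples = c("A", "B"))
  spec <- out$specific
  expect_equal(spec[out$donor_end == 200 & out$acceptor_start == 300],
               "A")
  expect_true(is.na(spec[out$donor_end == 200 &
                           out$acceptor_start == 500]))
  expect_true(is.na(spec[out$donor_end == 400 &
                           out$acceptor_start == 500]))
  expect_equal(spec[out$donor_end == 400 & out$acceptor_start == 700],
               "B")
  sets <- attr(out, "sets")
  expect_equal(nrow(sets$A), 1)
  expect_equal(nrow(sets$B), 1)
})

test_that("specific-set assignment matches the rule exhaustively", {
  for (T1 in c(3, 5)) {
    for (a in 0:10) {
      for (b in 0:10) {
        rec <- lib4[1, ]
        rec$count_A <- a
        rec$count_B <- b
        out <- sample_specific_junctions(rec, T1 = T1,
                                         samples = c("A", "B"))
        want <- if (a >= T1 && b == 0) "A"
                else if (b >= T1 && a == 0) "B"
                else NA_character_
        expect_identical(out$specific, want)
      }
    }
  }
})

test_that("raising T1 never enlarges reliable or ASE sets", {
  set.seed(3)
  reads <- do.call(rbind, lapply(1:30, function(i)
    jread(sample(c(200, 400, 600), 1),
          sample(c(300, 500, 700), 1), sample(c("A", "B"), 1),
          sample(1:10, 1))))
  reads <- reads[reads$acceptor_start > reads$donor_end, ]
  rec <- count_junctions(reads, lib4, samples = c("A", "B"))
  sizes <- vapply(1:8, function(T1)
    nrow(detect_ase(rec, "A", T1 = T1)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  rel <- vapply(1:8, function(T1) sum(rec$count_A >= T1), integer(1))
  expect_true(all(diff(rel) <= 0))
})

test_that("annotation status uses first-match precedence", {
  rec <- lib4[1:3, ]
  key1 <- rec[1, c("chrom", "strand", "donor_end", "acceptor_start")]
  sets <- list(refseq = key1, ensembl = rec[1:2, c("chrom", "strand",
                                                   "donor_end",
                                                   "acceptor_start")])
  out <- classify_junction_status(rec, sets)
  expect_equal(out$db_status, c("refseq", "ensembl",
                                "combinatorial_novel"))
  none <- classify_junction_status(rec, list())
  expect_true(all(none$db_status == "combinatorial_novel"))
})
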