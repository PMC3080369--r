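# Annotation revision, region derivation, masks and junction library.

test_that("disjoint single-exon genes stay separate loci", {
  gm <- rbind(mk_gene("A", "chr1", 100, 300, "+"),
              mk_gene("B", "chr1", 1000, 1200, "+"))
  r <- revise_annotation(gm)
  expect_equal(nrow(r$loci), 2)
  expect_equal(nrow(r$elements), 2)
  expect_setequal(r$loci$genes, c("A", "B"))
})

test_that("overlapping same-strand genes merge with boundary fragmentation", {
  gm <- rbind(mk_gene("A", "chr1", 100, 300, "+"),
              mk_gene("B", "chr1", 200, 400, "+"))
  r <- revise_annotation(gm)
  expect_equal(nrow(r$loci), 1)
  expect_equal(r$loci$genes, "A,B")
  expect_equal(r$elements$start, c(100, 200, 300))
  expect_equal(r$elements$end, c(200, 300, 400))
  expect_equal(r$loci$model_length, 300)
})

test_that("antisense overlaps are kept as separate loci", {
  gm <- rbind(mk_gene("A", "chr1", 100, 300, "+"),
              mk_gene("B", "chr1", 200, 400, "-"))
  r <- revise_annotation(gm)
  expect_equal(nrow(r$loci), 2)
  expect_true(all(r$loci$genes %in% c("A", "B")))
})

test_that("malformed exon rows are rejected with a reason", {
  gm <- rbind(mk_gene("A", "chr1", 100, 300, "+"),
              mk_gene("B", "chr1", 500, 400, "+"),
              mk_gene("C", "chr1", 700, 900, "."))
  r <- revise_annotation(gm)
  expect_equal(nrow(r$rejected), 2)
  expect_setequal(r$rejected$reason, c("end <= start", "bad strand"))
  expect_equal(nrow(r$loci), 1)
})

test_that("revision is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    gm <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(0:5000, 1)
      k <- sample(1:3, 1)
      starts <- s + cumsum(c(0, rep(300, k - 1)))
      mk_gene(sprintf("G%d", i), "chr1", starts, starts + 150,
              sample(c("+", "-"), 1))
    }))
    r1 <- revise_annotation(gm)
    again <- data.frame(gene_id = r1$elements$locus_id,
                        chrom = r1$elements$chrom,
                        start = r1$elements$start,
                        end = r1$elements$end,
                        strand = r1$elements$strand,
                        stringsAsFactors = FALSE)
    r2 <- revise_annotation(again)
    expect_equal(r2$elements[, c("chrom", "start", "end", "strand")],
                 r1$elements[, c("chrom", "start", "end", "strand")])
    expect_equal(nrow(r2$loci), nrow(r1$loci))
  }
})

test_that("element union preserves the exon union per strand", {
  gm <- rbind(mk_gene("A", "chr1", c(100, 500), c(300, 800), "+"),
              mk_gene("B", "chr1", c(250, 700), c(600, 900), "+"))
  r <- revise_annotation(gm)
  # brute force: per-base union of input exons
  base_union <- rep(FALSE, 1000)
  for (i in seq_len(nrow(gm))) {
    base_union[(gm$start[i] + 1):gm$end[i]] <- TRUE
  }
  elem_union <- rep(FALSE, 1000)
  for (i in seq_len(nrow(r$elements))) {
    ix <- (r$elements$start[i] + 1):r$elements$end[i]
    expect_false(any(elem_union[ix]))  # non-overlap
    elem_union[ix] <- TRUE
  }
  expect_equal(elem_union, base_union)
})

test_that("intronic/intergenic derivation matches the complement", {
  gm <- mk_gene("A", "chr1", c(100, 300), c(200, 400), "+")
  r <- revise_annotation(gm)
  reg <- derive_nonannotated_regions(r, c(chr1 = 10000L))
  inr <- reg[reg$kind == "inR" & reg$strand == "+", ]
  igr <- reg[reg$kind == "igR" & reg$strand == "+", ]
  expect_equal(inr$start, 200)
  expect_equal(inr$end, 300)
  expect_equal(inr$host_locus_id, r$loci$locus_id)
  expect_equal(igr$start, c(0, 400))
  expect_equal(igr$end, c(100, 10000))
  # minus strand untouched by this annotation: one full igR
  minus <- reg[reg$strand == "-", ]
  expect_equal(minus$kind, "igR")
  expect_equal(minus$start, 0)
  expect_equal(minus$end, 10000)
})

test_that("empty annotation yields one igR per strand and locus bounds are checked", {
  r <- revise_annotation(mk_gene(character(0), character(0),
                                 integer(0), integer(0), character(0)))
  reg <- derive_nonannotated_regions(r, c(chr1 = 10000L))
  expect_equal(nrow(reg), 2)
  expect_true(all(reg$kind == "igR"))
  expect_equal(reg$end - reg$start, c(10000, 10000))

  r2 <- revise_annotation(mk_gene("A", "chr1", 100, 300, "+"))
  expect_error(derive_nonannotated_regions(r2, c(chr1 = 200L)),
               "beyond")
  expect_error(derive_nonannotated_regions(r2, c(chr9 = 1000L)),
               "missing")
})

test_that("single-exon loci contribute no intronic regions", {
  r <- revise_annotation(mk_gene("A", "chr1", 100, 300, "+"))
  reg <- derive_nonannotated_regions(r, c(chr1 = 1000L))
  expect_equal(sum(reg$kind == "inR"), 0)
})

test_that("elements, inR and igR tile each strand exactly", {
  ds <- simulate_dataset(small_sim_config(seed = 3))
  r <- revise_annotation(ds$annotation$genes)
  reg <- derive_nonannotated_regions(r, ds$chrom_sizes)
  for (chrom in names(ds$chrom_sizes)) {
    for (st in c("+", "-")) {
      e <- r$elements[r$elements$chrom == chrom &
                        r$elements$strand == st, ]
      g <- reg[reg$chrom == chrom & reg$strand == st, ]
      pieces <- rbind(e[, c("start", "end")], g[, c("start", "end")])
      pieces <- pieces[order(pieces$start), ]
      expect_equal(sum(pieces$end - pieces$start),
                   as.numeric(ds$chrom_sizes[[chrom]]))
      expect_equal(pieces$start[1], 0)
      expect_true(all(pieces$start[-1] == pieces$end[-nrow(pieces)]))
    }
  }
})

test_that("masking subtracts intervals and re-enumerates", {
  r <- revise_annotation(mk_gene("A", "chr2", 5000, 5100, "+"))
  reg <- derive_nonannotated_regions(r, c(chr2 = 10000L))
  # identity with no masks
  same <- apply_annotation_masks(reg, list())
  expect_equal(same[, names(reg)], reg)

  mask <- data.frame(chrom = "chr2", start = 200, end = 400)
  out <- apply_annotation_masks(reg, list(mask))
  plus_ig <- out[out$strand == "+" & out$kind == "igR", ]
  expect_equal(plus_ig$start, c(0, 400, 5100))
  expect_equal(plus_ig$end, c(200, 5000, 10000))
  # strand-agnostic mask cuts both strands
  minus_ig <- out[out$strand == "-", ]
  expect_equal(minus_ig$start, c(0, 400))
  # fully covered region removed
  cover <- data.frame(chrom = "chr2", start = 0, end = 10000)
  gone <- apply_annotation_masks(reg, list(cover))
  expect_equal(nrow(gone), 0)
})

test_that("junction library enumerates all element pairs", {
  gm3 <- mk_gene("A", "chr1", c(100, 300, 500), c(200, 400, 600), "+")
  lib3 <- build_junction_library(revise_annotation(gm3))
  expect_equal(nrow(lib3), 3)

  lib1 <- build_junction_library(
    revise_annotation(mk_gene("B", "chr1", 100, 200, "+")))
  expect_equal(nrow(lib1), 0)

  gm4 <- mk_gene("C", "chr1", c(100, 300, 500, 700),
                 c(200, 400, 600, 800), "+")
  lib4 <- build_junction_library(revise_annotation(gm4))
  expect_equal(nrow(lib4), 6)
  expect_equal(sum(lib4$status == "annotated_model"), 3)
  adj <- lib4[lib4$status == "annotated_model", ]
  expect_equal(sort(adj$donor_end), c(200, 400, 600))
})

test_that("minus-strand junction keys are mirrored", {
  gm <- mk_gene("A", "chr1", c(100, 300), c(200, 400), "-")
  lib <- build_junction_library(revise_annotation(gm))
  expect_equal(nrow(lib), 1)
  # donor is the transcriptionally upstream exon end: genomic right
  expect_equal(lib$donor_end, 300)
  expect_equal(lib$acceptor_start, 200)
  expect_true(lib$donor_end > lib$acceptor_start)
  expect_equal(lib$status, "annotated_model")
})

test_that("junction count law holds on simulated annotations", {
  ds <- simulate_dataset(small_sim_config(seed = 5))
  r <- revise_annotation(ds$annotation$genes)
  lib <- build_junction_library(r)
  k <- r$loci$n_elements
  expect_equal(nrow(lib), sum(k * (k - 1) / 2))
})
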