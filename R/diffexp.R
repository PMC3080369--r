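# Differential expression between two libraries without replicates:
# three exact count tests, BH adjustment, fold-change filtering and
# evidence-tier classification, plus the qRT-PCR 2^-ddCt utility.

#' Counts per million
#' @param count read count(s)
#' @param lib_size library size in mapped reads (> 0)
#' @return `1e6 * count / lib_size`
#' @export
normalize_cpm <- function(count, lib_size) {
  if (any(lib_size <= 0)) stop("lib_size must be > 0")
  1e6 * count / lib_size
}

# exact two-sided "minimum likelihood" p: sum of outcome probabilities
# not exceeding the observed outcome's (with the customary relative
# tolerance for ties)
.minlike_p <- function(dens, obs_index) {
  min(1, sum(dens[dens <= dens[obs_index] * (1 + 1e-7)]))
}

#' Exact conditional binomial test for two libraries
#'
#' Conditional on the total n = count_A + count_B, count_A is
#' Binomial(n, pi0) under the null of equal relative expression, with
#' pi0 = lib_A / (lib_A + lib_B). The two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param count_a,count_b feature read counts (vectorised)
#' @param lib_a,lib_b library sizes
#' @return p-value(s); 1 when n = 0
#' @export
binomial_two_library_test <- function(count_a, count_b, lib_a, lib_b) {
  if (any(count_a < 0) || any(count_b < 0)) {
    stop("counts must be non-negative")
  }
  n <- count_a + count_b
  p0 <- lib_a / (lib_a + lib_b)
  p0 <- rep_len(p0, length(n))
  vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(1)
    dens <- stats::dbinom(0:n[i], n[i], p0[i])
    .minlike_p(dens, count_a[i] + 1L)
  }, numeric(1))
}

#' Fisher exact test for two libraries
#'
#' Two-sided Fisher exact test on the 2x2 table of feature versus
#' remaining library counts.
#'
#' @inheritParams binomial_two_library_test
#' @return p-value(s)
#' @export
fisher_two_library_test <- function(count_a, count_b, lib_a, lib_b) {
  lib_a <- rep_len(lib_a, length(count_a))
  lib_b <- rep_len(lib_b, length(count_a))
  if (any(count_a > lib_a) || any(count_b > lib_b)) {
    stop("counts cannot exceed library sizes")
  }
  if (any(count_a < 0) || any(count_b < 0)) {
    stop("counts must be non-negative")
  }
  vapply(seq_along(count_a), function(i) {
    tab <- matrix(c(count_a[i], lib_a[i] - count_a[i],
                    count_b[i], lib_b[i] - count_b[i]),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
}

# beta-binomial density on log scale
.dbetabinom <- function(k, n, a, b) {
  exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Exact over-dispersed (negative-binomial) two-library test
#'
#' Models each library's feature count as a Gamma–Poisson (negative
#' binomial) with common over-dispersion `phi`; conditional on the
#' total n, count_A then follows a beta-binomial with mean
#' pi0 = lib_A / (lib_A + lib_B) and shape parameters pi0/phi and
#' (1 - pi0)/phi. At `phi = 0` the allocation collapses to the exact
#' binomial test.
#'
#' @inheritParams binomial_two_library_test
#' @param phi over-dispersion (>= 0; default 0.1)
#' @return p-value(s)
#' @export
nb_two_library_test <- function(count_a, count_b, lib_a, lib_b,
                                phi = 0.1) {
  if (phi < 0) stop("phi must be non-negative")
  if (phi == 0) {
    return(binomial_two_library_test(count_a, count_b, lib_a, lib_b))
  }
  n <- count_a + count_b
  p0 <- rep_len(lib_a / (lib_a + lib_b), length(n))
  a <- p0 / phi
  b <- (1 - p0) / phi
  vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(1)
    dens <- .dbetabinom(0:n[i], n[i], a[i], b[i])
    .minlike_p(dens, count_a[i] + 1L)
  }, numeric(1))
}

#' Benjamini–Hochberg step-up adjusted p-values
#' @param p vector of p-values in [0, 1]
#' @return q-values (monotone, clipped at 1)
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-library differential-expression test table
#'
#' Runs the three exact tests on every feature, BH-adjusts the
#' over-dispersed test's p-values (the conservative, DESeq-like arm of
#' the battery), and computes the fold change between the normalised
#' samples with a pseudocount.
#'
#' @param features data frame with `feature_id`, `count_A`, `count_B`
#' @param lib_a,lib_b library sizes for samples A and B
#' @param phi over-dispersion of the NB test
#' @param pseudocount added to each count for the fold change
#'   (default 0.5)
#' @return data frame with normalised counts, `log2fc`, `p_binomial`,
#'   `p_fisher`, `p_nb` and `q_nb`
#' @export
de_test_table <- function(features, lib_a, lib_b, phi = 0.1,
                          pseudocount = 0.5) {
  stopifnot(all(c("feature_id", "count_A", "count_B") %in%
                names(features)))
  out <- data.frame(
    feature_id = features$feature_id,
    count_A = features$count_A, count_B = features$count_B,
    lib_A = lib_a, lib_B = lib_b,
    norm_A = normalize_cpm(features$count_A, lib_a),
    norm_B = normalize_cpm(features$count_B, lib_b),
    stringsAsFactors = FALSE
  )
  out$log2fc <- log2(normalize_cpm(features$count_A + pseudocount,
                                   lib_a) /
                     normalize_cpm(features$count_B + pseudocount,
                                   lib_b))
  out$p_binomial <- binomial_two_library_test(features$count_A,
                                              features$count_B,
                                              lib_a, lib_b)
  out$p_fisher <- fisher_two_library_test(features$count_A,
                                          features$count_B,
                                          lib_a, lib_b)
  out$p_nb <- nb_two_library_test(features$count_A, features$count_B,
                                  lib_a, lib_b, phi = phi)
  out$q_nb <- bh_adjust(out$p_nb)
  out
}

#' Classify differential-expression evidence tiers
#'
#' Counts how many of the three tests pass their cutoff (adjusted q of
#' the over-dispersed test < `q_nb_cutoff`; raw p of the binomial and
#' Fisher tests < `p_cutoff`). Features meeting the fold-change
#' threshold are tiered strong/good/acceptable for 3/2/1 passing
#' tests; features significant in at least one test but below the
#' fold-change threshold are weak; everything else is no_change.
#'
#' @param de output of [de_test_table()]
#' @param q_nb_cutoff cutoff on `q_nb` (default 0.1)
#' @param p_cutoff cutoff on the raw binomial and Fisher p-values
#'   (default 1e-4)
#' @param fc_threshold fold-change threshold on the normalised samples
#'   (default 1.5)
#' @return `de` with `tests_passed`, `n_tests_passed` and `tier`
#'   (factor strong/good/acceptable/weak/no_change)
#' @export
classify_de <- function(de, q_nb_cutoff = 0.1, p_cutoff = 1e-4,
                        fc_threshold = 1.5) {
  pass_nb <- de$q_nb < q_nb_cutoff
  pass_bin <- de$p_binomial < p_cutoff
  pass_fis <- de$p_fisher < p_cutoff
  k <- pass_nb + pass_bin + pass_fis
  fc_ok <- 2^abs(de$log2fc) >= fc_threshold
  tier <- rep("no_change", nrow(de))
  tier[fc_ok & k == 1] <- "acceptable"
  tier[fc_ok & k == 2] <- "good"
  tier[fc_ok & k == 3] <- "strong"
  tier[!fc_ok & k >= 1] <- "weak"
  de$tests_passed <- vapply(seq_len(nrow(de)), function(i) {
    paste(c("nb", "binomial", "fisher")[c(pass_nb[i], pass_bin[i],
                                          pass_fis[i])],
          collapse = ",")
  }, character(1))
  de$n_tests_passed <- as.integer(k)
  de$tier <- factor(tier, levels = c("strong", "good", "acceptable",
                                     "weak", "no_change"))
  de
}

#' Relative expression from qRT-PCR threshold cycles (2^-ddCt)
#'
#' @param ct_target_case,ct_ref_case Ct of the target and reference
#'   gene in the case sample
#' @param ct_target_ctrl,ct_ref_ctrl Ct of the target and reference
#'   gene in the control sample
#' @return `2^-((ct_target_case - ct_ref_case) -
#'   (ct_target_ctrl - ct_ref_ctrl))`
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl,
                 ct_ref_ctrl) {
  ddct <- (ct_target_case - ct_ref_case) -
    (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
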