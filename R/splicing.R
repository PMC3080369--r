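# Junction counting against the combinatorial library, T1 reliability,
# alternative-splicing event detection, sample-specific junction
# calling and annotation-status classification.

#' Tally junction-mapped reads against the junction library
#'
#' @param junction_reads data frame with `chrom`, `strand`,
#'   `donor_end`, `acceptor_start`, `sample` and an optional `count`
#'   column (one read per row when absent)
#' @param library junction library from [build_junction_library()]
#' @param samples sample labels defining the count columns
#' @return data frame of junction records with non-zero totals:
#'   library columns plus one `count_<sample>` column per sample;
#'   unresolvable reads are dropped and reported in the `unresolved`
#'   attribute
#' @export
count_junctions <- function(junction_reads, library, samples = NULL) {
  if (is.null(samples)) {
    samples <- sort(unique(as.character(junction_reads$sample)))
  }
  jr <- as.data.frame(junction_reads, stringsAsFactors = FALSE)
  if (!"count" %in% names(jr)) jr$count <- 1L
  m <- match(.junction_key(jr), .junction_key(library))
  unresolved <- jr[is.na(m), , drop = FALSE]
  if (nrow(unresolved) > 0) {
    message(nrow(unresolved), " junction read record(s) did not match ",
            "the library and were excluded")
  }
  jr <- jr[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  records <- library
  for (s in samples) {
    cnt <- rep(0L, nrow(library))
    sel <- jr$sample == s
    if (any(sel)) {
      agg <- tapply(jr$count[sel], m[sel], sum)
      cnt[as.integer(names(agg))] <- as.integer(agg)
    }
    records[[paste0("count_", s)]] <- cnt
  }
  tot <- rowSums(as.matrix(records[, paste0("count_", samples),
                                   drop = FALSE]))
  out <- records[tot > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unresolved") <- unresolved
  out
}

#' Detect alternative-splicing events from reliable junctions
#'
#' Within each locus, junctions reliable in the given sample (count >=
#' T1) that share a donor coordinate form a multiple-donor event, and
#' those sharing an acceptor coordinate a multiple-acceptor event; a
#' pair sharing both yields two events.
#'
#' @param records junction records from [count_junctions()]
#' @param sample sample label under analysis
#' @param T1 reliability threshold in reads (default 5)
#' @return data frame `ase_id`, `locus_id`, `type`
#'   ("multiple_donor"/"multiple_acceptor"), `shared_site`,
#'   `n_junctions`, `junction_ids` (comma-separated)
#' @export
detect_ase <- function(records, sample, T1 = 5) {
  col <- paste0("count_", sample)
  stopifnot(col %in% names(records))
  rel <- records[records[[col]] >= T1, , drop = FALSE]
  empty <- data.frame(
    ase_id = character(0), locus_id = character(0), type = character(0),
    shared_site = integer(0), n_junctions = integer(0),
    junction_ids = character(0), stringsAsFactors = FALSE
  )
  if (nrow(rel) < 2) return(empty)
  group_by_site <- function(site_col, type) {
    key <- paste(rel$locus_id, rel[[site_col]], sep = "\r")
    sp <- split(seq_len(nrow(rel)), key)
    sp <- sp[lengths(sp) >= 2]
    if (length(sp) == 0) return(NULL)
    do.call(rbind, lapply(sp, function(ix) {
      data.frame(
        locus_id = rel$locus_id[ix[1]], type = type,
        shared_site = rel[[site_col]][ix[1]],
        n_junctions = length(ix),
        junction_ids = paste(sort(rel$junction_id[ix]), collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  }
  out <- rbind(group_by_site("donor_end", "multiple_donor"),
               group_by_site("acceptor_start", "multiple_acceptor"))
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[order(out$locus_id, out$type, out$shared_site), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$ase_id <- sprintf("ASE%05d", seq_len(nrow(out)))
  out[, c("ase_id", "locus_id", "type", "shared_site", "n_junctions",
          "junction_ids")]
}

#' Call sample-specific junctions
#'
#' A junction is specific to one sample when it is reliable there
#' (count >= T1) and received zero reads in the other sample; any
#' number of hits in the other sample — even below T1 — removes it
#' from both specific sets, avoiding a threshold-dependent exclusion.
#'
#' @param records junction records from [count_junctions()]
#' @param T1 reliability threshold in reads (default 5)
#' @param samples length-2 sample label vector
#' @return `records` with a `specific` column (a sample label or NA);
#'   the two per-sample subsets are attached as the `sets` attribute
#' @export
sample_specific_junctions <- function(records, T1 = 5, samples = NULL) {
  if (is.null(samples)) {
    samples <- sub("^count_", "",
                   grep("^count_", names(records), value = TRUE))
  }
  stopifnot(length(samples) == 2)
  a <- records[[paste0("count_", samples[1])]]
  b <- records[[paste0("count_", samples[2])]]
  specific <- rep(NA_character_, nrow(records))
  specific[a >= T1 & b == 0] <- samples[1]
  specific[b >= T1 & a == 0] <- samples[2]
  records$specific <- specific
  attr(records, "sets") <- stats::setNames(
    list(records[!is.na(specific) & specific == samples[1], ,
                 drop = FALSE],
         records[!is.na(specific) & specific == samples[2], ,
                 drop = FALSE]),
    samples)
  records
}

#' Classify junction annotation status
#'
#' Each junction is assigned the name of the first supplied annotation
#' junction set containing its key (the list order encodes precedence,
#' conventionally RefSeq > UCSC > Ensembl); junctions found in none are
#' putative novel junctions arising from the pure combinatorial
#' construction.
#'
#' @param records junction records
#' @param junction_sets named list of data frames with `chrom`,
#'   `strand`, `donor_end`, `acceptor_start`
#' @return `records` with a `db_status` column (a set name or
#'   "combinatorial_novel")
#' @export
classify_junction_status <- function(records, junction_sets = list()) {
  status <- rep("combinatorial_novel", nrow(records))
  key <- .junction_key(records)
  for (nm in rev(names(junction_sets))) {
    hit <- key %in% .junction_key(junction_sets[[nm]])
    status[hit] <- nm
  }
  records$db_status <- status
  records
}
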