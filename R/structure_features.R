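#' Names of the eight structural predictors
#'
#' Column order used throughout the package for feature tables and
#' classifier coefficients.
#' @export
structure_predictors <- function() {
  c("gene_span_len", "cds_total_len", "first_exon_len", "last_exon_len",
    "internal_exon_mean_len", "n_phase0", "n_phase1", "n_phase2")
}

#' Coding-exon phases of a transcript
#'
#' Returns the reading-frame phase of each coding exon, in translation
#' order, under the GFF3 phase-column convention: the number of bases
#' to skip at the start of the exon to reach the next codon boundary,
#' `(3 - (upstream coding length mod 3)) mod 3`.  The first exon always
#' has phase 0.  These values are exactly what [write_gff3()] places in
#' the phase column.
#'
#' @param t A validating `transcript_model`.
#' @return Integer vector of phases in `{0,1,2}`, one per coding exon.
#' @export
exon_phases <- function(t) {
  v <- validate_transcript(t)
  if (!v$pass)
    stop("transcript ", t$transcript_id, " fails validation: ",
         paste(v$reasons, collapse = "; "))
  lens <- segment_lengths(t)
  upstream <- c(0L, cumsum(lens)[-length(lens)])
  as.integer((3L - upstream %% 3L) %% 3L)
}

ineligible_error <- function(t, n) {
  stop(errorCondition(
    paste0("transcript ", t$transcript_id, " is ineligible: ", n,
           " coding exon(s); at least 4 (two internal exons) required"),
    class = c("bicyclr_ineligible", "error", "condition")))
}

#' Extract the eight structural predictors from a transcript
#'
#' Computes, from coding-segment coordinates alone:
#' \describe{
#'   \item{gene_span_len}{genomic span from the first base of the first
#'     coding segment to the last base of the last, introns included
#'     ("start codon through stop codon" on the genome axis);}
#'   \item{cds_total_len}{summed coding length;}
#'   \item{first_exon_len, last_exon_len}{lengths of the first/last
#'     coding exon in translation order;}
#'   \item{internal_exon_mean_len}{mean length of coding exons that are
#'     neither first nor last;}
#'   \item{n_phase0, n_phase1, n_phase2}{counts of internal exons
#'     starting in each phase (see [exon_phases()]).}
#' }
#' Transcripts with fewer than four coding exons (fewer than two
#' internal exons) cannot support the internal-exon statistics and
#' raise a classed `bicyclr_ineligible` error, distinct from
#' malformed-input errors.
#'
#' @param t A validating `transcript_model` with >= 4 coding exons.
#' @return One-row `data.frame` of features (plus `transcript_id` and
#'   `label`).
#' @export
extract_features <- function(t) {
  phases <- exon_phases(t)  # also validates
  lens <- segment_lengths(t)
  n <- length(lens)
  if (n < 4L) ineligible_error(t, n)
  internal <- 2:(n - 1L)
  ph <- phases[internal]
  data.frame(
    transcript_id          = t$transcript_id,
    gene_span_len          = max(t$segments$end) - min(t$segments$start) + 1L,
    cds_total_len          = sum(lens),
    first_exon_len         = lens[1L],
    last_exon_len          = lens[n],
    internal_exon_mean_len = mean(lens[internal]),
    n_phase0               = sum(ph == 0L),
    n_phase1               = sum(ph == 1L),
    n_phase2               = sum(ph == 2L),
    label                  = t$label,
    stringsAsFactors = FALSE
  )
}

#' Build a feature table from a set of transcripts
#'
#' Applies [extract_features()] to every transcript, collecting
#' non-validating and ineligible (< 4 exon) transcripts into a side
#' report with reasons instead of failing.  Row counts are conserved:
#' `nrow(features) + nrow(excluded)` equals the number of inputs.
#'
#' @param transcripts List of `transcript_model`s.
#' @return A list with `features` (data.frame, fixed column order) and
#'   `excluded` (data.frame with `transcript_id`, `reason`).
#' @export
feature_table <- function(transcripts) {
  cols <- c("transcript_id", structure_predictors(), "label")
  empty <- stats::setNames(
    data.frame(character(0), numeric(0), numeric(0), numeric(0), numeric(0),
               numeric(0), integer(0), integer(0), integer(0), character(0),
               stringsAsFactors = FALSE), cols)
  rows <- list(); excl <- list()
  for (t in transcripts) {
    v <- validate_transcript(t)
    if (!v$pass) {
      excl[[length(excl) + 1L]] <-
        data.frame(transcript_id = t$transcript_id,
                   reason = paste(v$reasons, collapse = "; "))
      next
    }
    if (nrow(t$segments) < 4L) {
      excl[[length(excl) + 1L]] <-
        data.frame(transcript_id = t$transcript_id,
                   reason = sprintf("ineligible: %d coding exon(s) (< 4)",
                                    nrow(t$segments)))
      next
    }
    rows[[length(rows) + 1L]] <- extract_features(t)
  }
  features <- if (length(rows)) do.call(rbind, rows) else empty
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(transcript_id = character(0), reason = character(0))
  rownames(features) <- NULL; rownames(excluded) <- NULL
  list(features = features[, cols], excluded = excluded)
}

#' Write / read a feature table TSV
#'
#' Fixed column order: transcript_id, the eight predictors, label.
#' @param features Feature data.frame.
#' @param path File path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_tsv <- function(features, path) {
  cols <- c("transcript_id", structure_predictors(), "label")
  stopifnot(all(cols %in% names(features)))
  utils::write.table(format(features[, cols], digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(transcript_id = "character",
                                   label = "character"))
}

#' Compare two exon-count distributions
#'
#' Two-sample Kolmogorov-Smirnov comparison of per-gene exon counts,
#' e.g. a candidate family against the genome-wide background.  Counts
#' are heavily tied, so the asymptotic p-value is used.
#'
#' @param group_a,group_b Non-empty numeric vectors of exon counts.
#' @return A list with `statistic` (KS D), `p_value`, `group_sizes`.
#' @export
compare_exon_count_distributions <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  ks <- suppressWarnings(stats::ks.test(group_a, group_b, exact = FALSE))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       group_sizes = c(length(group_a), length(group_b)))
}
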