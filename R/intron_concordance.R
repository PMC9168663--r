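## Intron-position concordance over gapped protein alignments.
## An intron annotated "after residue k" of a sequence is projected to the
## alignment column holding residue k; per-column counts across two families
## are compared with a Pearson correlation and a resampling null.

#' Construct an aligned protein family with intron annotations
#'
#' @param family_id Family identifier.
#' @param alignment Named character vector of gapped protein rows
#'   (gap character `-`), all the same width.
#' @param introns data.frame with columns `sequence_id`,
#'   `residue_index` (1-based position in the ungapped protein of the
#'   residue immediately preceding the intron; 0 marks an intron before
#'   residue 1) and `phase` (0/1/2, carried as metadata).
#' @return Object of class `aligned_family`.
#' @export
aligned_family <- function(family_id, alignment, introns) {
  stopifnot(is.character(alignment), length(alignment) >= 1L,
            !is.null(names(alignment)))
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L)
    stop("alignment is not rectangular in family ", family_id)
  introns <- as.data.frame(introns)
  need <- c("sequence_id", "residue_index", "phase")
  if (!all(need %in% names(introns)))
    stop("introns table must have columns ", paste(need, collapse = ", "))
  if (nrow(introns)) {
    unknown <- setdiff(unique(introns$sequence_id), names(alignment))
    if (length(unknown))
      stop("introns reference unknown sequence(s): ",
           paste(unknown, collapse = ", "))
    if (!all(introns$phase %in% 0:2))
      stop("intron phase must be 0, 1 or 2")
    ungapped <- vapply(alignment, function(s)
      sum(strsplit(s, "", fixed = TRUE)[[1L]] != "-"), integer(1))
    too_big <- introns$residue_index > ungapped[introns$sequence_id] |
      introns$residue_index < 0
    if (any(too_big))
      stop("residue_index out of range for sequence ",
           introns$sequence_id[which(too_big)[1L]])
  }
  structure(list(family_id = family_id, alignment = alignment,
                 introns = introns, width = widths[1L]),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %s: %d sequences x %d columns, %d intron(s)\n",
              x$family_id, length(x$alignment), x$width, nrow(x$introns)))
  invisible(x)
}

#' Read an aligned family from FASTA + intron TSV
#'
#' @param fasta_path Aligned protein FASTA (gaps as `-`).
#' @param introns_path TSV with header columns sequence_id,
#'   residue_index, phase.
#' @param family_id Family identifier (defaults to the FASTA filename).
#' @return An `aligned_family`.
#' @export
read_aligned_family <- function(fasta_path, introns_path,
                                family_id = basename(fasta_path)) {
  aln <- Biostrings::readAAStringSet(fasta_path)
  alignment <- stats::setNames(as.character(aln), names(aln))
  introns <- utils::read.delim(introns_path, stringsAsFactors = FALSE,
                               colClasses = c(sequence_id = "character"))
  aligned_family(family_id, alignment, introns)
}

#' Project intron positions onto alignment columns
#'
#' Each intron is assigned to the alignment column occupied by the
#' residue immediately preceding it (gap columns never receive
#' introns), and per-column counts and fractions are aggregated across
#' the family — the bin-size-1 intron-position histogram.  Introns
#' annotated before residue 1 (`residue_index = 0`) cannot be assigned
#' to a residue column; they are counted in `boundary_introns` and
#' excluded from the profile.
#'
#' @param fam An `aligned_family`.
#' @return Object of class `intron_profile`: `counts` (integer per
#'   column), `fraction` (`counts / n_seqs`), `n_seqs`, `width`,
#'   `boundary_introns`.
#' @export
project_introns <- function(fam) {
  stopifnot(inherits(fam, "aligned_family"))
  counts <- integer(fam$width)
  boundary <- 0L
  if (nrow(fam$introns)) {
    res_cols <- lapply(fam$alignment, function(s)
      which(strsplit(s, "", fixed = TRUE)[[1L]] != "-"))
    for (i in seq_len(nrow(fam$introns))) {
      sid <- fam$introns$sequence_id[i]
      ri <- fam$introns$residue_index[i]
      if (ri == 0L) { boundary <- boundary + 1L; next }
      cols <- res_cols[[sid]]
      if (ri > length(cols))
        stop("residue_index out of range for sequence ", sid)
      col <- cols[ri]
      counts[col] <- counts[col] + 1L
    }
  }
  structure(list(counts = counts, fraction = counts / length(fam$alignment),
                 n_seqs = length(fam$alignment), width = fam$width,
                 boundary_introns = boundary),
            class = "intron_profile")
}

profile_counts <- function(x) {
  if (inherits(x, "intron_profile")) x$counts else as.numeric(x)
}

#' Intron concordance between two families
#'
#' Pearson correlation, across alignment columns, of the two families'
#' per-column counts of sequences carrying an intron.  Large positive
#' values indicate shared gene structure and hence homology.
#'
#' @param a,b `intron_profile`s (or plain count vectors) over the same
#'   joint alignment (equal column counts); both must be non-constant.
#' @return Pearson R in `[-1, 1]`.
#' @export
concordance_R <- function(a, b) {
  ca <- profile_counts(a); cb <- profile_counts(b)
  if (length(ca) != length(cb))
    stop("profiles have different column counts (",
         length(ca), " vs ", length(cb), ")")
  if (stats::sd(ca) == 0 || stats::sd(cb) == 0)
    stop("undefined correlation: constant profile")
  stats::cor(ca, cb)
}

#' Null distribution of the concordance statistic
#'
#' Two resampling modes:
#' \describe{
#'   \item{permute_columns}{(self-contained default) per resample, the
#'     column assignment of `fam_b`'s profile is randomly permuted and
#'     R recomputed against `fam_a`'s profile — intron positions are
#'     kept, positional correspondence is destroyed.}
#'   \item{unrelated_families}{per resample, one of the supplied
#'     unrelated families is chosen, its aligned rows are resampled
#'     with replacement, re-projected, and correlated against
#'     `fam_a`'s profile; every unrelated family must share `fam_a`'s
#'     alignment width.}
#' }
#'
#' @param fam_a,fam_b `aligned_family` objects over the same joint
#'   alignment.
#' @param mode `"permute_columns"` or `"unrelated_families"`.
#' @param n_resamples Number of resamples (>= 1).
#' @param seed Integer seed; the sample is reproducible.
#' @param unrelated List of `aligned_family`s (unrelated mode only).
#' @return Object of class `concordance_null`: numeric `R` sample,
#'   `mode`, `n_resamples`, `seed`.
#' @export
null_distribution <- function(fam_a, fam_b,
                              mode = c("permute_columns", "unrelated_families"),
                              n_resamples = 200L, seed = 1L,
                              unrelated = NULL) {
  mode <- match.arg(mode)
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  pa <- profile_counts(project_introns(fam_a))
  pb <- profile_counts(project_introns(fam_b))
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0)
    stop("constant profile: correlation undefined under resampling")
  set.seed(seed)
  R <- if (mode == "permute_columns") {
    vapply(seq_len(n_resamples), function(i)
      stats::cor(pa, sample(pb)), numeric(1))
  } else {
    if (is.null(unrelated) || !length(unrelated))
      stop("unrelated_families mode requires at least one unrelated family")
    for (u in unrelated)
      if (u$width != length(pa))
        stop("unrelated family ", u$family_id,
             " does not share the alignment width of ", fam_a$family_id)
    vapply(seq_len(n_resamples), function(i) {
      u <- unrelated[[sample.int(length(unrelated), 1L)]]
      rows <- sample.int(length(u$alignment), length(u$alignment),
                         replace = TRUE)
      ids <- names(u$alignment)[rows]
      new_ids <- sprintf("%s_bs%d", ids, seq_along(ids))
      aln <- stats::setNames(u$alignment[rows], new_ids)
      intr <- do.call(rbind, lapply(seq_along(ids), function(j) {
        sub <- u$introns[u$introns$sequence_id == ids[j], , drop = FALSE]
        if (!nrow(sub)) return(NULL)
        sub$sequence_id <- new_ids[j]
        sub
      }))
      if (is.null(intr))
        intr <- data.frame(sequence_id = character(0),
                           residue_index = integer(0), phase = integer(0))
      boot <- aligned_family(paste0(u$family_id, "_boot"), aln, intr)
      pu <- profile_counts(project_introns(boot))
      if (stats::sd(pu) == 0) return(NA_real_)
      stats::cor(pa, pu)
    }, numeric(1))
  }
  structure(list(R = R, mode = mode, n_resamples = n_resamples, seed = seed),
            class = "concordance_null")
}

#' One-sided empirical p-value for excess concordance
#'
#' `p = (1 + #\{null >= R_obs\}) / (1 + n)`.
#'
#' @param R_obs Observed concordance R.
#' @param null_R A `concordance_null` or plain numeric null sample
#'   (non-empty; NAs dropped).
#' @return p in `(0, 1]`.
#' @export
empirical_p <- function(R_obs, null_R) {
  null <- if (inherits(null_R, "concordance_null")) null_R$R else as.numeric(null_R)
  null <- null[!is.na(null)]
  if (!length(null)) stop("empty null sample")
  (1 + sum(null >= R_obs)) / (1 + length(null))
}

#' Full intron-concordance test between two families
#'
#' Projects both families, computes the observed concordance R, draws a
#' resampling null and returns the one-sided empirical p-value.
#'
#' @inheritParams null_distribution
#' @return Object of class `concordance_result`: `R`, `null_R` sample,
#'   `p_empirical`, `n_resamples`, `mode`, `seed`.
#' @export
intron_concordance_test <- function(fam_a, fam_b,
                                    mode = "permute_columns",
                                    n_resamples = 200L, seed = 1L,
                                    unrelated = NULL) {
  R_obs <- concordance_R(project_introns(fam_a), project_introns(fam_b))
  null <- null_distribution(fam_a, fam_b, mode = mode,
                            n_resamples = n_resamples, seed = seed,
                            unrelated = unrelated)
  structure(list(R = R_obs, null_R = null$R,
                 p_empirical = empirical_p(R_obs, null),
                 n_resamples = n_resamples, mode = null$mode, seed = seed),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> R = %.4f, empirical p = %.4g (%s, %d resamples, mean null R = %.4f)\n",
              x$R, x$p_empirical, x$mode, x$n_resamples, mean(x$null_R, na.rm = TRUE)))
  invisible(x)
}

#' Plot an intron-position histogram
#'
#' Bin-size-1 barplot of the fraction of sequences carrying an intron
#' at each alignment column.
#'
#' @param profile An `intron_profile`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_intron_profile <- function(profile, ...) {
  stopifnot(inherits(profile, "intron_profile"))
  graphics::barplot(profile$fraction, names.arg = NULL, space = 0,
                    xlab = "alignment column",
                    ylab = "fraction of sequences with intron", ...)
  invisible(profile)
}

#' Write an intron profile or null sample as TSV
#' @param profile An `intron_profile`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "intron_profile"))
  utils::write.table(
    data.frame(column = seq_len(profile$width), count = profile$counts,
               fraction = profile$fraction),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
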