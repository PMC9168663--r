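## Synthetic annotation and alignment generators with recorded ground truth.
## The family class emulates a structurally stereotyped effector family:
## many short internal coding exons, predominantly phase 2 (exon counts
## floored at 5 with a mean near 17); the background class uses broad,
## conventional exon statistics.  Target phases are sampled first and exon
## lengths adjusted by 0-2 bases so the realized cumulative-length phase
## matches the target, which makes the phase histogram directly controllable.

#' Parameters for the genome-annotation simulator
#'
#' Distributional defaults: family exon counts are a shifted negative
#' binomial `min + NB(mu, size)` with min 5 and mean about 17; family
#' internal exons are short (lognormal, median ~45 bp: micro-exons) and
#' phase 2 with probability 0.9.  Background exon counts have a long
#' tail (min 1, mean ~6.5), internal exon lengths are broad (median
#' ~120 bp), and phases follow approximate genome-wide frequencies.
#' Intron lengths are short (median ~90 bp, floor 40), as in compact
#' insect genomes.  Lognormal length parameters are lists with
#' `meanlog`, `sdlog`, `min`; count parameters with `min`, `mu`, `size`.
#'
#' @param n_family,n_background Numbers of transcripts per class.
#' @param family_exon_count,background_exon_count Exon-count
#'   distributions.
#' @param family_internal_len,background_internal_len Internal-exon
#'   length distributions.
#' @param family_terminal_len,background_terminal_len First/last exon
#'   length distributions.
#' @param family_phase_probs,background_phase_probs Length-3 probability
#'   vectors over internal-exon phases 0/1/2.
#' @param intron_len Intron length distribution.
#' @param seed Integer seed.
#' @return Validated parameter list of class `genome_sim_params`.
#' @export
genome_sim_params <- function(
    n_family = 500L, n_background = 5000L,
    family_exon_count = list(min = 5L, mu = 12, size = 3),
    background_exon_count = list(min = 1L, mu = 5.5, size = 1.3),
    family_internal_len = list(meanlog = log(45), sdlog = 0.35, min = 9L),
    background_internal_len = list(meanlog = log(120), sdlog = 0.75, min = 12L),
    family_terminal_len = list(meanlog = log(130), sdlog = 0.5, min = 9L),
    background_terminal_len = list(meanlog = log(200), sdlog = 0.7, min = 9L),
    family_phase_probs = c(0.05, 0.05, 0.90),
    background_phase_probs = c(0.48, 0.30, 0.22),
    intron_len = list(meanlog = log(90), sdlog = 0.8, min = 40L),
    seed = 1L) {
  p <- list(n_family = as.integer(n_family),
            n_background = as.integer(n_background),
            family_exon_count = family_exon_count,
            background_exon_count = background_exon_count,
            family_internal_len = family_internal_len,
            background_internal_len = background_internal_len,
            family_terminal_len = family_terminal_len,
            background_terminal_len = background_terminal_len,
            family_phase_probs = family_phase_probs,
            background_phase_probs = background_phase_probs,
            intron_len = intron_len,
            seed = as.integer(seed))
  stopifnot(p$n_family >= 0L, p$n_background >= 0L)
  for (probs in list(p$family_phase_probs, p$background_phase_probs)) {
    if (length(probs) != 3L || any(probs < 0) || any(probs > 1) ||
        abs(sum(probs) - 1) > 1e-8)
      stop("phase probabilities must be 3 values in [0,1] summing to 1")
  }
  if (p$family_exon_count$min < 4L)
    stop("family exon-count floor must be >= 4 (eligibility requires two internal exons)")
  for (d in list(p$family_internal_len, p$background_internal_len,
                 p$family_terminal_len, p$background_terminal_len)) {
    if (d$min < 3L)
      stop("exon length floor must be >= 3 to allow 0-2 base phase adjustment")
  }
  if (p$intron_len$min < 4L) stop("intron length floor must be >= 4")
  structure(p, class = "genome_sim_params")
}

rlen <- function(n, d) pmax(as.integer(round(stats::rlnorm(n, d$meanlog, d$sdlog))),
                            as.integer(d$min))
rcount <- function(n, d) as.integer(d$min) + stats::rnbinom(n, mu = d$mu, size = d$size)

# Sample one gene model: exon lengths adjusted so each internal exon's
# cumulative-length phase equals its sampled target and the total CDS is a
# multiple of 3.  Returns lengths, intron lengths and realized phases.
sample_gene_structure <- function(class, p) {
  fam <- class == "family"
  K <- rcount(1L, if (fam) p$family_exon_count else p$background_exon_count)
  term_d <- if (fam) p$family_terminal_len else p$background_terminal_len
  int_d <- if (fam) p$family_internal_len else p$background_internal_len
  lens <- if (K == 1L) rlen(1L, term_d)
          else if (K == 2L) rlen(2L, term_d)
          else c(rlen(1L, term_d), rlen(K - 2L, int_d), rlen(1L, term_d))
  phase_target <- integer(0)
  if (K >= 3L) {
    probs <- if (fam) p$family_phase_probs else p$background_phase_probs
    phase_target <- sample(0:2, K - 2L, replace = TRUE, prob = probs)
    # realize each internal exon's phase by stretching the previous exon
    for (j in seq_len(K - 2L)) {
      i <- j + 1L                       # internal exon index
      cum <- sum(lens[seq_len(i - 1L)])
      need <- (3L - phase_target[j]) %% 3L   # required cum mod 3
      lens[i - 1L] <- lens[i - 1L] + (need - cum %% 3L) %% 3L
    }
  }
  total <- sum(lens)
  lens[K] <- lens[K] + (3L - total %% 3L) %% 3L
  introns <- if (K > 1L) rlen(K - 1L, p$intron_len) else integer(0)
  list(lens = as.integer(lens), introns = as.integer(introns),
       phase_target = phase_target)
}

#' Simulate a genome annotation with recorded ground truth
#'
#' Draws `n_family + n_background` transcript models (interleaved in a
#' shuffled order, random strands, laid out along one synthetic
#' contig), writes them as GFF3 plus a label table, and records a truth
#' feature table computed at generation time — the exact-oracle values
#' that [feature_table()] must reproduce from the written file.  Every
#' emitted transcript passes [validate_transcript()]; output is
#' byte-identical under a fixed seed.
#'
#' @param params A [genome_sim_params()] object.
#' @param out_dir Output directory (created if needed); files
#'   `annotation.gff3`, `labels.tsv`, `truth_features.tsv` and a
#'   `params.json` sidecar are written there.
#' @return List with `transcripts` (list of `transcript_model`),
#'   `truth` (data.frame of features for all transcripts with >= 4
#'   exons, plus label), `labels` (named vector), and the file `paths`.
#' @export
simulate_genome_annotation <- function(params = genome_sim_params(),
                                       out_dir = tempfile("simgenome")) {
  stopifnot(inherits(params, "genome_sim_params"))
  set.seed(params$seed)
  n <- params$n_family + params$n_background
  classes <- sample(c(rep("family", params$n_family),
                      rep("non_family", params$n_background)))
  cursor <- 1L
  transcripts <- vector("list", n)
  truth_rows <- list()
  for (i in seq_len(n)) {
    gs <- sample_gene_structure(classes[i], params)
    K <- length(gs$lens)
    strand <- sample(c("+", "-"), 1L)
    span <- sum(gs$lens) + sum(gs$introns)
    gstart <- cursor
    cursor <- cursor + span + sample(2000:20000, 1L)
    # offsets of each exon along the transcription axis
    off <- cumsum(c(0L, utils::head(gs$lens, -1L) + gs$introns))
    if (strand == "+") {
      starts <- gstart + off
      ends <- starts + gs$lens - 1L
    } else {
      gend <- gstart + span - 1L
      ends <- gend - off
      starts <- ends - gs$lens + 1L
    }
    tid <- sprintf("tx%06d", i)
    tm <- transcript_model(tid, sprintf("g%06d", i), "ctg_sim_1", strand,
                           starts, ends, label = classes[i])
    transcripts[[i]] <- tm
    if (K >= 4L) {
      internal <- gs$lens[2:(K - 1L)]
      upstream <- c(0L, cumsum(gs$lens)[-K])
      ph <- (3L - upstream %% 3L) %% 3L
      ph_int <- ph[2:(K - 1L)]
      stopifnot(identical(as.integer(ph_int), as.integer(gs$phase_target)))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = tid,
        gene_span_len = span,
        cds_total_len = sum(gs$lens),
        first_exon_len = gs$lens[1L],
        last_exon_len = gs$lens[K],
        internal_exon_mean_len = mean(internal),
        n_phase0 = sum(ph_int == 0L),
        n_phase1 = sum(ph_int == 1L),
        n_phase2 = sum(ph_int == 2L),
        label = classes[i], stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(gff3 = file.path(out_dir, "annotation.gff3"),
                labels = file.path(out_dir, "labels.tsv"),
                truth = file.path(out_dir, "truth_features.tsv"),
                params = file.path(out_dir, "params.json"))
  write_gff3(transcripts, paths$gff3)
  tids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  utils::write.table(data.frame(transcript_id = tids, label = classes),
                     paths$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_feature_tsv(truth, paths$truth)
  jsonlite::write_json(unclass(params), paths$params, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(transcripts = transcripts, truth = truth,
       labels = stats::setNames(classes, tids), paths = paths)
}

#' Simulate a labeled feature table from known coefficients
#'
#' Parameter-recovery harness for [fit_logistic()]: draws standard
#' normal predictor values and Bernoulli labels with success
#' probability `plogis(intercept + X beta)`.
#'
#' @param beta Named coefficient vector (any subset of
#'   [structure_predictors()] or arbitrary names).
#' @param intercept Intercept.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return data.frame with `transcript_id`, one column per coefficient
#'   name, and `label`; the generating coefficients are attached as
#'   attributes `truth_beta` / `truth_intercept`.
#' @export
simulate_features_from_model <- function(beta, intercept = 0, n = 1000L,
                                         seed = 1L) {
  stopifnot(n >= 1L, !is.null(names(beta)))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * length(beta)), nrow = n,
              dimnames = list(NULL, names(beta)))
  p <- stats::plogis(drop(intercept + X %*% beta))
  y <- stats::rbinom(n, 1L, p)
  out <- data.frame(transcript_id = sprintf("sim%06d", seq_len(n)),
                    X, label = ifelse(y == 1L, "family", "non_family"),
                    stringsAsFactors = FALSE)
  attr(out, "truth_beta") <- beta
  attr(out, "truth_intercept") <- intercept
  out
}

#' Parameters for the aligned-family simulator
#'
#' @param n_seqs Sequences per family.
#' @param width Alignment width (columns).
#' @param n_shared Size of the truth shared-intron column set.
#' @param share_prob Per-sequence probability of carrying an intron at
#'   each shared column.
#' @param noise_rate Expected number of extra (noise) introns per
#'   sequence (Poisson).
#' @param gap_rate Per-column gap probability per sequence.
#' @param seed Integer seed.
#' @return Validated list of class `alignment_sim_params`.
#' @export
alignment_sim_params <- function(n_seqs = 12L, width = 300L, n_shared = 10L,
                                 share_prob = 0.8, noise_rate = 1.5,
                                 gap_rate = 0.05, seed = 1L) {
  p <- list(n_seqs = as.integer(n_seqs), width = as.integer(width),
            n_shared = as.integer(n_shared), share_prob = share_prob,
            noise_rate = noise_rate, gap_rate = gap_rate,
            seed = as.integer(seed))
  stopifnot(p$n_seqs >= 2L, p$width >= 1L, p$n_shared >= 0L,
            p$share_prob >= 0, p$share_prob <= 1,
            p$noise_rate >= 0, p$gap_rate >= 0, p$gap_rate < 1)
  if (p$n_shared > p$width)
    stop("infeasible width: fewer columns than shared intron positions")
  structure(p, class = "alignment_sim_params")
}

amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

sim_one_family <- function(family_id, shared_cols, p) {
  ids <- sprintf("%s_seq%02d", family_id, seq_len(p$n_seqs))
  rows <- character(p$n_seqs)
  intr <- list()
  for (i in seq_len(p$n_seqs)) {
    gap <- stats::runif(p$width) < p$gap_rate
    if (all(gap)) gap[sample.int(p$width, 1L)] <- FALSE
    chars <- ifelse(gap, "-", sample(amino_acids, p$width, replace = TRUE))
    rows[i] <- paste(chars, collapse = "")
    res_cols <- which(!gap)
    carry <- shared_cols[stats::runif(length(shared_cols)) < p$share_prob]
    carry <- intersect(carry, res_cols)
    n_noise <- stats::rpois(1L, p$noise_rate)
    free <- setdiff(res_cols, carry)
    noise <- if (n_noise > 0L && length(free))
      sample(free, min(n_noise, length(free))) else integer(0)
    cols <- sort(unique(c(carry, noise)))
    if (length(cols)) {
      residue_index <- match(cols, res_cols)
      intr[[length(intr) + 1L]] <- data.frame(
        sequence_id = ids[i], residue_index = residue_index,
        phase = sample(0:2, length(cols), replace = TRUE))
    }
  }
  introns <- if (length(intr)) do.call(rbind, intr) else
    data.frame(sequence_id = character(0), residue_index = integer(0),
               phase = integer(0))
  aligned_family(family_id, stats::setNames(rows, ids), introns)
}

#' Simulate a pair of aligned families with controlled intron sharing
#'
#' With `related = TRUE` both families place introns at one truth set
#' of shared alignment columns (each sequence carries each shared
#' intron with probability `share_prob`, plus Poisson noise introns);
#' with `related = FALSE` the two families use independently drawn
#' column sets.  Gaps are inserted per column at `gap_rate` without
#' breaking the residue/intron correspondence.  Reproducible under the
#' seed in `params`.
#'
#' @param params An [alignment_sim_params()] object.
#' @param related Share one intron column set between the families?
#' @return List with `family_a`, `family_b` (both `aligned_family`),
#'   `shared_columns` truth (`$a`/`$b`, identical when related), and
#'   `params`.
#' @export
simulate_aligned_families <- function(params = alignment_sim_params(),
                                      related = TRUE) {
  stopifnot(inherits(params, "alignment_sim_params"))
  set.seed(params$seed)
  cols_a <- sort(sample.int(params$width, params$n_shared))
  cols_b <- if (related) cols_a else sort(sample.int(params$width, params$n_shared))
  fam_a <- sim_one_family("famA", cols_a, params)
  fam_b <- sim_one_family("famB", cols_b, params)
  list(family_a = fam_a, family_b = fam_b,
       shared_columns = list(a = cols_a, b = cols_b),
       params = params)
}

#' Write an aligned family to FASTA + intron TSV
#'
#' @param fam An `aligned_family`.
#' @param fasta_path,introns_path Output paths.
#' @export
write_aligned_family <- function(fam, fasta_path, introns_path) {
  stopifnot(inherits(fam, "aligned_family"))
  writeLines(as.vector(rbind(paste0(">", names(fam$alignment)),
                             fam$alignment)), fasta_path)
  utils::write.table(fam$introns, introns_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}
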