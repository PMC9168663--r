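# Independent oracles and fixture builders shared across tests.
# Everything here recomputes quantities from first principles, without
# calling the package functions under test.

# Build a transcript_model from exon/intron lengths along the
# transcription axis, starting at `origin` on the genome.
make_tx <- function(lens, introns = rep(100L, max(length(lens) - 1L, 0L)),
                    strand = "+", origin = 1000L, id = "tx1",
                    label = "unlabeled", seq_id = "ctg1") {
  stopifnot(length(introns) == length(lens) - 1L)
  off <- cumsum(c(0L, head(lens, -1L) + introns))
  span <- sum(lens) + sum(introns)
  if (strand == "+") {
    starts <- origin + off; ends <- starts + lens - 1L
  } else {
    gend <- origin + span - 1L
    ends <- gend - off; starts <- ends - lens + 1L
  }
  transcript_model(id, paste0(id, "_g"), seq_id, strand, starts, ends,
                   label = label)
}

# Brute-force phase oracle: lay the coding sequence out as repeating
# codon positions 1,2,3,1,2,3,... split at exon boundaries, and read the
# GFF3 phase off each exon's first-base codon position
# (pos 1 -> phase 0, pos 2 -> phase 2, pos 3 -> phase 1).
oracle_phases <- function(lens) {
  codon_pos <- rep_len(1:3, sum(lens))
  bounds <- cumsum(c(0L, head(lens, -1L))) + 1L
  first_pos <- codon_pos[bounds]
  unname(c(`1` = 0L, `2` = 2L, `3` = 1L)[as.character(first_pos)])
}

# Brute-force feature oracle from raw genomic segments (any row order).
oracle_features <- function(starts, ends, strand) {
  ord <- order(starts, decreasing = (strand == "-"))  # translation order
  starts <- starts[ord]; ends <- ends[ord]
  lens <- ends - starts + 1L
  n <- length(lens)
  stopifnot(n >= 4L)
  ph <- oracle_phases(lens)[2:(n - 1L)]
  list(gene_span_len = max(ends) - min(starts) + 1L,
       cds_total_len = sum(lens),
       first_exon_len = lens[1L],
       last_exon_len = lens[n],
       internal_exon_mean_len = mean(lens[2:(n - 1L)]),
       n_phase0 = sum(ph == 0L),
       n_phase1 = sum(ph == 1L),
       n_phase2 = sum(ph == 2L))
}

# Direct numerical maximizer of the binomial log-likelihood (the IRLS
# oracle): BFGS on standardized predictors for conditioning, coefficients
# transformed back to the raw scale.
oracle_logistic_ml <- function(X, y) {
  m <- colMeans(X); s <- apply(X, 2, sd)
  Z <- cbind(1, sweep(sweep(X, 2, m, "-"), 2, s, "/"))
  negll <- function(b) {
    eta <- drop(Z %*% b)
    -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  grad <- function(b) -drop(crossprod(Z, y - plogis(drop(Z %*% b))))
  fit <- optim(rep(0, ncol(Z)), negll, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  b <- fit$par
  c(intercept = b[1L] - sum(b[-1L] * m / s), b[-1L] / s)
}

# Exhaustive-scan oracle for the P/R-equalized cutoff.
oracle_select_cutoff <- function(probs, labels,
                                 thresholds = seq(0, 0.98, by = 0.02)) {
  best <- NULL
  for (t in thresholds) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    if (tp + fp == 0) next
    precision <- tp / (tp + fp); recall <- tp / (tp + fn)
    if (recall == 0) next
    cand <- c(score = abs(precision / recall - 1), sum = precision + recall,
              t = t)
    if (is.null(best) ||
        cand["score"] < best["score"] - 1e-15 ||
        (abs(cand["score"] - best["score"]) <= 1e-15 &&
         (cand["sum"] > best["sum"] + 1e-15 ||
          (abs(cand["sum"] - best["sum"]) <= 1e-15 && cand["t"] < best["t"]))))
      best <- cand
  }
  unname(best["t"])
}

# Small synthetic genome shared by several tests (kept small for speed).
small_genome_params <- function(seed = 11L)
  genome_sim_params(n_family = 40L, n_background = 200L, seed = seed)
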