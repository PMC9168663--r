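fam_from <- function(rows, introns, id = "fam") {
  if (is.null(names(rows))) names(rows) <- sprintf("s%02d", seq_along(rows))
  aligned_family(id, rows, introns)
}

no_introns <- data.frame(sequence_id = character(0),
                         residue_index = integer(0), phase = integer(0))

test_that("introns project to the column of the preceding residue across gaps", {
  fam <- fam_from(c(s1 = "A-CD"),
                  data.frame(sequence_id = "s1", residue_index = 2L,
                             phase = 0L))
  prof <- project_introns(fam)
  expect_identical(prof$counts, c(0L, 0L, 1L, 0L))  # residue 2 = 'C', column 3
})

test_that("a family without introns yields an all-zero profile", {
  fam <- fam_from(c(s1 = "ACDE", s2 = "AC-E"), no_introns)
  prof <- project_introns(fam)
  expect_identical(prof$counts, rep(0L, 4))
  expect_identical(prof$n_seqs, 2L)
})

test_that("identical rows with identical introns give even counts", {
  intr <- data.frame(sequence_id = c("s1", "s2"), residue_index = c(3L, 3L),
                     phase = c(2L, 2L))
  fam <- fam_from(c(s1 = "AC-DE", s2 = "AC-DE"), intr)
  prof <- project_introns(fam)
  expect_true(all(prof$counts %% 2L == 0L))
  expect_identical(prof$counts[4L], 2L)   # residue 3 = 'D' in column 4
  expect_equal(prof$fraction[4L], 1)
})

test_that("projection conserves total intron count and flags boundary introns", {
  set.seed(31)
  for (i in 1:10) {
    pair <- simulate_aligned_families(
      alignment_sim_params(n_seqs = 8L, width = 120L, seed = i), related = TRUE)
    for (fam in list(pair$family_a, pair$family_b)) {
      prof <- project_introns(fam)
      expect_identical(sum(prof$counts) + prof$boundary_introns,
                       nrow(fam$introns))
    }
  }
  # residue_index 0 is counted but never assigned a column
  fam <- fam_from(c(s1 = "ACD"),
                  data.frame(sequence_id = "s1", residue_index = 0L,
                             phase = 0L))
  prof <- project_introns(fam)
  expect_identical(sum(prof$counts), 0L)
  expect_identical(prof$boundary_introns, 1L)
})

test_that("residue_index beyond the ungapped length names the sequence", {
  expect_error(
    fam_from(c(sX = "A-CD"),
             data.frame(sequence_id = "sX", residue_index = 4L, phase = 0L)),
    "out of range for sequence sX")
})

test_that("an all-gap column shifts the profile without changing counts", {
  intr <- data.frame(sequence_id = c("s1", "s2"), residue_index = c(2L, 1L),
                     phase = c(0L, 1L))
  fam <- fam_from(c(s1 = "ACDE", s2 = "AC-E"), intr)
  before <- project_introns(fam)$counts
  gapped <- fam_from(c(s1 = "AC-DE", s2 = "AC--E"), intr)
  after <- project_introns(gapped)$counts
  expect_identical(after, c(before[1:2], 0L, before[3:4]))
  expect_identical(sum(after), sum(before))
})

test_that("concordance R matches the Pearson formula on small vectors", {
  expect_equal(concordance_R(c(2, 0, 3, 1), c(2, 0, 3, 1)), 1)
  expect_equal(concordance_R(c(1, 0), c(0, 1)), -1)
  expect_equal(concordance_R(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_error(concordance_R(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  expect_error(concordance_R(c(1, 2), c(1, 2, 3)), "different column counts")
})

test_that("the permutation null is seeded, reproducible and centred near zero", {
  pair <- simulate_aligned_families(
    alignment_sim_params(n_seqs = 10L, width = 200L, seed = 77L),
    related = TRUE)
  n1 <- null_distribution(pair$family_a, pair$family_b, "permute_columns",
                          n_resamples = 100L, seed = 5L)
  n2 <- null_distribution(pair$family_a, pair$family_b, "permute_columns",
                          n_resamples = 100L, seed = 5L)
  expect_identical(n1$R, n2$R)
  expect_lt(abs(mean(n1$R)), 0.1)
})

test_that("a constant profile is a hard error for the null", {
  flat_a <- fam_from(c(s1 = "ACDE"),
                     data.frame(sequence_id = "s1",
                                residue_index = 1:4, phase = rep(0L, 4)))
  fam_b <- fam_from(c(s1 = "ACDE"),
                    data.frame(sequence_id = "s1", residue_index = 2L,
                               phase = 0L), id = "famB")
  expect_error(null_distribution(flat_a, fam_b, "permute_columns", 10L, 1L),
               "constant profile")
})

test_that("unrelated-families null resamples rows of the supplied families", {
  pair <- simulate_aligned_families(
    alignment_sim_params(n_seqs = 10L, width = 200L, noise_rate = 3,
                         seed = 19L), related = FALSE)
  extra <- simulate_aligned_families(
    alignment_sim_params(n_seqs = 10L, width = 200L, noise_rate = 3,
                         seed = 23L), related = FALSE)
  null <- null_distribution(pair$family_a, pair$family_b,
                            "unrelated_families", n_resamples = 50L,
                            seed = 3L, unrelated = list(extra$family_a))
  expect_length(null$R, 50L)
  expect_lt(abs(mean(null$R, na.rm = TRUE)), 0.2)
  expect_error(
    null_distribution(pair$family_a, pair$family_b, "unrelated_families",
                      10L, 1L, unrelated = NULL),
    "requires at least one unrelated family")
})

test_that("empirical p-values follow the add-one resampling formula", {
  expect_equal(empirical_p(0.9, rep(0.1, 199)), 1 / 200)
  null <- seq(-0.5, 0.5, length.out = 199)       # odd n, obs at the median
  expect_equal(empirical_p(median(null), null), (1 + 100) / 200)
  expect_equal(empirical_p(0.2, 0.5), 1)
  expect_error(empirical_p(0.2, numeric(0)), "empty null")
})

test_that("the full concordance test separates related from unrelated pairs", {
  rel <- simulate_aligned_families(
    alignment_sim_params(n_seqs = 12L, width = 250L, share_prob = 0.8,
                         seed = 101L), related = TRUE)
  res <- intron_concordance_test(rel$family_a, rel$family_b,
                                 n_resamples = 199L, seed = 11L)
  expect_gt(res$R, 0.3)
  expect_lte(res$p_empirical, 0.01)

  unrel <- simulate_aligned_families(
    alignment_sim_params(n_seqs = 12L, width = 250L, share_prob = 0.8,
                         seed = 103L), related = FALSE)
  res_u <- intron_concordance_test(unrel$family_a, unrel$family_b,
                                   n_resamples = 199L, seed = 11L)
  expect_lt(res_u$R, 0.3)
})
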