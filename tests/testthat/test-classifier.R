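# Labeled feature table with standard-normal predictors (classifier-side
# tests don't need genomic realism).
sim_table <- function(beta, intercept = 0, n = 500L, seed = 1L)
  simulate_features_from_model(beta, intercept = intercept, n = n, seed = seed)

mixed_sign_beta <- c(gene_span_len = -0.4, cds_total_len = -0.6,
                      first_exon_len = -0.2, last_exon_len = 0.3,
                      internal_exon_mean_len = -0.8, n_phase0 = -1.1,
                      n_phase1 = -0.5, n_phase2 = 1.3)

test_that("intercept-only fit recovers logit of the positive fraction", {
  dat <- data.frame(label = rep(c("family", "non_family"), each = 50))
  m <- fit_logistic(dat, predictors = character(0))
  expect_lt(abs(m$intercept), 1e-8)      # logit(0.5) = 0
  dat2 <- data.frame(label = rep(c("family", "non_family"), c(30, 70)))
  m2 <- fit_logistic(dat2, predictors = character(0))
  expect_equal(m2$intercept, qlogis(0.3), tolerance = 1e-8)
})

test_that("IRLS matches stats::glm and a direct likelihood maximizer", {
  dat <- sim_table(mixed_sign_beta, intercept = -0.3, n = 500L, seed = 21L)
  m <- fit_logistic(dat)
  expect_false(m$training_meta$separation)

  # cross-check 1: glm (same likelihood, different implementation)
  y <- as.numeric(dat$label == "family")
  g <- glm(y ~ ., data = cbind(y = y, dat[names(mixed_sign_beta)]),
           family = binomial())
  expect_equal(unname(m$intercept), unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(unname(m$coefficients),
               unname(coef(g)[names(mixed_sign_beta)]), tolerance = 1e-6)

  # cross-check 2: direct numerical maximization of the log-likelihood
  X <- as.matrix(dat[names(mixed_sign_beta)])
  ml <- oracle_logistic_ml(X, y)
  expect_lt(max(abs(c(m$intercept, m$coefficients) - ml)), 1e-6)
})

test_that("single-class input and non-finite features are hard errors", {
  dat <- sim_table(mixed_sign_beta, n = 50L)
  dat$label <- "family"
  expect_error(fit_logistic(dat), "at least one family and one non_family")
  dat2 <- sim_table(mixed_sign_beta, n = 50L)
  dat2$n_phase2[1] <- NA
  expect_error(fit_logistic(dat2), "non-finite")
})

test_that("perfect separation is flagged but returns finite coefficients", {
  dat <- data.frame(n_phase2 = rep(c(10, 0), each = 25),
                    label = rep(c("family", "non_family"), each = 25))
  expect_warning(m <- fit_logistic(dat, predictors = "n_phase2"),
                 "separation")
  expect_true(m$training_meta$separation)
  expect_true(all(is.finite(c(m$intercept, m$coefficients))))
  # ridge keeps the same data finite and quiet about the iteration cap
  mr <- suppressWarnings(fit_logistic(dat, predictors = "n_phase2",
                                      ridge = 1))
  expect_identical(mr$training_meta$ridge, 1)
})

test_that("predict_prob evaluates the logistic response", {
  # a reference coefficient vector with the family-characteristic signs,
  # applied to an all-zero feature row
  coefs <- c(gene_span_len = -0.0000642, cds_total_len = -0.0206,
             first_exon_len = -0.00632, last_exon_len = 0.0103,
             internal_exon_mean_len = -0.0655, n_phase0 = -3.32,
             n_phase1 = -1.12, n_phase2 = 1.21)
  model <- structure(list(coefficients = coefs, intercept = 6.26,
                          cutoff = 0.72, se = NULL,
                          training_meta = list()),
                     class = "bicycle_classifier")
  zero_row <- as.data.frame(as.list(setNames(rep(0, 8), names(coefs))))
  expect_equal(predict_prob(model, zero_row), plogis(6.26), tolerance = 1e-12)
  expect_equal(plogis(6.26), 0.9981, tolerance = 1e-4)

  expect_equal(predict_prob(structure(list(coefficients = coefs * 0,
                                           intercept = 0, cutoff = NA,
                                           training_meta = list()),
                                      class = "bicycle_classifier"),
                            zero_row), 0.5)
  expect_error(predict_prob(model, zero_row[, -1, drop = FALSE]),
               "lacks predictor column")
})

test_that("precision-recall curve counts are exact on enumerable cases", {
  c1 <- precision_recall_curve(c(0.9, 0.9, 0.1), c(1, 1, 0))
  row <- c1[c1$threshold == 0.5, ]
  expect_equal(row$precision, 1); expect_equal(row$recall, 1)

  c2 <- precision_recall_curve(c(0.9, 0.6, 0.1), c(1, 0, 0))
  row <- c2[c2$threshold == 0.5, ]
  expect_equal(row$precision, 0.5); expect_equal(row$recall, 1)

  expect_equal(c2$recall[c2$threshold == 0], 1)      # everything positive
  expect_true(all(c2$tp + c2$fp + c2$fn + c2$tn == 3))
  expect_error(precision_recall_curve(c(0.1, 0.2), c(0, 0)), "no positive")
})

test_that("recall is non-increasing in threshold on random curves", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    probs <- runif(n); labels <- rbinom(n, 1, 0.4)
    if (!any(labels == 1)) labels[1] <- 1
    curve <- precision_recall_curve(probs, labels)
    expect_true(all(diff(curve$recall) <= 1e-12))
    expect_true(all(curve$tp + curve$fp + curve$fn + curve$tn == n))
  }
})

test_that("select_cutoff equals the exhaustive grid scan", {
  set.seed(8)
  for (i in 1:30) {
    n <- sample(20:100, 1)
    probs <- round(runif(n), 2)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.6))
    if (!any(labels == 1)) labels[1] <- 1
    curve <- precision_recall_curve(probs, labels)
    sel <- tryCatch(select_cutoff(curve), error = function(e) NULL)
    oracle <- oracle_select_cutoff(probs, labels)
    if (is.null(sel)) expect_null(oracle) else
      expect_equal(sel$cutoff, oracle)
  }
})

test_that("a curve where precision equals recall exactly at 0.72 selects 0.72", {
  # probabilities placed so that only the 0.72 grid point balances P and R:
  # 4 positives and 1 negative at 0.73, 1 positive at 0.71 (picked up by
  # every grid point at or below 0.70, lost at 0.72; nothing survives 0.74).
  probs <- c(0.73, 0.73, 0.73, 0.73, 0.71, 0.73)
  labels <- c(1, 1, 1, 1, 1, 0)
  curve <- precision_recall_curve(probs, labels)
  at <- curve[abs(curve$threshold - 0.72) < 1e-9, ]
  expect_equal(at$precision, at$recall)   # 4/5 each
  expect_equal(select_cutoff(curve)$cutoff, 0.72)
})

test_that("perfectly separable scores select the smallest all-correct threshold", {
  probs <- c(0.9, 0.85, 0.8, 0.1, 0.05)
  labels <- c(1, 1, 1, 0, 0)
  sel <- select_cutoff(precision_recall_curve(probs, labels))
  # grid points up to 0.10 still sweep in a negative (precision < 1);
  # 0.12 is the first threshold with precision = recall = 1, and the
  # P = R = 1 tie from 0.12 to 0.80 breaks toward the lowest threshold
  expect_equal(sel$cutoff, 0.12)
  expect_equal(sel$precision, 1); expect_equal(sel$recall, 1)
})

test_that("cross-validation is reproducible and skips degenerate replicates", {
  dat <- sim_table(mixed_sign_beta, n = 200L, seed = 3L)
  cv1 <- cross_validate(dat, reps = 5L, seed = 42L)
  cv2 <- cross_validate(dat, reps = 5L, seed = 42L)
  expect_identical(cv1$cutoffs, cv2$cutoffs)
  expect_true(all(cv1$cutoffs[!is.na(cv1$cutoffs)] %in% seq(0, 0.98, 0.02)))

  cv0 <- cross_validate(dat, reps = 0L)
  expect_length(cv0$cutoffs, 0)
  expect_true(!is.null(cv0$error))
})

test_that("ablation: full row reproduces the full model; zero-weight drop is inert", {
  beta <- mixed_sign_beta
  beta["first_exon_len"] <- 0            # a predictor with no true effect
  dat <- sim_table(beta, intercept = -0.2, n = 800L, seed = 17L)
  full <- suppressWarnings(train_classifier(dat))
  rep <- suppressWarnings(ablate_predictors(dat, full))

  full_row <- rep[rep$config == "full", ]
  expect_equal(full_row$precision, full$training_meta$cutoff_precision)
  expect_equal(full_row$recall, full$training_meta$cutoff_recall)

  drop0 <- rep[rep$config == "drop_first_exon_len", ]
  expect_lt(abs(drop0$precision - full_row$precision), 0.02)
  expect_lt(abs(drop0$recall - full_row$recall), 0.02)
  expect_identical(nrow(rep), 17L)       # full + 8 drop-one + 8 single
})

test_that("candidate classification is deterministic and needs a cutoff", {
  dat <- sim_table(mixed_sign_beta, n = 300L, seed = 9L)
  model <- suppressWarnings(train_classifier(dat))
  r1 <- classify_candidates(model, dat)
  r2 <- classify_candidates(model, dat)
  expect_identical(r1, r2)
  expect_identical(sum(r1$candidate) + sum(!r1$candidate), nrow(dat))

  empty <- dat[0, ]
  expect_identical(nrow(classify_candidates(model, empty)), 0L)

  nocut <- model; nocut$cutoff <- NA_real_
  expect_error(classify_candidates(nocut, dat), "cutoff")
})

test_that("classifier JSON round trips coefficients, cutoff and metadata", {
  dat <- sim_table(mixed_sign_beta, n = 300L, seed = 13L)
  model <- suppressWarnings(train_classifier(dat))
  path <- tempfile(fileext = ".json")
  write_classifier_json(model, path)
  back <- read_classifier_json(path)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$cutoff, model$cutoff)
  expect_identical(back$training_meta$n_pos, model$training_meta$n_pos)
})
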