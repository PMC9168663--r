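## Binomial logit-link classifier over the eight structural predictors.
## The fit is Newton/IRLS on internally standardized predictors (raw-scale
## coefficients are returned); quasi-separation is flagged, never silent.

# Numerically stable log(1 + exp(eta))
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

binomial_loglik <- function(beta, X, y, lambda = 0, pen_idx = NULL) {
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1pexp(eta))
  if (lambda > 0 && length(pen_idx))
    ll <- ll - lambda / 2 * sum(beta[pen_idx]^2)
  ll
}

#' Fit the binomial logit-link structural classifier
#'
#' Maximum-likelihood logistic regression of family membership
#' (`family` coded 1, `non_family` 0; other labels are dropped) on the
#' structural predictors, fitted by iteratively reweighted least
#' squares (Newton with step halving).  Predictors are standardized
#' internally for conditioning; coefficients are reported on the raw
#' scale.  Convergence is declared when the largest absolute
#' coefficient change falls below `tol`.  When fitted probabilities
#' saturate at 0/1 (quasi-separation, expected when the family's gene
#' structure is as stereotyped as the bicycle family's) the fit stops
#' at the iteration cap, sets a `separation` flag in `training_meta`
#' and warns; an optional ridge penalty `ridge` (applied to the
#' standardized slopes, recorded in `training_meta`) keeps estimates
#' finite if preferred.
#'
#' @param features Labeled feature table (see [feature_table()]); only
#'   rows labeled `family`/`non_family` are used.
#' @param predictors Character vector of predictor columns; default is
#'   every column of [structure_predictors()] present in `features`.
#' @param ridge Non-negative ridge penalty on standardized slopes.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   maximum absolute coefficient change (standardized scale).
#' @return An object of class `bicycle_classifier`: named raw-scale
#'   `coefficients`, `intercept`, `cutoff` (NA until selected),
#'   standard errors `se`, and `training_meta`.
#' @export
fit_logistic <- function(features,
                         predictors = intersect(structure_predictors(),
                                                names(features)),
                         ridge = 0, max_iter = 100L, tol = 1e-10) {
  lab <- features$label
  keep <- lab %in% c("family", "non_family")
  dat <- features[keep, , drop = FALSE]
  y <- as.numeric(dat$label == "family")
  if (!length(y) || all(y == 1) || all(y == 0))
    stop("training data must contain at least one family and one non_family row")
  Xr <- as.matrix(dat[, predictors, drop = FALSE])
  storage.mode(Xr) <- "double"
  if (any(!is.finite(Xr)))
    stop("non-finite feature values in training data")

  p <- ncol(Xr)
  if (p > 0) {
    m <- colMeans(Xr)
    s <- apply(Xr, 2, stats::sd)
    if (any(s == 0))
      stop("constant predictor(s): ", paste(predictors[s == 0], collapse = ", "))
    Z <- sweep(sweep(Xr, 2, m, "-"), 2, s, "/")
  } else {
    m <- s <- numeric(0)
    Z <- matrix(0, nrow = length(y), ncol = 0)
  }
  X <- cbind(`(Intercept)` = 1, Z)
  pen_idx <- if (p > 0) 2:(p + 1L) else integer(0)
  lambdaD <- diag(c(0, rep(ridge, p)), nrow = p + 1L)

  beta <- rep(0, p + 1L)
  ll <- binomial_loglik(beta, X, y, ridge, pen_idx)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + lambdaD
    g <- drop(crossprod(X, y - mu))
    if (ridge > 0) g <- g - drop(lambdaD %*% beta)
    delta <- tryCatch(solve(H, g), error = function(e)
      stop("singular information matrix during IRLS: ", conditionMessage(e)))
    # step halving if the (penalized) log-likelihood does not improve
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- binomial_loglik(cand, X, y, ridge, pen_idx)
      if (ll_new >= ll - 1e-12 || step < 2^-30) break
      step <- step / 2
    }
    beta <- beta + step * delta
    ll <- ll_new
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
  }

  mu <- stats::plogis(drop(X %*% beta))
  separation <- !converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)
  if (separation)
    warning("possible (quasi-)separation: fitted probabilities saturate ",
            "or IRLS hit the iteration cap; coefficients may be unstable",
            call. = FALSE)

  # back-transform to raw scale
  if (p > 0) {
    slopes <- beta[-1L] / s
    intercept <- beta[1L] - sum(beta[-1L] * m / s)
  } else {
    slopes <- numeric(0)
    intercept <- beta[1L]
  }
  names(slopes) <- predictors

  # standard errors from the raw-scale observed information (unpenalized)
  Xraw <- cbind(`(Intercept)` = 1, Xr)
  w <- pmax(mu * (1 - mu), 1e-12)
  se <- rep(NA_real_, p + 1L)
  cov_try <- tryCatch(solve(crossprod(Xraw, Xraw * w)), error = function(e) NULL)
  if (!is.null(cov_try)) se <- sqrt(pmax(diag(cov_try), 0))
  names(se) <- c("(Intercept)", predictors)

  structure(list(
    coefficients = slopes,
    intercept = unname(intercept),
    cutoff = NA_real_,
    se = se,
    training_meta = list(
      n_pos = sum(y == 1), n_neg = sum(y == 0),
      converged = converged, iterations = iter,
      separation = separation, ridge = ridge, tol = tol,
      predictors = predictors)
  ), class = "bicycle_classifier")
}

#' @export
print.bicycle_classifier <- function(x, ...) {
  cat("<bicycle_classifier>\n")
  cat(sprintf("  intercept: %.6g   cutoff: %s\n", x$intercept,
              if (is.na(x$cutoff)) "(not selected)" else format(x$cutoff)))
  print(x$coefficients)
  meta <- x$training_meta
  cat(sprintf("  trained on %d family / %d non_family rows; converged=%s%s\n",
              meta$n_pos, meta$n_neg, meta$converged,
              if (isTRUE(meta$separation)) " [separation flagged]" else ""))
  invisible(x)
}

#' Predict family-membership probabilities
#'
#' Evaluates the logistic response `1/(1 + exp(-(intercept + x'beta)))`
#' for each row of a feature table.
#'
#' @param model A `bicycle_classifier`.
#' @param features Feature table containing every predictor column the
#'   model was trained on.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "bicycle_classifier"))
  need <- names(model$coefficients)
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols))
    stop("feature table lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[, need, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values")
  stats::plogis(drop(model$intercept + X %*% model$coefficients))
}

#' Precision-recall curve over the probability-cutoff grid
#'
#' At each threshold t a row is predicted positive iff its probability
#' is >= t; precision = TP/(TP+FP) (recorded as NA when no row is
#' predicted positive) and recall = TP/(TP+FN).
#'
#' @param probs Probabilities.
#' @param labels 0/1 vector (or `family`/`non_family` characters) of
#'   the same length, with at least one positive.
#' @param thresholds Threshold grid; default 0 to 0.98 in steps of 0.02.
#' @return A data.frame of class `pr_curve` with columns `threshold`,
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `recall`.
#' @export
precision_recall_curve <- function(probs, labels,
                                   thresholds = seq(0, 0.98, by = 0.02)) {
  if (is.character(labels)) labels <- as.numeric(labels == "family")
  labels <- as.numeric(labels)
  if (length(probs) != length(labels))
    stop("probs and labels must have the same length")
  if (!any(labels == 1)) stop("no positive labels")
  npos <- sum(labels == 1)
  rows <- lapply(thresholds, function(t) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- npos - tp
    tn <- sum(!pred & labels == 0)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / npos)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Select the precision/recall-equalized cutoff
#'
#' Scans the threshold grid for the cutoff whose precision-to-recall
#' ratio is closest to 1.  Thresholds with undefined precision (no
#' predicted positives) or zero recall are excluded.  Ties are broken
#' deterministically: larger precision + recall, then lower threshold.
#'
#' @param curve A `pr_curve`.
#' @return List with `cutoff`, `precision`, `recall` at the cutoff, and
#'   the `tie_break` rule applied.
#' @export
select_cutoff <- function(curve) {
  ok <- !is.na(curve$precision) & curve$recall > 0
  if (!any(ok))
    stop("no threshold with defined precision/recall ratio")
  cand <- curve[ok, , drop = FALSE]
  score <- abs(cand$precision / cand$recall - 1)
  ord <- order(score, -(cand$precision + cand$recall), cand$threshold)
  best <- cand[ord[1L], ]
  list(cutoff = best$threshold, precision = best$precision,
       recall = best$recall,
       tie_break = "min |P/R - 1|, then max P + R, then min threshold")
}

#' Train the classifier and select its cutoff
#'
#' Convenience wrapper: [fit_logistic()] on the labeled rows, then a
#' training-set precision-recall curve and [select_cutoff()], with the
#' chosen cutoff stored in the model.
#'
#' @inheritParams fit_logistic
#' @param thresholds Cutoff grid for [precision_recall_curve()].
#' @return A `bicycle_classifier` with `cutoff` set; the training curve
#'   is attached as `training_meta$pr_curve`.
#' @export
train_classifier <- function(features,
                             predictors = intersect(structure_predictors(),
                                                    names(features)),
                             ridge = 0,
                             thresholds = seq(0, 0.98, by = 0.02), ...) {
  model <- fit_logistic(features, predictors = predictors, ridge = ridge, ...)
  keep <- features$label %in% c("family", "non_family")
  dat <- features[keep, , drop = FALSE]
  probs <- predict_prob(model, dat)
  curve <- precision_recall_curve(probs, dat$label, thresholds)
  sel <- select_cutoff(curve)
  model$cutoff <- sel$cutoff
  model$training_meta$cutoff_precision <- sel$precision
  model$training_meta$cutoff_recall <- sel$recall
  model$training_meta$pr_curve <- curve
  model
}

# precision/recall of probs vs labels at one fixed cutoff
pr_at_cutoff <- function(probs, labels, cutoff) {
  if (is.character(labels)) labels <- as.numeric(labels == "family")
  pred <- probs >= cutoff
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Cross-validate the cutoff selection
#'
#' Repeatedly samples a fraction of the labeled rows (unstratified),
#' trains on that fraction, and selects the precision/recall-equalized
#' cutoff on the held-out remainder.  Replicates whose train or test
#' portion contains a single class (or where no cutoff is selectable)
#' are skipped and counted.
#'
#' @param features Labeled feature table.
#' @param train_frac Training fraction (default 0.7).
#' @param reps Number of replicates (default 100).
#' @param seed Integer seed; results are fully reproducible.
#' @param thresholds Cutoff grid.
#' @param ridge Passed to [fit_logistic()].
#' @return List with per-replicate `cutoffs` (NA where skipped),
#'   `mean`, `sd`, `n_skipped`, `reps`, `seed`; with `reps = 0` an
#'   empty summary carrying an `error` flag.
#' @export
cross_validate <- function(features, train_frac = 0.7, reps = 100L,
                           seed = 1L, thresholds = seq(0, 0.98, by = 0.02),
                           ridge = 0) {
  if (reps < 1L)
    return(list(cutoffs = numeric(0), mean = NA_real_, sd = NA_real_,
                n_skipped = 0L, reps = 0L, seed = seed,
                error = "reps must be >= 1"))
  keep <- features$label %in% c("family", "non_family")
  dat <- features[keep, , drop = FALSE]
  n <- nrow(dat)
  n_train <- round(train_frac * n)
  if (n_train < 1L || n_train >= n)
    stop("train_frac leaves an empty train or test set")
  set.seed(seed)
  cutoffs <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n_train)
    train <- dat[idx, , drop = FALSE]
    test <- dat[-idx, , drop = FALSE]
    if (length(unique(train$label)) < 2L || length(unique(test$label)) < 2L)
      next
    cutoffs[r] <- tryCatch({
      model <- suppressWarnings(fit_logistic(train, ridge = ridge))
      probs <- predict_prob(model, test)
      select_cutoff(precision_recall_curve(probs, test$label, thresholds))$cutoff
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(cutoffs)
  list(cutoffs = cutoffs, mean = mean(cutoffs[ok]), sd = stats::sd(cutoffs[ok]),
       n_skipped = sum(!ok), reps = reps, seed = seed)
}

#' Predictor ablation report
#'
#' Retrains the classifier with each predictor removed one at a time
#' (drop-one) and with each predictor on its own (single), and
#' evaluates precision and recall of every configuration on the
#' labeled rows at the full model's cutoff.  The `full` row reproduces
#' the full model's precision/recall without refitting.
#'
#' @param features Labeled feature table the full model was trained on.
#' @param full_model A `bicycle_classifier` with a selected cutoff.
#' @param ridge Passed to the refits (defaults to the full model's).
#' @return data.frame with columns `config`, `type`
#'   (`full`/`drop_one`/`single`), `predictor`, `precision`, `recall`,
#'   `failed`.
#' @export
ablate_predictors <- function(features, full_model,
                              ridge = full_model$training_meta$ridge) {
  stopifnot(inherits(full_model, "bicycle_classifier"))
  if (is.na(full_model$cutoff))
    stop("full_model has no selected cutoff")
  preds <- names(full_model$coefficients)
  keep <- features$label %in% c("family", "non_family")
  dat <- features[keep, , drop = FALSE]
  labels <- as.numeric(dat$label == "family")
  cutoff <- full_model$cutoff

  eval_config <- function(predictors) {
    model <- suppressWarnings(
      fit_logistic(dat, predictors = predictors, ridge = ridge))
    pr_at_cutoff(predict_prob(model, dat), labels, cutoff)
  }

  rows <- list()
  pr_full <- pr_at_cutoff(predict_prob(full_model, dat), labels, cutoff)
  rows[[1L]] <- data.frame(config = "full", type = "full",
                           predictor = NA_character_,
                           precision = pr_full["precision"],
                           recall = pr_full["recall"], failed = FALSE)
  for (p in preds) {
    pr <- tryCatch(eval_config(setdiff(preds, p)), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      config = paste0("drop_", p), type = "drop_one", predictor = p,
      precision = if (is.null(pr)) NA_real_ else pr["precision"],
      recall = if (is.null(pr)) NA_real_ else pr["recall"],
      failed = is.null(pr))
  }
  for (p in preds) {
    pr <- tryCatch(eval_config(p), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      config = paste0("only_", p), type = "single", predictor = p,
      precision = if (is.null(pr)) NA_real_ else pr["precision"],
      recall = if (is.null(pr)) NA_real_ else pr["recall"],
      failed = is.null(pr))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score transcripts and flag family candidates
#'
#' Applies a trained classifier (with a selected cutoff) to a feature
#' table; rows with probability >= cutoff are flagged as candidates.
#'
#' @param model A `bicycle_classifier` with a cutoff.
#' @param features Feature table.
#' @return data.frame: the input features plus `prob` and `candidate`.
#' @export
classify_candidates <- function(model, features) {
  stopifnot(inherits(model, "bicycle_classifier"))
  if (is.na(model$cutoff))
    stop("model has no selected cutoff; run train_classifier() or ",
         "select_cutoff() first")
  if (nrow(features) == 0L) {
    out <- features
    out$prob <- numeric(0)
    out$candidate <- logical(0)
    return(out)
  }
  probs <- predict_prob(model, features)
  out <- features
  out$prob <- probs
  out$candidate <- probs >= model$cutoff
  out
}

#' Serialize / read a classifier as JSON
#'
#' The JSON holds the named coefficients, intercept, cutoff and
#' training metadata (the training PR curve is omitted).
#'
#' @param model A `bicycle_classifier`.
#' @param path File path.
#' @return `path` (write) or the classifier (read).
#' @export
write_classifier_json <- function(model, path) {
  stopifnot(inherits(model, "bicycle_classifier"))
  meta <- model$training_meta
  meta$pr_curve <- NULL
  obj <- list(coefficients = as.list(model$coefficients),
              intercept = model$intercept,
              cutoff = model$cutoff,
              se = as.list(model$se),
              training_meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutoff <- obj$cutoff
  if (is.null(cutoff)) cutoff <- NA_real_
  structure(list(
    coefficients = unlist(obj$coefficients),
    intercept = obj$intercept,
    cutoff = as.numeric(cutoff),
    se = unlist(obj$se),
    training_meta = obj$training_meta
  ), class = "bicycle_classifier")
}
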