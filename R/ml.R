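# Classification tasks on the feature table: SVM with an RBF kernel and
# L2-regularised (multinomial) logistic regression, evaluated by balanced
# accuracy over 50 repeated stratified 80/20 splits or leave-one-group-out
# folds over participants.

task_label_column <- function(task) {
  switch(task,
    type = "type", gender = "gender", age = "age_group",
    participant = "participant",
    stop("unknown task: ", task))
}

family_columns <- function(table, family) {
  ff <- feature_families()
  feats <- if (identical(family, "all")) ff$feature else {
    if (!family %in% ff$family) stop("unknown feature family: ", family)
    ff$feature[ff$family == family]
  }
  cols <- intersect(feats, names(table))
  if (length(cols) == 0L) stop("no feature columns of family '", family,
                               "' present in the table")
  cols
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recall over the classes present in `truth`
#' (robust to class imbalance; the trivial constant classifier scores `1/k`
#' on a k-class problem).
#'
#' @param truth,estimate factors or character vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, estimate) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(estimate[truth == cl] == cl)
  }, numeric(1)))
}

# z-score scaler fitted on training rows
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$mu), 2L, scaler$sd, `/`)
}

# fit SVM-RBF (cost 1, gamma = 1/(n_features * overall variance)) or
# L2 logistic regression (glmnet ridge at lambda = 1/n_train, the strength-1
# penalty) on standardised features
fit_classifier <- function(x, y, model = c("svm", "lr"), standardize = TRUE) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- factor(y)
  scaler <- if (standardize) fit_scaler(x) else list(mu = rep(0, ncol(x)),
                                                     sd = rep(1, ncol(x)))
  xs <- apply_scaler(scaler, x)
  fit <- if (model == "svm") {
    g <- 1 / (ncol(xs) * max(var(as.vector(xs)), 1e-12))
    e1071::svm(xs, y, kernel = "radial", cost = 1, gamma = g, scale = FALSE)
  } else {
    lam <- 1 / length(y)
    fam <- if (nlevels(y) > 2L) "multinomial" else "binomial"
    glmnet::glmnet(xs, y, family = fam, alpha = 0,
                   lambda = c(100 * lam, lam), standardize = FALSE)
  }
  structure(list(model = model, fit = fit, scaler = scaler,
                 levels = levels(y), features = colnames(x),
                 lambda = if (model == "lr") 1 / length(y) else NULL),
            class = "papilla_fit")
}

#' @export
predict.papilla_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- apply_scaler(object$scaler, x)
  if (object$model == "svm") {
    as.character(predict(object$fit, xs))
  } else {
    as.character(predict(object$fit, xs, s = object$lambda, type = "class"))
  }
}

# decision-based confidence in [0, 1]: fraction of pairwise contests won
# (SVM) or the maximum class probability (logistic regression)
predict_confidence <- function(object, newdata) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- apply_scaler(object$scaler, x)
  if (object$model == "svm") {
    pr <- predict(object$fit, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    cls <- as.character(pr)
    k <- length(object$levels)
    if (k == 2L) {
      conf <- 1 / (1 + exp(-abs(dv[, 1])))
    } else {
      pairs <- strsplit(colnames(dv), "/")
      wins <- sapply(seq_along(pairs), function(j) {
        winner <- ifelse(dv[, j] > 0, pairs[[j]][1], pairs[[j]][2])
        winner == cls
      })
      conf <- rowSums(wins) / (k - 1)
    }
    list(class = cls, confidence = as.numeric(conf))
  } else {
    pr <- predict(object$fit, xs, s = object$lambda, type = "response")
    if (length(dim(pr)) == 3L) {
      pm <- pr[, , 1]
      cls <- colnames(pm)[max.col(pm)]
      conf <- apply(pm, 1L, max)
    } else {
      p1 <- as.numeric(pr)
      cls <- ifelse(p1 > 0.5, object$levels[2], object$levels[1])
      conf <- pmax(p1, 1 - p1)
    }
    list(class = cls, confidence = as.numeric(conf))
  }
}

# stratified train/test split: ~test_fraction of each class in the test set;
# singleton classes stay in training (logged by the caller via attributes)
stratified_split <- function(y, test_fraction) {
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- floor(test_fraction * length(idx))
    if (length(idx) >= 2L && n_test >= 1L) {
      test <- c(test, sample(idx, n_test))
    }
  }
  sort(test)
}

#' Evaluate a classification task
#'
#' Fits the chosen model on the selected feature family and reports balanced
#' accuracy over repeated stratified 80/20 random splits (default 50) or
#' leave-one-group-out (LOGO) folds in which each participant's segments form
#' the test set once. Features are z-scored on each training split and the
#' scaling applied to the test rows. Classes absent from a LOGO fold's test
#' set are skipped in the macro mean. Deterministic given `seed`.
#'
#' @param table feature table from [assemble_features()] (optionally pruned).
#' @param task one of `"type"`, `"gender"`, `"age"` (age group),
#'   `"participant"`.
#' @param family `"baseline"`, `"curvature"`, `"topological"` or `"all"`.
#' @param model `"svm"` (RBF kernel) or `"lr"` (logistic regression).
#' @param scheme `"random"` (repeated stratified splits) or `"logo"`.
#' @param n_splits number of random splits.
#' @param test_fraction test proportion for random splits.
#' @param standardize z-score features on each training split.
#' @param seed integer seed.
#' @return A `papilla_eval`: per-split scores, mean and sd of balanced
#'   accuracy, aggregate confusion matrix, and the split definitions (used by
#'   [permutation_importance()]).
#' @export
evaluate_task <- function(table, task = c("type", "gender", "age", "participant"),
                          family = "all", model = c("svm", "lr"),
                          scheme = c("random", "logo"), n_splits = 50L,
                          test_fraction = 0.2, standardize = TRUE, seed = 1) {
  task <- match.arg(task)
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  if (task == "participant" && scheme == "logo") {
    stop("scheme 'logo' is incompatible with the participant task: ",
         "the held-out participant's label never appears in training")
  }
  label_col <- task_label_column(task)
  feats <- family_columns(table, family)

  keep <- stats::complete.cases(table[, c(label_col, feats)])
  tab <- table[keep, , drop = FALSE]
  y <- factor(tab[[label_col]])
  if (nlevels(y) < 2L) stop("task '", task, "' has fewer than 2 classes")
  x <- tab[, feats, drop = FALSE]

  test_sets <- if (scheme == "random") {
    lapply(seq_len(n_splits), function(s) {
      with_seed(derive_seed(seed, s), stratified_split(y, test_fraction))
    })
  } else {
    parts <- unique(tab$participant)
    if (length(parts) < 2L) stop("LOGO needs at least 2 participants")
    lapply(parts, function(p) which(tab$participant == p))
  }

  classes <- levels(y)
  # folds whose training rows expose fewer than 2 classes cannot be fitted
  # (possible for LOGO on very small cohorts); skip them with a warning
  usable <- vapply(test_sets, function(te) {
    length(unique(y[setdiff(seq_along(y), te)])) >= 2L
  }, logical(1))
  if (!all(usable)) {
    warning(sum(!usable), " fold(s) skipped: training rows contain a single class")
    test_sets <- test_sets[usable]
  }
  if (length(test_sets) == 0L) {
    stop("no usable folds: every training set contains a single class")
  }
  confusion <- matrix(0L, nlevels(y), nlevels(y),
                      dimnames = list(truth = classes, predicted = classes))
  scores <- numeric(length(test_sets))
  for (s in seq_along(test_sets)) {
    te <- test_sets[[s]]
    tr <- setdiff(seq_along(y), te)
    fit <- fit_classifier(x[tr, , drop = FALSE], y[tr], model = model,
                          standardize = standardize)
    pred <- predict(fit, x[te, , drop = FALSE])
    scores[s] <- balanced_accuracy(y[te], pred)
    pred_f <- factor(pred, levels = classes)
    confusion <- confusion + as.matrix(table(y[te], pred_f))
  }

  structure(list(task = task, family = family, model = model, scheme = scheme,
                 scores = tibble::tibble(
                   split = seq_along(test_sets),
                   balanced_accuracy = scores,
                   n_test = lengths(test_sets)),
                 mean = mean(scores), sd = sd(scores),
                 confusion = confusion, n = nrow(tab),
                 classes = classes, feature_columns = feats,
                 label_column = label_col, test_sets = test_sets,
                 standardize = standardize, seed = seed),
            class = "papilla_eval")
}

#' @export
print.papilla_eval <- function(x, ...) {
  cat(sprintf("<papilla_eval> task %s | %s features | %s | %s\n",
              x$task, x$family, toupper(x$model), x$scheme))
  cat(sprintf("  balanced accuracy %.3f +/- %.3f over %d splits (n = %d)\n",
              x$mean, x$sd, nrow(x$scores), x$n))
  invisible(x)
}
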