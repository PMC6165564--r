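#' @title Machine-learning validation of the encoding scheme
#' @description The encoder is validated by checking that classification of
#'   movement patterns from encoded signals is at least as good as from the
#'   raw signals: features are extracted from both groups, split 70/30 with
#'   stratification, and classified with linear discriminant analysis (LDA),
#'   cross-checked with a linear support vector machine (SVM).
#' @name ml_validation
NULL

#' F1 score from precision and recall
#'
#' Harmonic mean \code{2 * P * R / (P + R)}; defined as 0 (with a warning)
#' when both precision and recall are zero.
#'
#' @param precision,recall scalars in [0, 1].
#' @return scalar in [0, 1].
#' @examples
#' f1_score(0.9, 0.9)  # 0.9
#' f1_score(0.6, 0.3)  # 0.4
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) {
    warning("precision + recall is zero; F1 defined as 0")
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' Stratified 70/30 train-test split
#'
#' Splits a labeled feature set into 70% training and 30% testing rows,
#' stratified by class (each class contributes \code{round(0.7 * n_class)}
#' training rows).  Deterministic for a fixed seed; train and test are
#' disjoint and exhaustive.
#'
#' @param features an \code{"act_features"} data frame (or any data frame
#'   with a \code{label} column).
#' @param seed integer seed for the permutation.
#' @return list with \code{train} and \code{test} data frames.
#' @export
split_70_30 <- function(features, seed = 1L) {
  lab <- features$label
  if (is.null(lab)) stop("feature set has no label column", call. = FALSE)
  counts <- table(lab)
  if (any(counts < 2L))
    stop("every class needs at least 2 rows for a stratified split",
         call. = FALSE)
  # strata in order of first appearance: the partition is invariant under
  # class renaming
  strata <- factor(lab, levels = unique(lab))
  rng <- local({ set.seed(seed)
                 lapply(split(seq_along(lab), strata), sample) })
  tr <- unlist(lapply(rng, function(ix) ix[seq_len(round(0.7 * length(ix)))]),
               use.names = FALSE)
  te <- setdiff(seq_along(lab), tr)
  list(train = features[sort(tr), , drop = FALSE],
       test = features[sort(te), , drop = FALSE])
}

# z-score by train statistics; impute NA with train median; drop columns
# that are constant in training (they carry no discriminant information and
# break covariance-based fits)
standardize_features <- function(train, test) {
  xcols <- setdiff(names(train), "label")
  xtr <- as.matrix(train[, xcols, drop = FALSE])
  xte <- as.matrix(test[, xcols, drop = FALSE])
  med <- apply(xtr, 2L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_along(xcols)) {
    xtr[is.na(xtr[, j]), j] <- med[j]
    xte[is.na(xte[, j]), j] <- med[j]
  }
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2L, stats::sd)
  keep <- which(sdv > 0)
  if (!length(keep)) stop("all features constant in training data",
                          call. = FALSE)
  xtr <- scale(xtr[, keep, drop = FALSE], mu[keep], sdv[keep])
  xte <- scale(xte[, keep, drop = FALSE], mu[keep], sdv[keep])
  list(train = xtr, test = xte)
}

# L2-regularized squared-hinge linear SVM (primal, BFGS), one-vs-rest for
# more than two classes; deterministic, no RNG
svm_linear_fit <- function(x, y, C = 1) {
  classes <- sort(unique(y))
  fit_binary <- function(ypm) {
    n <- nrow(x); p <- ncol(x)
    obj <- function(th) {
      w <- th[1:p]; b <- th[p + 1L]
      m <- 1 - ypm * (drop(x %*% w) + b)
      0.5 * sum(w^2) + C * sum(pmax(m, 0)^2) / n
    }
    grd <- function(th) {
      w <- th[1:p]; b <- th[p + 1L]
      m <- 1 - ypm * (drop(x %*% w) + b)
      a <- ifelse(m > 0, m, 0) * ypm
      c(w - 2 * C * drop(crossprod(x, a)) / n, -2 * C * sum(a) / n)
    }
    stats::optim(rep(0, p + 1L), obj, grd, method = "BFGS",
                 control = list(maxit = 200))$par
  }
  W <- vapply(classes, function(cl) fit_binary(ifelse(y == cl, 1, -1)),
              numeric(ncol(x) + 1L))
  list(classes = classes, W = W)
}

svm_linear_predict <- function(fit, x) {
  scores <- x %*% fit$W[-nrow(fit$W), , drop = FALSE] +
    matrix(fit$W[nrow(fit$W), ], nrow(x), length(fit$classes), byrow = TRUE)
  fit$classes[max.col(scores, ties.method = "first")]
}

# per-class precision/recall/F1 and macro/positive-class summary
score_predictions <- function(truth, pred) {
  classes <- sort(unique(truth))
  tab <- table(factor(truth, classes), factor(pred, classes))
  per <- data.frame(class = classes,
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  for (i in seq_along(classes)) {
    tp <- tab[i, i]
    prec <- if (sum(tab[, i]) == 0) 0 else tp / sum(tab[, i])
    rec <- if (sum(tab[i, ]) == 0) 0 else tp / sum(tab[i, ])
    per$precision[i] <- prec
    per$recall[i] <- rec
    per$f1[i] <- if (prec + rec == 0) 0 else f1_score(prec, rec)
  }
  if (length(classes) == 2L) {
    pos <- grep("severe|abnormal", classes, ignore.case = TRUE, value = TRUE)
    pos <- if (length(pos) == 1L) pos else classes[2L]
    f1 <- per$f1[per$class == pos]
  } else {
    f1 <- mean(per$f1)
  }
  list(accuracy_pct = 100 * mean(truth == pred), f1 = f1, per_class = per,
       confusion = tab)
}

#' Fit a classifier on the training split and score the test split
#'
#' Features are z-scored with training statistics only; missing entries are
#' imputed with the training median and training-constant columns dropped.
#' \code{"lda"} fits linear discriminant analysis (no shrinkage);
#' \code{"svm"} fits a linear support vector machine (squared-hinge primal,
#' C = 1).  Binary tasks report the positive-class F1 (the
#' "Severe"/"Abnormal"-style label when recognizable), multi-class tasks the
#' macro-averaged F1.
#'
#' @param train,test data frames with feature columns plus \code{label}.
#' @param classifier \code{"lda"} or \code{"svm"}.
#' @param C SVM regularization constant.
#' @return An object of class \code{"act_classification"}: accuracy (in
#'   percent), F1, per-class precision/recall table, confusion matrix,
#'   classifier name, train/test sizes.
#' @export
classify <- function(train, test, classifier = c("lda", "svm"), C = 1) {
  classifier <- match.arg(classifier)
  if (length(unique(train$label)) < 2L)
    stop("training data must contain at least 2 classes", call. = FALSE)
  std <- standardize_features(train, test)
  ytr <- train$label
  pred <- if (classifier == "lda") {
    # collinearity among quantized features is expected; LDA still predicts
    fit <- tryCatch(suppressWarnings(MASS::lda(std$train, grouping = ytr)),
                    error = function(e)
                      stop("LDA fit failed (degenerate class covariance?): ",
                           conditionMessage(e), call. = FALSE))
    as.character(stats::predict(fit, std$test)$class)
  } else {
    fit <- svm_linear_fit(std$train, ytr, C = C)
    svm_linear_predict(fit, std$test)
  }
  sc <- score_predictions(test$label, pred)
  structure(c(sc, list(classifier = classifier, n_train = nrow(train),
                       n_test = nrow(test))),
            class = "act_classification")
}

#' @export
print.act_classification <- function(x, ...) {
  cat(sprintf("<act_classification> %s: accuracy %.1f%%, F1 %.3f (train %d / test %d)\n",
              x$classifier, x$accuracy_pct, x$f1, x$n_train, x$n_test))
  invisible(x)
}

#' Compare classification of raw versus encoded feature sets
#'
#' For each classifier, runs repeated stratified 70/30 splits (same seeds on
#' both groups) and summarizes accuracy and F1 per group, together with the
#' encoded-minus-raw accuracy gap and the fraction of seeds in which the
#' encoded group is at least as accurate as the raw group.
#'
#' @param raw_set,encoded_set \code{"act_features"} sets with matching
#'   labels, row for row.
#' @param classifiers character vector from \code{c("lda", "svm")}.
#' @param n_seeds number of repeated splits; default 25.
#' @param seed base seed; split s uses seed \code{seed + s - 1}.
#' @return An object of class \code{"act_comparison"}: \code{summary} data
#'   frame (classifier, group, mean/sd accuracy and F1), \code{gap} (encoded
#'   minus raw mean accuracy per classifier), \code{frac_encoded_ge_raw},
#'   and the per-seed accuracy tables.
#' @export
compare_raw_vs_encoded <- function(raw_set, encoded_set,
                                   classifiers = c("lda", "svm"),
                                   n_seeds = 25L, seed = 1L) {
  if (!identical(as.character(raw_set$label),
                 as.character(encoded_set$label)))
    stop("raw and encoded sets must carry identical labels, row for row",
         call. = FALSE)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  seeds <- seed + seq_len(n_seeds) - 1L
  per_seed <- list()
  summ <- NULL
  gap <- frac <- numeric(0)
  for (clf in classifiers) {
    acc <- matrix(NA_real_, n_seeds, 2L,
                  dimnames = list(NULL, c("raw", "encoded")))
    f1 <- acc
    for (s in seq_len(n_seeds)) {
      for (grp in c("raw", "encoded")) {
        set_ <- if (grp == "raw") raw_set else encoded_set
        sp <- split_70_30(set_, seed = seeds[s])
        r <- classify(sp$train, sp$test, classifier = clf)
        acc[s, grp] <- r$accuracy_pct
        f1[s, grp] <- r$f1
      }
    }
    per_seed[[clf]] <- list(accuracy = acc, f1 = f1, seeds = seeds)
    summ <- rbind(summ, data.frame(
      classifier = clf, group = c("raw", "encoded"),
      mean_accuracy_pct = colMeans(acc), sd_accuracy_pct = apply(acc, 2, stats::sd),
      mean_f1 = colMeans(f1), sd_f1 = apply(f1, 2, stats::sd),
      row.names = NULL))
    gap[clf] <- mean(acc[, "encoded"]) - mean(acc[, "raw"])
    frac[clf] <- mean(acc[, "encoded"] >= acc[, "raw"])
  }
  structure(list(summary = summ, gap = gap, frac_encoded_ge_raw = frac,
                 per_seed = per_seed),
            class = "act_comparison")
}

#' @export
print.act_comparison <- function(x, ...) {
  cat("<act_comparison> raw vs encoded feature classification\n")
  print(x$summary, row.names = FALSE, digits = 4)
  for (clf in names(x$gap))
    cat(sprintf("  %s: encoded - raw gap %+0.2f pp; encoded >= raw in %.0f%% of seeds\n",
                clf, x$gap[clf], 100 * x$frac_encoded_ge_raw[clf]))
  invisible(x)
}

#' Classification accuracy as a function of encoding bit depth
#'
#' For each candidate bit depth, encodes every signal, extracts features,
#' and evaluates a classifier over repeated stratified splits; returns the
#' mean accuracy per bit depth.  Used to show that very low bit depths (3
#' bits) preserve -- and typically sharpen -- the movement patterns that
#' drive classification.
#'
#' @param signals list of \code{"act_norm"} signals (or numeric series, with
#'   \code{fs} supplied).
#' @param labels class label per signal.
#' @param bits_list bit depths to sweep, e.g. \code{c(3, 4, 6, 8, 12)}.
#' @param classifier \code{"lda"} or \code{"svm"}.
#' @param n_seeds repeated splits per bit depth.
#' @param seed base seed.
#' @param fs sampling frequency when \code{signals} are bare vectors.
#' @return data frame with columns \code{bits}, \code{mean_accuracy_pct},
#'   \code{sd_accuracy_pct}.
#' @export
bit_sweep <- function(signals, labels, bits_list = c(3, 4, 6, 8, 12),
                      classifier = c("lda", "svm"), n_seeds = 10L,
                      seed = 1L, fs = NULL) {
  classifier <- match.arg(classifier)
  if (!length(bits_list)) stop("bits_list must be non-empty", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("bit sweep needs at least 2 classes", call. = FALSE)
  out <- data.frame(bits = as.integer(bits_list),
                    mean_accuracy_pct = NA_real_, sd_accuracy_pct = NA_real_)
  for (i in seq_along(bits_list)) {
    b <- bits_list[i]
    enc <- lapply(signals, function(s) {
      if (inherits(s, "act_norm")) encode_floor(s, bits = b)
      else encode_floor(s, bits = b, fs = fs)
    })
    fset <- feature_set(enc, labels, group = "encoded")
    accs <- vapply(seq_len(n_seeds), function(s) {
      sp <- split_70_30(fset, seed = seed + s - 1L)
      classify(sp$train, sp$test, classifier = classifier)$accuracy_pct
    }, numeric(1L))
    out$mean_accuracy_pct[i] <- mean(accs)
    out$sd_accuracy_pct[i] <- stats::sd(accs)
  }
  out
}
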