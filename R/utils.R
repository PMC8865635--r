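# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses (and advances) the
# current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` reproducible child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Linear SVM (libsvm via e1071) with the study's fixed hyperparameters:
# linear kernel, C = cost (default 1), no feature scaling. Class penalty
# weights are inverse to the class frequencies of the training fold:
# balanced folds behave exactly as unweighted SVMs do, while unbalanced
# folds (unavoidable in leave-one-out schemes) are not biased toward the
# majority class -- without this, leave-one-subject-out accuracy on null
# data collapses far below chance because the held-out observation always
# belongs to the fold's minority class. Returns predicted labels for
# `newx`. Degenerate training sets (constant features or one class) yield
# NA so callers can fall back to chance.
svm_predict <- function(x, y, newx, cost = 1) {
  y <- factor(y)
  if (nlevels(y) < 2L) return(rep(NA_character_, nrow(newx)))
  w <- length(y) / (nlevels(y) * table(y))
  fit <- tryCatch(
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
               class.weights = w),
    error = function(e) NULL)
  if (is.null(fit)) return(rep(NA_character_, nrow(newx)))
  as.character(predict(fit, newx))
}

# Stratified leave-one-out CV accuracy of the linear SVM for a two-class
# sample: each fold holds out one observation of each class (classes of
# unequal size contribute their surplus observations to single-class
# folds), so training folds stay balanced wherever the data allow it.
# Fully unstratified LOO would make every training fold unbalanced
# against the held-out observation's class, which biases inseparable or
# noise-level folds away from chance. x: observations x features, y:
# labels. NA predictions count as 0.5 (chance) so degenerate folds do not
# bias the estimate.
loo_cv_accuracy <- function(x, y, cost = 1) {
  y <- as.character(y)
  idx <- split(seq_along(y), y)
  nf <- max(lengths(idx))
  correct <- numeric(0)
  for (f in seq_len(nf)) {
    test <- unlist(lapply(idx, function(i) if (f <= length(i)) i[f]))
    p <- svm_predict(x[-test, , drop = FALSE], y[-test],
                     x[test, , drop = FALSE], cost = cost)
    correct <- c(correct,
                 ifelse(is.na(p), 0.5, as.numeric(p == y[test])))
  }
  mean(correct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
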