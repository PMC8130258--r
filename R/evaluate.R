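#' k-fold cross-validated predictive scores for food security
#'
#' Holds the network structure fixed and re-estimates the CPTs within each
#' fold, mirroring predictive validation in which structure is learned once
#' but parameters vary with the training subset. Rows are shuffled with the
#' seed and split into k near-equal contiguous folds (remainder rows go one
#' each to the leading folds). For every held-out household the exact
#' posterior of the outcome given all its other variables is computed, and
#' three scores are accumulated over all held-out predictions: the Brier
#' score, the information reward, and the Bayesian information reward whose
#' prior is the empirical food-insecure frequency of that fold's training
#' split.
#'
#' @param structure a valid [bn_structure] containing the outcome variable.
#' @param data a complete data.frame of 0-based integer state columns.
#' @param k number of folds (>= 2, default 10).
#' @param seed integer seed controlling the shuffle; the same seed gives a
#'   bitwise-identical report.
#' @param outcome name of the binary outcome column (state 1 = food
#'   insecure); default `"FS"`.
#' @param pseudocount smoothing pseudocount passed to [fit_cpts()].
#' @return An object of class `fsbn_scores`: list with `S_B`, `S_IR`,
#'   `S_BIR`, `folds`, `seed`, `n`.
#' @export
cross_validate <- function(structure, data, k = 10L, seed = 1L,
                           outcome = "FS", pseudocount = 1) {
  if (k < 2L) stop("k must be at least 2")
  n <- nrow(data)
  if (n < k) stop("fewer rows than folds")
  if (!(outcome %in% names(data))) stop("outcome column '", outcome, "' missing")
  perm <- with_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- fold_assignment(n, k)
  p_ins <- numeric(n)
  prior_of_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- which(fold_of == f)
    train <- data[-test, , drop = FALSE]
    net <- fit_cpts(structure, train, pseudocount = pseudocount)
    post <- posterior_given_rest(net, outcome, data[test, , drop = FALSE])
    p_ins[test] <- post[, 2L]
    prior_of_fold[[f]] <- mean(train[[outcome]] == 1L)
  }
  truth <- as.integer(data[[outcome]] == 1L)
  p_true <- ifelse(truth == 1L, p_ins, 1 - p_ins)
  bir_per_fold <- vapply(seq_len(k), function(f) {
    idx <- which(fold_of == f)
    bayesian_information_reward(p_ins[idx], truth[idx], prior_of_fold[[f]]) *
      length(idx)
  }, 1)
  structure(list(S_B = brier_score(p_ins, truth),
                 S_IR = information_reward(p_true),
                 S_BIR = sum(bir_per_fold) / n,
                 folds = as.integer(k), seed = as.integer(seed),
                 n = as.integer(n)),
            class = "fsbn_scores")
}

#' @export
print.fsbn_scores <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validation over %d households (seed %d)\n", x$folds, x$n,
    x$seed))
  cat(sprintf("  Brier score                 S_B   = %.4f\n", x$S_B))
  cat(sprintf("  Information reward          S_IR  = %.4f\n", x$S_IR))
  cat(sprintf("  Bayesian information reward S_BIR = %.4f\n", x$S_BIR))
  invisible(x)
}

# fold labels for positions 1..n after shuffling: near-equal contiguous
# chunks, remainder distributed one per leading fold
fold_assignment <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  rep(seq_len(k), times = sizes)
}

#' Train/test confusion matrix for food-security prediction
#'
#' Splits the data at random (by seed) into a training fraction and a test
#' remainder, fits CPTs on the training part with the structure fixed,
#' predicts each test household's most probable food-security state given
#' all its other variables (ties toward "food secure"), and tabulates the
#' result with food insecure as the positive class.
#'
#' @inheritParams cross_validate
#' @param train_fraction fraction of rows used for fitting (default 0.9).
#' @return An object of class `fsbn_confusion`: list with the 2x2 `table`
#'   (rows = true state, columns = predicted state) and counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_split <- function(structure, data, train_fraction = 0.9, seed = 1L,
                            outcome = "FS", pseudocount = 1) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  n <- nrow(data)
  n_train <- floor(train_fraction * n)
  if (n_train >= n || n_train < 1L) stop("empty train or test split")
  perm <- with_seed(seed, sample.int(n))
  train <- data[perm[seq_len(n_train)], , drop = FALSE]
  test <- data[perm[(n_train + 1L):n], , drop = FALSE]
  net <- fit_cpts(structure, train, pseudocount = pseudocount)
  post <- posterior_given_rest(net, outcome, test)
  pred <- max.col(post, ties.method = "first") - 1L  # ties toward state 0
  truth <- as.integer(test[[outcome]])
  tab <- table(factor(truth, levels = 0:1, labels = c("secure", "insecure")),
               factor(pred, levels = 0:1, labels = c("secure", "insecure")),
               dnn = c("true", "predicted"))
  structure(list(table = tab,
                 tp = tab["insecure", "insecure"],
                 fp = tab["secure", "insecure"],
                 tn = tab["secure", "secure"],
                 fn = tab["insecure", "secure"],
                 seed = as.integer(seed), n_test = nrow(test)),
            class = "fsbn_confusion")
}

#' @export
print.fsbn_confusion <- function(x, ...) {
  cat("Predictive confusion matrix (positive = food insecure), n_test =",
      x$n_test, "\n")
  print(x$table)
  invisible(x)
}

# evaluate 'expr' under a temporary RNG state so callers' streams survive
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
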