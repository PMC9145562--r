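# Stratified k-fold cross-validation of the species classifier.

#' Stratified fold assignment
#'
#' Spreads each class's members across the k folds as evenly as possible
#' (per-class fold counts differ by at most one), so every training set
#' keeps approximately the full data's class proportions. Deterministic
#' given `seed`.
#'
#' @param labels Class labels (factor or character).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector in `1..k`, aligned with `labels`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1L) {
  y <- as.factor(labels)
  if (any(table(y) < 2)) {
    small <- names(which(table(y) < 2))
    abort(sprintf("class(es) with fewer than 2 members: %s",
                  paste(small, collapse = ", ")),
          "antmorph_stratification_error")
  }
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    # a fresh permutation of 1..k recycled over the class, then shuffled:
    # per-class fold counts differ by <= 1 and remainders land on random folds
    fold[idx] <- sample(rep_len(sample.int(k), length(idx)))
  }
  fold
}

#' Cross-validate the neural-network species classifier
#'
#' Stratified k-fold cross-validation: for each fold, the network is trained
#' on the remaining folds (predictor scaling learned from those rows only)
#' and evaluated on the held-out fold. Per-fold confusion matrices and
#' performance measures are reported together with their arithmetic mean.
#'
#' @param table A [specimen_table()] with >= 2 species.
#' @param k Number of folds.
#' @param hidden,learn_rate,epochs,tol Passed to [train_nn()].
#' @param seed Seed driving both the fold assignment and the per-fold weight
#'   initializations.
#' @param average Metric aggregation, `"macro"` or `"micro"`.
#' @return An object of class `cv_report`: list with `folds` (per fold:
#'   `confusion`, `metrics`, `test_size`) and `summary` (data frame of
#'   per-fold metric rows plus a terminal `averaged` row).
#' @export
cross_validate <- function(table, k = 10, hidden = c(10, 10, 10),
                           learn_rate = 0.2, epochs = 3000, tol = 1e-8,
                           seed = 1L, average = "macro") {
  mm <- build_model_matrix(table)
  if (nlevels(mm$y) < 2) {
    abort("need at least 2 species for classification",
          "antmorph_validation_error")
  }
  fold <- stratified_folds(mm$y, k = k, seed = seed)
  classes <- levels(mm$y)
  folds <- list()
  rows <- list()
  for (f in sort(unique(fold))) {
    test <- fold == f
    model <- train_nn(mm$x[!test, , drop = FALSE], mm$y[!test],
                      hidden = hidden, learn_rate = learn_rate,
                      epochs = epochs, tol = tol, seed = seed + f)
    pred <- predict(model, mm$x[test, , drop = FALSE])$class
    pred <- factor(as.character(pred), levels = classes)
    confusion <- table(truth = factor(mm$y[test], levels = classes),
                       prediction = pred)
    stopifnot(sum(confusion) == sum(test))
    met <- classification_metrics(unclass(confusion), average = average)
    folds[[length(folds) + 1L]] <- list(fold = f, confusion = confusion,
                                        metrics = met, test_size = sum(test))
    rows[[length(rows) + 1L]] <- data.frame(fold = as.character(f),
                                            t(met), stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, rows)
  avg <- colMeans(summary_df[, -1, drop = FALSE])
  summary_df <- rbind(summary_df,
                      data.frame(fold = "averaged", t(avg),
                                 stringsAsFactors = FALSE))
  rownames(summary_df) <- NULL
  structure(list(folds = folds, summary = summary_df, k = k,
                 average = average, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (%s-averaged metrics)\n",
              x$k, x$average))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
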