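# two well-separated Gaussian blobs in 43 dimensions
blob_data <- function(n = 25, gap = 8, k = 2, seed = 7) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n * 43, mean = gap * (i - 1)), ncol = 43)
  }))
  list(x = x, y = factor(rep(letters[seq_len(k)], each = n)))
}

test_that("model matrix has 43 aligned columns with infection interactions", {
  tab <- toy_table(n_per_cell = 3)
  mm <- build_model_matrix(tab)
  expect_identical(dim(mm$x), c(nrow(tab), 43L))
  expect_identical(length(mm$y), nrow(tab))
  un <- !tab$infected
  inter_cols <- paste0(trait_codes(), ":infected")
  expect_true(all(mm$x[un, inter_cols] == 0))
  expect_equal(mm$x[!un, inter_cols], mm$x[!un, trait_codes()],
               ignore_attr = TRUE)
  expect_identical(colnames(mm$x)[22], "infected")

  tab81 <- simulate_specimens(study_scenario(), seed = 1)
  expect_identical(dim(build_model_matrix(tab81)$x), c(81L, 43L))
})

test_that("training is deterministic, attains separable data, flags divergence", {
  d <- blob_data()
  m1 <- train_nn(d$x, d$y, epochs = 800, seed = 3)
  m2 <- train_nn(d$x, d$y, epochs = 800, seed = 3)
  expect_identical(m1$layers, m2$layers)
  m3 <- train_nn(d$x, d$y, epochs = 800, seed = 4)
  expect_false(identical(m1$layers, m3$layers))

  pred <- predict(m1, d$x)
  expect_equal(mean(pred$class == d$y), 1.0)

  expect_error(train_nn(d$x, d$y, learn_rate = Inf, epochs = 50),
               "learn_rate", class = "antmorph_divergence_error")
  expect_error(train_nn(d$x, factor(rep("a", nrow(d$x)))),
               class = "antmorph_validation_error")
})

test_that("training loss is non-increasing for a small step size", {
  d <- blob_data(n = 15)
  m <- train_nn(d$x, d$y, learn_rate = 0.01, epochs = 400, tol = 0)
  expect_true(all(diff(m$loss) <= 1e-9))
})

test_that("probabilities sum to one; untrained nets are near-uniform; ties break low", {
  d <- blob_data(n = 10, k = 3)
  m <- train_nn(d$x, d$y, epochs = 0)
  p <- predict(m, d$x)$prob
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_true(all(abs(p - 1 / 3) < 0.2))

  # exact tie: zero weights give identical output activations
  m0 <- m
  m0$layers <- lapply(m0$layers, function(l) {
    l$w[] <- 0; l$b[] <- 0; l
  })
  pr <- predict(m0, d$x)
  expect_true(all(abs(pr$prob - 1 / 3) < 1e-12))
  expect_true(all(pr$class == levels(d$y)[1]))

  expect_error(predict(m, d$x[, 1:10]), class = "antmorph_dimension_error")
})

test_that("stratified folds spread classes evenly and partition the data", {
  # exact divisibility: every fold gets one of each class
  y <- rep(c("a", "b", "c"), each = 10)
  f <- stratified_folds(y, k = 10, seed = 1)
  expect_identical(sort(unique(f)), 1:10)
  for (cl in c("a", "b", "c")) {
    expect_true(all(table(f[y == cl]) == 1))
  }

  # pigeonhole: class of 6 into 10 folds -> six folds of 1, four of 0
  y2 <- c(rep("big", 40), rep("small", 6))
  f2 <- stratified_folds(y2, k = 10, seed = 2)
  counts <- table(factor(f2[y2 == "small"], levels = 1:10))
  expect_identical(sort(as.integer(counts)), c(rep(0L, 4), rep(1L, 6)))

  # study-like sizes: per-fold class counts within +/-1 of n/k
  y3 <- rep(c("ny", "so", "un"), c(39, 25, 17))
  f3 <- stratified_folds(y3, k = 10, seed = 3)
  for (cl in unique(y3)) {
    counts <- table(factor(f3[y3 == cl], levels = 1:10))
    expect_lte(diff(range(counts)), 1)
  }
  # partition: disjoint test sets covering every row
  expect_length(f3, length(y3))
  expect_true(all(f3 %in% 1:10))

  expect_identical(stratified_folds(y3, k = 10, seed = 5),
                   stratified_folds(y3, k = 10, seed = 5))
  expect_error(stratified_folds(c("a", "b", "b"), k = 2),
               class = "antmorph_stratification_error")
})

test_that("metrics match hand values and the binary MCC closed form", {
  perfect <- classification_metrics(diag(5, 3))
  expect_equal(unname(perfect), rep(1, 5))

  uniform <- classification_metrics(matrix(1, 2, 2))
  expect_equal(unname(uniform[["accuracy"]]), 0.5)
  expect_equal(unname(uniform[["mcc"]]), 0)

  # worked 2x2 example against the brute-force binary formula
  m <- matrix(c(3, 2, 1, 4), 2, byrow = TRUE)  # tp=3 fn=1 fp=2 tn=4
  tp <- 3; fn <- 1; fp <- 2; tn <- 4
  binary <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mcc(m), binary, tolerance = 1e-12)

  # property: multiclass MCC reduces to the binary formula on random 2x2s
  set.seed(11)
  for (i in 1:200) {
    cm <- matrix(rpois(4, 5), 2)
    if (sum(cm) == 0) next
    tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    binary <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    expect_equal(mcc(cm), binary, tolerance = 1e-12)
  }

  # micro aggregation pools counts: precision equals accuracy then
  cm3 <- matrix(c(5, 1, 0, 2, 6, 1, 0, 1, 4), 3, byrow = TRUE)
  mic <- classification_metrics(cm3, average = "micro")
  expect_equal(unname(mic[["precision"]]), unname(mic[["accuracy"]]))
  expect_error(classification_metrics(matrix(0, 2, 2)),
               class = "antmorph_validation_error")
})

test_that("cross-validation partitions rows and scores the separable scenario", {
  sc <- small_scenario(n_un = 8, n_inf = 8)
  tab <- simulate_specimens(sc, seed = 13)
  cv <- cross_validate(tab, k = 4, seed = 13, epochs = 2000)
  sizes <- vapply(cv$folds, `[[`, 0, "test_size")
  expect_equal(sum(sizes), nrow(tab))
  for (f in cv$folds) expect_equal(sum(f$confusion), f$test_size)
  avg <- cv$summary[cv$summary$fold == "averaged", -1]
  expect_equal(unlist(avg),
               colMeans(as.matrix(cv$summary[cv$summary$fold != "averaged", -1])),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_gte(avg$accuracy, 0.95)
})

test_that("label permutation drives accuracy to chance", {
  sc <- small_scenario(n_un = 10, n_inf = 10)
  tab <- simulate_specimens(sc, seed = 17)
  df <- as.data.frame(tab)
  set.seed(17)
  df$species <- sample(as.character(df$species))
  perm <- specimen_table(df)
  cv <- cross_validate(perm, k = 5, seed = 17, epochs = 400)
  avg <- cv$summary[cv$summary$fold == "averaged", ]
  expect_lt(avg$accuracy, 0.6)
  expect_gt(avg$accuracy, 0.1)
  # macro sensitivity near 1/k_classes
  expect_lt(abs(avg$sensitivity - 1 / 3), 0.25)
})
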