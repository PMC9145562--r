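# From-scratch feed-forward neural network species classifier.
#
# Architecture: 43 inputs (21 traits + infection indicator + 21
# trait x infection products), three hidden layers of ten units, one output
# unit per species. Every node uses the logistic activation; class
# probabilities are the output activations normalized by their sum, and the
# model is trained by full-batch gradient descent on the multiclass
# cross-entropy.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Build the classifier model matrix
#'
#' Predictors are the 21 raw trait values, the infection indicator (0/1),
#' and the 21 trait-by-infection product columns (zero for uninfected
#' specimens, equal to the trait columns for infected ones). Column scaling
#' is deliberately NOT applied here: [train_nn()] learns it from its
#' training rows so cross-validation cannot leak test information.
#'
#' @param table A [specimen_table()].
#' @return List with `x` (n x 43 numeric matrix) and `y` (factor of species
#'   labels aligned with the rows).
#' @export
build_model_matrix <- function(table) {
  table <- specimen_table(table)
  tm <- trait_matrix(table)
  inf <- as.numeric(table$infected)
  inter <- tm * inf
  colnames(inter) <- paste0(colnames(tm), ":infected")
  x <- cbind(tm, infected = inf, inter)
  list(x = x, y = factor(as.character(table$species)))
}

.init_layers <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(i) {
    n_in <- sizes[i]
    n_out <- sizes[i + 1]
    lim <- sqrt(6 / (n_in + n_out))   # Xavier-style uniform
    list(w = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
         b = rep(0, n_out))
  })
}

.forward <- function(layers, x) {
  a <- vector("list", length(layers) + 1)
  a[[1]] <- x
  for (i in seq_along(layers)) {
    a[[i + 1]] <- sigmoid(sweep(a[[i]] %*% layers[[i]]$w, 2,
                                layers[[i]]$b, "+"))
  }
  a
}

# probabilities: logistic output activations normalized to sum to 1
.normalize <- function(a_out) {
  a_out / pmax(rowSums(a_out), .Machine$double.eps)
}

#' Train the neural-network species classifier
#'
#' Full-batch gradient descent with backpropagation on the multiclass
#' cross-entropy loss. Predictor columns are z-scaled with parameters
#' estimated from the supplied rows (stored in the model and re-applied at
#' prediction time); constant columns get unit scale. Deterministic given
#' `seed`.
#'
#' @param x Numeric predictor matrix (rows = specimens).
#' @param y Factor of class labels (>= 2 levels present).
#' @param hidden Hidden layer sizes; default three layers of ten units.
#' @param learn_rate Gradient-descent step size.
#' @param epochs Maximum number of full-batch epochs.
#' @param tol Stop early when the loss decreases by less than this between
#'   epochs.
#' @param seed Seed for weight initialization.
#' @return An object of class `nn_model`: layer weights, class levels,
#'   column scaling, the per-epoch loss trace, and the hyperparameters.
#' @export
train_nn <- function(x, y, hidden = c(10, 10, 10), learn_rate = 0.2,
                     epochs = 3000, tol = 1e-8, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    abort("need at least 2 classes", "antmorph_validation_error")
  }
  if (!all(is.finite(x))) {
    abort("predictor matrix contains non-finite values",
          "antmorph_validation_error")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  k <- nlevels(y)
  ymat <- diag(k)[as.integer(y), , drop = FALSE]
  n <- nrow(xs)

  set.seed(as.integer(seed))
  layers <- .init_layers(c(ncol(xs), hidden, k))
  nl <- length(layers)
  loss_trace <- numeric(0)
  loss_prev <- Inf
  for (ep in seq_len(epochs)) {
    a <- .forward(layers, xs)
    p <- .normalize(a[[nl + 1]])
    loss <- -sum(ymat * log(pmax(p, 1e-12))) / n
    if (!is.finite(loss)) {
      abort("training loss diverged; reduce learn_rate",
            "antmorph_divergence_error")
    }
    loss_trace <- c(loss_trace, loss)
    if (abs(loss_prev - loss) < tol) break
    loss_prev <- loss
    # output layer: dL/da = (-y/a + 1/sum(a)) / n, then through the logistic
    a_out <- a[[nl + 1]]
    s <- rowSums(a_out)
    delta <- ((-ymat / pmax(a_out, 1e-12) + 1 / s) / n) * a_out * (1 - a_out)
    for (i in rev(seq_len(nl))) {
      gw <- crossprod(a[[i]], delta)
      gb <- colSums(delta)
      if (i > 1) {
        back <- delta %*% t(layers[[i]]$w)
        ah <- a[[i]]
        delta <- back * ah * (1 - ah)
      }
      layers[[i]]$w <- layers[[i]]$w - learn_rate * gw
      layers[[i]]$b <- layers[[i]]$b - learn_rate * gb
      if (!all(is.finite(layers[[i]]$w)) || !all(is.finite(layers[[i]]$b))) {
        abort("training diverged (non-finite weights); reduce learn_rate",
              "antmorph_divergence_error")
      }
    }
  }
  structure(
    list(layers = layers, classes = levels(y), center = center,
         scale = scale_, loss = loss_trace,
         hyper = list(hidden = hidden, learn_rate = learn_rate,
                      epochs = epochs, tol = tol, seed = seed)),
    class = "nn_model"
  )
}

#' Predict species from a trained network
#'
#' @param object An `nn_model` from [train_nn()].
#' @param x Predictor matrix with the same columns as at training time.
#' @param ... Unused.
#' @return List with `prob` (rows summing to 1 over the class levels) and
#'   `class` (factor; argmax with ties broken toward the first class in
#'   canonical level order).
#' @export
predict.nn_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != length(object$center)) {
    abort(sprintf("predictor matrix has %d columns; model expects %d",
                  ncol(x), length(object$center)),
          "antmorph_dimension_error")
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  a <- .forward(object$layers, xs)
  p <- .normalize(a[[length(a)]])
  colnames(p) <- object$classes
  cls <- factor(object$classes[max.col(p, ties.method = "first")],
                levels = object$classes)
  list(prob = p, class = cls)
}

#' @export
print.nn_model <- function(x, ...) {
  sizes <- c(length(x$center), x$hyper$hidden, length(x$classes))
  cat(sprintf("<nn_model> layers %s, %d epochs run, final loss %.5f\n",
              paste(sizes, collapse = "-"), length(x$loss),
              if (length(x$loss)) tail(x$loss, 1) else NA_real_))
  invisible(x)
}
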