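# Principal component ordination of trait tables, used to compare
# uninfected, infected and reconstructed specimens in a common
# low-dimensional space.

#' Fit a PCA of the trait columns
#'
#' Correlation-matrix PCA by default (`scale = TRUE`), since the traits
#' share micrometre units but differ in magnitude. Component signs follow a
#' deterministic convention: the loading with the largest absolute value on
#' each axis is positive.
#'
#' @param table A [specimen_table()] (or any data frame with the trait
#'   columns), >= 3 rows.
#' @param n_axes Number of axes retained for reporting (all are kept
#'   internally).
#' @param scale Scale traits to unit variance before decomposition.
#' @return An object of class `morph_pca`: `scores` (retained axes),
#'   `loadings`, `var_explained` (fractions, all axes), `sdev`, `center`,
#'   `scale`, `n_axes`.
#' @export
fit_pca <- function(table, n_axes = 2, scale = TRUE) {
  m <- as.matrix(as.data.frame(table)[, trait_codes(), drop = FALSE])
  if (nrow(m) < 3) {
    abort("PCA needs at least 3 specimens", "antmorph_validation_error")
  }
  pc <- prcomp(m, center = TRUE, scale. = scale)
  # deterministic sign: largest-magnitude loading positive per axis
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(
    list(scores = pc$x[, seq_len(min(n_axes, ncol(pc$x))), drop = FALSE],
         scores_all = pc$x,
         loadings = pc$rotation,
         var_explained = pc$sdev^2 / sum(pc$sdev^2),
         sdev = pc$sdev,
         center = pc$center,
         scale = if (isFALSE(pc$scale)) NULL else pc$scale,
         n_axes = n_axes),
    class = "morph_pca"
  )
}

#' Project specimens into a fitted PCA space
#'
#' New specimens (e.g. reconstructed ones) are centred and scaled with the
#' parameters stored at fit time, then rotated onto the retained axes.
#'
#' @param pca A `morph_pca` from [fit_pca()].
#' @param table Table with the same trait columns.
#' @return Score matrix (rows x retained axes).
#' @export
project_pca <- function(pca, table) {
  m <- as.data.frame(table)
  missing_tr <- setdiff(trait_codes(), names(m))
  if (length(missing_tr)) {
    abort(sprintf("trait column(s) missing for projection: %s",
                  paste(missing_tr, collapse = ", ")),
          "antmorph_schema_error")
  }
  m <- as.matrix(m[, trait_codes(), drop = FALSE])
  m <- sweep(m, 2, pca$center)
  if (!is.null(pca$scale)) m <- sweep(m, 2, pca$scale, "/")
  m %*% pca$loadings[, seq_len(min(pca$n_axes, ncol(pca$loadings))),
                     drop = FALSE]
}

#' Per-species ordination plots
#'
#' For each species, fits a PCA on its observed specimens, projects any
#' reconstructed specimens of that species into the same space, and writes
#' one figure: filled circles = uninfected, filled triangles = infected,
#' empty triangles = reconstructed (predicted wild-type) values.
#'
#' @param table A [specimen_table()] of observed specimens.
#' @param recon Optional `reconstructed_table` (its reconstructed rows are
#'   overlaid).
#' @param dir Output directory, created if needed.
#' @param scale Passed to [fit_pca()].
#' @return Invisibly, the figure file paths (one per species).
#' @export
plot_ordination <- function(table, recon = NULL, dir, scale = TRUE) {
  table <- specimen_table(table)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in levels(table$species)) {
    sub <- as.data.frame(table)[as.character(table$species) == s, ]
    pca <- fit_pca(sub, n_axes = 2, scale = scale)
    rec_scores <- NULL
    if (!is.null(recon)) {
      rsub <- as.data.frame(recon)
      rsub <- rsub[as.character(rsub$species) == s & rsub$reconstructed, ]
      if (nrow(rsub)) rec_scores <- project_pca(pca, rsub)
    }
    path <- file.path(dir, sprintf("ordination_%s.png", s))
    grDevices::png(path, width = 650, height = 600)
    ve <- round(100 * pca$var_explained[1:2], 1)
    plot(pca$scores[, 1], pca$scores[, 2],
         type = "n",
         xlab = sprintf("PC1 (%.1f%%)", ve[1]),
         ylab = sprintf("PC2 (%.1f%%)", ve[2]),
         main = s)
    un <- !sub$infected
    points(pca$scores[un, 1], pca$scores[un, 2], pch = 16)
    points(pca$scores[!un, 1], pca$scores[!un, 2], pch = 17)
    leg <- c("uninfected", "infected")
    pchs <- c(16, 17)
    if (!is.null(rec_scores)) {
      points(rec_scores[, 1], rec_scores[, 2], pch = 2)
      leg <- c(leg, "reconstructed")
      pchs <- c(pchs, 2)
    }
    legend("topright", legend = leg, pch = pchs, bty = "n")
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  invisible(paths)
}
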