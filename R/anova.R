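# Linear-model stage: the global trait x infection x species model on the
# long-format table, per-trait species x infection models on species-scaled
# values, marginal-mean infection contrasts, and Bonferroni adjustment.

.status_factor <- function(infected) {
  factor(ifelse(infected, "infected", "uninfected"),
         levels = c("uninfected", "infected"))
}

# one row per specimen x trait; trait levels in canonical order
to_long <- function(table, traits = trait_codes()) {
  n <- nrow(table)
  data.frame(
    specimen_id = rep(table$specimen_id, times = length(traits)),
    species = factor(rep(as.character(table$species), times = length(traits))),
    status = .status_factor(rep(table$infected, times = length(traits))),
    trait = factor(rep(traits, each = n), levels = traits),
    value = unlist(lapply(traits, function(tr) table[[tr]]),
                   use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

.check_cells <- function(table) {
  tab <- table(as.character(table$species), table$infected)
  if (ncol(tab) < 2 || any(tab == 0)) {
    empty <- character(0)
    for (s in rownames(tab)) {
      for (st in c("uninfected", "infected")) {
        col <- st == "infected"
        cnt <- if (as.character(col) %in% colnames(tab)) tab[s, as.character(col)] else 0
        if (cnt == 0) empty <- c(empty, sprintf("%s:%s", s, st))
      }
    }
    abort(sprintf("empty species x infection cell(s): %s",
                  paste(empty, collapse = ", ")),
          "antmorph_design_error")
  }
  invisible(TRUE)
}

# anova(lm) -> tidy sequential table, with df bookkeeping asserted
.tidy_anova <- function(fit) {
  a <- anova(fit)
  out <- data.frame(
    term = rownames(a),
    df = a$Df,
    sum_sq = a$`Sum Sq`,
    mean_sq = a$`Mean Sq`,
    statistic = a$`F value`,
    p_value = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  stopifnot(sum(out$df) == length(fit$residuals) - 1)
  out
}

#' Fit the global trait-by-infection-by-species model
#'
#' Stacks the table to long format (one row per specimen x trait) and fits
#' `value ~ trait * status * species`, reporting the sequential (Type I)
#' ANOVA decomposition in model order: trait, status, species, their three
#' two-way interactions, the three-way interaction, and residuals. A
#' significant trait:status:species term indicates that infection moves
#' different traits differently in different species.
#'
#' @param table A [specimen_table()] (raw micrometres) or a `scaled_table`.
#' @param prescale How to transform trait values before stacking: a single
#'   number used as a division factor (default `1000`, expressing
#'   micrometre measurements in millimetres — the convention under which
#'   trait differences dominate the decomposition, as in published tables
#'   of this design), `"species_z"` (per-species standardization, which
#'   removes the trait and species main effects), or `"none"`. Ignored when
#'   `table` is already scaled.
#' @param traits Trait codes to stack; defaults to the full registry.
#'   Factors with a single observed level (e.g. one trait, or one species)
#'   are dropped from the model formula, so the design degrades gracefully
#'   to the nested comparisons it implies.
#' @return An object of class `morph_anova`: list with `anova` (tidy
#'   sequential table), `model` (the `lm` fit) and `n_obs`.
#' @export
fit_global_model <- function(table, prescale = 1000, traits = trait_codes()) {
  if (inherits(table, "scaled_table")) {
    tab <- table
  } else if (identical(prescale, "species_z")) {
    tab <- scale_by_species(table)
  } else if (identical(prescale, "none")) {
    tab <- specimen_table(table)
  } else if (is.numeric(prescale) && length(prescale) == 1 && prescale > 0) {
    tab <- as.data.frame(specimen_table(table))
    for (tr in trait_codes()) tab[[tr]] <- tab[[tr]] / prescale
  } else {
    abort("prescale must be \"species_z\", \"none\" or a positive number",
          "antmorph_validation_error")
  }
  .check_cells(tab)
  stopifnot(all(traits %in% trait_codes()))
  long <- to_long(tab, traits = traits)
  vars <- c("trait", "status", "species")
  vars <- vars[vapply(vars, function(v) length(unique(long[[v]])) > 1, TRUE)]
  if (!length(vars)) {
    abort("no predictor varies in this design", "antmorph_design_error")
  }
  fml <- stats::reformulate(paste(vars, collapse = " * "), response = "value")
  fit <- lm(fml, data = long)
  structure(
    list(anova = .tidy_anova(fit), model = fit, n_obs = nrow(long),
         prescale = if (inherits(table, "scaled_table")) "pre-scaled" else prescale),
    class = "morph_anova"
  )
}

#' @export
print.morph_anova <- function(x, ...) {
  cat(sprintf("Sequential ANOVA (%d observations)\n", x$n_obs))
  print(x$anova, digits = 4)
  invisible(x)
}

#' Fit one species-by-infection model per trait
#'
#' On per-species standardized values, fits
#' `value ~ species * status` separately for each of the 21 traits and
#' returns the sequential ANOVA per trait together with the
#' species:status interaction p-values, Bonferroni-adjusted across the
#' trait family.
#'
#' @param table A [specimen_table()] (standardized internally) or a
#'   `scaled_table` from [scale_by_species()].
#' @param family_size Bonferroni family for the interaction p-values;
#'   defaults to the number of traits.
#' @return An object of class `trait_models`: list with `models` (named list
#'   of `lm` fits), `data` (named list of per-trait model frames), `anova`
#'   (stacked tidy tables with a `trait` column) and `interaction`
#'   (data frame: trait, df, statistic, p_raw, p_adjusted).
#' @export
fit_trait_models <- function(table, family_size = NULL) {
  tab <- if (inherits(table, "scaled_table")) table else scale_by_species(table)
  .check_cells(tab)
  traits <- trait_codes()
  if (is.null(family_size)) family_size <- length(traits)
  status <- .status_factor(tab$infected)
  species <- factor(as.character(tab$species))
  models <- list()
  datas <- list()
  tabs <- list()
  inter <- list()
  for (tr in traits) {
    d <- data.frame(value = tab[[tr]], species = species, status = status)
    fit <- lm(value ~ species * status, data = d)
    a <- .tidy_anova(fit)
    ri <- match("species:status", a$term)
    models[[tr]] <- fit
    datas[[tr]] <- d
    tabs[[tr]] <- cbind(trait = tr, a)
    inter[[tr]] <- data.frame(
      trait = tr, df = a$df[ri], statistic = a$statistic[ri],
      p_raw = a$p_value[ri], stringsAsFactors = FALSE
    )
  }
  inter <- do.call(rbind, inter)
  inter$p_adjusted <- pmin(1, family_size * inter$p_raw)
  rownames(inter) <- NULL
  structure(
    list(models = models, data = datas,
         anova = do.call(rbind, tabs), interaction = inter,
         family_size = family_size),
    class = "trait_models"
  )
}

#' Infection contrasts of the marginal means, per species and trait
#'
#' For every trait model, estimates the uninfected-minus-infected difference
#' of the fitted cell means within each species (via estimated marginal
#' means), with its standard error, t statistic on the residual df, raw
#' p-value, and Bonferroni-adjusted p-value
#' (`p_adjusted = min(1, family_size * p_raw)`).
#'
#' On the standardized scale these estimates are directly comparable across
#' traits and species; positive values mean uninfected specimens are larger.
#'
#' @param fits A `trait_models` object from [fit_trait_models()].
#' @param family_size Bonferroni family size per species; defaults to the
#'   number of traits.
#' @return Data frame: species, trait, estimate, se, df, statistic, p_raw,
#'   p_adjusted.
#' @export
estimate_contrasts <- function(fits, family_size = NULL) {
  if (!inherits(fits, "trait_models")) {
    abort("`fits` must come from fit_trait_models()",
          "antmorph_validation_error")
  }
  if (is.null(family_size)) family_size <- length(fits$models)
  rows <- list()
  for (tr in names(fits$models)) {
    em <- emmeans::emmeans(fits$models[[tr]], ~ status | species,
                           data = fits$data[[tr]])
    ct <- summary(emmeans::contrast(em, method = "pairwise"), adjust = "none")
    rows[[tr]] <- data.frame(
      species = as.character(ct$species),
      trait = tr,
      estimate = ct$estimate,      # uninfected - infected
      se = ct$SE,
      df = ct$df,
      statistic = ct$t.ratio,
      p_raw = ct$p.value,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, family_size * out$p_raw)
  rownames(out) <- NULL
  out[order(out$species, match(out$trait, trait_codes())), ]
}

#' Residual diagnostic plots
#'
#' Writes the residual-vs-fitted and normal quantile plots for a fitted
#' model. Provided for visual checking only; no automated gate is applied.
#'
#' @param fit An `lm` object (or a `morph_anova`, whose model is used).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the two file paths.
#' @export
residual_diagnostics <- function(fit, dir, prefix = "model") {
  if (inherits(fit, "morph_anova")) fit <- fit$model
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_residuals_vs_fitted.png",
                                           "_qq.png")))
  grDevices::png(paths[1], width = 600, height = 500)
  suppressWarnings(plot(fit, which = 1))   # leverage-one notes are benign here
  grDevices::dev.off()
  grDevices::png(paths[2], width = 600, height = 500)
  suppressWarnings(plot(fit, which = 2))
  grDevices::dev.off()
  invisible(paths)
}
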