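# Per-species standardization: subtract the arithmetic mean, divide by the
# sample SD, separately for each species, to remove species-specific body
# size before the per-trait models. Metadata is retained so the scaling can
# be inverted exactly.

#' Standardize trait values within species
#'
#' For every species x trait cell, subtracts the species mean and divides by
#' the species sample SD (n-1 divisor). The scaling parameters are stored in
#' the `"scaling"` attribute so [invert_scaling()] reproduces the input
#' exactly.
#'
#' @param table A [specimen_table()]; every species needs >= 2 specimens and
#'   no trait may be constant within a species.
#' @return A data frame of class `scaled_table` (same shape as the input;
#'   trait columns now unitless, mean 0 / SD 1 within species), with
#'   attribute `scaling`: a data frame (species, trait, center, scale).
#' @export
scale_by_species <- function(table) {
  table <- specimen_table(table)
  traits <- trait_codes()
  out <- as.data.frame(table)
  meta <- list()
  for (s in levels(table$species)) {
    rows <- which(as.character(table$species) == s)
    if (length(rows) < 2) {
      abort(sprintf("species %s has fewer than 2 specimens", s),
            "antmorph_validation_error")
    }
    for (tr in traits) {
      v <- table[[tr]][rows]
      ctr <- mean(v)
      scl <- sd(v)
      if (!is.finite(scl) || scl == 0) {
        abort(sprintf("trait %s is constant within species %s", tr, s),
              "antmorph_degenerate_scale_error")
      }
      out[[tr]][rows] <- (v - ctr) / scl
      meta[[length(meta) + 1L]] <- data.frame(
        species = s, trait = tr, center = ctr, scale = scl,
        stringsAsFactors = FALSE
      )
    }
  }
  attr(out, "scaling") <- do.call(rbind, meta)
  class(out) <- c("scaled_table", "data.frame")
  out
}

#' Invert a per-species scaling
#'
#' @param scaled A `scaled_table` from [scale_by_species()].
#' @return The original [specimen_table()], recovered to full precision.
#' @export
invert_scaling <- function(scaled) {
  if (!inherits(scaled, "scaled_table")) {
    abort("`scaled` must come from scale_by_species()",
          "antmorph_validation_error")
  }
  meta <- attr(scaled, "scaling")
  out <- as.data.frame(scaled)
  for (i in seq_len(nrow(meta))) {
    rows <- which(as.character(out$species) == meta$species[i])
    tr <- meta$trait[i]
    out[[tr]][rows] <- out[[tr]][rows] * meta$scale[i] + meta$center[i]
  }
  attr(out, "scaling") <- NULL
  specimen_table(out)
}
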