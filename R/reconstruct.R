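# Distribution-mapping reconstruction of wild-type trait values.
#
# Within a species, each trait is modelled as Gaussian separately for
# infected and uninfected specimens. An infected specimen's observed value y
# is expressed as its standardized position within the infected distribution,
#   d = (y - mu_inf) / sigma_inf,
# and carried onto the uninfected distribution at the same standardized
# position:
#   p = d * sigma_un + mu_inf + s,    s = mu_un - mu_inf,
# i.e. p = d * sigma_un + mu_un. The map is affine and strictly increasing,
# so it transfers the infected sample's moments exactly onto
# (mu_un, sigma_un) and preserves specimen order within a trait.

#' Estimate per-group Gaussian moments
#'
#' Maximum-likelihood mean and SD per species x infection status x trait.
#' The ML variance uses divisor n; set `divisor = "unbiased"` for n-1. The
#' convention used is recorded in the result so outputs are self-describing.
#'
#' @param table A [specimen_table()]; every species x status cell needs
#'   >= 2 specimens.
#' @param divisor `"ml"` (divide by n, the default) or `"unbiased"` (n-1).
#' @return An object of class `group_moments`: data frame with one row per
#'   species x trait (mu_inf, sigma_inf, mu_un, sigma_un, s = mu_un -
#'   mu_inf, n_inf, n_un) and attribute `divisor`.
#' @export
#' @examples
#' tab <- simulate_specimens(study_scenario(), seed = 1)
#' head(estimate_moments(tab))
estimate_moments <- function(table, divisor = c("ml", "unbiased")) {
  divisor <- match.arg(divisor)
  table <- specimen_table(table)
  sdev <- function(v) {
    if (divisor == "ml") sqrt(mean((v - mean(v))^2)) else sd(v)
  }
  rows <- list()
  for (s in levels(table$species)) {
    for (st in c(FALSE, TRUE)) {
      n <- sum(table$species == s & table$infected == st)
      if (n < 2) {
        abort(sprintf("cell %s:%s has %d specimen(s); need >= 2",
                      s, if (st) "infected" else "uninfected", n),
              "antmorph_insufficient_data_error")
      }
    }
    inf_rows <- table$species == s & table$infected
    un_rows <- table$species == s & !table$infected
    for (tr in trait_codes()) {
      vi <- table[[tr]][inf_rows]
      vu <- table[[tr]][un_rows]
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, trait = tr,
        mu_inf = mean(vi), sigma_inf = sdev(vi),
        mu_un = mean(vu), sigma_un = sdev(vu),
        s = mean(vu) - mean(vi),
        n_inf = length(vi), n_un = length(vu),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$sigma_inf <= 0 | out$sigma_un <= 0)) {
    bad <- out[out$sigma_inf <= 0 | out$sigma_un <= 0, c("species", "trait")]
    abort(sprintf("degenerate (zero-SD) group(s): %s",
                  paste(paste(bad$species, bad$trait, sep = ":"),
                        collapse = ", ")),
          "antmorph_degenerate_moments_error")
  }
  structure(out, divisor = divisor,
            class = c("group_moments", "data.frame"))
}

#' Standardized distance within the infected distribution
#'
#' @param y Observed infected trait value(s).
#' @param mu_inf,sigma_inf Infected group mean and SD; `sigma_inf > 0`.
#' @return `d = (y - mu_inf) / sigma_inf`.
#' @export
standardized_distance <- function(y, mu_inf, sigma_inf) {
  if (any(sigma_inf <= 0)) {
    abort("sigma_inf must be > 0", "antmorph_degenerate_moments_error")
  }
  (y - mu_inf) / sigma_inf
}

#' Predicted wild-type trait value
#'
#' Maps an infected observation onto the uninfected distribution:
#' `p = d * sigma_un + mu_inf + s` with `s = mu_un - mu_inf` (equivalently
#' `p = d * sigma_un + mu_un`; both forms are computed and asserted equal).
#'
#' @param y Observed infected trait value(s).
#' @param mu_inf,sigma_inf Infected group moments; `sigma_inf > 0`.
#' @param mu_un,sigma_un Uninfected group moments; `sigma_un > 0`.
#' @return Predicted wild-type value(s) `p`.
#' @export
#' @examples
#' predict_wildtype(12, mu_inf = 10, sigma_inf = 2, mu_un = 14, sigma_un = 3)
predict_wildtype <- function(y, mu_inf, sigma_inf, mu_un, sigma_un) {
  if (any(sigma_un <= 0)) {
    abort("sigma_un must be > 0", "antmorph_degenerate_moments_error")
  }
  d <- standardized_distance(y, mu_inf, sigma_inf)
  s <- mu_un - mu_inf
  p <- d * sigma_un + mu_inf + s
  stopifnot(isTRUE(all.equal(p, d * sigma_un + mu_un, tolerance = 1e-12)))
  p
}

#' Reconstruct wild-type trait values for infected specimens
#'
#' Every infected specimen's every trait is mapped through
#' [predict_wildtype()] using its own species' group moments; uninfected
#' specimens pass through unchanged. The standardized distances are kept in
#' the `"d"` attribute (matrix: infected specimens x traits).
#'
#' @param table A [specimen_table()].
#' @param moments Optional precomputed [estimate_moments()] result; estimated
#'   from `table` when omitted.
#' @param min_cell Cells smaller than this trigger a warning (moment
#'   estimates from very few specimens are unstable) but reconstruction
#'   proceeds.
#' @return A data frame of class `reconstructed_table`: the input table with
#'   infected specimens' traits replaced by their predicted wild-type values
#'   and a logical `reconstructed` column.
#' @export
reconstruct_table <- function(table, moments = NULL, min_cell = 5) {
  table <- specimen_table(table)
  if (is.null(moments)) moments <- estimate_moments(table)
  small <- moments[moments$n_inf < min_cell | moments$n_un < min_cell,
                   c("species", "n_inf", "n_un")]
  small <- unique(small)
  if (nrow(small)) {
    warning(sprintf(
      "species with cell size below %d (moment estimates unstable): %s",
      min_cell,
      paste(sprintf("%s (inf %d, un %d)", small$species, small$n_inf,
                    small$n_un), collapse = "; ")))
  }
  out <- as.data.frame(table)
  inf_idx <- which(out$infected)
  d_mat <- matrix(NA_real_, length(inf_idx), length(trait_codes()),
                  dimnames = list(out$specimen_id[inf_idx], trait_codes()))
  for (s in unique(as.character(out$species[inf_idx]))) {
    rows <- inf_idx[as.character(out$species[inf_idx]) == s]
    ms <- moments[moments$species == s, ]
    if (!nrow(ms)) {
      abort(sprintf("no moments available for species %s", s),
            "antmorph_insufficient_data_error")
    }
    for (tr in trait_codes()) {
      mrow <- ms[ms$trait == tr, ]
      y <- out[[tr]][rows]
      d_mat[rownames(d_mat) %in% out$specimen_id[rows], tr] <-
        standardized_distance(y, mrow$mu_inf, mrow$sigma_inf)
      out[[tr]][rows] <- predict_wildtype(y, mrow$mu_inf, mrow$sigma_inf,
                                          mrow$mu_un, mrow$sigma_un)
    }
  }
  out$reconstructed <- out$infected
  attr(out, "d") <- d_mat
  attr(out, "moments") <- moments
  class(out) <- c("reconstructed_table", "data.frame")
  out
}
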