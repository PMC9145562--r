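#' Construct and validate a specimen table
#'
#' A specimen table holds one row per ant worker: a unique `specimen_id`, a
#' `species` label, a logical `infected` flag, and one strictly positive
#' numeric column per registered trait (micrometres). It is the exchange
#' object between every analysis stage.
#'
#' Validation is total: any malformed input raises a typed error
#' (`antmorph_schema_error` for missing columns, `antmorph_validation_error`
#' for bad values) rather than silently coercing.
#'
#' @param x A data frame with columns `specimen_id`, `species`, `infected`
#'   and all codes in [trait_codes()].
#' @return A validated data frame of class `specimen_table`; trait columns
#'   appear in canonical order after the three metadata columns.
#' @export
#' @examples
#' tab <- simulate_specimens(study_scenario(), seed = 1)
#' head(tab[, 1:6])
specimen_table <- function(x) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data.frame", "antmorph_validation_error")
  }
  traits <- trait_codes()
  need <- c("specimen_id", "species", "infected", traits)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(
      sprintf("missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "antmorph_schema_error"
    )
  }
  x <- as.data.frame(x)[, need, drop = FALSE]
  x$specimen_id <- as.character(x$specimen_id)
  if (anyDuplicated(x$specimen_id)) {
    dup <- unique(x$specimen_id[duplicated(x$specimen_id)])
    abort(sprintf("duplicated specimen_id: %s", paste(dup, collapse = ", ")),
          "antmorph_validation_error")
  }
  x$species <- as.factor(as.character(x$species))
  if (!is.logical(x$infected)) {
    abort("`infected` must be logical (see read_specimen_table for encodings)",
          "antmorph_validation_error")
  }
  if (anyNA(x$infected)) {
    abort("`infected` contains missing values", "antmorph_validation_error")
  }
  for (tr in traits) {
    v <- x[[tr]]
    if (!is.numeric(v)) {
      abort(sprintf("trait column %s is not numeric", tr),
            "antmorph_validation_error")
    }
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      abort(
        sprintf("trait %s has non-positive or non-finite value(s) in row(s): %s",
                tr, paste(x$specimen_id[bad], collapse = ", ")),
        "antmorph_validation_error"
      )
    }
  }
  class(x) <- c("specimen_table", "data.frame")
  x
}

#' @export
print.specimen_table <- function(x, ...) {
  cat(sprintf("<specimen_table> %d specimens, %d species, %d infected\n",
              nrow(x), nlevels(x$species), sum(x$infected)))
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Summarize specimen counts per species and infection status
#'
#' @param table A [specimen_table()].
#' @return A data frame with one row per species (`species`, `n_uninfected`,
#'   `n_infected`, `n`) plus a terminal `total` row.
#' @export
#' @examples
#' summarize_specimens(simulate_specimens(study_scenario(), seed = 1))
summarize_specimens <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) {
    out <- data.frame(species = "total", n_uninfected = 0L,
                      n_infected = 0L, n = 0L, stringsAsFactors = FALSE)
    return(out)
  }
  sp <- as.character(table$species)
  inf <- table$infected
  species <- sort(unique(sp))
  rows <- lapply(species, function(s) {
    data.frame(species = s,
               n_uninfected = sum(sp == s & !inf),
               n_infected = sum(sp == s & inf),
               n = sum(sp == s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(species = "total",
                        n_uninfected = sum(!inf),
                        n_infected = sum(inf),
                        n = nrow(table),
                        stringsAsFactors = FALSE))
}

# trait-value matrix (specimens x traits), canonical column order
trait_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, trait_codes(), drop = FALSE])
  rownames(m) <- table$specimen_id
  m
}
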