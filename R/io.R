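# Reading and writing specimen tables as delimited text.
#
# Column naming in deposited datasets varies, so the reader maps header
# synonyms onto the canonical schema before validation. The synonym map is
# user-extendable.

#' Default header synonym map
#'
#' Maps canonical column names to the header spellings accepted by
#' [read_specimen_table()]. Matching is case-insensitive. Extend by
#' concatenating your own entries onto an element.
#'
#' @return Named list: canonical name -> accepted header spellings.
#' @export
default_synonyms <- function() {
  list(
    specimen_id = c("specimen_id", "id", "specimen", "sample", "code"),
    species = c("species", "taxon", "species_name"),
    infected = c("infected", "infection", "infection_status", "status",
                 "parasitized")
  )
}

# accepted encodings of the infection indicator
.parse_infected <- function(v) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  yes <- c("1", "true", "t", "yes", "infected", "parasitized")
  no <- c("0", "false", "f", "no", "uninfected", "healthy", "wild-type",
          "wildtype")
  out <- rep(NA, length(s))
  out[s %in% yes] <- TRUE
  out[s %in% no] <- FALSE
  if (anyNA(out)) {
    bad <- unique(s[is.na(out)])
    abort(sprintf("unknown infection encoding: %s",
                  paste(bad, collapse = ", ")),
          "antmorph_parse_error")
  }
  out
}

#' Read a specimen table from delimited text
#'
#' Reads a CSV (or TSV) file with a header row naming the species and
#' infection columns plus all 21 trait columns, maps header synonyms onto
#' the canonical schema, parses the infection encoding (`0/1`, `TRUE/FALSE`,
#' `infected/uninfected`, ...), and validates the result. Trait values are
#' taken to be micrometres; `scale_factor` rescales deposits stored in other
#' units (e.g. `1000` for millimetres).
#'
#' @param path Path to the file.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @param synonyms Header synonym map, see [default_synonyms()].
#' @param scale_factor Multiplier applied to all trait values on read.
#' @return A validated [specimen_table()]; row order preserved.
#' @export
read_specimen_table <- function(path, sep = ",", synonyms = default_synonyms(),
                                scale_factor = 1) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "antmorph_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(raw)
  canon <- function(key) {
    hit <- which(tolower(nm) %in% tolower(synonyms[[key]]))
    if (length(hit) >= 1) nm[hit[1]] else NA_character_
  }
  sp_col <- canon("species")
  inf_col <- canon("infected")
  id_col <- canon("specimen_id")
  if (is.na(sp_col) || is.na(inf_col)) {
    miss <- c(if (is.na(sp_col)) "species", if (is.na(inf_col)) "infected")
    abort(sprintf("missing required column(s): %s",
                  paste(miss, collapse = ", ")),
          "antmorph_schema_error")
  }
  # trait headers matched case-sensitively first, then case-insensitively
  traits <- trait_codes()
  tr_cols <- vapply(traits, function(tr) {
    if (tr %in% nm) return(tr)
    hit <- which(tolower(nm) == tolower(tr))
    if (length(hit)) nm[hit[1]] else NA_character_
  }, character(1))
  if (anyNA(tr_cols)) {
    abort(sprintf("missing trait column(s): %s",
                  paste(traits[is.na(tr_cols)], collapse = ", ")),
          "antmorph_schema_error")
  }
  out <- data.frame(
    specimen_id = if (!is.na(id_col)) as.character(raw[[id_col]]) else
      sprintf("spec_%03d", seq_len(nrow(raw))),
    species = raw[[sp_col]],
    infected = .parse_infected(raw[[inf_col]]),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(traits)) {
    v <- raw[[tr_cols[i]]]
    if (!is.numeric(v)) {
      suppressWarnings(v2 <- as.numeric(v))
      if (anyNA(v2) & !anyNA(v)) {
        abort(sprintf("trait column %s contains non-numeric value(s)",
                      traits[i]),
              "antmorph_validation_error")
      }
      v <- v2
    }
    out[[traits[i]]] <- v * scale_factor
  }
  specimen_table(out)
}

#' Write a specimen table to delimited text
#'
#' Full numeric precision is preserved so that `read(write(t))` round-trips
#' exactly.
#'
#' @param table A [specimen_table()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_specimen_table <- function(table, path, sep = ",") {
  table <- specimen_table(table)
  df <- as.data.frame(table)
  # format doubles losslessly (17 significant digits survives the round trip)
  for (tr in trait_codes()) df[[tr]] <- sprintf("%.17g", df[[tr]])
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write to: %s", path), "antmorph_io_error")
  invisible(path)
}
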