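# Synthetic morphometric data with the statistical structure the analysis
# assumes: per-species baseline trait means, a shared multiplicative
# log-normal body-size factor inducing positive trait correlations, Gaussian
# per-trait measurement noise, and additive species-specific infection
# effects expressed in within-species SD units.

#' Specify one synthetic species
#'
#' The generative model for a specimen of this species is, per trait j,
#' \deqn{y_j = b_j e^{z} + \epsilon_j + I \cdot \delta_j \sigma_j,}
#' with \eqn{b_j} the baseline mean, \eqn{z \sim N(0, \code{size_sd}^2)} a
#' body-size factor shared by all traits of the specimen,
#' \eqn{\epsilon_j \sim N(0, \code{trait_noise_sd}_j^2)} independent noise,
#' \eqn{I} the infection indicator, \eqn{\delta_j} the infection shift in
#' within-species SD units, and \eqn{\sigma_j} the (analytic) within-group
#' SD of trait j implied by `size_sd` and `trait_noise_sd`.
#'
#' @param name Species label.
#' @param baseline_means Named numeric over [trait_codes()] (or a scalar,
#'   recycled): uninfected trait means in micrometres; strictly positive.
#' @param size_sd SD of the shared log-size factor (log scale); >= 0.
#' @param trait_noise_sd Per-trait noise SD in micrometres (scalar recycled);
#'   >= 0.
#' @param infection_shift Signed infection effect per trait, in within-species
#'   SD units (scalar recycled).
#' @param n_uninfected,n_infected Specimen counts per cell; each >= 2.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, baseline_means, size_sd, trait_noise_sd,
                         infection_shift, n_uninfected, n_infected) {
  traits <- trait_codes()
  expand <- function(v, what) {
    if (length(v) == 1) v <- setNames(rep(v, length(traits)), traits)
    if (is.null(names(v))) names(v) <- traits
    if (!all(traits %in% names(v))) {
      abort(sprintf("%s must cover all traits", what),
            "antmorph_validation_error")
    }
    v[traits]
  }
  baseline_means <- expand(baseline_means, "baseline_means")
  trait_noise_sd <- expand(trait_noise_sd, "trait_noise_sd")
  infection_shift <- expand(infection_shift, "infection_shift")
  if (any(baseline_means <= 0)) {
    abort("baseline_means must be strictly positive",
          "antmorph_validation_error")
  }
  if (size_sd < 0 || any(trait_noise_sd < 0)) {
    abort("size_sd and trait_noise_sd must be non-negative",
          "antmorph_validation_error")
  }
  if (n_uninfected < 2 || n_infected < 2) {
    abort("n_uninfected and n_infected must each be >= 2",
          "antmorph_validation_error")
  }
  structure(
    list(name = name, baseline_means = baseline_means, size_sd = size_sd,
         trait_noise_sd = trait_noise_sd, infection_shift = infection_shift,
         n_uninfected = as.integer(n_uninfected),
         n_infected = as.integer(n_infected)),
    class = "species_spec"
  )
}

#' Analytic within-group trait SD of a species spec
#'
#' The SD of \eqn{b e^{z} + \epsilon} for one trait:
#' \eqn{\sqrt{b^2 e^{s^2}(e^{s^2} - 1) + \tau^2}} with `s = size_sd` and
#' `tau` the trait noise SD. This is the unit in which `infection_shift`
#' is expressed.
#'
#' @param spec A [species_spec()].
#' @return Named numeric over traits.
#' @export
within_species_sd <- function(spec) {
  s2 <- spec$size_sd^2
  b <- spec$baseline_means
  sqrt(b^2 * exp(s2) * (exp(s2) - 1) + spec$trait_noise_sd^2)
}

#' Specify a simulation scenario
#'
#' @param species List of [species_spec()] objects (distinct names).
#' @param seed Integer RNG seed; fully determines the generated table.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(species, seed = 1L) {
  if (!length(species) || !all(vapply(species, inherits, TRUE, "species_spec"))) {
    abort("`species` must be a non-empty list of species_spec objects",
          "antmorph_validation_error")
  }
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    abort("species names must be distinct", "antmorph_validation_error")
  }
  structure(list(species = species, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Study-like default scenario
#'
#' Three ant species with the group sizes of the motivating field study
#' (uninfected/infected 20/19, 15/10 and 11/6), baseline trait means typical
#' of Temnothorax workers scaled per species so that species are well
#' separated, a 4% shared body-size factor, 1% measurement noise, and
#' infection shifts of -0.8, -0.5 and +0.6 within-species SDs: traits shrink
#' under infection in the first two species and enlarge in the third.
#'
#' @param n_per_cell Optional length-2 numeric (uninfected, infected) to
#'   override every species' cell counts, e.g. for large-sample simulations.
#' @param infection_shift Optional length-3 numeric overriding the per-species
#'   shifts (in within-species SD units).
#' @param seed Seed stored in the scenario.
#' @return A [scenario_spec()].
#' @export
#' @examples
#' summarize_specimens(simulate_specimens(study_scenario(), seed = 7))
study_scenario <- function(n_per_cell = NULL, infection_shift = c(-0.8, -0.5, 0.6),
                           seed = 1L) {
  base <- c(
    CL = 560, CWb = 500, EL = 140, FRS = 120, ML = 650, MW = 330,
    NOH = 150, NOL = 170, PEH = 230, PEW = 150, PoOC = 250, PPH = 180,
    PPL = 110, PPW = 200, SL = 430, SPL = 120, SPBA = 120, SPST = 160,
    SPTI = 120, SPWI = 160, PEL = 250
  )
  mult <- c(1.00, 1.35, 0.70)   # >= 6 within-species SDs apart (size_sd 4%)
  counts <- list(c(20, 19), c(15, 10), c(11, 6))
  if (!is.null(n_per_cell)) counts <- rep(list(n_per_cell), 3)
  nm <- c("T_nylanderi", "T_sordidulus", "T_unifasciatus")
  sp <- lapply(1:3, function(i) {
    species_spec(
      name = nm[i],
      baseline_means = base * mult[i],
      size_sd = 0.04,
      trait_noise_sd = 0.01 * base * mult[i],
      infection_shift = infection_shift[i],
      n_uninfected = counts[[i]][1],
      n_infected = counts[[i]][2]
    )
  })
  scenario_spec(sp, seed = seed)
}

#' Generate a synthetic specimen table
#'
#' Deterministic given the seed: the same seed yields byte-identical tables.
#' Group counts match the scenario exactly.
#'
#' @param scenario A [scenario_spec()].
#' @param seed Optional seed overriding `scenario$seed`.
#' @return A validated [specimen_table()].
#' @export
simulate_specimens <- function(scenario, seed = NULL) {
  if (!inherits(scenario, "scenario_spec")) {
    abort("`scenario` must be a scenario_spec", "antmorph_validation_error")
  }
  set.seed(if (is.null(seed)) scenario$seed else as.integer(seed))
  traits <- trait_codes()
  rows <- list()
  idx <- 0L
  for (sp in scenario$species) {
    n <- sp$n_uninfected + sp$n_infected
    infected <- rep(c(FALSE, TRUE), c(sp$n_uninfected, sp$n_infected))
    sigma_w <- within_species_sd(sp)
    z <- rnorm(n, 0, sp$size_sd)
    eps <- matrix(rnorm(n * length(traits), 0,
                        rep(sp$trait_noise_sd, each = n)),
                  nrow = n)
    vals <- outer(exp(z), sp$baseline_means) + eps +
      outer(infected, sp$infection_shift * sigma_w)
    colnames(vals) <- traits
    df <- data.frame(
      specimen_id = sprintf("%s_%03d", sp$name, seq_len(n) + idx),
      species = sp$name,
      infected = infected,
      stringsAsFactors = FALSE
    )
    idx <- idx + n
    rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(vals))
  }
  specimen_table(do.call(rbind, rows))
}

#' Read / write scenario specifications as YAML
#'
#' One document per scenario: a `seed` and a list of species blocks with the
#' [species_spec()] fields (vector fields may be scalars, recycled over the
#' trait registry).
#'
#' @param path File path.
#' @return `read_scenario()` returns a [scenario_spec()].
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  sp <- lapply(doc$species, function(s) {
    species_spec(
      name = s$name,
      baseline_means = unlist(s$baseline_means),
      size_sd = s$size_sd,
      trait_noise_sd = unlist(s$trait_noise_sd),
      infection_shift = unlist(s$infection_shift),
      n_uninfected = s$n_uninfected,
      n_infected = s$n_infected
    )
  })
  scenario_spec(sp, seed = if (is.null(doc$seed)) 1L else doc$seed)
}

#' @rdname read_scenario
#' @param scenario A [scenario_spec()] to serialize.
#' @export
write_scenario <- function(scenario, path) {
  doc <- list(
    seed = scenario$seed,
    species = lapply(scenario$species, function(s) {
      list(name = s$name,
           baseline_means = as.list(s$baseline_means),
           size_sd = s$size_sd,
           trait_noise_sd = as.list(s$trait_noise_sd),
           infection_shift = as.list(s$infection_shift),
           n_uninfected = s$n_uninfected,
           n_infected = s$n_infected)
    })
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}
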