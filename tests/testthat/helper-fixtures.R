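# Fixtures are built in code: small specimen tables and reduced scenarios.

# minimal hand-built table: n specimens per (species x status) cell,
# trait values drawn around per-species baselines
toy_table <- function(n_per_cell = 3, species = c("A", "B"), seed = 42,
                      noise_sd = 5) {
  set.seed(seed)
  traits <- trait_codes()
  base <- seq(100, 600, length.out = length(traits))
  rows <- list()
  id <- 0
  for (i in seq_along(species)) {
    for (inf in c(FALSE, TRUE)) {
      for (r in seq_len(n_per_cell)) {
        id <- id + 1
        vals <- base * (1 + 0.2 * (i - 1)) + rnorm(length(traits), 0, noise_sd)
        row <- data.frame(specimen_id = sprintf("t%03d", id),
                          species = species[i], infected = inf,
                          stringsAsFactors = FALSE)
        row[traits] <- as.list(abs(vals) + 1)
        rows[[id]] <- row
      }
    }
  }
  specimen_table(do.call(rbind, rows))
}

# scenario with tiny counts for fast simulation-based tests
small_scenario <- function(n_un = 10, n_inf = 10, shifts = c(-0.8, -0.5, 0.6),
                           size_sd = 0.04, noise_frac = 0.01, mult = c(1, 1.35, 0.7)) {
  base <- seq(100, 600, length.out = 21)
  names(base) <- trait_codes()
  sp <- lapply(seq_along(mult), function(i) {
    species_spec(paste0("sp", i), baseline_means = base * mult[i],
                 size_sd = size_sd, trait_noise_sd = noise_frac * base * mult[i],
                 infection_shift = shifts[i],
                 n_uninfected = n_un, n_infected = n_inf)
  })
  scenario_spec(sp)
}
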