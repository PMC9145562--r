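test_that("moment estimation matches hand arithmetic and records its divisor", {
  tab <- toy_table(n_per_cell = 2, species = "A")
  df <- as.data.frame(tab)
  df$CL <- c(10, 14, 10, 14)   # uninfected pair then infected pair
  mom <- estimate_moments(specimen_table(df))
  row <- mom[mom$trait == "CL", ]
  expect_equal(row$mu_inf, 12)
  expect_equal(row$sigma_inf, 2)   # ML divisor n
  expect_equal(row$mu_un, 12)
  expect_equal(row$s, 0)
  expect_equal(row$sigma_inf, row$sigma_un)
  expect_identical(attr(mom, "divisor"), "ml")

  mom2 <- estimate_moments(specimen_table(df), divisor = "unbiased")
  expect_equal(mom2[mom2$trait == "CL", "sigma_inf"], sd(c(10, 14)))

  # s is exactly mu_un - mu_inf everywhere
  big <- simulate_specimens(small_scenario(), seed = 2)
  m <- estimate_moments(big)
  expect_equal(m$s, m$mu_un - m$mu_inf, tolerance = 0)

  # undersized cell -> typed error naming it
  small <- as.data.frame(toy_table(n_per_cell = 3, species = "A"))
  small <- small[!(small$infected & duplicated(small$infected)), ]
  err <- tryCatch(estimate_moments(specimen_table(small)), error = identity)
  expect_s3_class(err, "antmorph_insufficient_data_error")
  expect_match(conditionMessage(err), "infected")
})

test_that("moment estimates are consistent at large n", {
  set.seed(77)
  base <- setNames(rep(100, 21), trait_codes())
  sp <- species_spec("a", baseline_means = base, size_sd = 0,
                     trait_noise_sd = 5, infection_shift = 0,
                     n_uninfected = 5000, n_infected = 5000)
  tab <- simulate_specimens(scenario_spec(list(sp)), seed = 77)
  m <- estimate_moments(tab)
  row <- m[m$trait == "CL", ]
  expect_lt(abs(row$mu_un - 100), 3 * 5 / sqrt(5000))
  expect_lt(abs(row$sigma_un - 5), 3 * 5 / sqrt(2 * 5000))
})

test_that("the distribution map evaluates the printed formulas", {
  expect_equal(standardized_distance(12, mu_inf = 10, sigma_inf = 2), 1)
  expect_equal(standardized_distance(10, 10, 2), 0)
  expect_equal(standardized_distance(12, 10, 2), 1)
  # worked example: d = 1, p = 1*3 + 10 + 4 = 17
  expect_equal(predict_wildtype(12, mu_inf = 10, sigma_inf = 2,
                                mu_un = 14, sigma_un = 3), 17)
  # y = mu_inf maps to mu_un
  expect_equal(predict_wildtype(10, 10, 2, 14, 3), 14)
  # identical distributions -> identity
  expect_equal(predict_wildtype(12.34, 10, 2, 10, 2), 12.34)
  expect_error(standardized_distance(1, 0, 0),
               class = "antmorph_degenerate_moments_error")
  expect_error(predict_wildtype(1, 0, 1, 0, 0),
               class = "antmorph_degenerate_moments_error")
})

test_that("reconstruction transfers moments exactly and preserves order", {
  tab <- simulate_specimens(small_scenario(n_un = 12, n_inf = 9), seed = 5)
  mom <- estimate_moments(tab)
  rec <- reconstruct_table(tab, moments = mom)
  expect_true(all(rec$reconstructed == rec$infected))
  # uninfected rows untouched
  for (tr in trait_codes()) {
    expect_identical(rec[[tr]][!rec$infected], tab[[tr]][!tab$infected])
  }
  for (s in unique(as.character(tab$species))) {
    inf <- tab$infected & as.character(tab$species) == s
    for (tr in trait_codes()) {
      v <- rec[[tr]][inf]
      row <- mom[mom$species == s & mom$trait == tr, ]
      # ML moments of the reconstructed sample equal the uninfected targets
      expect_equal(mean(v), row$mu_un, tolerance = 1e-9)
      expect_equal(sqrt(mean((v - mean(v))^2)), row$sigma_un,
                   tolerance = 1e-9)
      # affine and strictly increasing: specimen order preserved
      expect_identical(order(v), order(tab[[tr]][inf]))
      expect_true(all(is.finite(v)))
    }
  }
})

test_that("matched infected and uninfected moments give the identity map", {
  tab <- toy_table(n_per_cell = 4, species = "A", seed = 12)
  df <- as.data.frame(tab)
  # force infected cell to duplicate the uninfected cell's values
  for (tr in trait_codes()) df[[tr]][df$infected] <- df[[tr]][!df$infected]
  t2 <- specimen_table(df)
  rec <- suppressWarnings(reconstruct_table(t2))
  for (tr in trait_codes()) {
    expect_equal(rec[[tr]], t2[[tr]], tolerance = 1e-9)
  }
})

test_that("swapping the group roles inverts the reconstruction", {
  tab <- simulate_specimens(small_scenario(n_un = 10, n_inf = 8), seed = 8)
  mom <- estimate_moments(tab)
  rec <- reconstruct_table(tab, moments = mom)
  swapped <- mom
  swapped[, c("mu_inf", "sigma_inf", "mu_un", "sigma_un")] <-
    mom[, c("mu_un", "sigma_un", "mu_inf", "sigma_inf")]
  swapped$s <- -mom$s
  back <- reconstruct_table(specimen_table(
    as.data.frame(rec)[, c("specimen_id", "species", "infected",
                           trait_codes())]),
    moments = swapped)
  for (tr in trait_codes()) {
    expect_equal(back[[tr]], tab[[tr]], tolerance = 1e-9)
  }
})

test_that("reconstruction recovers the counterfactual healthy distribution", {
  # infected values are an affine transform of latent healthy draws; after
  # reconstruction they should be indistinguishable from healthy samples
  set.seed(123)
  reps <- 30
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 400
    healthy <- rnorm(n, 500, 20)
    latent <- rnorm(n, 500, 20)
    infected_obs <- 0.8 * latent - 60          # shrunk and shifted
    mu_inf <- mean(infected_obs)
    s_inf <- sqrt(mean((infected_obs - mu_inf)^2))
    mu_un <- mean(healthy)
    s_un <- sqrt(mean((healthy - mu_un)^2))
    p <- predict_wildtype(infected_obs, mu_inf, s_inf, mu_un, s_un)
    pvals[r] <- suppressWarnings(stats::ks.test(p, healthy)$p.value)
  }
  expect_gt(mean(pvals > 0.01), 0.9)
})

test_that("small cells warn but proceed", {
  tab <- simulate_specimens(small_scenario(n_un = 3, n_inf = 3), seed = 4)
  expect_warning(reconstruct_table(tab, min_cell = 5), "cell size")
})
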