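test_that("death phase respects its limiting probabilities", {
  lat <- uniform_lattice("NORMAL", 8, 8)
  set.seed(1)
  expect_identical(death_phase(lat, step_config(p_death = 0, immune_alpha = 0)), lat)
  gone <- death_phase(lat, step_config(p_death = 1))
  expect_true(all(is.na(gone)))
  # vacancies stay vacant
  lat[2, 2] <- NA_integer_
  kept <- death_phase(lat, step_config(p_death = 0, immune_alpha = 0))
  expect_true(is.na(kept[2, 2]))
})

test_that("wild-type cells die at the configured baseline rate", {
  # 1e5 Bernoulli trials via repeated death phases on a 100x100 normal field
  lat <- uniform_lattice("NORMAL", 100, 100)
  cfg <- step_config(p_death = 0.05, immune_alpha = 0)
  set.seed(7)
  deaths <- 0L
  for (i in 1:10) deaths <- deaths + sum(is.na(death_phase(lat, cfg)))
  n <- 10 * 10000
  sigma <- sqrt(n * 0.05 * 0.95)
  expect_lt(abs(deaths - n * 0.05), 4 * sigma)
})

test_that("immune elimination adds mutation-dependent mortality unless evaded", {
  # non-evading 8-locus mutants: p = 1 - (1-p_d)(1-alpha*8/9)
  lat <- acdsim:::as_lattice(matrix(255L, 50, 50))
  cfg <- step_config(p_death = 0.05, immune_alpha = 0.45)
  set.seed(8)
  deaths <- 0L
  for (i in 1:20) deaths <- deaths + sum(is.na(death_phase(lat, cfg)))
  n <- 20 * 2500
  p <- 1 - (1 - 0.05) * (1 - 0.45 * 8 / 9)
  expect_lt(abs(deaths - n * p), 4 * sqrt(n * p * (1 - p)))
  # full cancer evades: mortality back at baseline
  lat2 <- uniform_lattice("CANCER_FULL", 50, 50)
  deaths2 <- 0L
  for (i in 1:20) deaths2 <- deaths2 + sum(is.na(death_phase(lat2, cfg)))
  expect_lt(abs(deaths2 - n * 0.05), 4 * sqrt(n * 0.05 * 0.95))
})

test_that("birth copies the only live neighbour and leaves isolated vacancies", {
  lat <- make_lattice(3, 3, NA)
  lat[2, 1] <- acdsim:::genotype_to_code(make_archetype("CANCER_FULL"))
  fit <- matrix(NA_real_, 3, 3); fit[2, 1] <- 2
  set.seed(2)
  out <- birth_phase(lat, fit)
  expect_equal(out[2, 2], lat[2, 1])   # forced copy
  expect_true(is.na(out[2, 3]))        # synchronous: offspring cannot parent
  expect_true(is.na(out[1, 3]))        # no von Neumann neighbour
  # no vacancies: nothing changes
  full <- uniform_lattice("NORMAL", 4, 4)
  expect_identical(birth_phase(full, matrix(1, 4, 4)), full)
})

test_that("parents are chosen proportionally to fitness", {
  # vacancy flanked by fitness 3 (up) and 1 (down): up wins ~75%
  base <- make_lattice(1, 3, NA)
  base[1, 1] <- 100L; base[3, 1] <- 200L
  fit <- matrix(NA_real_, 3, 1); fit[1, 1] <- 3; fit[3, 1] <- 1
  set.seed(3)
  wins <- 0L
  for (i in 1:10000) {
    out <- birth_phase(base, fit)
    wins <- wins + (out[2, 1] == 100L)
  }
  expect_lt(abs(wins / 10000 - 0.75), 4 * sqrt(0.75 * 0.25 / 10000))
  # all-floor fitness: uniform choice
  fit0 <- matrix(NA_real_, 3, 1); fit0[1, 1] <- 1e-6; fit0[3, 1] <- 1e-6
  wins0 <- 0L
  for (i in 1:10000) wins0 <- wins0 + (birth_phase(base, fit0)[2, 1] == 100L)
  expect_lt(abs(wins0 / 10000 - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("one-way mutation never clears a locus and hits the expected rate", {
  lat <- acdsim:::as_lattice(matrix(7L, 40, 40))  # prod_gf1..3 on
  set.seed(4)
  out <- mutation_phase(lat, 0.2)
  expect_true(all(bitwAnd(out, 7L) == 7L))        # set bits persist
  new_bits <- sum(acdsim:::popcount9(out)) - sum(acdsim:::popcount9(lat))
  n_trials <- 1600 * 6                            # six unset loci per cell
  expect_lt(abs(new_bits - n_trials * 0.2), 4 * sqrt(n_trials * 0.2 * 0.8))
  expect_identical(mutation_phase(lat, 0), lat)
})

test_that("a full step conserves sites and normalised metrics", {
  lat <- tiny_lattice("HT_WARBURG")
  cfg <- step_config(mutation_rate = 0.005)
  set.seed(6)
  out <- sim_step(lat, cfg, step = 1L)
  expect_equal(dim(out$lattice), dim(lat))
  m <- out$metrics
  expect_equal(m$live_count + sum(is.na(out$lattice)), length(lat))
  expect_equal(m$prop_normal + m$prop_cancer + m$prop_hypertumour +
                 m$prop_partial_ht + m$prop_other, 1, tolerance = 1e-12)
})

test_that("monotype lattices are absorbing when mutation is off", {
  for (arch in c("NORMAL", "HT_WARBURG")) {
    lat <- uniform_lattice(arch, 12, 12)
    cfg <- step_config(mutation_rate = 0)
    sim <- run_simulation(lat, cfg, n_steps = 60, seed = 9)
    cls <- if (arch == "NORMAL") "prop_normal" else "prop_hypertumour"
    expect_true(all(sim$metrics[[cls]][sim$metrics$live_count > 0] == 1))
  }
})

test_that("normal cells never reappear after extinction", {
  # high mutation drives normals extinct; no reverse mutation can restore them
  lat <- uniform_lattice("NORMAL", 15, 15)
  cfg <- step_config(mutation_rate = 0.05)
  sim <- run_simulation(lat, cfg, n_steps = 400, seed = 10)
  n_norm <- sim$metrics$prop_normal * sim$metrics$live_count
  died_at <- which(n_norm == 0)[1]
  expect_false(is.na(died_at))
  expect_true(all(n_norm[died_at:length(n_norm)] == 0))
})

test_that("runs are reproducible and seeds matter", {
  lat <- tiny_lattice("HT_NO_WARBURG")
  cfg <- step_config(mutation_rate = 0.002)
  a <- run_simulation(lat, cfg, n_steps = 40, seed = 123)
  b <- run_simulation(lat, cfg, n_steps = 40, seed = 123)
  c <- run_simulation(lat, cfg, n_steps = 40, seed = 124)
  expect_identical(a$metrics, b$metrics)
  expect_identical(unclass(a$final_lattice), unclass(b$final_lattice))
  expect_false(identical(a$metrics, c$metrics))
})

test_that("the compiled core and the R reference loop agree bit for bit", {
  lat <- tiny_lattice("HT_WARBURG")
  cfg <- step_config(mutation_rate = 0.01)
  a <- run_simulation(lat, cfg, n_steps = 30, seed = 42, use_cpp = TRUE)
  b <- run_simulation(lat, cfg, n_steps = 30, seed = 42, use_cpp = FALSE)
  expect_identical(as.data.frame(a$metrics), as.data.frame(b$metrics))
  expect_identical(unclass(a$final_lattice), unclass(b$final_lattice))
})

test_that("births only copy genotypes present on the lattice (heredity)", {
  lat <- tiny_lattice("HT_NO_WARBURG")
  initial_codes <- unique(stats::na.omit(as.vector(unclass(lat))))
  cfg <- step_config(mutation_rate = 0)   # no mutation: codes can only copy
  sim <- run_simulation(lat, cfg, n_steps = 50, seed = 11)
  final_codes <- unique(stats::na.omit(as.vector(unclass(sim$final_lattice))))
  expect_true(all(final_codes %in% initial_codes))
})
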