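test_that("logistic boundary constants solve to the printed values", {
  k <- solve_logistic_constants(5)
  expect_equal(round(k[["k0"]], 4), 1.0067)
  expect_equal(round(k[["k2"]], 4), -0.0067)
  # the two boundary conditions: F(0) = 0 and k0 + k2 = 1 (the t -> Inf limit)
  f <- fitness_function("LOGISTIC", k1 = 5)
  expect_lt(abs(eval_F(f, 0)), 1e-12)
  expect_equal(k[["k0"]] + k[["k2"]], 1)
  for (k1 in c(0.5, 2, 5, 12)) {
    kk <- solve_logistic_constants(k1)
    ff <- fitness_function("LOGISTIC", k1 = k1)
    expect_lt(abs(eval_F(ff, 0)), 1e-12)
    expect_equal(kk[["k0"]] + kk[["k2"]], 1)
    expect_equal(kk[["k2"]], 1 - kk[["k0"]])
  }
})

test_that("transformation families evaluate correctly and stay monotone", {
  expect_equal(eval_F(fitness_function("LINEAR", A = 2, B = 1), 3), 7)
  # printed rounded constants give |F(0)| below 1e-4
  f_printed <- fitness_function("LOGISTIC", k0 = 1.0067, k1 = 5, k2 = -0.0067)
  expect_lt(abs(eval_F(f_printed, 0)), 1e-4)
  # large-t plateau of the solved logistic is 1
  f <- fitness_function("LOGISTIC", k1 = 5)
  expect_equal(eval_F(f, 50), 1, tolerance = 1e-12)
  fams <- list(fitness_function("LINEAR", A = 0.7, B = -0.2),
               f,
               fitness_function("CONVEX", p = 2),
               fitness_function("CONCAVE", p = 0.5),
               fitness_function("CUSTOM", fn = function(t) sqrt(t + 1)))
  t <- seq(0, 6, by = 0.1)
  for (ff in fams) expect_true(all(diff(eval_F(ff, t)) >= 0))
  expect_error(eval_F(f, -0.1), "non-negative")
  expect_error(fitness_function("CONCAVE", p = 1.2))
  expect_error(fitness_function("LINEAR", A = -1))
})

test_that("interface fitness charges the production cost to cancer cells only", {
  s <- interface_scenario(c(4, 3, 2, 1), c = 0.5, r = 0.5)
  w <- interface_fitness(s, fitness_function("LINEAR", A = 1, B = 0))
  expect_equal(unname(w), c(3.5, 2.5, 2, 1))
  expect_false(hypertumour_progresses(w))
  # higher cost flips the interface: omega = (1.5, 0.5, 2, 1)
  s2 <- interface_scenario(c(4, 3, 2, 1), c = 2.5, r = 0.5)
  w2 <- interface_fitness(s2, fitness_function("LINEAR", A = 1, B = 0))
  expect_equal(unname(w2), c(1.5, 0.5, 2, 1))
  expect_true(hypertumour_progresses(w2))
  expect_true(hypertumour_progresses(c(1, 1, 2, 2)))
  # logistic spot value: omega1 = F(3) - 0.1
  s3 <- interface_scenario(c(3, 2.4, 1.2, 0.96), c = 0.1, r = 0.5)
  w3 <- interface_fitness(s3, fitness_function("LOGISTIC", k1 = 5))
  expect_equal(w3[["omega1"]], 0.8999543, tolerance = 1e-6)
  # with zero cost, monotone F preserves the strict g ordering
  w4 <- interface_fitness(interface_scenario(c(4, 3, 2, 1)),
                          fitness_function("LOGISTIC", k1 = 5))
  expect_true(all(diff(unname(w4)) < 0))
  expect_error(interface_scenario(c(1, 2, 3, 4)))
})

test_that("drug deltas follow F(r g) - F(g) and are cost-free", {
  f_lin <- fitness_function("LINEAR", A = 2, B = 3)
  s <- interface_scenario(c(4, 3, 2, 1), c = 1.2, r = 0.25)
  d <- drug_deltas(s, f_lin)
  expect_equal(unname(d), (0.25 - 1) * 2 * c(4, 3, 2, 1))
  # independent of c
  s_free <- interface_scenario(c(4, 3, 2, 1), c = 0, r = 0.25)
  expect_equal(drug_deltas(s_free, f_lin), d)
  # r -> 1 limit: deltas vanish
  s_weak <- interface_scenario(c(4, 3, 2, 1), c = 0, r = 1 - 1e-9)
  expect_lt(max(abs(drug_deltas(s_weak, f_lin))), 1e-7)
  # logistic spot value: delta1 = F(1) - F(2)
  f_log <- fitness_function("LOGISTIC", k1 = 5)
  s_log <- interface_scenario(c(2, 1.5, 1, 0.5), r = 0.5)
  expect_equal(drug_deltas(s_log, f_log)[["domega1"]], -0.496631, tolerance = 1e-5)
})

test_that("phi reproduces the logistic sign structure at spot points", {
  f <- fitness_function("LOGISTIC", k1 = 5)
  # cancer near the inflection: the drug hurts it more -> phi < 0
  s_neg <- interface_scenario(c(2, 1.9, 1, 0.9), r = 0.5)
  expect_equal(phi(s_neg, f, "1-3"), -0.0696314, tolerance = 1e-5)
  # cancer on the plateau, hypertumour near the inflection -> phi > 0
  s_pos <- interface_scenario(c(3, 2.9, 1.2, 1.1), r = 0.8)
  expect_equal(phi(s_pos, f, "1-3"), 0.2819137, tolerance = 1e-5)
  # the 2-4 pair uses cells 2 and 4
  d <- drug_deltas(s_pos, f)
  expect_equal(phi(s_pos, f, "2-4"), d[["domega2"]] - d[["domega4"]])
  # phi never depends on the production cost
  s_cost <- interface_scenario(c(3, 2.9, 1.2, 1.1), c = 5, r = 0.8)
  expect_equal(phi(s_cost, f, "1-3"), phi(s_pos, f, "1-3"))
})

test_that("phi grids carry both signs for the logistic and only negative for linear", {
  f_log <- fitness_function("LOGISTIC", k1 = 5)
  grid8 <- phi_grid(f_log, r = 0.8)
  at <- function(gr, gv, rv) gr$phi[which.min((gr$g - gv)^2 + (gr$ratio - rv)^2)]
  expect_gt(at(grid8, 3, 0.4), 0)
  grid5 <- phi_grid(f_log, r = 0.5)
  expect_lt(at(grid5, 2, 0.5), 0)
  f_lin <- fitness_function("LINEAR", A = 1.3, B = 0.2)
  expect_true(all(phi_grid(f_lin, r = 0.5)$phi < 0))
  # smoothness: adjacent entries along the default grid differ only slightly
  one_row <- dplyr::filter(grid5, g == grid5$g[1])
  expect_lt(max(abs(diff(one_row$phi))), 0.05)
  expect_error(phi_grid(f_log, ratio_values = c(0.5, 1)), "strictly")
})

test_that("the linear theorem holds in 10000 random trials and concavity breaks it", {
  set.seed(99)
  res <- verify_linear_theorem(10000)
  expect_true(res$ok)
  expect_null(res$counterexample)
  # symbolic equivalence at the numeric level: (r-1) A g1 < (r-1) A g3 <=> g1 > g3
  A <- 2.7; r <- 0.4; g1 <- 3.2; g3 <- 1.1
  expect_true(((r - 1) * A * g1 < (r - 1) * A * g3) == (g1 > g3))
  # a concave family member admits phi > 0 (drug can impede progression)
  f_con <- fitness_function("CONCAVE", p = 0.25, scale = 2)
  grid <- phi_grid(f_con, r = 0.8)
  expect_gt(max(grid$phi), 0)
})

test_that("the strict concentration ordering forces omega3 > omega4 and omega1 > omega2", {
  set.seed(17)
  fams <- list(fitness_function("LINEAR", A = 1.5, B = 0),
               fitness_function("LOGISTIC", k1 = 3),
               fitness_function("CONVEX", p = 3),
               fitness_function("CONCAVE", p = 0.4))
  for (f in fams) {
    for (i in 1:25) {
      g <- sort(stats::runif(4, 0.05, 4), decreasing = TRUE)
      if (any(diff(g) == 0)) next
      w <- interface_fitness(interface_scenario(g, c = stats::runif(1, 0, 1)), f)
      expect_gte(w[["omega3"]], w[["omega4"]])
      expect_gte(w[["omega1"]], w[["omega2"]])
    }
  }
})
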