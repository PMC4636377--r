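test_that("endpoint formula and its symmetries", {
  rec <- list(U_i = 1e6, R_i = 1e6, U_f = 5e5, R_f = 5e5, T = 10)
  expect_equal(endpoint_selection(rec)$s, 0)

  rec2 <- list(U_i = 1e6, R_i = 1e6, U_f = exp(1) * 1e6, R_f = 1e6, T = 10)
  expect_equal(endpoint_selection(rec2)$s, 0.1)
  expect_equal(endpoint_selection(rec2)$fitness, 1.1)

  # swapping the roles of U and R negates s
  swapped <- list(U_i = rec2$R_i, R_i = rec2$U_i,
                  U_f = rec2$R_f, R_f = rec2$U_f, T = 10)
  expect_equal(endpoint_selection(swapped)$s, -0.1)

  expect_error(endpoint_selection(list(U_i = 0, R_i = 1, U_f = 1, R_f = 1,
                                       T = 10)), "pseudo-counts")
})

test_that("endpoint estimate is unbiased under counting noise", {
  s_true <- 0.05; n_cells <- 50000
  est <- vapply(1:100, function(sd) {
    rec <- simulate_competition(s_true, T = 10, noise_sd = 0, seed = sd)
    set.seed(sd)
    u <- stats::rbinom(1, n_cells, rec$U_f / (rec$U_f + rec$R_f))
    endpoint_selection(list(U_i = rec$U_i, R_i = rec$R_i,
                            U_f = u, R_f = n_cells - u, T = rec$T))$s
  }, 0)
  expect_lt(abs(mean(est) - s_true), 0.005)
})

test_that("count corrections follow the stated algebra", {
  rec <- list(U_i = 1100, R_i = 900, U_f = 1100, R_f = 900, T = 10)
  out <- correct_counts(rec, phi = 0.1)
  expect_equal(out$record$R_i, 1000)
  expect_equal(out$record$U_i, 1000)
  expect_equal(out$s_raw, 0)

  ident <- correct_counts(rec, phi = 0, s_m = 0)
  expect_equal(ident$record[c("U_i", "R_i", "U_f", "R_f")],
               rec[c("U_i", "R_i", "U_f", "R_f")])

  # marker cost is added to the raw coefficient
  withcost <- correct_counts(rec, phi = 0.1, s_m = 0.02)
  expect_equal(withcost$s, 0.02)

  expect_error(correct_counts(list(U_i = 50, R_i = 900, U_f = 50,
                                   R_f = 900, T = 10), phi = 0.1),
               "non-positive")
  expect_error(correct_counts(rec, phi = 1), "phi")
})

test_that("planted phi and marker cost are recovered", {
  s_true <- 0.06; phi <- 0.08; s_m <- 0.01
  est <- vapply(1:50, function(sd) {
    # reference proliferates with marker burden: observable advantage of
    # the mutant is s_true - s_m; scoring misassigns phi of the reference
    rec <- simulate_competition(s_true - s_m, T = 10, noise_sd = 0,
                                seed = sd)
    obs <- rec
    for (side in c("i", "f")) {
      R <- rec[[paste0("R_", side)]]; U <- rec[[paste0("U_", side)]]
      obs[[paste0("R_", side)]] <- R * (1 - phi)
      obs[[paste0("U_", side)]] <- U + R * phi
    }
    correct_counts(obs, phi = phi, s_m = s_m)$s
  }, 0)
  expect_lt(abs(mean(est) - s_true), 0.005)
})

test_that("slope fitness handles orientation, controls and scaling", {
  gens <- seq(0, 20, by = 4)
  mk <- function(slope, orient = "mutant-in-channel-1", scale = 1) {
    s <- data.frame(generation = gens,
                    ch1 = scale * exp(slope * gens) + 10,
                    ch2 = scale * 1 + 5, bg1 = 10, bg2 = 5)
    attr(s, "orientation") <- orient
    s
  }
  flat <- slope_fitness(list(mk(0)))
  expect_equal(flat$s, 0, tolerance = 1e-10)

  both <- slope_fitness(list(mk(0.08), mk(-0.08, "mutant-in-channel-2")))
  expect_equal(both$s, 0.08, tolerance = 1e-10)
  expect_true(both$dye_swap)

  # invariance to a common positive factor on both channels
  sc <- slope_fitness(list(mk(0.08, scale = 7)))
  expect_equal(sc$s, 0.08, tolerance = 1e-10)

  # parental-vs-parental control slope is subtracted
  ctl <- slope_fitness(list(mk(0.10)), control = mk(0.02))
  expect_equal(ctl$s, 0.08, tolerance = 1e-10)
  expect_equal(ctl$control_slope, 0.02, tolerance = 1e-10)

  # dye-swap symmetry on noiseless data
  a <- slope_fitness(list(mk(0.08)))
  b <- slope_fitness(list(mk(-0.08, "mutant-in-channel-2")))
  expect_equal(a$slopes[[1]], b$slopes[[1]], tolerance = 1e-10)
})

test_that("slope estimator recovers s under noise within +-0.01", {
  s_true <- 0.1
  est <- vapply(1:100, function(sd) {
    reps <- lapply(1:6, function(r) {
      rec <- simulate_competition(
        if (r <= 3) s_true else -s_true, T = 10, noise_sd = 0.02,
        seed = sd * 100 + r)
      s <- rec$series
      if (r > 3) attr(s, "orientation") <- "mutant-in-channel-2"
      s
    })
    slope_fitness(reps)$s
  }, 0)
  expect_lt(abs(mean(est) - s_true), 0.01)
})

test_that("concentration response ANOVA behaves at the extremes", {
  same <- data.frame(condition = rep(c("0", "4", "8"), each = 3),
                     s = 0.05)
  out <- concentration_response(same)
  expect_equal(out$anova$F, 0)
  expect_equal(out$anova$p, 1)

  set.seed(1)
  two <- data.frame(condition = rep(c("0", "8"), each = 3),
                    s = c(stats::rnorm(3, 0, 0.001),
                          stats::rnorm(3, 0.1, 0.001)))
  out2 <- concentration_response(two)
  expect_lt(out2$anova$p, 0.005)
  expect_lt(out2$contrasts$p[1], 0.005)
  expect_equal(out2$contrasts$condition, "8")

  expect_error(concentration_response(
    data.frame(condition = "0", s = c(1, 2))), "two conditions")
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(2024)
  rejections <- vapply(1:1000, function(i) {
    d <- data.frame(condition = rep(c("0", "4", "8"), each = 4),
                    s = stats::rnorm(12, 0.05, 0.01))
    concentration_response(d)$anova$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
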