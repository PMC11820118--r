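test_that("ansatz covariates follow their closed forms", {
  expect_equal(ansatz_x(4, 100, "count"), 4)
  expect_equal(ansatz_x(4, 100, "fraction"), 0.04)
  expect_equal(ansatz_x(4, 100, "sqrt"), 0.4)
  expect_equal(ansatz_x(0, 137, "count"), 0)
  expect_equal(ansatz_x(0, 137, "fraction"), 0)
  expect_equal(ansatz_x(0, 137, "sqrt"), 0)
  # fraction and sqrt coincide only at L = 1
  expect_equal(ansatz_x(3, 1, "fraction"), ansatz_x(3, 1, "sqrt"))
})

test_that("through-origin fit recovers exact lines and degenerate data", {
  obs <- variant_observations(paste0("v", 1:3), "Y->F", 1:3, 150,
                              c(-2, -4, -6))
  law <- fit_scaling_constant(obs, "count")
  expect_equal(law$S, -2)
  expect_equal(law$r_squared, 1)

  zero <- variant_observations(paste0("v", 1:3), "Y->F", 1:3, 150,
                               c(0, 0, 0))
  expect_equal(fit_scaling_constant(zero, "count")$S, 0)

  mixed <- obs
  mixed$pair[2] <- "R->K"
  expect_error(fit_scaling_constant(mixed, "count"), "mix")

  flagged <- obs
  flagged$multi_type <- TRUE
  expect_error(fit_scaling_constant(flagged, "count"), "multi-type")

  single <- obs[1, ]
  class(single) <- class(obs)
  one <- fit_scaling_constant(single, "count")
  expect_equal(one$S, -2)
  expect_true(is.na(one$S_err))
})

test_that("fits on noisy synthetic families recover the truth within 2 SE", {
  for (seed in c(1, 7, 13)) {
    fam <- synth_variant_family(pair = "R->K", ansatz = "fraction",
                                S_truth = -1300, n_obs = 20,
                                noise_sd = 2, seed = seed)
    law <- fit_scaling_constant(fam, "fraction")
    expect_lt(abs(law$S - (-1300)), 2 * law$S_err)
  }
})

test_that("slope estimates are unbiased with near-nominal CI coverage", {
  hits <- 0
  ests <- numeric(100)
  errs <- numeric(100)
  for (seed in 1:100) {
    fam <- synth_variant_family(pair = "Y->F", ansatz = "count",
                                S_truth = -0.4, n_obs = 20,
                                noise_sd = 2, seed = seed)
    law <- fit_scaling_constant(fam, "count")
    ests[seed] <- law$S
    errs[seed] <- law$S_err
    if (abs(law$S - (-0.4)) < 1.96 * law$S_err) hits <- hits + 1
  }
  expect_lt(abs(mean(ests) - (-0.4)), mean(errs))  # bias within one SE
  expect_gte(hits, 88)  # ~95% coverage within Monte-Carlo error
})

test_that("ansatz selection identifies the generating law and collinearity", {
  fam <- synth_variant_family(pair = "F/Y->X", ansatz = "sqrt",
                              S_truth = -56, n_obs = 24,
                              lengths = c(100L, 200L, 300L),
                              noise_sd = 1, seed = 5)
  sel <- select_ansatz(fam)
  expect_equal(sel$best, "sqrt")
  expect_false(sel$indistinguishable)
  expect_named(sel$laws, c("count", "fraction", "sqrt"))

  const_L <- synth_variant_family(pair = "R->K", ansatz = "fraction",
                                  S_truth = -1300, n_obs = 12,
                                  lengths = 137L, noise_sd = 1, seed = 2)
  selc <- select_ansatz(const_L)
  expect_true(selc$indistinguishable)
  expect_true(is.na(selc$best))
})

test_that("reversing the mutation direction flips S and preserves R^2", {
  fam <- synth_variant_family(pair = "R->K", ansatz = "fraction",
                              S_truth = -1300, n_obs = 20, noise_sd = 2,
                              seed = 3)
  law <- fit_scaling_constant(fam, "fraction")
  flipped <- fam
  flipped$pair <- "K->R"
  flipped$delta_tc <- -flipped$delta_tc
  law2 <- fit_scaling_constant(flipped, "fraction")
  expect_equal(law2$S, -law$S)
  expect_equal(law2$r_squared, law$r_squared)
  # and reverse_law implements the same antisymmetry
  rev <- reverse_law(law)
  expect_equal(rev$S, -law$S)
  expect_equal(rev$pair, "K->R")
})

test_that("predictions use S * x with |x| * S_err and respect pair matching", {
  laws <- published_laws()
  # one R->K substitution in a 200-residue PLD costs 6.5 K
  p <- predict_delta_tc(mutation_spec("R", "K", 1), 200, laws[["R->K"]])
  expect_equal(p$value, -6.5)
  expect_equal(p$error, 0.5)
  # one Arg deletion at L = 100 costs 6.4 K
  p2 <- predict_delta_tc(mutation_spec("R", "X", 1), 100, laws[["R->X"]])
  expect_equal(p2$value, -6.4)
  # zero mutations change nothing
  p0 <- predict_delta_tc(mutation_spec("R", "K", 0), 200, laws[["R->K"]])
  expect_equal(p0$value, 0)
  expect_equal(p0$error, 0)
  # reversed direction flips the sign via antisymmetry
  pr <- predict_delta_tc(mutation_spec("K", "R", 1), 200, laws[["R->K"]])
  expect_equal(pr$value, 6.5)
  expect_error(predict_delta_tc(mutation_spec("A", "S", 1), 200,
                                laws[["R->K"]]), "does not match")
  # G->S ships without a constant and refuses to predict
  expect_error(predict_delta_tc(mutation_spec("G", "S", 1), 200,
                                laws[["G->S"]]), "no published constant")
})

test_that("cumulative predictions add values and propagate errors", {
  laws <- published_laws()
  single <- cumulative_prediction(list(mutation_spec("R", "K", 1)), 200,
                                  laws)
  expect_equal(single$value, -6.5)
  both <- cumulative_prediction(list(mutation_spec("Y", "F", 2),
                                     mutation_spec("R", "K", 1)), 200,
                                laws)
  expect_equal(both$value, -0.8 + -6.5)
  expect_equal(both$error, sqrt((2 * 0.04)^2 + 0.5^2))
  empty <- cumulative_prediction(list(), 200, laws)
  expect_equal(empty$value, 0)
  expect_equal(empty$error, 0)
})

test_that("the prediction grid reproduces the published summary values", {
  grid <- build_table1()
  cell <- function(pair, L) grid[grid$pair == pair & grid$L == L, ]
  expect_equal(cell("R->K", 100)$value_rounded, -13)
  expect_equal(cell("R->K", 100)$error_rounded, 1)
  expect_equal(cell("N->Q", 300)$value_rounded, 0.17)
  expect_equal(cell("N->Q", 300)$error_rounded, 0.02)
  # count-ansatz rows are length-free
  expect_equal(unique(cell("Y->F", 100)$value_rounded,
                      cell("Y->F", 300)$value_rounded), -0.4)
  expect_equal(length(unique(grid$value[grid$pair == "A->S"])), 1)
})
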