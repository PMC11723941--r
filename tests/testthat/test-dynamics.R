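test_that("introduce perturbs the state proportionally", {
  expect_equal(as.numeric(introduce(pure_hermaphrodites(), "XYn", 1e-6)),
               c(1 - 1e-6, 1e-6, 0, 0))
  expect_equal(as.numeric(introduce(population_state(0.5, 0.5), "XXc", 1e-6)),
               c(0.4999995, 0.4999995, 1e-6, 0))
  st <- population_state(0.5, 0.5)
  expect_identical(introduce(st, "XXc", 0), st)
  expect_error(introduce(population_state(0, 1), "XYn", 1e-6), "all zero")
  expect_error(introduce(pure_hermaphrodites(), "XYn", 1), "freq")
})

test_that("a fixed point converges within the detection window", {
  res <- iterate_to_equilibrium(pure_hermaphrodites(), cms_params(), window = 20)
  expect_true(res$converged)
  expect_lte(res$generations, 20)
  expect_equal(res$classification, "hermaphroditism")
})

test_that("male invasion reaches the closed-form androdioecious equilibrium", {
  p <- cms_params(alpha = 4)
  res <- iterate_to_equilibrium(introduce(pure_hermaphrodites(), "XYn"), p)
  expect_true(res$converged)
  expect_equal(res$classification, "androdioecy")
  expect_equal(male_frequency(res$state), 1 / 3, tolerance = 1e-6)
})

test_that("without males, invading CMS fixes and the population dies out", {
  # g above 1 - s d and no pollen limitation: invasion = fixation = extinction
  p <- cms_params(g = 1.5, s = 0.4, d = 0.1, model = 1)
  res <- iterate_to_equilibrium(introduce(pure_hermaphrodites(), "XXc"), p)
  # the run either hits N_S = 0 outright or settles onto the moribund
  # all-female boundary; both are extinction
  expect_equal(res$classification, "extinction")
  expect_equal(cms_frequency(res$state), 1, tolerance = 1e-9)
  expect_lt(res$state[["XXn"]], 1e-10)
})

test_that("classification maps phenotype presence to the six labels", {
  p <- cms_params()
  expect_equal(classify(pure_hermaphrodites(), p), "hermaphroditism")
  expect_equal(classify(population_state(0.7, 0.3), p), "androdioecy")
  expect_equal(classify(population_state(0.7, 0, 0.3), p), "gynodioecy")
  expect_equal(classify(population_state(0.4, 0.2, 0.3, 0.1), p), "trioecy")
  expect_equal(classify(population_state(0, 0.2, 0.5, 0.3), p), "dioecy")
  expect_equal(classify(population_state(0, 0, 1, 0), p), "extinction")
  lab <- classify(population_state(0.5, 0.5), p, converged = FALSE)
  expect_true(attr(lab, "provisional"))
})

test_that("scenario outcomes line up with the closed-form thresholds", {
  # s=0.4, d=0.1, alpha=5: invasion at g > 1.0645..., fixation at g >= 1.32
  inside <- run_scenario(trioecy_params(g = 1.1), "males_first")
  expect_equal(inside$classification, "trioecy")
  above <- run_scenario(trioecy_params(g = 1.5), "males_first")
  expect_equal(above$classification, "dioecy")
  expect_equal(male_frequency(above$final$state), 0.5, tolerance = 1e-6)
  below <- run_scenario(trioecy_params(g = 1.0), "males_first")
  expect_equal(below$classification, "androdioecy")
})

test_that("females-first rescue introduces males at the CMS brink", {
  # alpha below the male-invasion threshold 3.2: males cannot pre-empt CMS,
  # which is destined to fix; males are injected when CMS reaches 0.99
  p <- cms_params(g = 1.5, alpha = 2, s = 0.4, d = 0.1, e_m = 0.8)
  sc <- run_scenario(p, "females_first")
  expect_true(sc$stages$cms_first$stopped_at_cms)
  expect_gte(cms_frequency(sc$stages$cms_first$state), 0.99)
  expect_named(sc$stages, c("cms_first", "male_invasion"))
  expect_true(sc$final$converged || sc$final$extinct)
})

test_that("invasion order does not change a polymorphic equilibrium", {
  p <- trioecy_params(g = 1.1)
  mf <- run_scenario(p, "males_first")
  ff <- run_scenario(p, "females_first")
  expect_equal(mf$classification, "trioecy")
  expect_equal(ff$classification, "trioecy")
  expect_lt(max(abs(as.numeric(mf$final$state) - as.numeric(ff$final$state))),
            1e-6)
})

test_that("trioecious classification is insensitive to the presence cutoff", {
  res <- run_scenario(trioecy_params(g = 1.1), "males_first")$final
  for (eps in c(1e-6, 1e-5, 1e-4, 1e-3))
    expect_equal(as.character(classify(res$state, trioecy_params(), eps = eps)),
                 "trioecy")
})

test_that("equilibrium CMS frequency rises with e_m inside the trioecy band", {
  freqs <- vapply(c(0.2, 0.5, 0.8), function(em) {
    p <- cms_params(g = 1.1, alpha = 5, s = 0.4, d = 0.1, e_m = em)
    cms_frequency(run_scenario(p, "males_first")$final$state)
  }, 0)
  expect_true(all(diff(freqs) > 0))
})

test_that("bisection recovers a known invasion boundary", {
  p <- cms_params(model = 1)
  cms_invades <- function(pp) {
    res <- iterate_to_equilibrium(introduce(pure_hermaphrodites(), "XXc", 1e-6),
                                  pp, max_gen = 5e4)
    res$extinct || cms_frequency(res$state) > 1e-5
  }
  thr <- bisect_threshold(p, "g", 0.8, 1.5, cms_invades, tol = 1e-4)
  expect_equal(thr, 1, tolerance = 1e-3)
  expect_error(bisect_threshold(p, "g", 1.2, 1.5, cms_invades, tol = 1e-4),
               "sign")
})

test_that("trajectories record every generation and aggregate frequencies", {
  p <- cms_params(alpha = 4)
  tr <- trajectory(introduce(pure_hermaphrodites(), "XYn", 0.01), p, 100)
  expect_equal(nrow(tr), 101)
  expect_equal(tr$generation[1], 0)
  expect_equal(tr$male_freq, tr$f_XYn + tr$f_XYc)
  expect_equal(tr$CMS_freq, tr$f_XXc + tr$f_XYc)
  expect_true(all(abs(rowSums(tr[, paste0("f_", c("XXn", "XYn", "XXc",
                                                  "XYc"))]) - 1) < 1e-12))
  # the recorded generations reproduce repeated application of the map
  st <- introduce(pure_hermaphrodites(), "XYn", 0.01)
  for (t in 1:5) st <- step_generation(st, p)
  expect_equal(as.numeric(st), as.numeric(tr[6, 2:5]), tolerance = 1e-14)
})
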