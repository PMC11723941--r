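test_that("gamete pools match hand-computed cases", {
  # pure hermaphrodites: no pollen limitation can bite, selfing splits ovules
  p <- cms_params(s = 0.3, d = 0.2)
  gp <- gamete_pools(pure_hermaphrodites(), p)
  expect_equal(gp$P_bar, 1)
  expect_equal(gp$P_X, 1)
  expect_equal(gp$P_Y, 0)
  expect_equal(gp$S1_XXn, 0.3)
  expect_equal(gp$O_XXn, 0.7)
  expect_equal(gp$N_S, 0.7 + 0.3 * 0.8)

  # half hermaphrodites, half males, alpha = 5: pollen-weighted X share
  gp2 <- gamete_pools(population_state(0.5, 0.5), cms_params(alpha = 5))
  expect_equal(gp2$P_bar, 3)
  expect_equal(gp2$P_X, (0.5 + 0.5 * 2.5) / 3)
  expect_equal(gp2$P_Y, 1 - (0.5 + 0.5 * 2.5) / 3)

  # all females: no pollen at all, the zero-pollen convention applies
  for (m in 1:3) {
    gp3 <- gamete_pools(population_state(0, 0, 1, 0),
                        cms_params(g = 1.5, model = m))
    expect_equal(gp3$P_X, 0)
    expect_equal(gp3$P_Y, 0)
    expect_equal(gp3$O_XXc, 0)
    expect_equal(gp3$N_S, 0)
  }
})

test_that("delayed selfing appears only in model 3", {
  st <- population_state(0.3, 0.1, 0.55, 0.05)  # pollen-poor population
  p2 <- cms_params(g = 1.3, alpha = 2, s = 0.2, e_m = 0.9, model = 2)
  p3 <- cms_params(g = 1.3, alpha = 2, s = 0.2, e_m = 0.9, model = 3)
  expect_equal(gamete_pools(st, p2)$S2_XXn, 0)
  gp3 <- gamete_pools(st, p3)
  outx <- min(1, gp3$P_bar)
  expect_gt(gp3$S2_XXn, 0)
  expect_equal(gp3$S2_XXn, (1 - outx) * (1 - 0.2) * 0.3)
  # female unfertilized ovules abort: no female term ever enters S2
  expect_equal(gp3$O_XXc, outx * 1.3 * 0.55)
})

test_that("one-generation step reproduces hand-computed oracle", {
  p <- cms_params(alpha = 5, model = 1)
  nxt <- step_generation(population_state(0.8, 0.2), p)
  P_Y <- 0.5 / 1.8
  expect_equal(as.numeric(nxt), c(1 - P_Y, P_Y, 0, 0), tolerance = 1e-12)
})

test_that("hermaphroditism is a fixed point and CMS cannot arise de novo", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_params(model = sample(1:3, 1))
    expect_equal(as.numeric(step_generation(pure_hermaphrodites(), p)),
                 c(1, 0, 0, 0))
    # states without CMS stay without CMS
    f <- runif(2)
    st <- population_state(f[1] / sum(f), f[2] / sum(f))
    nxt <- step_generation(st, p)
    expect_equal(unname(nxt[["XXc"]] + nxt[["XYc"]]), 0)
  }
})

test_that("step output is a valid frequency vector for random inputs", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_params(model = sample(1:3, 1))
    st <- random_state()
    nxt <- step_generation(st, p)
    expect_true(all(as.numeric(nxt) >= 0))
    expect_lt(abs(sum(nxt) - 1), 1e-12)
  }
})

test_that("the map is invariant under joint rescaling of G_h and P_h", {
  set.seed(7)
  for (i in 1:25) {
    base <- random_params(model = sample(1:3, 1))
    scaled <- do.call(cms_params, modifyList(unclass(base),
                                             list(G_h = 10, P_h = 10)))
    st <- random_state()
    expect_equal(as.numeric(step_generation(st, base)),
                 as.numeric(step_generation(st, scaled)), tolerance = 1e-12)
  }
})

test_that("models 2 and 3 coincide with model 1 when pollen is not limiting", {
  set.seed(13)
  for (i in 1:25) {
    # male + hermaphrodite states with alpha >= 1 always have P_bar >= P_h
    f <- runif(2)
    st <- population_state(f[1] / sum(f), f[2] / sum(f))
    base <- unclass(random_params(1))
    steps <- lapply(1:3, function(m) {
      p <- do.call(cms_params, modifyList(base, list(model = m)))
      expect_gte(gamete_pools(st, p)$P_bar, p$P_h)
      as.numeric(step_generation(st, p))
    })
    expect_equal(steps[[1]], steps[[2]], tolerance = 1e-14)
    expect_equal(steps[[1]], steps[[3]], tolerance = 1e-14)
  }
})

test_that("step agrees with an independent seed-by-seed enumeration oracle", {
  set.seed(99)
  for (i in 1:60) {
    p <- random_params(model = sample(1:3, 1))
    st <- random_state()
    expect_equal(as.numeric(step_generation(st, p)),
                 as.numeric(enumeration_step(st, p)), tolerance = 1e-12)
  }
})

test_that("R and compiled implementations of the step are identical", {
  set.seed(5)
  for (i in 1:50) {
    p <- random_params(model = sample(1:3, 1))
    st <- random_state()
    expect_equal(as.numeric(step_generation(st, p)),
                 as.numeric(triocms:::cpp_step(as.numeric(st),
                                               triocms:::params_vector(p))),
                 tolerance = 1e-15)
  }
})

test_that("an all-female population signals extinction with its state", {
  st <- population_state(0, 0, 1, 0)
  p <- cms_params(g = 2, model = 2)
  cond <- tryCatch(step_generation(st, p), population_extinct = identity)
  expect_s3_class(cond, "population_extinct")
  expect_equal(as.numeric(cond$state), c(0, 0, 1, 0))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(cms_params(g = -0.1), "g")
  expect_error(cms_params(s = 1.2), "s")
  expect_error(cms_params(model = 4), "model")
  expect_error(cms_params(P_h = 0), "positive")
  expect_warning(cms_params(alpha = 0.5), "trade-off")
  expect_error(population_state(0.5, 0.4), "sum to 1")
  expect_error(population_state(1.2, -0.2), "non-negative")
})
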