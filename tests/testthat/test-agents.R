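test_that("items age, die at max_age, and never exceed carrying capacity", {
  it <- data.frame(x = rep(1, 5), y = rep(1, 5), age = 99L)
  expect_equal(nrow(item_population_step(it, capacity = 100, max_age = 100)), 0)
  # at capacity: zero births
  set.seed(1)
  it <- data.frame(x = runif(50), y = runif(50), age = 10L)
  out <- item_population_step(it, capacity = 50, reproduce_prob = 1)
  expect_equal(nrow(out), 50)
  expect_equal(out$age, rep(11L, 50))
  # capacity is a hard ceiling even with certain reproduction
  out <- item_population_step(it, capacity = 55, reproduce_prob = 1)
  expect_equal(nrow(out), 55)
})

test_that("item births match the binomial expectation", {
  set.seed(2)
  n <- 1000
  births <- replicate(200, {
    it <- data.frame(x = runif(n, 0, 500), y = runif(n, 0, 500),
                     age = sample(0:50, n, replace = TRUE))
    nrow(item_population_step(it, capacity = 10000)) - n
  })
  se <- sd(births) / sqrt(length(births))
  expect_lt(abs(mean(births) - 0.1 * n), 3 * se)
})

test_that("signalers with ample energy travel home and display every step there", {
  cfg <- small_cfg(init_energy_min = 600, init_energy_max = 600,
                   n_food_init = 0)
  res <- run_sim(cfg, seed = 1, n_steps = 20, record = TRUE)
  # the walk home on a 100-unit torus takes at most 8 steps at speed 10
  expect_true(all(res$true_efforts >= 12 & res$true_efforts <= 20))
  expect_true(all(res$state$signalers$displaying))
  expect_equal(res$state$signalers$energy, rep(580, 20))
  # displaying happens at the home territory
  expect_equal(res$state$signalers$x, res$state$signalers$home_x)
  expect_equal(res$state$signalers$y, res$state$signalers$home_y)
  # once home, the signaler displays in every remaining step
  D <- res$history$displaying
  first <- apply(D, 2, function(z) which(z)[1])
  expect_equal(unname(res$true_efforts), unname(21 - first))
})

test_that("agents below threshold forage instead of displaying", {
  cfg <- small_cfg(init_energy_min = 100, init_energy_max = 100)
  res <- run_sim(cfg, seed = 2, n_steps = 1)
  expect_equal(unname(res$true_efforts), rep(0L, 20))
  expect_false(any(res$state$signalers$displaying))
  # energy change is bounded below by the step cost (dense food: most gain)
  expect_true(all(res$state$signalers$energy >= 100 - cfg$step_cost))
})

test_that("without food the energy ledger is exactly the step cost, floored at zero", {
  cfg <- small_cfg(init_energy_min = 5, init_energy_max = 5, n_food_init = 0)
  res <- run_sim(cfg, seed = 3, n_steps = 10, record = TRUE)
  e <- res$history$signaler_energy
  for (t in 1:10)
    expect_equal(e[t, ], rep(max(5 - t, 0), 20))
  expect_equal(res$history$receiver_energy[10, ], rep(0, 20))
})

test_that("rich signalers without display items log lost opportunities and do not display", {
  cfg <- small_cfg(init_energy_min = 900, init_energy_max = 900,
                   n_display_init = 0, n_food_init = 0,
                   flags = build_flags(items_needed = TRUE))
  res <- run_sim(cfg, seed = 4, n_steps = 5)
  expect_equal(unname(res$true_efforts), rep(0L, 20))
  expect_gt(res$lost_opportunities, 0)
  expect_false(any(res$state$signalers$displaying))
})

test_that("lost opportunities occur only in item-needing builds", {
  for (seq_ in c(FALSE, TRUE)) {
    cfg <- small_cfg(flags = build_flags(items_needed = FALSE,
                                         sequential = seq_))
    expect_equal(run_sim(cfg, seed = 5)$lost_opportunities, 0)
  }
})

test_that("display effort equals the count of displaying steps", {
  for (items in c(FALSE, TRUE)) {
    cfg <- small_cfg(flags = build_flags(items_needed = items))
    res <- run_sim(cfg, seed = 6, record = TRUE)
    expect_equal(unname(res$true_efforts),
                 unname(colSums(res$history$displaying)))
  }
})

test_that("receiver estimates are bounded by true display effort", {
  set.seed(10)
  for (b in all_builds()) {
    cfg <- small_cfg(flags = b, init_energy_max = 1000)
    res <- run_sim(cfg, seed = 7)
    expect_true(all(res$estimates >= 0))
    # both observation schemes can never credit more than the true total
    expect_true(all(t(res$estimates) <= res$true_efforts + 1e-12))
  }
})

test_that("sequential receivers hold estimates only for visited, displaying signalers", {
  # no receiver energy: no observation at all
  cfg <- small_cfg(init_energy_min = 0, init_energy_max = 0, n_food_init = 0,
                   flags = build_flags(sequential = TRUE))
  res <- run_sim(cfg, seed = 8)
  expect_true(all(res$estimates == 0))
})
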