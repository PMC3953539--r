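test_that("initialization draws the documented distributions", {
  cfg <- sim_config(n_food_init = 250)
  w <- init_world(cfg, seed = 1)$state
  expect_length(w$signalers$energy, 20)
  expect_length(w$receivers$energy, 20)
  e <- c(w$signalers$energy, w$receivers$energy)
  expect_true(all(e == floor(e) & e >= 0 & e <= 1000))
  expect_length(w$food$x, 250)
  expect_true(all(w$food$age >= 0 & w$food$age <= 100))
  expect_true(all(w$food$x >= 0 & w$food$x < 500))
  # no display items outside item-needing builds
  expect_length(w$display_items$x, 0)
  w2 <- init_world(sim_config(flags = build_flags(items_needed = TRUE),
                              n_display_init = 300), seed = 1)$state
  expect_length(w2$display_items$x, 300)
  # homes form the even 5 x 4 grid, unique per signaler
  expect_equal(sort(unique(w$signalers$home_x)), c(50, 150, 250, 350, 450))
  expect_equal(sort(unique(w$signalers$home_y)), c(62.5, 187.5, 312.5, 437.5))
  expect_equal(anyDuplicated(cbind(w$signalers$home_x, w$signalers$home_y)), 0)
  # every receiver tour is a permutation of all territories
  expect_true(all(apply(w$receivers$tour, 1,
                        function(t) identical(sort(t), 0:19))))
})

test_that("identical config and seed give bit-identical results", {
  cfg <- small_cfg(flags = build_flags(items_needed = TRUE, sequential = TRUE))
  a <- run_sim(cfg, seed = 42)
  b <- run_sim(cfg, seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(run_sim(cfg, seed = 43)$state, a$state))
})

test_that("a zero-step run leaves efforts and estimates at zero", {
  res <- run_sim(small_cfg(), seed = 1, n_steps = 0)
  expect_true(all(res$true_efforts == 0))
  expect_true(all(res$estimates == 0))
  expect_equal(res$lost_opportunities, 0)
})

test_that("every agent acts exactly once per step", {
  # no items: the schedule is exactly the 40 mobile agents
  cfg <- small_cfg(n_food_init = 0)
  res <- run_sim(cfg, seed = 2, n_steps = 50, record = TRUE)
  expect_equal(res$history$n_scheduled, rep(40L, 50))
  expect_equal(res$history$n_acted, rep(40L, 50))
  # with items, only agents removed mid-step (consumed items) skip their turn
  cfg <- small_cfg(flags = build_flags(items_needed = TRUE))
  res <- run_sim(cfg, seed = 3, n_steps = 50, record = TRUE)
  expect_true(all(res$history$n_acted <= res$history$n_scheduled))
  expect_true(all(res$history$n_scheduled >= 40))
})

test_that("scheduler permutations are uniform over positions", {
  set.seed(9)
  n <- 8
  pos <- replicate(4000, which(signalsim:::cpp_shuffle(n) == 1L))
  p <- chisq.test(tabulate(pos, n))$p.value
  expect_gt(p, 0.001)
})

test_that("item populations never exceed carrying capacity", {
  cfg <- small_cfg(n_food_init = 100, food_capacity = 120,
                   n_display_init = 50, display_capacity = 60,
                   flags = build_flags(items_needed = TRUE))
  res <- run_sim(cfg, seed = 4, n_steps = 200, record = TRUE)
  expect_true(all(res$history$pop_food <= 120))
  expect_true(all(res$history$pop_display <= 60))
  expect_lte(res$state$pop_max[["food"]], 120)
  expect_lte(res$state$pop_max[["display"]], 60)
})

test_that("perfect information yields exact concordance", {
  # lek observation of cumulative effort with free movement (step_cost 0)
  # and abundant food: every receiver reads every signaler's final effort
  cfg <- sim_config(step_cost = 0, n_food_init = 25000)
  res <- run_sim(cfg, seed = 11)
  expect_true(all(t(res$estimates) == res$true_efforts))
  expect_identical(run_concordance(res), 1)
})

test_that("run results serialize to the documented 20 x 21 layout", {
  res <- run_sim(small_cfg(), seed = 5)
  tab <- rating_table(res)
  expect_equal(dim(tab), c(21, 20))
  expect_equal(tab[1, ], res$true_efforts)
  dir <- tempfile()
  paths <- write_run_result(res, dir)
  csv <- read.csv(paths[1], check.names = FALSE)
  expect_equal(dim(csv), c(20, 22)) # signaler id + true + 20 receivers
  expect_equal(csv$true_effort, unname(res$true_efforts))
  meta <- jsonlite::read_json(paths[2])
  expect_equal(meta$seed, 5)
  expect_equal(meta$lost_opportunities, res$lost_opportunities)
})
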