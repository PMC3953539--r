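# balanced synthetic sweep table with a known generating model
make_table <- function(b_items = -0.2, b_seq = 0, b_rt = 0, b_food = 0,
                       sigma = 0, reps = 2, seed = 1) {
  set.seed(seed)
  g <- expand.grid(items_needed = 0:1, sequential = 0:1, realtime = 0:1,
                   food_level = c(250, 1000, 5000, 25000),
                   replicate = seq_len(reps))
  g$display_level <- ifelse(g$items_needed == 1, 2500, NA)
  g$W <- 0.7 + b_food * g$food_level / 25000 + b_items * g$items_needed +
    b_seq * g$sequential + b_rt * g$realtime + rnorm(nrow(g), 0, sigma)
  g
}

test_that("partial eta-squared is the documented ratio", {
  expect_equal(partial_eta_squared(1, 3), 0.25)
  expect_equal(partial_eta_squared(0, 3), 0)
  expect_true(is.nan(partial_eta_squared(0, 0)))
})

test_that("a noiseless generating model is recovered exactly", {
  fit <- suppressWarnings(fit_glm(make_table(b_items = -0.2, b_food = 0.1)))
  co <- fit$table
  expect_equal(co$estimate[co$term == "items_needed"], -0.2,
               tolerance = 1e-12)
  expect_equal(co$estimate[co$term == "food"], 0.1, tolerance = 1e-12)
  expect_equal(co$estimate[co$term == "(Intercept)"], 0.7,
               tolerance = 1e-12)
  # all variation not taken by food is explained by the items factor
  expect_equal(co$eta_sq_partial[co$term == "items_needed"], 1)
})

test_that("binary-factor coefficients equal adjusted condition-mean differences", {
  tab <- make_table(b_items = -0.15, b_seq = -0.1, b_rt = -0.02,
                    b_food = 0.2, sigma = 0.05, reps = 4, seed = 9)
  fit <- fit_glm(tab)
  co <- fit$table
  # the design is balanced and binary factors are mutually orthogonal, so
  # each coefficient is the raw difference of condition means
  for (f in c("items_needed", "sequential", "realtime")) {
    d <- mean(tab$W[tab[[f]] == 1]) - mean(tab$W[tab[[f]] == 0])
    expect_equal(co$estimate[co$term == f], d, tolerance = 1e-10)
  }
})

test_that("the OLS fit satisfies the normal equations", {
  tab <- make_table(sigma = 0.08, reps = 3, seed = 4)
  fit <- fit_glm(tab)
  X <- model.matrix(fit$model)
  expect_lt(max(abs(crossprod(X, residuals(fit$model)))), 1e-10)
})

test_that("eta-squared is invariant to a location shift of W", {
  tab <- make_table(b_items = -0.1, sigma = 0.05, seed = 2)
  e1 <- fit_glm(tab)$table$eta_sq_partial
  tab$W <- tab$W + 0.3
  expect_equal(fit_glm(tab)$table$eta_sq_partial, e1)
})

test_that("degenerate designs raise informative errors", {
  tab <- make_table()
  tab$sequential <- tab$items_needed # collinear
  expect_error(fit_glm(tab), "collinear|rank")
  tab2 <- make_table()
  tab2$realtime <- 0
  expect_error(fit_glm(tab2), "realtime")
})

test_that("sequential and marginal sums of squares are both available", {
  tab <- make_table(b_items = -0.2, b_seq = -0.1, sigma = 0.03, seed = 6)
  f1 <- fit_glm(tab, ss_type = "sequential")
  f2 <- fit_glm(tab, ss_type = "marginal")
  # balanced orthogonal design: the two decompositions coincide
  expect_equal(f1$table$eta_sq_partial, f2$table$eta_sq_partial,
               tolerance = 1e-8)
  # raw food coding changes the food coefficient scale only
  f3 <- fit_glm(tab, food_coding = "raw")
  expect_equal(f3$table$estimate[f3$table$term == "food"] * 25000,
               f1$table$estimate[f1$table$term == "food"])
})

test_that("condition summaries produce figure-ready means and errors", {
  tab <- make_table(b_items = -0.2, sigma = 0, reps = 2)
  s <- condition_summaries(tab)
  expect_setequal(unique(s$factor),
                  c("items_needed", "sequential", "realtime", "display_level"))
  row <- s[s$factor == "items_needed" & s$level == 1 & s$food_level == 250, ]
  expect_equal(row$mean_W, 0.5)
  expect_equal(row$sem, 0)
  expect_equal(row$n, 8L) # 4 build combinations x 2 replicates
  # single-run cells report zero-width errors
  s1 <- condition_summaries(make_table(reps = 1))
  expect_true(all(s1$sem[s1$n == 1] == 0))
})
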