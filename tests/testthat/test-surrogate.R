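test_that("design encoding maps the feasible box onto [-1, 1]", {
  expect_equal(encode_design(30, 1)[1, ], c(spacing = -1, pruning = -1))
  expect_equal(encode_design(80, 4)[1, ], c(spacing = 1, pruning = 1))
  expect_equal(encode_design(55, 4)[1, ], c(spacing = 0, pruning = 1))
  expect_error(encode_design(85, 2), "bounds")
  expect_error(encode_design(55, 5), "pruning code")
  oh <- encode_design(design_grid(), encoding = "onehot")
  expect_identical(dim(oh), c(44L, 5L))
  expect_true(all(rowSums(oh[, -1]) == 1))
})

test_that("output scaling round-trips training targets exactly", {
  set.seed(4)
  Y <- cbind(runif(12, 95, 125), runif(12, 20, 60), runif(12, 0, 1))
  sc <- melonopt:::make_yscaler(Y)
  expect_equal(melonopt:::descale_y(melonopt:::scale_y(Y, sc), sc), Y,
               tolerance = 1e-12)
  # constant column degenerates gracefully
  Y2 <- cbind(Y[, 1:2], 0.5)
  sc2 <- melonopt:::make_yscaler(Y2)
  expect_equal(melonopt:::descale_y(melonopt:::scale_y(Y2, sc2), sc2), Y2,
               tolerance = 1e-12)
})

noiseless_trial <- function(noise_frac = 0) {
  sc <- trial_scenario(spacings = seq(30, 80, 5), design = "factorial",
                       noise_frac = noise_frac)
  generate_trial(sc, seed = 3)
}

test_that("smooth noiseless response surfaces are fit essentially exactly", {
  ds <- noiseless_trial()
  fit <- train_surrogate(ds, surrogate_config(restarts = 2,
                                              split_mode = "none", seed = 9))
  expect_lt(fit$model$meta$train_mse, 1e-6)
  pred <- predict(fit$model, ds$treatments)
  expect_equal(pred$duration, ds$responses$duration, tolerance = 1e-2)
  expect_equal(pred$yield, ds$responses$yield, tolerance = 1e-2)
})

test_that("training is reproducible and refuses incomplete responses", {
  ds <- noiseless_trial()
  cfg <- surrogate_config(restarts = 2, split_mode = "none", seed = 17,
                          max_epochs = 60)
  f1 <- train_surrogate(ds, cfg)
  f2 <- train_surrogate(ds, cfg)
  expect_identical(f1$model$theta, f2$model$theta)
  expect_identical(f1$report$train$mse, f2$report$train$mse)

  ds_bad <- ds
  ds_bad$responses$yield[c(3, 7)] <- NA
  expect_error(train_surrogate(ds_bad, cfg),
               paste0("incomplete.*", ds$responses$label[3]))
})

test_that("constant targets are reproduced with the R flag unset", {
  ds <- noiseless_trial()
  ds$responses$ci <- 0.5
  ds$responses$duration <- 100
  ds$responses$yield <- 40
  fit <- train_surrogate(ds, surrogate_config(restarts = 1,
                                              split_mode = "none",
                                              max_epochs = 5, seed = 2))
  pred <- predict(fit$model, ds$treatments)
  expect_equal(pred$ci, rep(0.5, nrow(pred)), tolerance = 1e-9)
  expect_equal(pred$yield, rep(40, nrow(pred)), tolerance = 1e-9)
  expect_false(fit$report$train$r_defined)
})

test_that("prediction is deterministic, shaped for the grid, and clamps Ci", {
  ds <- noiseless_trial()
  fit <- train_surrogate(ds, surrogate_config(restarts = 1,
                                              split_mode = "none",
                                              max_epochs = 50, seed = 5))
  two <- predict(fit$model, data.frame(spacing = c(60, 60),
                                       pruning_code = c(2, 2)))
  expect_equal(two[1, ], two[2, ], ignore_attr = TRUE)
  grid_pred <- predict(fit$model, design_grid())
  expect_identical(nrow(grid_pred), 44L)
  expect_true(all(grid_pred$ci >= 0 & grid_pred$ci <= 1))
})

test_that("the residual Jacobian matches finite differences", {
  layout <- melonopt:::mlp_layout(c(2, 5, 4, 3))
  theta <- melonopt:::with_seed(29, runif(layout$count, -0.7, 0.7))
  X <- melonopt:::with_seed(30, matrix(runif(14, -1, 1), 7, 2))
  jb <- melonopt:::mlp_jacobian(theta, layout, X)
  h <- 1e-6
  num <- vapply(seq_len(layout$count), function(p) {
    tp <- theta; tp[p] <- tp[p] + h
    tm <- theta; tm[p] <- tm[p] - h
    as.vector(melonopt:::mlp_forward(tp, layout, X) -
                melonopt:::mlp_forward(tm, layout, X)) / (2 * h)
  }, numeric(21))
  expect_lt(max(abs(jb$J - num)), 1e-7)
})

test_that("the LM trainer reaches the unique least-squares optimum that
           closed-form and minpack.lm solvers find", {
  # an identity-output network with no hidden layer is a linear model:
  # the loss has a unique global minimum all three routes must agree on
  ds <- noiseless_trial(noise_frac = 0.05)  # noise is irrelevant here
  X <- encode_design(ds$treatments$spacing, ds$treatments$pruning_code)
  Y <- as.matrix(ds$responses[, c("duration", "yield", "ci")])
  ysc <- melonopt:::make_yscaler(Y)
  Ys <- melonopt:::scale_y(Y, ysc)
  layout <- melonopt:::mlp_layout(c(2, 3))
  theta0 <- melonopt:::with_seed(21, runif(layout$count, -0.5, 0.5))
  cfg <- surrogate_config(hidden_sizes = 4, max_epochs = 200,
                          mse_target = 0, seed = 1)
  ours <- melonopt:::train_lm(theta0, layout, X, Ys, X, Ys, cfg)
  exact <- stats::lm.fit(cbind(X, 1), Ys)
  exact_mse <- mean(exact$residuals^2)
  ref <- minpack.lm::nls.lm(
    par = theta0,
    fn = function(p) as.vector(melonopt:::mlp_forward(p, layout, X) - Ys),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  expect_equal(ours$train_mse, exact_mse, tolerance = 1e-10)
  expect_equal(mean(ref$fvec^2), exact_mse, tolerance = 1e-8)
})

test_that("the gradient-descent fallback reduces the loss", {
  ds <- noiseless_trial()
  cfg_gd <- surrogate_config(restarts = 1, split_mode = "none",
                             method = "gd", max_epochs = 300, seed = 8)
  fit <- train_surrogate(ds, cfg_gd)
  # far looser than LM, but clearly below the variance of scaled targets
  expect_lt(fit$model$meta$train_mse, 0.2)
})

test_that("more restarts do not hurt held-out accuracy", {
  sc <- trial_scenario(spacings = seq(30, 80, 10), design = "factorial",
                       noise_frac = 0)
  ds <- generate_trial(sc, seed = 13)
  heldout_rmse <- function(restarts, seed) {
    cfg <- surrogate_config(restarts = restarts, split_mode = "random",
                            max_epochs = 40, seed = seed)
    fit <- train_surrogate(ds, cfg)
    idx <- fit$report$split$test
    if (!length(idx)) idx <- fit$report$split$val
    pred <- predict(fit$model, ds$treatments[idx, , drop = FALSE])
    obs <- ds$responses[idx, c("duration", "yield", "ci")]
    sqrt(mean(as.matrix(pred[, c("duration", "yield", "ci")] - obs)^2))
  }
  seeds <- 1:8
  r1 <- vapply(seeds, function(s) heldout_rmse(1, s), 0)
  r5 <- vapply(seeds, function(s) heldout_rmse(5, s), 0)
  expect_lte(stats::median(r5), stats::median(r1))
})

test_that("surrogates serialize to JSON and restore bit-identically", {
  ds <- noiseless_trial()
  fit <- train_surrogate(ds, surrogate_config(restarts = 1,
                                              split_mode = "none",
                                              max_epochs = 40, seed = 6))
  path <- tempfile(fileext = ".json")
  write_surrogate(fit$model, path)
  back <- read_surrogate(path)
  expect_identical(predict(back, design_grid()),
                   predict(fit$model, design_grid()))
})
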