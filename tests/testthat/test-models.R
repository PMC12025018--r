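test_that("flatten widths match the independent shape oracle", {
  for (spec in list(branch_spec("ECG"), branch_spec("SPO2"),
                    branch_spec("ECG", input_len = 512),
                    branch_spec("SPO2", input_len = 128))) {
    expect_identical(flatten_width(spec),
                     oracle_shapes(spec$input_len, spec$conv_layers, "same"))
  }
  expect_identical(flatten_width(branch_spec("ECG")), 2040L)   # 68 x 30
  expect_identical(flatten_width(branch_spec("SPO2")), 330L)   # 11 x 30
})

test_that("the printed SpO2 stack is infeasible under valid padding", {
  expect_error(propagate_shape(branch_spec("SPO2", padding = "valid")),
               "conv3 \\(kernel 15\\) infeasible")
  # oracle agrees that valid padding cannot work
  expect_true(is.na(oracle_shapes(88, branch_spec("SPO2")$conv_layers, "valid")))
  # and valid padding on a long-enough input still matches the oracle
  sp <- branch_spec("ECG", input_len = 2048, padding = "valid")
  expect_identical(flatten_width(sp), oracle_shapes(2048, sp$conv_layers, "valid"))
})

test_that("built branches have the stated layer sequence", {
  m <- build_branch(branch_spec("ECG"), seed = 1)
  types <- vapply(m$layers, function(l) l$type, character(1))
  expect_identical(types, c("batchnorm", rep(c("conv", "relu", "maxpool"), 3),
                            "flatten", "dropout", "dense"))
  expect_equal(m$layers[[12]]$rate, 0.25)
  expect_identical(m$layers[[13]]$n_out, 2L)
  convs <- m$layers[types == "conv"]
  expect_identical(vapply(convs, function(l) l$kernel, integer(1)), c(100L, 10L, 30L))
  expect_identical(vapply(convs, function(l) l$c_out, integer(1)), c(3L, 50L, 30L))
  expect_identical(vapply(convs, function(l) l$stride, integer(1)), c(2L, 1L, 1L))
})

test_that("softmax outputs are probabilities for random inputs", {
  m <- build_branch(branch_spec("SPO2"), seed = 2)
  set.seed(3)
  P <- nn_predict(m, matrix(rnorm(5 * 88), 5))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  expect_true(all(P >= 0))
})

test_that("selective dropout rates follow both published rules", {
  # matched structures: rate ratio rule, slowest sensor gets 0
  p1 <- selective_dropout_rates(c(100, 8), c(1100, 88), "MATCHED_FS")
  expect_equal(p1$rates, c(1 - 8 / 100, 0))
  expect_equal(p1$rates[1], 0.92)
  # mismatched flatten widths: neuron ratio rule on the wider branch
  p2 <- selective_dropout_rates(c(100, 8), c(2040, 330), "MISMATCHED_NEURONS")
  expect_equal(p2$rates, c(1 - 330 / 2040, 0))
  expect_equal(p2$rates[1], 0.8382353, tolerance = 1e-6)
  # equal rates -> identity
  p3 <- selective_dropout_rates(c(64, 64), c(500, 500), "MATCHED_FS")
  expect_equal(p3$rates, c(0, 0))
  expect_warning(selective_dropout_rates(100, 2040), "no-op")
  expect_error(selective_dropout_rates(c(100, -8), c(1, 1)), "positive")
})

test_that("dropout rates are in [0,1), zero the slowest sensor, and are monotone in fs", {
  set.seed(4)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    fs <- sort(stats::runif(k, 1, 200))
    neurons <- sample(50:3000, k)
    pl <- selective_dropout_rates(fs, neurons, "MATCHED_FS")
    expect_true(all(pl$rates >= 0 & pl$rates < 1))
    expect_identical(which(pl$rates == 0), which.min(fs))
    expect_true(all(diff(pl$rates[order(fs)]) >= 0))
  }
})

test_that("fusion concatenates 2040 + 330 features and validates plans", {
  be <- build_branch(branch_spec("ECG"), 1)
  bs <- build_branch(branch_spec("SPO2"), 2)
  fm <- build_fusion(be, bs, fusion_plan(), seed = 3)
  expect_identical(fm$concat_width, 2370L)
  expect_identical(fm$head$layers[[1]]$n_in, 2370L)
  expect_equal(fm$dropout_plan$rates, c(1 - 330 / 2040, 0))
  bad_plan <- fusion_plan(dropout_plan = selective_dropout_rates(c(100, 8), c(999, 330)))
  expect_error(build_fusion(be, bs, bad_plan), "inconsistent with branch flatten widths")
})

test_that("fusion training freezes every branch parameter", {
  pair <- fixture_window_pair(2, 90, seed = 17, filter_ecg = TRUE)
  hy <- train_hyper(epochs = 1, batch_size = 32)
  be <- train_branch(build_branch(branch_spec("ECG"), 1), pair$ecg, pair$ecg, hy, 2)$model
  bs <- train_branch(build_branch(branch_spec("SPO2"), 3), pair$spo2, pair$spo2, hy, 4)$model
  fm <- build_fusion(be, bs, fusion_plan(), seed = 5)
  before <- nn_param_vector(fm)
  head_before <- apneafusion:::nn_param_vector(fm$head)
  res <- train_fusion(fm, pair, pair, train_hyper(epochs = 1, batch_size = 32), 6)
  expect_identical(nn_param_vector(res$model), before)       # frozen, bit-level
  expect_false(identical(apneafusion:::nn_param_vector(res$model$head), head_before))
})

test_that("dropout is inactive at inference regardless of rate", {
  pair <- fixture_window_pair(1, 60, seed = 23)
  be <- build_branch(branch_spec("ECG"), 1)
  bs <- build_branch(branch_spec("SPO2"), 2)
  mk <- function(rate) {
    dp <- selective_dropout_rates(c(100, 8), c(2040L, 330L))
    dp$rates <- c(rate, 0)
    build_fusion(be, bs, fusion_plan(dropout_plan = dp), seed = 9)
  }
  p_hi <- fusion_predict(mk(0.9), pair$ecg$windows[1:3, ], pair$spo2$windows[1:3, ])
  p_lo <- fusion_predict(mk(0.0), pair$ecg$windows[1:3, ], pair$spo2$windows[1:3, ])
  expect_identical(p_hi, p_lo)
})

test_that("too-short inputs error at the failing layer", {
  # 4 -> 2 -> 2 -> 1 -> 1: the third pool would produce length 0
  sp <- branch_spec("SPO2", input_len = 4L)
  expect_error(build_branch(sp), "pool after conv3 infeasible")
})

test_that("checkpoints write a readable manifest and full parameter vector", {
  m <- build_branch(branch_spec("SPO2"), seed = 7)
  dir <- file.path(tempdir(), "ckpt1")
  save_checkpoint(m, dir)
  v <- as.numeric(readLines(file.path(dir, "params.txt")))
  expect_identical(length(v), length(nn_param_vector(m)))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$kind, "branch")
  expect_identical(man$spec$channel, "SPO2")
})
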