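test_that("one S-CLB pass visits S(S-1)/2 pairs and the error trace never increases", {
  d <- gaussian_blobs(synth_spec(n = 150, overlap = 2, seed = 41))
  m <- train_multimodel(d, S = 4, T = 8, eta = 0.5, mode = "sclb",
                        n_exc = 1, seed = 41)
  expect_identical(attr(m$log, "n_tentative"), 6L)  # 4*3/2
  expect_length(m$error_trace, 7)  # tau = 0..6
  expect_true(all(diff(m$error_trace) <= 0))
})

test_that("prospective exchange accounting is S(S-1) n_exc / 2 exactly", {
  set.seed(3)
  for (rep in 1:10) {
    S <- sample(2:10, 1)
    n_exc <- sample(1:4, 1)
    expect_equal(prospective_collaborations("sclb", S = S, n_exc = n_exc),
                 S * (S - 1) * n_exc / 2)
  }
  # and a live run agrees: tau counts pairs, each worth n_exc exchanges
  d <- gaussian_blobs(synth_spec(n = 120, overlap = 2, seed = 13))
  m <- train_multimodel(d, S = 5, T = 5, eta = 0.5, mode = "sclb",
                        n_exc = 2, seed = 13)
  expect_equal(attr(m$log, "n_tentative") * 2,
               prospective_collaborations("sclb", S = 5, n_exc = 2))
})

test_that("the smallest S-CLB instance visits exactly one pair", {
  d <- gaussian_blobs(synth_spec(n = 80, overlap = 2, seed = 29))
  m <- train_multimodel(d, S = 2, T = 5, eta = 0.5, mode = "sclb",
                        n_exc = 1, seed = 29)
  expect_identical(attr(m$log, "n_tentative"), 1L)
  expect_lte(nrow(m$log), 1)
})

test_that("rejected pairs revert models and subsets bitwise", {
  d <- gaussian_blobs(synth_spec(n = 140, overlap = 2, seed = 53))
  plan <- stratified_subsample(d, S = 3, eta = 0.5, seed = 53)
  ens <- lapply(plan$subsets, function(idx)
    gb_train(dataset_subset(d, idx), 8, training_ids = d$ids[idx]))
  err <- collboost:::multimodel_empirical_error(ens, d)
  # strict acceptance rejects every non-improving exchange, including neutral
  res <- sclb_pair(ens, plan$subsets, j = 2, k = 1, n_exc = 1, d, err,
                   strict = TRUE)
  if (!res$accepted) {
    expect_identical(res$ens, ens)
    expect_identical(res$subsets, plan$subsets)
    expect_equal(res$err, err)
  } else {
    expect_lt(res$err, err)
  }
})

test_that("the stored error trace matches independent re-evaluation of the final model", {
  d <- gaussian_blobs(synth_spec(n = 160, overlap = 2.2, seed = 67))
  m <- train_multimodel(d, S = 4, T = 10, eta = 0.5, mode = "sclb",
                        n_exc = 2, seed = 67)
  pred <- predict(m, d$x)
  expect_equal(error_rate(d$y, pred$label),
               m$error_trace[length(m$error_trace)])
})

test_that("swaps conserve subset sizes and shift class counts by at most n_exc", {
  d <- gaussian_blobs(synth_spec(n = 160, overlap = 1.8, seed = 71))
  n_exc <- 2
  m0 <- train_multimodel(d, S = 4, T = 8, eta = 0.5, mode = "none", seed = 71)
  m1 <- train_multimodel(d, S = 4, T = 8, eta = 0.5, mode = "sclb",
                         n_exc = n_exc, seed = 71)
  for (j in 1:4) {
    expect_length(m1$subsets[[j]], length(m0$subsets[[j]]))
    expect_equal(anyDuplicated(m1$subsets[[j]]), 0)
  }
  # class counts can only change where an accepted pair touched a subset
  acc_taus <- unique(m1$log$tau[m1$log$successful])
  pos0 <- vapply(m0$subsets, function(s) sum(d$y[s] > 0), numeric(1))
  pos1 <- vapply(m1$subsets, function(s) sum(d$y[s] > 0), numeric(1))
  passes_per_subset <- 3  # each of S=4 subsets joins S-1 pairs per pass
  expect_true(all(abs(pos1 - pos0) <= n_exc * passes_per_subset))
})

test_that("identical subsets make every swap a guarded no-op", {
  d <- gaussian_blobs(synth_spec(n = 60, overlap = 3, seed = 83))
  m0 <- train_multimodel(d, S = 2, T = 6, eta = 1, mode = "none", seed = 83)
  m1 <- train_multimodel(d, S = 2, T = 6, eta = 1, mode = "sclb",
                         n_exc = 1, seed = 83)
  expect_equal(predict(m1, d$x)$phi, predict(m0, d$x)$phi)
})

test_that("S-CLB refuses to run with a single ensemble", {
  d <- gaussian_blobs(synth_spec(n = 40, seed = 3))
  expect_error(train_multimodel(d, S = 1, T = 3, mode = "sclb"), "S >= 2")
})
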