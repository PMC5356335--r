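test_that("the margin is y times the raw ensemble output", {
  m <- constant_model(0.8)
  expect_equal(margin(m, c(0), 1), 0.8)
  expect_equal(margin(m, c(0), -1), -0.8)
  d <- gaussian_blobs(synth_spec(n = 40, seed = 14))
  gb <- gb_train(d, T = 6)
  expect_equal(margin(gb, d$x, d$y), d$y * gb_predict_raw(gb, d$x))
})

test_that("weakest/strongest-correct selection matches brute-force filter and sort", {
  set.seed(55)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    d <- gaussian_blobs(synth_spec(n = max(n, 4), overlap = 1, seed = rep))
    gb <- gb_train(d, T = 3)
    k <- sample(1:4, 1)
    mg <- margin(gb, d$x, d$y)
    correct <- which(mg > 0)
    ord <- correct[order(mg[correct], d$ids[correct])]
    expect_equal(select_weakest_correct(gb, d, k),
                 d$ids[ord[seq_len(min(k, length(ord)))]])
    ord2 <- correct[order(-mg[correct], d$ids[correct])]
    expect_equal(select_strongest_correct(gb, d, k),
                 d$ids[ord2[seq_len(min(k, length(ord2)))]])
  }
})

test_that("selection is empty when nothing is classified correctly", {
  d <- labeled_dataset(matrix(c(1, 2), ncol = 1), c(-1, 1))
  m <- constant_model(1)  # predicts +1 everywhere: instance 1 is wrong
  expect_length(select_weakest_correct(m, dataset_subset(d, 1), 2), 0)
  expect_length(select_strongest_correct(m, dataset_subset(d, 1), 2), 0)
})

test_that("p_c = 0 produces no collaboration events and equals plain subbagging bitwise", {
  d <- gaussian_blobs(synth_spec(n = 120, overlap = 2, seed = 31))
  plan <- stratified_subsample(d, S = 3, eta = 0.5, seed = 31)
  res <- train_wclb(d, plan, T = 8, wclb_config(p_c = 0, n_exc = 2, seed = 31))
  expect_equal(nrow(res$log), 0)
  expect_identical(attr(res$log, "n_tentative"), 0L)
  plain <- lapply(plan$subsets, function(idx)
    gb_train(dataset_subset(d, idx), 8, training_ids = d$ids[idx]))
  for (j in 1:3)
    expect_identical(res$ensembles[[j]]$stumps, plain[[j]]$stumps)
})

test_that("p_c = 1 fires exactly T * n_exc tentative collaborations", {
  d <- gaussian_blobs(synth_spec(n = 80, overlap = 3, seed = 17))
  plan <- stratified_subsample(d, S = 2, eta = 0.5, seed = 17)
  res <- train_wclb(d, plan, T = 5, wclb_config(p_c = 1, n_exc = 2, seed = 17))
  expect_identical(attr(res$log, "n_tentative"), 10L)
  expect_equal(length(unique(paste(res$log$round, res$log$rep))), 10)
})

test_that("the W-CLB schedule averages T * p_c * n_exc tentative events", {
  d <- gaussian_blobs(synth_spec(n = 40, overlap = 3, seed = 2))
  plan <- stratified_subsample(d, S = 2, eta = 0.5, seed = 2)
  counts <- vapply(1:300, function(s) {
    res <- train_wclb(d, plan, T = 20,
                      wclb_config(p_c = 0.1, n_exc = 3, seed = s))
    attr(res$log, "n_tentative")
  }, integer(1))
  expected <- 20 * 0.1 * 3  # = 6
  se <- sqrt(expected * (1 - 0.1)) / sqrt(300)  # binomial count SE / sqrt(runs)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("exchanges conserve subset sizes and weights, and only remove positive margins", {
  d <- gaussian_blobs(synth_spec(n = 100, overlap = 1.5, seed = 77))
  plan <- stratified_subsample(d, S = 4, eta = 0.4, seed = 77)
  p <- length(plan$subsets[[1]])
  res <- train_wclb(d, plan, T = 10, wclb_config(p_c = 0.5, n_exc = 2, seed = 7))
  for (sub in res$subsets) {
    expect_length(sub, p)
    expect_equal(anyDuplicated(sub), 0)
  }
  applied <- res$log[res$log$successful, ]
  expect_gt(nrow(applied), 0)
  expect_true(all(applied$removed_margin > 0))
  expect_true(all(applied$added_margin > 0))
})

test_that("the duplicate guard blocks exchanges that would repeat an instance", {
  # eta = 1: every subset holds every instance, so any incoming copy collides
  d <- gaussian_blobs(synth_spec(n = 30, overlap = 4, seed = 19))
  plan <- stratified_subsample(d, S = 2, eta = 1, seed = 19)
  res <- train_wclb(d, plan, T = 4, wclb_config(p_c = 1, n_exc = 1, seed = 19))
  expect_gt(nrow(res$log), 0)
  expect_false(any(res$log$successful))
  for (sub in res$subsets) expect_equal(sort(sub), 1:30)
})

test_that("W-CLB needs at least two ensembles", {
  d <- gaussian_blobs(synth_spec(n = 40, seed = 23))
  plan <- stratified_subsample(d, S = 1, eta = 0.5, seed = 23)
  expect_warning(res <- train_wclb(d, plan, T = 3, wclb_config(p_c = 1, seed = 1)),
                 "S >= 2")
  expect_equal(nrow(res$log), 0)
})

test_that("W-CLB does not hurt mean test error on overlapping classes", {
  # paired seeded runs against non-collaborative subbagging, same plans
  spec <- synth_spec(n = 150, d = 2, overlap = 2.56, seed = 1)
  res <- paired_compare(
    config_a = list(S = 3, T = 10, eta = 0.5, mode = "none"),
    config_b = list(S = 3, T = 10, eta = 0.5, mode = "wclb",
                    p_c = 0.2, n_exc = 2),
    synth = spec, n_seeds = 12, n_test = 400, seed = 99)
  expect_gte(res$mean_delta, -0.01)  # small-sample guard band
})
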