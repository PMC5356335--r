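test_that("load_csv maps a binary label column onto -1/+1 and keeps row order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,outcome",
               "1.0,2.0,case",
               "3.5,0.5,control",
               "2.0,2.0,control",
               "0.1,9.0,case"), path)
  d <- load_csv(path, "outcome", "case")
  expect_equal(d$y, c(1, -1, -1, 1))
  expect_equal(d$ids, 0:3)
  expect_equal(unname(d$x[, "a"]), c(1.0, 3.5, 2.0, 0.1))
})

test_that("load_csv rejects malformed inputs with a diagnostic", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,lab", "1,x", "2,y", "3,z"), path)
  expect_error(load_csv(path, "lab", "x"), "not binary")
  expect_error(load_csv(path, "nope", "x"), "'nope' not found")
  writeLines(c("a,lab", "1,x", "oops,y"), path)
  expect_error(load_csv(path, "lab", "x"), "column 'a'")
  writeLines(c("a,lab", "1,x", ",y"), path)
  expect_error(load_csv(path, "lab", "x"), "column 'a'")
  writeLines("a,lab", path)
  expect_error(load_csv(path, "lab", "x"), "empty")
})

test_that("datasets survive a write/load CSV round trip", {
  d <- gaussian_blobs(synth_spec(n = 30, d = 3, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d, path)
  d2 <- load_csv(path, "label", "1")
  expect_equal(d2$x, d$x, ignore_attr = TRUE)
  expect_equal(d2$y, d$y)
})

test_that("labeled_dataset validates labels, missing values and ids", {
  x <- matrix(1:6, ncol = 2)
  expect_error(labeled_dataset(x, c(0, 1, -1)), "-1 or \\+1")
  expect_error(labeled_dataset(x, c(1, 1)), "length")
  xm <- x; xm[2, 1] <- NA
  expect_error(labeled_dataset(xm, c(1, -1, 1)), "row 2, column 1")
  expect_error(labeled_dataset(x, c(1, -1, 1), ids = c(1, 1, 2)), "unique")
})

test_that("stratified subsampling preserves class proportions exactly", {
  d <- gaussian_blobs(synth_spec(n = 100, imbalance = 0.6, seed = 3))
  expect_equal(sum(d$y > 0), 60)
  for (seed in 1:20) {
    plan <- stratified_subsample(d, S = 4, eta = 0.5, seed = seed)
    for (sub in plan$subsets) {
      expect_length(sub, 50)
      expect_equal(anyDuplicated(sub), 0)
      expect_equal(sum(d$y[sub] > 0), 30)  # round(0.5 * 60)
      expect_equal(sum(d$y[sub] < 0), 20)
    }
  }
})

test_that("eta = 1 subsets are permutations of the full index set", {
  d <- gaussian_blobs(synth_spec(n = 10, seed = 5))
  plan <- stratified_subsample(d, S = 3, eta = 1, seed = 1)
  for (sub in plan$subsets) expect_equal(sort(sub), 1:10)
})

test_that("subsampling is deterministic and rejects class-emptying eta", {
  d <- gaussian_blobs(synth_spec(n = 40, seed = 2))
  p1 <- stratified_subsample(d, S = 3, eta = 0.4, seed = 9)
  p2 <- stratified_subsample(d, S = 3, eta = 0.4, seed = 9)
  expect_identical(p1, p2)
  single <- edge_fixtures()$single_positive
  expect_error(stratified_subsample(single, S = 2, eta = 0.3, seed = 1),
               "class")
})

test_that("subsample indices are in range, distinct and stratified across random configs", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(20:80, 1)
    imb <- runif(1, 0.3, 0.7)
    d <- gaussian_blobs(synth_spec(n = n, imbalance = imb, seed = rep))
    eta <- runif(1, 0.3, 1)
    S <- sample(1:5, 1)
    plan <- try(stratified_subsample(d, S, eta, seed = rep), silent = TRUE)
    if (inherits(plan, "try-error")) next
    parent_frac <- mean(d$y > 0)
    for (sub in plan$subsets) {
      expect_true(all(sub >= 1 & sub <= n))
      expect_equal(anyDuplicated(sub), 0)
      expect_lte(abs(mean(d$y[sub] > 0) - parent_frac), 1 / length(sub) + 1e-12)
    }
  }
})

test_that("train/test split conserves ids and hits the requested sizes", {
  d <- gaussian_blobs(synth_spec(n = 10, seed = 4))
  sp <- train_test_split(d, 0.3, seed = 1)
  expect_length(sp$test$y, 3)
  expect_length(sp$train$y, 7)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0)
  expect_setequal(c(sp$train$ids, sp$test$ids), d$ids)
  expect_error(train_test_split(d, 0.5, seed = 1), "0.2")
})

test_that("uniform splitting is unbiased in the test positive fraction", {
  d <- gaussian_blobs(synth_spec(n = 100, seed = 6))
  fracs <- vapply(1:400, function(s) {
    sp <- train_test_split(d, 0.3, seed = s)
    mean(sp$test$y > 0)
  }, numeric(1))
  # hypergeometric SE of a fold positive fraction ~ 0.077; 3 SE of the mean
  expect_lt(abs(mean(fracs) - 0.5), 3 * 0.077 / sqrt(400))
})
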