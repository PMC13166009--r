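test_that("surrogate accuracy is deterministic and monotone in depth", {
  a <- decode_genome(rep(0.5, 28))
  expect_identical(surrogate_accuracy(a, seed = 7), surrogate_accuracy(a, seed = 7))
  expect_false(identical(surrogate_accuracy(a, seed = 7),
                         surrogate_accuracy(a, seed = 8)))
  # deeper network, other things equal, scores higher (jitter is +/-0.02,
  # the depth term moves by 0.55 * (1 - exp(-p/3e5)) * dL/10 >> 0.04 here)
  g_shallow <- rep(0.5, 28); g_shallow[1] <- 0.05
  g_deep <- rep(0.5, 28); g_deep[1] <- 0.95
  expect_gt(surrogate_accuracy(decode_genome(g_deep), 1),
            surrogate_accuracy(decode_genome(g_shallow), 1))
  expect_true(surrogate_accuracy(a, 1) >= 0 && surrogate_accuracy(a, 1) <= 1)
})

test_that("penalized genomes never reach the evaluator", {
  calls <- 0L
  spy <- external_evaluator(function(arch, seed) {
    calls <<- calls + 1L
    0.5
  }, label = "spy")
  # all standard conv at 512 channels, 10 layers: far over budget
  g_over <- c(1, rep(0.1, 9), rep(1, 9), rep(0, 9))
  r <- evaluate_genome(g_over, spy, seed = 1)
  expect_equal(r$fitness, -1000)
  expect_false(r$evaluated)
  expect_identical(calls, 0L)
  expect_false(r$report$fpga_ok)
  # structural violation: skip first
  g_skip <- rep(0.5, 28); g_skip[2] <- 0.9
  r2 <- evaluate_genome(g_skip, spy, seed = 1)
  expect_equal(r2$fitness, -1000)
  expect_identical(calls, 0L)
  # a valid genome (distinct pooling positions) does reach it
  g_ok <- rep(0.5, 28)
  g_ok[23:25] <- c(0.1, 0.45, 0.8)
  r3 <- evaluate_genome(g_ok, spy, seed = 1)
  expect_identical(calls, 1L)
  expect_equal(r3$fitness, nas_fitness(0.5, r3$report$total))
})

test_that("search returns a feasible best, logs diagnostics, and is reproducible", {
  res <- nas_search(pop_size = 10, generations = 20, seed = 5)
  expect_true(res$report$fpga_ok)
  expect_lt(res$report$total, 1e6)
  expect_equal(res$best_fitness,
               nas_fitness(res$accuracy, res$report$total))
  # maximized best fitness never decreases (elitism through negation)
  expect_true(all(diff(res$history$best_fitness) >= 0))
  expect_equal(nrow(res$history), 20)
  expect_true(all(res$history$valid_fraction >= 0 &
                    res$history$valid_fraction <= 1))
  # evaluator economy: at most one call per evaluation performed
  expect_lte(res$evaluator_calls, res$optim$evals)
  res2 <- nas_search(pop_size = 10, generations = 20, seed = 5)
  expect_identical(res$best_genome, res2$best_genome)
  expect_identical(res$history, res2$history)
  g <- glance(res)
  expect_equal(g$fpga_ok, TRUE)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("stratified split matches fractions per class and globally", {
  s <- stratified_split(rep(1:4, each = 750), seed = 42)
  expect_equal(lengths(s), c(train = 2100L, val = 450L, test = 450L))
  s2 <- stratified_split(rep(letters[1:4], each = 25), seed = 1)
  expect_equal(lengths(s2), c(train = 70L, val = 15L, test = 15L))
  # partition property
  all_idx <- sort(unlist(s2, use.names = FALSE))
  expect_identical(all_idx, 1:100)
  expect_length(intersect(s2$train, s2$val), 0)
  expect_length(intersect(s2$val, s2$test), 0)
  # per-class proportions within one item
  labs <- rep(1:4, each = 750)
  for (split_name in names(s)) {
    tab <- table(labs[s[[split_name]]])
    frac <- c(train = 0.70, val = 0.15, test = 0.15)[[split_name]]
    expect_true(all(abs(tab - 750 * frac) <= 1), info = split_name)
  }
  # deterministic, seed-sensitive shuffling
  expect_identical(stratified_split(labs, seed = 3), stratified_split(labs, seed = 3))
  expect_false(identical(stratified_split(labs, seed = 3)$train,
                         stratified_split(labs, seed = 4)$train))
  expect_error(stratified_split(integer(0)), "at least one")
})

test_that("synthetic images are balanced, bounded and reproducible", {
  set1 <- generate_synthetic_images(5, size = c(32, 32), seed = 9)
  expect_equal(dim(set1$images), c(20, 32, 32))
  expect_equal(unname(as.vector(set1$counts)), rep(5L, 4))
  expect_true(all(set1$images >= 0 & set1$images <= 1))
  set2 <- generate_synthetic_images(5, size = c(32, 32), seed = 9)
  expect_identical(set1$images, set2$images)
  expect_false(identical(
    set1$images, generate_synthetic_images(5, size = c(32, 32), seed = 10)$images))
  # class textures are distinguishable at least by simple statistics:
  # the central spot class is brightest at the center
  center <- set1$images[, 14:18, 14:18]
  center_mean <- apply(center, 1, mean)
  pit <- which(set1$labels == "pituitary")
  no_t <- which(set1$labels == "no_tumor")
  expect_gt(mean(center_mean[pit]), mean(center_mean[no_t]))
  expect_s3_class(autoplot(set1), "ggplot")
})
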