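test_that("Levy steps use the Mantegna scale and are heavy-tailed", {
  expect_equal(chaonas:::levy_sigma(1.5), 0.696575, tolerance = 1e-5)
  v <- levy_flight(1e5, seed = 3)
  expect_identical(v, levy_flight(1e5, seed = 3))
  bulk <- v[abs(v) <= quantile(abs(v), 0.9)]
  expect_gt(max(abs(v)), 10 * sd(bulk))
})

test_that("omega schedule runs from 0 to 0.2", {
  expect_equal(omega_coef(0, 100), 0, tolerance = 1e-15)
  expect_equal(omega_coef(100, 100), 0.2)
  expect_equal(omega_coef(50, 100), 0.2 * cos(pi / 4))
})

test_that("jump quantization matches the printed arithmetic", {
  f_jump <- (-100 - 100) / 1000
  expect_equal(f_jump, -0.2)
  expect_equal(floor(0.5 / f_jump) * f_jump, 0.6)
})

test_that("roles split 40/40/10/10 by rank with stable ties", {
  r20 <- assign_roles(seq_len(20))
  expect_equal(as.vector(table(r20)[c("leader", "explorer", "follower", "loser")]),
               c(8L, 8L, 2L, 2L))
  r30 <- assign_roles(seq_len(30))
  expect_equal(as.vector(table(r30)[c("leader", "explorer", "follower", "loser")]),
               c(12L, 12L, 3L, 3L))
  # equal fitness: role follows index order
  tied <- assign_roles(rep(1, 10))
  expect_equal(tied[1:4], rep("leader", 4))
  expect_equal(tied[9:10], c("follower", "loser"))
})

test_that("diversity is the mean normalized per-dimension spread", {
  same <- matrix(0.3, nrow = 4, ncol = 5)
  expect_equal(population_diversity(same, 0, 1), 0)
  corners <- rbind(rep(0, 5), rep(1, 5))
  expect_equal(population_diversity(corners, 0, 1), 0.5)
})

test_that("reinitialization replaces exactly the worst ceiling(fraction N)", {
  pos <- matrix(0.5, nrow = 20, ncol = 3)
  fit <- seq_len(20)
  chaos <- chaonas:::chaos_stream("tent", 99)
  rb <- chaonas:::reinit_bottom(pos, fit, 0.2, 0, 1, chaos)
  expect_length(rb$replaced, 4)
  expect_setequal(rb$replaced, 17:20)
  changed <- which(rowSums(rb$positions != pos) > 0)
  expect_true(all(changed %in% 17:20))
})

test_that("chaotic initialization maps unit values into the box", {
  res <- heoa_optimize(objective("sphere", dim = 4),
                       heoa_config(pop_size = 6, max_iters = 4, seed = 5))
  expect_true(all(res$best_position >= -100 & res$best_position <= 100))
  # bounds [0,1]: initial best equals the best raw chaotic row
  f <- function(x) sum(x^2)
  r01 <- heoa_optimize(f, heoa_config(pop_size = 6, max_iters = 4, seed = 5),
                       dim = 4, lower = 0, upper = 1)
  vals <- chaos_orbit("tent", 24, seed = chaonas:::derive_seed(5L, "init"))
  pop <- matrix(vals, nrow = 6, byrow = TRUE)
  expect_equal(r01$initial_best, min(apply(pop, 1, f)))
})

test_that("every evaluated point stays inside the box", {
  violations <- 0L
  obj <- objective("rastrigin", dim = 8)
  watched <- function(x) {
    if (any(x < obj$lower - 1e-12 | x > obj$upper + 1e-12)) violations <<- violations + 1L
    evaluate_objective(obj, x)
  }
  heoa_optimize(watched, heoa_config(pop_size = 12, max_iters = 60, seed = 2),
                dim = 8, lower = obj$lower, upper = obj$upper)
  expect_identical(violations, 0L)
})

test_that("elitist bookkeeping: history non-increasing, final equals minimum seen", {
  seen <- numeric(0)
  obj <- objective("griewank", dim = 6)
  watched <- function(x) {
    v <- evaluate_objective(obj, x)
    seen <<- c(seen, v)
    v
  }
  res <- heoa_optimize(watched, tiny_config(), dim = 6, lower = obj$lower,
                       upper = obj$upper)
  expect_true(all(diff(res$trace$best) <= 0))
  expect_equal(res$best_fitness, min(seen))
  expect_lte(res$best_fitness, res$initial_best)
})

test_that("evaluation counter is exact", {
  res <- heoa_optimize(objective("rastrigin", dim = 5),
                       heoa_config(pop_size = 10, max_iters = 50, seed = 8))
  n_reinit_evals <- sum(res$trace$reinit) * ceiling(0.2 * 10)
  expect_identical(res$evals, as.integer(10 + 50 * 10 + n_reinit_evals))
})

test_that("runs are deterministic given the seed and sensitive to it", {
  a <- heoa_optimize(objective("ackley", dim = 5), tiny_config())
  b <- heoa_optimize(objective("ackley", dim = 5), tiny_config())
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_position, b$best_position)
  c <- heoa_optimize(objective("ackley", dim = 5),
                     heoa_config(pop_size = 10, max_iters = 40, seed = 12))
  expect_false(identical(a$trace$best, c$trace$best))
})

test_that("exploration occupies the first quarter with the stated boundary", {
  r4 <- heoa_optimize(objective("sphere", dim = 3),
                      heoa_config(pop_size = 5, max_iters = 4, seed = 1))
  expect_equal(sum(r4$trace$phase == "exploration"), 1)
  r40 <- heoa_optimize(objective("sphere", dim = 3), tiny_config())
  expect_equal(sum(r40$trace$phase == "exploration"), 10)
  expect_equal(r40$trace$phase[1], "exploration")
})

test_that("with the logistic map and no reinit, initialization matches the original scheme", {
  cfg_mc <- heoa_config(pop_size = 8, max_iters = 8, seed = 4, map = "logistic",
                        reinit = FALSE, chaotic_draws = TRUE)
  cfg_orig <- heoa_config(pop_size = 8, max_iters = 8, seed = 4, map = "logistic",
                          reinit = FALSE, chaotic_draws = FALSE)
  a <- heoa_optimize(objective("sphere", dim = 4), cfg_mc)
  b <- heoa_optimize(objective("sphere", dim = 4), cfg_orig)
  expect_identical(a$initial_best, b$initial_best)
  expect_true(all(!a$trace$reinit))
})

test_that("tidiers return trace and one-row summaries", {
  res <- heoa_optimize(objective("sphere", dim = 4), tiny_config())
  tr <- tidy(res)
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c("iteration", "phase", "best", "diversity", "reinit"))
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_equal(g$best_fitness, res$best_fitness)
  expect_s3_class(autoplot(res), "ggplot")
})
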