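test_that("decode is total, deterministic and respects the gene layout", {
  g <- rep(0.5, 28)
  a <- decode_genome(g)
  expect_identical(decode_genome(g)$layers, a$layers)
  expect_equal(nrow(a$layers), 6)          # L = floor(2 + 9 * 0.5)
  expect_true(all(a$layers$out_channels == 272))  # 32 + 0.5 * 480
  expect_equal(a$fc_dim, 256L)
  expect_equal(a$dropout, 0.4)
  expect_equal(a$classes, 4L)

  expect_equal(nrow(decode_genome(rep(0, 28))$layers), 2)   # lower bound
  expect_equal(nrow(decode_genome(rep(1, 28))$layers), 10)  # min-cap at 1.0
  expect_error(decode_genome(rep(0.5, 27)), "28")
  expect_error(decode_genome(c(rep(0.5, 27), 1.2)), "\\[0, 1\\]")
})

test_that("layer-count decoding covers 2..10 over a uniform gene grid", {
  g <- rep(0.5, 28)
  L <- vapply(seq(0, 1, length.out = 1000), function(x) {
    g[1] <- x
    nrow(decode_genome(g)$layers)
  }, numeric(1))
  expect_setequal(L, 2:10)
})

test_that("decoded channels live on the 16-multiples lattice in [32, 512]", {
  set.seed(20)
  for (k in 1:50) {
    ch <- decode_genome(runif(28))$layers$out_channels
    expect_true(all(ch %% 16 == 0))
    expect_true(all(ch >= 32 & ch <= 512))
  }
})

test_that("structural validation flags the defined violations", {
  g <- rep(0.5, 28)
  # three poolings on 224 leaves 28x28: valid
  g[20:22] <- 0.5; g[23:25] <- c(0.1, 0.4, 0.9)
  expect_length(validate_architecture(decode_genome(g)), 0)
  # skip in first position
  g2 <- rep(0.5, 28); g2[2] <- 0.9
  expect_match(validate_architecture(decode_genome(g2)), "skip", all = FALSE)
  # colliding pooling slots
  g3 <- rep(0.5, 28); g3[20:22] <- 0.5; g3[23:25] <- 0.1
  expect_match(validate_architecture(decode_genome(g3)), "duplicate", all = FALSE)
  # spatial collapse on a hypothetical deep pooling stack
  a <- decode_genome(rep(0.5, 28))
  a$input <- c(4L, 4L, 1L)
  a$layers$pooling_after <- c("max", "max", "max", "none", "none", "none")
  expect_match(validate_architecture(a), "collapse", all = FALSE)
})

test_that("parameter counts follow the 3x3-with-bias conventions", {
  g <- rep(0, 28)
  g[1] <- 0.05                     # 2 layers
  g[2:3] <- c(0.1, 0.5)            # standard then depthwise separable
  g[11] <- 0                       # 32 channels
  g[12] <- (64 - 32) / 480         # 64 channels
  a <- decode_genome(g)
  rep_ <- count_params(a)
  expect_equal(rep_$per_layer$params[1], 9 * 1 * 32 + 32)            # 320
  expect_equal(rep_$per_layer$params[2], 9 * 32 + 32 + 32 * 64 + 64) # 2432
  # classifier: GAP -> 64 -> fc64 -> 4
  expect_equal(rep_$per_layer$params[3], 64 * 64 + 64)
  expect_equal(rep_$per_layer$params[4], 64 * 4 + 4)
  expect_equal(rep_$total, sum(rep_$per_layer$params))

  # skip is an identity with zero parameters that forwards its input width
  g[3] <- 0.9
  rep2 <- count_params(decode_genome(g))
  expect_equal(rep2$per_layer$params[2], 0)
  expect_equal(rep2$per_layer$params[3], 32 * 64 + 64)
})

test_that("fitness trades accuracy against compactness behind a hard gate", {
  expect_equal(nas_fitness(1, 0), 0.7)
  expect_equal(nas_fitness(0.5294, 724200), 0.15332)
  expect_equal(nas_fitness(0.99, 1.2e6), -1000)
  expect_equal(nas_fitness(0, 1e6), -1000)     # gate is >= 1e6
  expect_error(nas_fitness(1.2, 100), "\\[0, 1\\]")
  # strict monotonicity below the gate
  expect_gt(nas_fitness(0.8, 5e5), nas_fitness(0.7, 5e5))
  expect_gt(nas_fitness(0.8, 4e5), nas_fitness(0.8, 5e5))
  # penalty dominance: any feasible non-negative-accuracy candidate wins
  expect_gt(nas_fitness(0, 999999), nas_fitness(1, 1e6))
})
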