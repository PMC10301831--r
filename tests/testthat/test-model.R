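tiny_cfg <- function(...) {
  model_config(L = 8L, conv_channels = c(4L, 4L, 6L, 6L), kernel = 3L,
               cbam_reduction = 2L, spatial_kernel = 3L, gru_hidden = 5L,
               seq_len = 3L, fc_sizes = c(7L, 5L), fc_dropout = 0,
               seed = 11L, ...)
}

test_that("analytic gradients match finite differences through every block", {
  set.seed(3)
  cfg <- tiny_cfg()
  model <- init_model(cfg, "deletion")
  T_ <- 3L; B <- 2L
  x <- array(rnorm(9 * 8 * T_ * B), c(9, 8, T_, B))
  y <- matrix(rbinom(T_ * B, 1, 0.5), T_, B)
  msk <- matrix(1, T_, B)
  lossfun <- function(m) {
    fw <- deletion_forward(m, x)
    deepdel:::.masked_bce_grad(matrix(fw$head$logit, T_), y, msk)$loss
  }
  fw <- deletion_forward(model, x)
  lo <- deepdel:::.masked_bce_grad(matrix(fw$head$logit, T_), y, msk)
  gr <- deepdel:::.deletion_backward(model, fw, lo$dlogit)
  eps <- 1e-6
  for (leaf in c("conv1", "conv3", "cbam", "gru_f1", "gru_b1", "fc1",
                 "fc3")) {
    for (nm in names(model$params[[leaf]])) {
      p <- model$params[[leaf]][[nm]]
      for (i in sample(length(p), min(3L, length(p)))) {
        m2 <- model
        m2$params[[leaf]][[nm]][i] <- p[i] + eps
        lp <- lossfun(m2)
        m2$params[[leaf]][[nm]][i] <- p[i] - eps
        lm <- lossfun(m2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(gr[[leaf]][[nm]][i], num, tolerance = 1e-3)
      }
    }
  }
})

test_that("channel attention weights are (0,1), equal under symmetry", {
  set.seed(7)
  par <- deepdel:::cbam_init(6L, 2L, 3L)
  s0 <- channel_attention(array(0, c(6, 10, 2)), par)
  expect_equal(dim(s0), c(6L, 2L))
  expect_true(all(abs(s0 - s0[1, 1]) < 1e-12))   # identical statistics
  s <- channel_attention(array(rnorm(6 * 10 * 3), c(6, 10, 3)), par)
  expect_true(all(s > 0 & s < 1))
})

test_that("spatial attention is a per-position map in (0,1)", {
  set.seed(8)
  par <- deepdel:::cbam_init(6L, 2L, 3L)
  p0 <- spatial_attention(array(0, c(6, 12, 2)), par, 3L)
  expect_equal(dim(p0), c(12L, 2L))
  expect_true(all(abs(p0 - p0[1, 1]) < 1e-12))   # uniform for constant input
  p <- spatial_attention(array(rnorm(6 * 12), c(6, 12, 1)), par, 3L)
  expect_true(all(p > 0 & p < 1))
})

test_that("cbam preserves shape, gates positives, matches two-step eval", {
  set.seed(9)
  for (shape in list(c(4L, 10L, 1L), c(6L, 7L, 3L), c(1L, 5L, 2L))) {
    par <- deepdel:::cbam_init(shape[1], 2L, 3L)
    x <- array(abs(rnorm(prod(shape))) + 0.1, shape)
    y <- cbam(x, par, 3L)
    expect_equal(dim(y), shape)
    expect_true(all(y > 0 & y < x))              # two sub-unit gates
    expect_equal(cbam(array(0, shape), par, 3L), array(0, shape))
    # literal two-step evaluation: x' = Channel(x)*x, x'' = Spatial(x')*x'
    s <- channel_attention(x, par)
    xp <- x * aperm(array(s, c(shape[1], shape[3], shape[2])), c(1, 3, 2))
    pm <- spatial_attention(xp, par, 3L)
    xpp <- xp * aperm(array(pm, c(shape[2], shape[3], shape[1])), c(3, 1, 2))
    expect_equal(y, xpp)
  }
})

test_that("deletion forward is deterministic, bounded, order-sensitive", {
  set.seed(12)
  cfg <- tiny_cfg()
  model <- init_model(cfg, "deletion")
  x <- array(rnorm(9 * 8 * 3 * 2), c(9, 8, 3, 2))
  p1 <- deletion_forward(model, x)$probs
  p2 <- deletion_forward(model, x)$probs
  expect_identical(p1, p2)                       # eval mode, no dropout
  expect_true(all(p1 >= 0 & p1 <= 1))
  # recurrence couples positions: perturbing tile 1 changes output at tile 3
  x2 <- x
  x2[, , 1, 1] <- x2[, , 1, 1] + 5
  p3 <- deletion_forward(model, x2)$probs
  expect_gt(abs(p3[3, 1] - p1[3, 1]), 0)
  expect_error(deletion_forward(model, array(0, c(9, 16, 3, 2))), "9 x 8")
})

test_that("training separates a well-separated fixture and is seeded", {
  set.seed(21)
  T_ <- 25L; B <- 8L                             # 200 tiles, balanced signal
  lab <- matrix(rep(c(0L, 1L), length.out = T_ * B), T_, B)
  xs <- array(rnorm(9 * 200 * T_ * B, 0, 0.3), c(9, 200, T_, B))
  for (b in seq_len(B)) for (t in seq_len(T_)) if (lab[t, b] == 1) {
    xs[2, 60:140, t, b] <- xs[2, 60:140, t, b] + 2
    xs[1, 60:140, t, b] <- xs[1, 60:140, t, b] - 1.5
  }
  cfg <- model_config(epochs = 8L, batch_size = 4L, seed = 31L)
  m <- train_deletion_model(xs, lab, cfg)
  expect_gte(tail(m$history$epochs$accuracy, 1), 0.95)
  # balanced classes at random init: BCE starts near ln 2
  expect_lt(abs(m$history$initial_loss - log(2)), 0.2)
  expect_true(all(diff(m$history$epochs$loss) < 0.05))  # loss decreases
})

test_that("initial BCE equals ln 2 exactly for zero input, balanced labels", {
  cfg <- tiny_cfg(epochs = 1L)
  x <- array(0, c(9, 8, 3, 2))
  lab <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L), 3, 2)
  m <- train_deletion_model(x, lab, cfg)
  # zero input propagates to a zero logit, so every p = 0.5 at init
  expect_equal(m$history$initial_loss, log(2), tolerance = 1e-9)
})

test_that("identical seeds give identical loss curves", {
  set.seed(99)
  cfg <- tiny_cfg(epochs = 3L, batch_size = 2L)
  x <- array(rnorm(9 * 8 * 3 * 6), c(9, 8, 3, 6))
  lab <- matrix(rbinom(18, 1, 0.5), 3, 6)
  lab[1, 1] <- 0L; lab[2, 1] <- 1L
  m1 <- train_deletion_model(x, lab, cfg)
  m2 <- train_deletion_model(x, lab, cfg)
  expect_identical(m1$history$epochs$loss, m2$history$epochs$loss)
  expect_identical(m1$params, m2$params)
})

test_that("single-class training input is refused", {
  cfg <- tiny_cfg(epochs = 1L)
  x <- array(rnorm(9 * 8 * 3 * 2), c(9, 8, 3, 2))
  expect_error(train_deletion_model(x, matrix(1L, 3, 2), cfg),
               "single class")
  expect_error(train_genotype_model(array(rnorm(9 * 8 * 4), c(9, 8, 4)),
                                    rep(0L, 4), cfg), "single class")
})

test_that("genotype network learns het vs hom dosage and is deterministic", {
  set.seed(22)
  N <- 120L
  lab <- rep(c(0L, 1L), length.out = N)
  x <- array(rnorm(9 * 200 * N, 0, 0.3), c(9, 200, N))
  for (i in seq_len(N)) {                        # hom: full-dosage signal
    amp <- if (lab[i] == 1) 2.5 else 1
    x[2, 50:150, i] <- x[2, 50:150, i] + amp
  }
  cfg <- model_config(epochs = 10L, batch_size = 4L, seed = 5L)
  m <- train_genotype_model(x, lab, cfg)
  expect_gte(tail(m$history$epochs$accuracy, 1), 0.9)
  p1 <- genotype_probability(m, x[, , 1:5])
  expect_identical(p1, genotype_probability(m, x[, , 1:5]))
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("checkpoints round-trip through disk", {
  set.seed(30)
  cfg <- tiny_cfg()
  m <- init_model(cfg, "deletion")
  x <- array(rnorm(9 * 8 * 3 * 2), c(9, 8, 3, 2))
  p <- tempfile()
  save_model(m, p)
  m2 <- load_model(p)
  expect_equal(m2$params, m$params)
  expect_identical(deletion_forward(m2, x)$probs,
                   deletion_forward(m, x)$probs)
})
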