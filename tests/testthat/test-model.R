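test_that("FiLM modulation is the elementwise affine map", {
  film_modulate <- function(h, gamma, beta) {
    if (length(h) != length(gamma) || length(h) != length(beta))
      stop("length mismatch")
    gamma * h + beta
  }
  h <- c(1, 2)
  expect_identical(film_modulate(h, c(1, 1), c(0, 0)), h)
  expect_identical(film_modulate(h, c(0, 0), c(0.3, -1)), c(0.3, -1))
  expect_identical(film_modulate(h, c(2, -1), c(0.5, 0)), c(2.5, -2))
})

test_that("initialization is seed-deterministic and variant wiring is structural", {
  cfg <- toy_config("film")
  s1 <- init_model(cfg, seed = 5)
  s2 <- init_model(cfg, seed = 5)
  expect_identical(s1$params, s2$params)
  expect_false(identical(s1$params, init_model(cfg, seed = 6)$params))
  # film with 2 layers: generator emits 2 (gamma, beta) head pairs
  expect_true(all(c("gamW1", "betW1", "gamW2", "betW2") %in% names(s1$params)))
  # concatenation: no generator, no compound encoder
  sc <- init_model(toy_config("concatenation"), seed = 5)
  expect_false(any(grepl("^gamW|^betW|^ec_", names(sc$params))))
  # scale has no beta heads, shift no gamma heads
  expect_false(any(grepl("^betW", names(init_model(toy_config("scale"), 1)$params))))
  expect_false(any(grepl("^gamW", names(init_model(toy_config("shift"), 1)$params))))
  expect_error(model_config("film", n_genes = 0), class = "filmsens_config_error")
  expect_error(model_config("film", n_genes = 5, g = -1),
               class = "filmsens_config_error")
})

test_that("a hand-built toy state reproduces manual forward arithmetic", {
  # 2 genes, 1 FiLM layer, g = 2, c = 2, trunk width 2, no BN/dropout,
  # all weights set to known constants
  cfg <- model_config("film", n_genes = 2, g = 2, c_width = 2, n_film = 1,
                      trunk = 2, dropout = 0, batchnorm = FALSE)
  st <- init_model(cfg, seed = 1)
  p <- st$params
  p$gate <- c(1, 1)
  p$ex_W <- matrix(c(1, 0, 0, 1), 2); p$ex_b <- c(0, 0)
  p$ec_W <- matrix(0, 513, 2); p$ec_W[513, ] <- c(1, 0.5); p$ec_b <- c(0, 0)
  p$gamW1 <- matrix(c(0.1, 0, 0, 0), 2); p$gamb1 <- c(1, 1)
  p$betW1 <- matrix(0, 2, 2); p$betb1 <- c(0, 0.2)
  p$blk1_W <- matrix(c(1, 1, 0, 1), 2); p$blk1_b <- c(0, 0)
  p$t1_W <- matrix(c(1, 0, 1, 1), 2); p$t1_b <- c(0, 0)
  p$out_W <- matrix(c(1, 2), 2); p$out_b <- 0.5
  st$params <- p
  x <- c(0.5, -0.2)
  u <- c(rep(0, 512), 2)                     # concentration 2
  # hand propagation:
  h <- pmax(x, 0)                            # ex: identity W, relu -> (0.5, 0)
  ce <- pmax(c(2 * 1, 2 * 0.5), 0)           # (2, 1)
  gam <- c(1 + 0.1 * 2, 1)                   # (1.2, 1)
  bet <- c(0, 0.2)
  a <- gam * h + bet                         # (0.6, 0.2)
  blk <- pmax(c(a[1] + a[2], a[2]), 0)       # (0.8, 0.2)
  t1 <- pmax(c(blk[1], blk[1] + blk[2]), 0)  # (0.8, 1.0)
  y_hand <- t1[1] * 1 + t1[2] * 2 + 0.5      # 3.3
  expect_equal(forward_viability(st, x, u), y_hand, tolerance = 1e-12)
})

test_that("identity conditioning reduces every variant to the unconditioned trunk", {
  inp <- toy_inputs()
  for (variant in c("film", "scale", "shift")) {
    cfg <- toy_config(variant, batchnorm = TRUE)
    st <- init_model(cfg, seed = 3)
    clamped <- filmsens:::model_forward(st, inp$X, inp$U, mode = "eval",
                                        clamp_identity = TRUE)$y
    # zeroing the generator heads is the structural identity conditioning
    st0 <- st
    for (nm in grep("^gamW|^betW|^betb", names(st0$params), value = TRUE))
      st0$params[[nm]][] <- 0
    for (nm in grep("^gamb", names(st0$params), value = TRUE))
      st0$params[[nm]][] <- 1
    manual <- filmsens:::model_forward(st0, inp$X, inp$U, mode = "eval")$y
    expect_equal(clamped, manual, tolerance = 1e-12)
  }
})

test_that("forward pass is deterministic in eval mode and concentration-sensitive", {
  cfg <- toy_config("film", batchnorm = TRUE, dropout = 0.2)
  st <- init_model(cfg, seed = 8)
  inp <- toy_inputs()
  y1 <- forward_viability(st, inp$X, inp$U)
  y2 <- forward_viability(st, inp$X, inp$U)
  expect_identical(y1, y2)
  # same fingerprint, different concentration -> different prediction
  u1 <- inp$U[1, ]; u2 <- u1; u2[513] <- u1[513] * 100
  expect_false(isTRUE(all.equal(forward_viability(st, inp$X[1, ], u1),
                                forward_viability(st, inp$X[1, ], u2))))
  expect_error(forward_viability(st, inp$X[, -1], inp$U),
               class = "filmsens_shape_error")
  expect_error(forward_viability(st, inp$X, inp$U[, -1]),
               class = "filmsens_shape_error")
})

test_that("conditioning parameters are extractable and respect variant constraints", {
  inp <- toy_inputs()
  u <- inp$U[1, ]
  st <- init_model(toy_config("film"), seed = 2)
  cp1 <- extract_conditioning(st, u)
  cp2 <- extract_conditioning(st, u)
  expect_identical(cp1, cp2)
  expect_length(cp1, 2L)
  expect_length(cp1[[1]]$gamma, 5L)
  ssc <- extract_conditioning(init_model(toy_config("scale"), 2), u)
  expect_true(all(vapply(ssc, function(l) all(l$beta == 0), TRUE)))
  ssh <- extract_conditioning(init_model(toy_config("shift"), 2), u)
  expect_true(all(vapply(ssh, function(l) all(l$gamma == 1), TRUE)))
  expect_error(extract_conditioning(init_model(toy_config("concatenation"), 2), u),
               class = "filmsens_unsupported_variant_error")
})

test_that("variant constraints survive training", {
  sim <- tiny_sim()
  des <- benchmark_design(sim$dataset)
  for (variant in c("scale", "shift")) {
    fit <- train_benchmark(sim$dataset, variant = variant, seed = 1,
                           options = list(epochs = 2, batch = 128))
    cp <- extract_conditioning(fit$state, des$train_set$U[1, ])
    if (variant == "scale")
      expect_true(all(vapply(cp, function(l) all(l$beta == 0), TRUE)))
    else
      expect_true(all(vapply(cp, function(l) all(l$gamma == 1), TRUE)))
  }
})

test_that("model states serialize and reload bit-exactly", {
  dir <- withr::local_tempdir()
  st <- init_model(toy_config("film", batchnorm = TRUE), seed = 4)
  inp <- toy_inputs()
  path <- file.path(dir, "m.rds")
  save_model(st, path)
  st2 <- load_model(path)
  expect_identical(forward_viability(st2, inp$X, inp$U),
                   forward_viability(st, inp$X, inp$U))
})

test_that("backpropagated gradients match finite differences", {
  for (variant in c("film", "concatenation")) {
    for (bn in c(TRUE, FALSE)) {
      cfg <- toy_config(variant, batchnorm = bn)
      st <- init_model(cfg, seed = 42)
      inp <- toy_inputs(n = 6L)
      loss_of <- function(s) {
        fw <- filmsens:::model_forward(s, inp$X, inp$U, mode = "train")
        mean((fw$y - inp$y)^2)
      }
      fw <- filmsens:::model_forward(st, inp$X, inp$U, mode = "train",
                                     keep_cache = TRUE)
      bw <- filmsens:::model_backward(st, fw$cache,
                                      2 * (fw$y - inp$y) / length(inp$y))
      eps <- 1e-5
      set.seed(13)
      for (nm in c("ex_W", "out_W", "gate",
                   if (variant == "film") c("gamW1", "betb2", "ec_W"))) {
        i <- sample(length(st$params[[nm]]), 1L)
        sp <- st; sp$params[[nm]][i] <- st$params[[nm]][i] + eps
        sm <- st; sm$params[[nm]][i] <- st$params[[nm]][i] - eps
        fd <- (loss_of(sp) - loss_of(sm)) / (2 * eps)
        expect_equal(unname(bw$grads[[nm]][i]), fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("the prediction is differentiable in the concentration input", {
  sim <- tiny_sim()
  fit <- train_benchmark(sim$dataset, variant = "film", seed = 2,
                         options = list(epochs = 3, batch = 128))
  des <- fit$design
  fw <- filmsens:::model_forward(fit$state, des$val_set$X[1:8, ],
                                 des$val_set$U[1:8, ], mode = "eval",
                                 keep_cache = TRUE)
  bw <- filmsens:::model_backward(fit$state, fw$cache, rep(1, 8))
  expect_true(any(bw$dU[, 513] != 0))
})

test_that("the learned shift parameters encode concentration", {
  # PC1 of beta across a compound's concentrations tracks the dose
  rs <- vapply(1:3, function(sd) {
    sim <- tiny_sim()
    fit <- train_benchmark(sim$dataset, variant = "film", seed = sd,
                           options = list(epochs = 8, batch = 256))
    conc <- default_grid()
    fp <- fit$design$fpmat[1, ]
    betas <- t(vapply(conc, function(cc) {
      u <- make_compound_features(fp, cc, transform = "log10uM")
      extract_conditioning(fit$state, u)[[1]]$beta
    }, numeric(fit$state$config$g)))
    cor(pca_project(betas, 1)$scores[, 1], log10(conc))
  }, numeric(1))
  expect_gt(median(abs(rs)), 0.5)
})
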