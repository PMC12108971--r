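test_that("built architectures have the intended input and branch widths", {
  ts <- build_model(model_spec("tsfnn"))
  expect_identical(dim(ts$branches$num$layers[[1]]$W), c(7L, 16L))
  expect_identical(dim(ts$branches$cat$layers[[1]]$W), c(20L, 16L))
  expect_identical(dim(ts$head[[1]]$W), c(32L, 16L))
  expect_identical(dim(ts$head[[length(ts$head)]]$W), c(16L, 1L))

  ann <- build_model(model_spec("ann"))
  expect_identical(dim(ann$branches$main$layers[[1]]$W), c(17L, 32L))

  nn <- build_model(model_spec("nnn"))
  expect_identical(dim(nn$branches$num$layers[[1]]$W), c(7L, 16L))

  cn_raw <- build_model(model_spec("cnn", use_embedding = FALSE))
  expect_identical(dim(cn_raw$branches$cat$layers[[1]]$W), c(10L, 16L))

  tw <- build_model(model_spec("two_way"))
  expect_identical(dim(tw$head[[1]]$W), c(32L, 1L))
})

test_that("two-way and fusion defaults use a similar number of hidden nodes", {
  hidden_nodes <- function(net) {
    stacks <- c(lapply(net$branches, `[[`, "layers"), list(net$head))
    dense_outs <- unlist(lapply(stacks, function(ls) {
      vapply(Filter(function(l) l$type == "dense", ls),
             function(l) ncol(l$W), integer(1))
    }))
    sum(dense_outs[dense_outs > 1]) # hidden widths, excluding the output node
  }
  tw <- hidden_nodes(build_model(model_spec("two_way")))
  ts <- hidden_nodes(build_model(model_spec("tsfnn")))
  expect_true(max(tw, ts) / min(tw, ts) <= 1.6)
})

test_that("weight initialization is reproducible from the seed", {
  a <- build_model(model_spec("tsfnn", seed = 7L))
  b <- build_model(model_spec("tsfnn", seed = 7L))
  expect_identical(a, b)
  c <- build_model(model_spec("tsfnn", seed = 8L))
  expect_false(identical(a, c))
})

test_that("the forward pass matches hand-computed arithmetic on a 2-2-1 net", {
  net <- list(
    branches = list(main = list(input = "all", layers = list(
      list(type = "dense",
           W = matrix(c(0.5, -1, 0.25, 2), 2, 2), b = matrix(c(0.1, -0.2), 1)),
      list(type = "activation", fun = "relu")
    ))),
    head = list(list(type = "dense", W = matrix(c(1, -0.5), 2, 1),
                     b = matrix(0.3, 1, 1)))
  )
  x <- matrix(c(0.2, 0.8), 1, 2)
  # by hand: h1 = relu(0.2*0.5 + 0.8*(-1) + 0.1) = relu(-0.6) = 0
  #          h2 = relu(0.2*0.25 + 0.8*2 - 0.2) = 1.45
  #          logit = 0*1 + 1.45*(-0.5) + 0.3 = -0.425
  out <- tsfnn:::net_forward(net, list(all = x), training = FALSE)
  expect_equal(out$logit, -0.425, tolerance = 1e-12)
  expect_equal(tsfnn:::sigmoid(out$logit), 1 / (1 + exp(0.425)), tolerance = 1e-12)
})

test_that("batch normalization standardizes a mini-batch before scale/shift", {
  set.seed(42)
  x <- matrix(rnorm(64 * 5, mean = 3, sd = 2), 64, 5)
  bn <- tsfnn:::make_batchnorm(5)
  out <- tsfnn:::layer_forward(bn, x, training = TRUE)$out
  expect_true(all(abs(colMeans(out)) < 1e-10))
  # unit variance up to the stabilizing epsilon in the denominator
  expect_true(all(abs(colMeans(out^2) - 1) < 1e-4))
})

test_that("numeric gradients confirm backpropagation through all layer types", {
  set.seed(1)
  layers <- list(
    tsfnn:::make_dense(4, 3),
    tsfnn:::make_batchnorm(3),
    tsfnn:::make_activation("relu"),
    tsfnn:::make_dense(3, 1)
  )
  x <- matrix(rnorm(6 * 4), 6, 4)
  y <- c(1, 0, 1, 1, 0, 0)
  loss_fn <- function(ls) {
    p <- tsfnn:::sigmoid(tsfnn:::seq_forward(ls, x, training = TRUE)$out[, 1])
    tsfnn:::bce_loss(p, y)
  }
  fwd <- tsfnn:::seq_forward(layers, x, training = TRUE)
  p <- tsfnn:::sigmoid(fwd$out[, 1])
  analytic <- tsfnn:::seq_backward(fwd$layers, fwd$caches,
                                   matrix((p - y) / length(y), ncol = 1))$grads
  eps <- 1e-6
  for (li in c(1, 2, 4)) {
    for (nm in tsfnn:::trainable_names(layers[[li]])) {
      g <- analytic[[li]][[nm]]
      for (k in sample(length(g), min(4, length(g)))) {
        up <- layers; up[[li]][[nm]][k] <- up[[li]][[nm]][k] + eps
        dn <- layers; dn[[li]][[nm]][k] <- dn[[li]][[nm]][k] - eps
        numeric_g <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
        expect_equal(g[k], numeric_g, tolerance = 1e-4)
      }
    }
  }
})

test_that("training separates a linearly separable fixture", {
  d <- make_separable_fixture(20L, seed = 2L)
  # oracle: a logistic fit on the decisive item also separates the classes
  glm_fit <- suppressWarnings(
    glm(fractured ~ canal_wall_thickness, family = binomial(), data = d)
  )
  glm_acc <- mean(as.integer(predict(glm_fit, type = "response") >= 0.5) == d$fractured)
  expect_identical(glm_acc, 1)

  m <- train_model(d, quick_spec("tsfnn", epochs = 120L, seed = 2L))
  acc <- mean(predict(m, d)$.pred == d$fractured)
  expect_identical(acc, 1)
  expect_lte(m$loss[length(m$loss)], m$loss[1])
})

test_that("training refuses single-class data and logs a loss history", {
  d <- tiny_dataset(8L, 4L)
  expect_error(train_model(d[d$fractured == 1, ], quick_spec()), "both classes")
  m <- train_model(d, quick_spec(epochs = 12L))
  expect_length(m$loss, 12L)
  expect_true(all(is.finite(m$loss)))
  expect_identical(nrow(tidy(m)), 12L)
  expect_identical(glance(m)$architecture, "tsfnn")
})

test_that("toggling batch normalization changes the learned model", {
  d <- tiny_dataset(10L, 6L)
  on <- train_model(d, quick_spec("tsfnn", seed = 4L))
  off <- train_model(d, quick_spec("tsfnn", seed = 4L, use_batch_norm = FALSE))
  expect_false(identical(on$net, off$net))
  types_on <- vapply(on$net$branches$num$layers, `[[`, character(1), "type")
  expect_true("batchnorm" %in% types_on)
  types_off <- vapply(off$net$branches$num$layers, `[[`, character(1), "type")
  expect_false("batchnorm" %in% types_off)
})

test_that("prediction is a deterministic probability in [0, 1] with the tie rule", {
  d <- tiny_dataset(10L, 6L)
  m <- train_model(d, quick_spec("two_way", seed = 6L))
  p1 <- predict(m, d)
  p2 <- predict(m, d)
  expect_identical(p1, p2)
  expect_true(all(p1$.prob >= 0 & p1$.prob <= 1))
  expect_identical(p1$.pred, as.integer(p1$.prob >= 0.5))

  # zeroing the output node forces probability exactly 0.5 -> positive call
  m0 <- train_model(d, quick_spec("nnn", seed = 6L))
  last <- length(m0$net$head)
  m0$net$head[[last]]$W[] <- 0
  m0$net$head[[last]]$b[] <- 0
  tie <- predict(m0, d[1, ])
  expect_identical(tie$.prob, 0.5)
  expect_identical(tie$.pred, 1L)
})

test_that("a fine-tuned embedding trains and predicts end to end", {
  d <- tiny_dataset(12L, 8L)
  m <- train_model(d, quick_spec("tsfnn", seed = 9L, fine_tune_embedding = TRUE))
  p <- predict(m, d)
  expect_true(all(is.finite(p$.prob)))
  # the embedding weights moved away from their pre-trained values
  pre_W <- m$embedding$layers[[1]]$W
  tuned_W <- m$net$branches$cat$layers[[1]]$W
  expect_false(identical(pre_W, tuned_W))
})

test_that("trained models survive a JSON round trip", {
  d <- tiny_dataset(10L, 6L)
  m <- train_model(d, quick_spec("tsfnn", seed = 12L))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(m2$spec$architecture, "tsfnn")
  d2 <- tiny_dataset(5L, 3L, seed = 77L)
  expect_equal(predict(m2, d2)$.prob, predict(m, d2)$.prob, tolerance = 1e-12)
  expect_identical(predict(m2, d2)$.pred, predict(m, d2)$.pred)
  expect_error(read_model(study_fixture_path()))
})
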