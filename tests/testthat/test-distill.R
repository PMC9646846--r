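teacher_records <- function(stims, K = 3, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(stims, function(v) {
    logits_records(model_id = c("m1", "m2"), subject_id = c("a", "b"),
                   stimulus_id = rep(v, 2),
                   logits_matrix = matrix(rnorm(2 * K), 2))
  }))
}

test_that("soft labels are the temperature softmax of the consensus logits", {
  r <- logits_records("m", "a", "V1",
                      matrix(c(log(4), 0), 1))
  # T = 1, one subject: the subject's own softmax
  s1 <- make_teacher_soft_labels(r, "V1", temperature = 1)
  expect_equal(s1$soft[1, ], softmax(c(log(4), 0)))
  # closed form at T = 2: exp(log(4)/2) = 2 -> (2/3, 1/3)
  s2 <- make_teacher_soft_labels(r, "V1", temperature = 2)
  expect_equal(s2$soft[1, ], c(2 / 3, 1 / 3), tolerance = 1e-12)
  # large T flattens toward uniform
  s500 <- make_teacher_soft_labels(r, "V1", temperature = 500)
  expect_lt(max(abs(s500$soft - 0.5)), 0.01)
  expect_error(make_teacher_soft_labels(r, c("V1", "V9")), "missing|no teacher")
})

test_that("soft label rows are probability vectors over ten classes", {
  r <- do.call(rbind, lapply(sprintf("V%d", 1:4), function(v)
    logits_records("m", c("a", "b", "c"), rep(v, 3),
                   matrix(rnorm(30), 3))))
  sl <- make_teacher_soft_labels(r, sprintf("V%d", 1:4), temperature = 5)
  expect_equal(rowSums(sl$soft), rep(1, 4))
  expect_true(all(sl$soft > 0))
  big <- make_teacher_soft_labels(r, sprintf("V%d", 1:4), temperature = 500)
  expect_lt(max(abs(big$soft - 0.1)), 0.01)
})

test_that("the distillation objective interpolates the two pure losses", {
  set.seed(20)
  z <- matrix(rnorm(12 * 4), 12)
  y <- sample(0:3, 12, replace = TRUE)
  s <- softmax(matrix(rnorm(12 * 4), 12))
  l0 <- distill_loss(z, y, s, 0)
  l1 <- distill_loss(z, y, s, 1)
  p <- softmax(z)
  # lambda = 0: plain cross-entropy on hard labels
  expect_equal(l0, -mean(log(p[cbind(1:12, y + 1)])), tolerance = 1e-12)
  # lambda = 1: hard labels are irrelevant
  expect_equal(distill_loss(z, sample(0:3, 12, replace = TRUE), s, 1), l1)
  # linear (hence convex-combination bounded) in lambda
  for (lam in c(0.25, 0.5, 0.9)) {
    l <- distill_loss(z, y, s, lam)
    expect_equal(l, (1 - lam) * l0 + lam * l1, tolerance = 1e-12)
    expect_gte(l, min(l0, l1) - 1e-12)
    expect_lte(l, max(l0, l1) + 1e-12)
  }
  # one-hot soft labels collapse both terms to the same loss
  onehot <- diag(4)[y + 1, ]
  for (lam in c(0, 0.3, 1)) {
    expect_equal(distill_loss(z, y, onehot, lam), l0, tolerance = 1e-12)
  }
  expect_error(distill_loss(z, y, s, 1.2), "lambda")
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  z <- matrix(rnorm(5 * 3), 5)
  y <- c(0L, 2L, 1L, 0L, 2L)
  s <- softmax(matrix(rnorm(5 * 3), 5))
  for (lam in c(0, 0.4, 1)) {
    g <- distill_loss_grad(z, y, s, lam)
    h <- 1e-6
    num <- matrix(0, 5, 3)
    for (i in 1:5) for (j in 1:3) {
      zp <- z; zp[i, j] <- zp[i, j] + h
      zm <- z; zm[i, j] <- zm[i, j] - h
      num[i, j] <- (distill_loss(zp, y, s, lam) -
                      distill_loss(zm, y, s, lam)) / (2 * h)
    }
    expect_lt(max(abs(g - num)), 1e-5)
  }
})

test_that("lambda = 0 distillation equals plain training with the same seed", {
  set.seed(22)
  x <- matrix(rnorm(40 * 6), 40)
  y <- sample(0:2, 40, replace = TRUE)
  s <- softmax(matrix(rnorm(40 * 3), 40))
  spec <- classifier_spec("linear_student", n_classes = 3, epochs = 30,
                          seed = 5)
  plain <- train_classifier(spec, x, y)
  distilled0 <- distill_student(spec, x, y, s, lambda = 0)
  expect_identical(logits(plain, x), logits(distilled0, x))
  # lambda = 1 ignores the hard labels entirely
  d1a <- distill_student(spec, x, y, s, lambda = 1)
  d1b <- distill_student(spec, x, sample(y), s, lambda = 1)
  expect_identical(logits(d1a, x), logits(d1b, x))
  expect_error(distill_student(spec, x, y, s[1:10, ], 0.5), "misaligned")
})

test_that("a soft_label_set aligns to training rows by stimulus id", {
  stims <- sprintf("V%d", 1:6)
  r <- teacher_records(stims)
  sl <- make_teacher_soft_labels(r, stims, temperature = 2)
  set.seed(23)
  x <- matrix(rnorm(6 * 4), 6)
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  spec <- classifier_spec("linear_student", n_classes = 3, epochs = 10,
                          seed = 1)
  # shuffled presentation order must give the same mixed targets
  ord <- c(3, 1, 6, 2, 5, 4)
  m1 <- distill_student(spec, x[ord, ], y[ord], sl, 0.7,
                        stimulus_ids = stims[ord])
  m2 <- distill_student(spec, x[ord, ], y[ord], sl$soft[ord, ], 0.7)
  expect_identical(logits(m1, x), logits(m2, x))
  expect_error(distill_student(spec, x, y, sl, 0.7), "stimulus_ids")
})

test_that("the grid sweep reports means, spreads and a validation winner", {
  cfg <- small_config(seed = 4)
  w <- generate_world(cfg)
  labels <- stats::setNames(w$stimuli$class_label, w$stimuli$stimulus_id)
  split <- make_split(w$stimuli, seed = 4)
  # a compact synthetic teacher: informative logits on train+val stimuli
  tv <- c(split$train_stimuli, split$val_stimuli)
  set.seed(24)
  recs <- do.call(rbind, lapply(tv, function(v)
    logits_records("t", c("a", "b"), rep(v, 2),
                   matrix(rnorm(2 * cfg$n_classes, sd = 0.5), 2) +
                     rep(2 * (seq_len(cfg$n_classes) - 1 == labels[v]),
                         each = 2))))
  vf <- w$video_features
  rownames(vf) <- w$stimuli$stimulus_id
  res <- run_grid(recs, vf, labels, split,
                  temperatures = c(1, 5), lambdas = c(0.5, 1),
                  n_runs = 2, seed = 9)
  expect_equal(nrow(res$grid), 4)
  expect_true(all(c("val_mean", "val_sd", "test_mean", "test_sd") %in%
                    names(res$grid)))
  expect_equal(res$best$val_mean, max(res$grid$val_mean))
  expect_equal(res$baseline$lambda, 0)
  single <- run_grid(recs, vf, labels, split, temperatures = 1,
                     lambdas = 0.5, n_runs = 1, seed = 9)
  expect_equal(single$grid$test_sd, 0)
})
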