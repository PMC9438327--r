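# Small planted-signal design shared by several forest tests: the label is
# a deterministic threshold rule on one feature among noise.
planted_data <- function(n, n_noise = 5L, seed = 1L, flip = 0) {
  set.seed(seed)
  X <- data.frame(signal = runif(n))
  for (i in seq_len(n_noise)) X[[paste0("noise", i)]] <- rnorm(n)
  w <- as.integer(X$signal > 0.5)
  if (flip > 0) {
    k <- which(runif(n) < flip)
    w[k] <- 1L - w[k]
  }
  list(X = X, w = w)
}

fast_config <- function(n_trees = 60L, ...) {
  forest_config(n_trees = n_trees, min_node_size = 10L,
                bootstrap_size = 100000L,
                baseline_features = character(0), ...)
}

test_that("sample weights invert (label, chromosome) class counts", {
  w1 <- compute_sample_weights(rep(1, 10), rep("chr1", 10))
  expect_equal(w1, rep(0.1, 10))
  lab <- rep(c(1, 0), c(2, 8))
  chr <- rep(c("chr1", "chr2"), c(2, 8))
  w2 <- compute_sample_weights(lab, chr)
  expect_equal(w2, rep(c(0.5, 0.125), c(2, 8)))
  expect_true(all(abs(tapply(w2, paste(lab, chr), sum) - 1) < 1e-12))
  expect_equal(compute_sample_weights(c(0, 1), c("a", "b")), c(1, 1))
})

test_that("weighted accuracy rounds half up and balances classes", {
  expect_equal(weighted_accuracy(c(0.9, 0.1), c(1, 0)), 1)
  # one class fully right, the other fully wrong, balanced weights
  w_hat <- c(rep(0.9, 2), rep(0.9, 8))
  w <- c(rep(1, 2), rep(0, 8))
  wt <- compute_sample_weights(w)
  expect_equal(weighted_accuracy(w_hat, w, wt), 0.5)
  expect_equal(weighted_accuracy(0.5, 1), 1)  # exact 0.5 calls class 1
})

test_that("a planted threshold rule is learned almost perfectly", {
  d <- planted_data(3000L, seed = 21)
  train <- 1:2000; test <- 2001:3000
  fit <- picnc_forest(d$X[train, ], d$w[train], config = fast_config(seed = 2))
  p <- predict(fit, d$X[test, ])
  expect_true(all(p >= 0 & p <= 1))
  acc <- weighted_accuracy(p, d$w[test], compute_sample_weights(d$w[test]))
  expect_gt(acc, 0.95)
  # degenerate labels are rejected
  expect_error(picnc_forest(d$X, rep(1L, nrow(d$X))), "degenerate")
})

test_that("permuted labels yield chance-level accuracy", {
  accs <- vapply(1:5, function(s) {
    d <- planted_data(1200L, seed = 100 + s)
    w_perm <- sample(d$w)
    fit <- picnc_forest(d$X[1:800, ], w_perm[1:800],
                        config = fast_config(seed = s))
    p <- predict(fit, d$X[801:1200, ])
    weighted_accuracy(p, w_perm[801:1200],
                      compute_sample_weights(w_perm[801:1200]))
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("forests are deterministic given the seed", {
  d <- planted_data(600L, seed = 31)
  cfg <- fast_config(n_trees = 20L, seed = 7)
  f1 <- picnc_forest(d$X, d$w, config = cfg)
  f2 <- picnc_forest(d$X, d$w, config = cfg)
  expect_identical(predict(f1, d$X), predict(f2, d$X))
  expect_identical(variable_importance(f1), variable_importance(f2))
})

test_that("probability calibration tracks the balanced positive rate", {
  d <- planted_data(1500L, seed = 41, flip = 0.2)
  fit <- picnc_forest(d$X, d$w, config = fast_config(seed = 3))
  p <- predict(fit, d$X)
  expect_lt(abs(mean(p) - mean(d$w)), 0.05)
})

test_that("corrected importance finds the informative feature and zeroes constants", {
  hits <- vapply(1:6, function(s) {
    d <- planted_data(800L, n_noise = 10L, seed = 200 + s, flip = 0.1)
    fit <- picnc_forest(d$X, d$w,
                        config = fast_config(n_trees = 40L, seed = s))
    imp <- variable_importance(fit)
    names(which.max(imp)) == "signal"
  }, NA)
  expect_gte(sum(hits), 5L)
  # a constant feature can never split
  d <- planted_data(500L, seed = 51)
  d$X$flat <- 1
  fit <- picnc_forest(d$X, d$w, config = fast_config(n_trees = 20L, seed = 1))
  expect_identical(unname(variable_importance(fit)["flat"]), 0)
})

test_that("noise features do not lift validation accuracy materially", {
  deltas <- vapply(1:5, function(s) {
    d <- planted_data(1200L, n_noise = 2L, seed = 300 + s, flip = 0.1)
    train <- 1:800; test <- 801:1200
    wt <- compute_sample_weights(d$w[test])
    cfg <- fast_config(seed = s, p_variables = 1)
    base <- picnc_forest(d$X[train, ], d$w[train], config = cfg)
    a0 <- weighted_accuracy(predict(base, d$X[test, ]), d$w[test], wt)
    Xn <- d$X
    for (i in 1:10) Xn[[paste0("extra", i)]] <- rnorm(1200)
    noisy <- picnc_forest(Xn[train, ], d$w[train], config = cfg)
    a1 <- weighted_accuracy(predict(noisy, Xn[test, ]), d$w[test], wt)
    a1 - a0
  }, 0)
  expect_lt(mean(deltas), 0.03)
})

test_that("a depth-1 single-feature tree reproduces the exhaustive Gini split", {
  set.seed(61)
  n <- 400L
  X <- data.frame(x = runif(n))
  w <- as.integer(X$x > 0.37)
  k <- sample(n, 40L); w[k] <- 1L - w[k]
  cfg <- forest_config(n_trees = 1L, min_node_size = 1L, bootstrap_size = n,
                       baseline_features = character(0), max_depth = 1L,
                       p_variables = 1, bootstrap = FALSE, seed = 5)
  fit <- picnc_forest(X, w, config = cfg)
  p <- predict(fit, X)
  # exhaustive oracle over all midpoint thresholds, maximizing the Gini
  # impurity decrease (the tree's own criterion) on the full sample
  xs <- sort(unique(X$x))
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  gini <- function(v) { p1 <- mean(v); 2 * p1 * (1 - p1) }
  dec <- vapply(cuts, function(cut) {
    L <- w[X$x <= cut]; R <- w[X$x > cut]
    gini(w) - (length(L) * gini(L) + length(R) * gini(R)) / n
  }, 0)
  best <- cuts[which.max(dec)]
  # the tree's two leaves match the oracle partition's class-1 proportions
  oracle_pred <- ifelse(X$x <= best, mean(w[X$x <= best]),
                        mean(w[X$x > best]))
  expect_equal(p, oracle_pred, tolerance = 1e-8)
})

test_that("prediction validates the training schema", {
  d <- planted_data(300L, seed = 71)
  fit <- picnc_forest(d$X, d$w, config = fast_config(n_trees = 5L, seed = 1))
  expect_error(predict(fit, d$X[, -1]), "signal")
  bad <- d$X; bad$noise1[3] <- NA
  expect_error(predict(fit, bad), "missing values")
})

test_that("leave-one-chromosome-out never trains on the scored chromosome", {
  bundle <- small_bundle()
  ann <- bundle$annotations
  w <- label_sites(ann$chrom, ann$pos, bundle$scores)
  cfg <- forest_config(n_trees = 30L, min_node_size = 25L, seed = 9)
  pred <- loco_predict(ann, w, config = cfg)
  expect_identical(nrow(pred), sum(ann$is_snp))
  expect_true(all(pred$w_hat >= 0 & pred$w_hat <= 1))
  folds <- attr(pred, "folds")
  for (k in names(folds)) expect_false(k %in% folds[[k]])
  expect_setequal(paste(pred$chrom, pred$pos, pred$alt),
                  paste(ann$chrom, ann$pos, ann$alt)[ann$is_snp])
  one_chrom <- ann[ann$chrom == "chr1", ]
  expect_error(loco_predict(one_chrom, w[ann$chrom == "chr1"], cfg),
               "at least 2 chromosomes")
})

test_that("identical data per chromosome gives symmetric LOCO predictions", {
  d <- planted_data(300L, seed = 81, flip = 0.1)
  block <- cbind(chrom = NA, pos = 1:300, ref = "A", alt = "C", d$X,
                 is_snp = rep(c(FALSE, TRUE), c(250, 50)))
  ann <- do.call(rbind, lapply(1:3, function(k)
    within(block, chrom <- paste0("chr", k))))
  labels <- rep(d$w, 3)
  labels[ann$is_snp] <- NA
  cfg <- forest_config(n_trees = 40L, min_node_size = 10L,
                       baseline_features = character(0), seed = 11)
  pred <- loco_predict(ann, labels, config = cfg)
  means <- tapply(pred$w_hat, pred$chrom, mean)
  expect_lt(max(means) - min(means), 0.1)
})

test_that("hyperparameter tuning honours the parity scheme and tie-breaks", {
  d <- planted_data(600L, seed = 91, flip = 0.15)
  chrom <- paste0("chr", rep(1:4, length.out = 600L))
  base <- forest_config(min_node_size = 10L, baseline_features = character(0))
  one <- tune_hyperparameters(d$X, d$w, chrom, k = "chr1",
                              grid_trees = 25L, grid_p = 1 / 2,
                              config = base)
  expect_identical(one$n_trees, 25L)
  expect_equal(one$p_variables, 1 / 2)
  grid <- attr(one, "grid")
  expect_identical(nrow(grid), 1L)
  two <- tune_hyperparameters(d$X, d$w, chrom, k = "chr1",
                              grid_trees = c(10L, 30L), grid_p = 1 / 2,
                              config = base)
  g2 <- attr(two, "grid")
  expect_identical(two$n_trees,
                   g2$n_trees[order(-g2$accuracy, -g2$n_trees)][1])
  expect_error(tune_hyperparameters(d$X, d$w, chrom, k = "chr1",
                                    grid_trees = integer(0)),
               "empty tuning grid")
  expect_error(tune_hyperparameters(d$X, d$w, rep("chr1", 600L), "chr1"),
               "at least 3 chromosomes")
})

test_that("per-split sampling mode trains and predicts through the same surface", {
  d <- planted_data(800L, seed = 95)
  cfg <- forest_config(n_trees = 30L, min_node_size = 10L,
                       bootstrap_size = 800L,
                       baseline_features = character(0),
                       sampling = "per_split", seed = 2)
  fit <- picnc_forest(d$X[1:600, ], d$w[1:600], config = cfg)
  p <- predict(fit, d$X[601:800, ])
  acc <- weighted_accuracy(p, d$w[601:800],
                           compute_sample_weights(d$w[601:800]))
  expect_gt(acc, 0.9)
})
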