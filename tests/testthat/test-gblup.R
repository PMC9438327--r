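# Simulate a PSD kernel plus phenotypes with known variance components.
sim_gblup_data <- function(n, m, s_u = 1, s_cds = 0.5, s_e = 1, seed = 1L) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 2L, 0.3), n, m)
  G <- grm(X)
  m_cds <- max(10L, m %/% 5L)
  X_cds <- X[, seq_len(m_cds), drop = FALSE]
  w <- runif(m_cds)
  G_cds <- weighted_grm(X_cds, w)
  Q <- cbind(1, rnorm(n))
  draw <- function(K, s2) {
    ev <- eigen(K, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    drop(ev$vectors %*% (sqrt(ev$values * s2) * rnorm(n)))
  }
  y <- drop(Q %*% c(1, 0.5)) + draw(G, s_u) + draw(G_cds, s_cds) +
    rnorm(n, 0, sqrt(s_e))
  list(y = y, Q = Q, G = G, G_cds = G_cds, X = X, X_cds = X_cds, w = w)
}

test_that("the relationship matrix matches the printed formula", {
  # two individuals, one SNP, dosages 0 and 2 at p = 0.5:
  # centered dosages (-1, +1), denominator 2 * 0.5 * 0.5
  G <- grm(matrix(c(0, 2), 2, 1), p = 0.5)
  expect_equal(G, matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # with p = 0.5 everywhere the matrix is proportional to ZZ'
  set.seed(3)
  X <- matrix(rbinom(40, 2, 0.5), 4, 10)
  Z <- X - 1
  expect_equal(grm(X, p = rep(0.5, 10)), tcrossprod(Z) / 5,
               tolerance = 1e-12)
  # brute-force double-loop oracle on a random fixture
  set.seed(4)
  X <- matrix(rbinom(20 * 50, 2L, runif(50, 0.1, 0.9)), 20, 50,
              byrow = TRUE)
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  Xk <- X[, keep]; pk <- p[keep]
  oracle <- matrix(0, 20, 20)
  den <- sum(2 * pk * (1 - pk))
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- sum((Xk[i, ] - 2 * pk) * (Xk[j, ] - 2 * pk)) / den
  expect_lt(max(abs(grm(X) - oracle)), 1e-10)
  expect_error(grm(matrix(2, 5, 3)), "monomorphic")
})

test_that("the weighted kernel matches the printed formula and its reductions", {
  set.seed(5)
  X <- matrix(rbinom(15 * 30, 2L, 0.4), 15, 30)
  # uniform weights reduce to XX'/m
  expect_equal(weighted_grm(X, rep(1, 30)), tcrossprod(X) / 30,
               tolerance = 1e-12)
  # single nonzero weight: rank at most 1
  w1 <- c(1, rep(0, 29))
  expect_lte(qr(weighted_grm(X, w1))$rank, 1L)
  # brute-force triple-loop oracle
  w <- runif(30)
  oracle <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15)
    oracle[i, j] <- sum(w * X[i, ] * X[j, ]) / sum(w)
  expect_lt(max(abs(weighted_grm(X, w) - oracle)), 1e-10)
  # scale invariance from the sum(w) normalization
  expect_equal(weighted_grm(X, w), weighted_grm(X, 7.3 * w),
               tolerance = 1e-12)
  expect_error(weighted_grm(X, rep(0, 30)), "empty kernel")
  ev <- eigen(weighted_grm(X, w), symmetric = TRUE, only.values = TRUE)
  expect_gt(min(ev$values), -1e-8)
})

test_that("percentile truncation uses the nearest-rank strict convention", {
  set.seed(6)
  w <- runif(1000)
  t90 <- truncate_weights(w, 90)
  expect_identical(attr(t90, "retained"), 1000L - 900L)
  expect_identical(sum(t90 > 0), 100L)
  # untouched weights keep their values; the rest are exactly zero
  expect_true(all(t90[t90 > 0] %in% w))
  expect_identical(as.numeric(truncate_weights(w, 0)), w)
  expect_error(truncate_weights(w, 100), "q < 100")
})

test_that("REML drives variances to the floor when y is exactly fixed effects", {
  set.seed(7)
  n <- 40L
  X <- matrix(rbinom(n * 60, 2L, 0.4), n, 60)
  G <- grm(X)
  Q <- cbind(1, rnorm(n))
  y <- drop(Q %*% c(2, 1))
  fit <- picnc_gblup(y, Q, G)
  expect_lt(fit$sigma2["u"], 1e-6)
  expect_equal(unname(coef(fit)), c(2, 1), tolerance = 1e-4)
})

test_that("REML recovers simulated variance components", {
  # light in-suite version of the recovery study (deeper run in the
  # acceptance suite): moderate n, a few seeds, generous bound
  est <- t(vapply(1:4, function(s) {
    d <- sim_gblup_data(250L, 400L, seed = 500 + s)
    fit <- picnc_gblup(d$y, d$Q, d$G, d$G_cds)
    fit$sigma2
  }, c(u = 0, u_cds = 0, e = 0)))
  m <- colMeans(est)
  expect_lt(abs(m["u"] - 1), 0.35)
  expect_lt(abs(m["u_cds"] - 0.5), 0.25)
  expect_lt(abs(m["e"] - 1), 0.35)
})

test_that("the restricted likelihood does not decrease over the fit", {
  d <- sim_gblup_data(120L, 200L, seed = 77)
  fit <- picnc_gblup(d$y, d$Q, d$G, d$G_cds)
  expect_gte(fit$loglik, fit$trace[1] - 1e-6)
  expect_true(all(is.finite(fit$trace)))
})

test_that("single-kernel GBLUP equals ridge regression with matched shrinkage", {
  set.seed(8)
  n <- 50L; m <- 100L
  X <- matrix(rbinom(n * m, 2L, 0.35), n, m)
  p <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * p)
  den <- sum(2 * p * (1 - p))
  G <- tcrossprod(Z) / den
  Q <- matrix(1, n, 1)
  y <- drop(Z %*% rnorm(m, 0, 0.3)) + rnorm(n)
  fit <- picnc_gblup(y, Q, G)
  # ridge oracle: marker effects with lambda = den * s_e / s_u, evaluated
  # at the REML variance ratio and the GBLUP intercept
  lambda <- den * fit$sigma2["e"] / fit$sigma2["u"]
  a_hat <- solve(crossprod(Z) + diag(lambda, m),
                 crossprod(Z, y - drop(Q %*% fit$alpha)))
  u_ridge <- drop(Z %*% a_hat)
  expect_gt(cor(fit$u, u_ridge), 0.999)
})

test_that("kernel and design validation fails loudly", {
  d <- sim_gblup_data(30L, 60L, seed = 9)
  bad <- d$G
  bad[1, 2] <- bad[1, 2] + 1   # asymmetric
  expect_error(picnc_gblup(d$y, d$Q, bad), "not symmetric")
  neg <- d$G - diag(0.5, 30)
  expect_error(picnc_gblup(d$y, d$Q, neg), "positive semi-definite")
  expect_error(picnc_gblup(d$y, matrix(1, 30, 2), d$G), "full column rank")
})

test_that("cross-panel prediction interpolates clones and respects zero variance", {
  d <- sim_gblup_data(60L, 120L, seed = 10)
  train <- 1:50; val <- 51:60
  # make validation individual 51 a clone of training individual 1
  G <- d$G
  G[51, ] <- G[1, ]; G[, 51] <- G[, 1]; G[51, 51] <- G[1, 1]
  Gc <- d$G_cds
  Gc[51, ] <- Gc[1, ]; Gc[, 51] <- Gc[, 1]; Gc[51, 51] <- Gc[1, 1]
  fit <- picnc_gblup(d$y[train], d$Q[train, ], G[train, train],
                     Gc[train, train])
  pred <- predict(fit, G, d$Q[val, ], train, val, G_cds_full = Gc)
  clone_fit <- drop(d$Q[51, ] %*% fit$alpha) + fit$u[1] + fit$u_cds[1]
  expect_equal(pred[1], clone_fit, tolerance = 1e-4)
  # with no genetic variance the prediction is the fixed-effect part
  y_fixed <- drop(d$Q[train, ] %*% c(1, 0.5))
  fit0 <- picnc_gblup(y_fixed, d$Q[train, ], G[train, train])
  pred0 <- predict(fit0, G, d$Q[val, ], train, val)
  expect_equal(pred0, drop(d$Q[val, ] %*% fit0$alpha), tolerance = 1e-5)
})

test_that("prediction accuracy is the Pearson correlation with guards", {
  y <- c(1.2, 0.3, -0.5, 2)
  expect_equal(prediction_accuracy(y, y), 1)
  expect_equal(prediction_accuracy(-y, y), -1)
  set.seed(11)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(prediction_accuracy(a, b),
               sum(scale(a) * scale(b)) / 29, tolerance = 1e-12)
  expect_error(prediction_accuracy(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(prediction_accuracy(1:2, 1:2), "length")
})

test_that("constant weights can never be significant in the permutation test", {
  pipeline <- function(w) sum(w > 0) / length(w) # accuracy surrogate
  res <- permutation_test(pipeline, rep(0.4, 50), q = 0, B = 10, seed = 1)
  expect_false(res$significant)
  expect_equal(res$permuted, rep(res$observed, 10))
})

test_that("leave-one-family-out pools held-out predictions", {
  bundle <- small_bundle()
  X <- t(bundle$snps$coding_family)
  X[is.na(X)] <- 0L
  Xb <- t(bundle$snps$background_family)
  G <- suppressWarnings(grm(cbind(X, Xb)))
  y <- bundle$phenotypes$y_family
  Q <- cbind(1, prcomp(cbind(X, Xb))$x[, 1:3])
  fams <- bundle$snps$families
  res <- leave_one_family_out(y, Q, G, fams)
  expect_true(is.finite(res$pooled_accuracy))
  expect_lte(res$pooled_accuracy, 1)
  expect_identical(sort(names(res$per_family)), sort(unique(fams)))
  expect_identical(sum(is.na(res$predictions)), 0L)
  expect_error(leave_one_family_out(y, Q, G, rep("famA", length(y))),
               "at least 2 usable families")
  fams2 <- fams
  fams2[1:2] <- "tiny"
  fams2[fams2 == "fam4"] <- "fam1"
  expect_warning(leave_one_family_out(y, Q, G, fams2), "size < 3")
})

test_that("half-sib structure makes family holdout harder than random folds", {
  # needs full-size families for the relatedness contrast to show, so the
  # panels are re-simulated at the generator's default family structure
  bundle <- small_bundle()
  res <- vapply(1:3, function(s) {
    cfg <- small_config()
    cfg$n_families <- 8L; cfg$family_size <- 25L
    cfg$seed <- cfg$seed + s
    snps <- simulate_snps(bundle$mutations, bundle$truth, bundle$genome,
                          cfg)
    ph <- simulate_phenotypes(snps, cfg)
    X <- t(snps$coding_family); X[is.na(X)] <- 0L
    Xb <- t(snps$background_family)
    G <- suppressWarnings(grm(cbind(X, Xb)))
    y <- ph$y_family
    Q <- matrix(1, length(y), 1)
    lofo <- leave_one_family_out(y, Q, G, snps$families)$pooled_accuracy
    # random folds of the same sizes ignore family boundaries
    set.seed(12)
    cv <- leave_one_family_out(y, Q, G,
                               sample(snps$families))$pooled_accuracy
    c(lofo = lofo, cv = cv)
  }, c(lofo = 0, cv = 0))
  expect_lt(mean(res["lofo", ]), mean(res["cv", ]))
})
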