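#' Genome-wide relationship matrix
#'
#' VanRaden-style cross-product of centered minor-allele dosages:
#' `G[i, i'] = sum_l (x_il - 2 p_l)(x_i'l - 2 p_l) / sum_l 2 p_l (1 - p_l)`.
#' Monomorphic SNPs (frequency 0 or 1) carry no information and are dropped
#' with a warning.
#'
#' @param X Individuals-by-SNPs dosage matrix (0/1/2).
#' @param p Optional allele frequencies per SNP; estimated as
#'   `colMeans(X) / 2` when omitted.
#' @return The n x n relationship matrix.
#' @export
grm <- function(X, p = NULL) {
  X <- as.matrix(X)
  if (is.null(p)) p <- colMeans(X) / 2
  stopifnot(length(p) == ncol(X))
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic")
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) dropped from the ",
            "relationship matrix", call. = FALSE)
    X <- X[, poly, drop = FALSE]
    p <- p[poly]
  }
  Z <- sweep(X, 2L, 2 * p)
  tcrossprod(Z) / sum(2 * p * (1 - p))
}

#' Conservation-weighted relationship matrix over coding SNPs
#'
#' `G_CDS = X W X' / sum(w)` with `W = diag(w)`; dosages enter uncentered
#' by default (set `center = TRUE` for the centered variant). The `sum(w)`
#' scaling makes the kernel invariant to rescaling all weights by a
#' positive constant.
#'
#' @param X_cds Individuals-by-SNPs dosage matrix at nonsynonymous SNPs.
#' @param w Non-negative SNP weights (e.g. predicted conservation,
#'   possibly truncated).
#' @param center Center dosages by twice the allele frequency first.
#' @return The n x n weighted relationship matrix.
#' @export
weighted_grm <- function(X_cds, w, center = FALSE) {
  X_cds <- as.matrix(X_cds)
  stopifnot(length(w) == ncol(X_cds), all(w >= 0))
  if (sum(w) == 0) stop("empty kernel: all SNP weights are zero")
  if (center) X_cds <- sweep(X_cds, 2L, colMeans(X_cds))
  tcrossprod(sweep(X_cds, 2L, w, `*`), X_cds) / sum(w)
}

#' Percentile truncation of SNP weights
#'
#' Sets weights at or below the `q`% percentile threshold to zero. The
#' threshold is the `floor(q * m / 100)`-th ascending order statistic and
#' only weights strictly greater than it are retained, so for `m` distinct
#' weights exactly `m - floor(q * m / 100)` survive. `q = 0` keeps all
#' weights.
#'
#' @param w Numeric weight vector.
#' @param q Percentile in \[0, 100).
#' @return Truncated weights; attributes `threshold` and `retained`.
#' @export
truncate_weights <- function(w, q) {
  stopifnot(q >= 0, q < 100)
  m <- length(w)
  idx <- floor(q * m / 100)
  thr <- if (idx >= 1) sort(w)[idx] else -Inf
  out <- ifelse(w > thr, w, 0)
  attr(out, "threshold") <- thr
  attr(out, "retained") <- sum(w > thr)
  out
}

check_kernel <- function(K, name) {
  K <- as.matrix(K)
  if (!isSymmetric(K, tol = 1e-8)) stop(name, " is not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(name, " is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  (K + t(K)) / 2
}

#' Two-kernel GBLUP fitted by REML
#'
#' Fits the mixed model `y = Q alpha + u + u_cds + e` with
#' `u ~ N(0, G sigma2_u)`, `u_cds ~ N(0, G_cds sigma2_cds)` and
#' `e ~ N(0, I sigma2_e)`. Variance components are estimated by
#' average-information REML with an EM fallback whenever an AI step would
#' leave the parameter space or decrease the restricted likelihood;
#' variances are floored at 1e-10. Fixed effects and BLUPs are recovered
#' from the mixed-model equations at the converged variances.
#'
#' @param y Phenotype vector.
#' @param Q Fixed-effect design matrix (intercept plus population-structure
#'   covariates), full column rank.
#' @param G Genome-wide relationship matrix.
#' @param G_cds Optional weighted coding-SNP relationship matrix; omit for
#'   the single-kernel model.
#' @param tol Relative restricted-log-likelihood convergence tolerance.
#' @param max_iter Iteration cap (error with trace on non-convergence).
#' @return An object of class `picnc_gblup` with variance components
#'   (`sigma2`), fixed effects (`alpha`), BLUPs (`u`, `u_cds`), fitted
#'   values and residuals.
#' @export
picnc_gblup <- function(y, Q, G, G_cds = NULL, tol = 1e-8,
                        max_iter = 200L) {
  y <- as.numeric(y)
  Q <- as.matrix(Q)
  n <- length(y)
  stopifnot(n >= 10L, nrow(Q) == n, all(is.finite(y)))
  if (qr(Q)$rank < ncol(Q)) stop("Q is not full column rank")
  G <- check_kernel(G, "G")
  kernels <- list(u = G)
  if (!is.null(G_cds)) kernels$u_cds <- check_kernel(G_cds, "G_cds")
  kernels$e <- diag(n)
  nk <- length(kernels)
  # initialize by splitting the OLS residual variance equally; keep a
  # positive floor so an exact fixed-effect fit still starts the iteration
  v0 <- max(stats::var(stats::lm.fit(Q, y)$residuals), 1e-6)
  s <- rep(v0 / nk, nk)
  names(s) <- names(kernels)
  floor_v <- 1e-10
  # restricted log-likelihood and the quantities reused by the updates
  reml_eval <- function(s) {
    V <- Reduce(`+`, Map(`*`, kernels, s))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VinvQ <- Vinv %*% Q
    QVQ <- crossprod(Q, VinvQ)
    P <- Vinv - VinvQ %*% solve(QVQ) %*% t(VinvQ)
    Py <- P %*% y
    list(P = P, Py = Py,
         ll = -0.5 * (2 * sum(log(diag(ch))) +
                        determinant(QVQ)$modulus[1] + sum(y * Py)))
  }
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  state <- reml_eval(s)
  if (is.null(state)) stop("V is numerically singular at the start values")
  for (iter in seq_len(max_iter)) {
    P <- state$P
    Py <- state$Py
    ll <- state$ll
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll_old) + 1) < tol) {
      converged <- TRUE
      break
    }
    PK <- lapply(kernels, function(K) P %*% K)
    KPy <- lapply(kernels, function(K) K %*% Py)
    score <- vapply(seq_len(nk), function(i)
      -0.5 * (sum(diag(PK[[i]])) - sum(Py * KPy[[i]])), 0)
    AI <- matrix(0, nk, nk)
    PKPy <- lapply(KPy, function(v) P %*% v)
    for (i in seq_len(nk)) for (j in i:nk)
      AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    # Candidate updates, all evaluated by look-ahead on the restricted
    # likelihood; the best one is taken, so every iteration is monotone:
    #  - EM (slow but safe, non-negative even for singular kernels)
    #  - AI Newton step, with components pinned at the variance floor
    #    dropped from the system and out-of-bound moves floored
    #  - a half AI step (helps when the full step overshoots)
    #  - a boundary candidate zeroing near-vanishing components (EM alone
    #    crawls when the optimum sits on the boundary)
    s_em <- pmax(vapply(seq_len(nk), function(i)
      s[i] + s[i]^2 * (sum(Py * KPy[[i]]) - sum(diag(PK[[i]]))) / n, 0),
      floor_v)
    cands <- list(s_em)
    pinned <- s <= floor_v * 1.01 & score < 0
    delta <- tryCatch({
      d <- rep(0, nk)
      if (any(!pinned))
        d[!pinned] <- solve(AI[!pinned, !pinned, drop = FALSE],
                            score[!pinned])
      d[pinned] <- floor_v - s[pinned]
      d
    }, error = function(e) NULL)
    if (!is.null(delta) && all(is.finite(delta))) {
      cands <- c(cands, list(pmax(s + delta, floor_v),
                             pmax(s + delta / 2, floor_v)))
    }
    small <- which(s_em < 0.05 * sum(s_em))
    for (i in small) {
      drop_cand <- s_em
      drop_cand[i] <- floor_v
      cands <- c(cands, list(drop_cand))
    }
    if (length(small) > 1L) {
      drop_all <- s_em
      drop_all[small] <- floor_v
      cands <- c(cands, list(drop_all))
    }
    state_new <- NULL
    s_new <- s
    for (cand in cands) {
      st <- reml_eval(cand)
      if (!is.null(st) && (is.null(state_new) || st$ll > state_new$ll)) {
        state_new <- st
        s_new <- cand
      }
    }
    if (is.null(state_new))
      stop("V became numerically singular at iteration ", iter)
    if (max(abs(s_new - s) / pmax(abs(s), 1e-8)) < 1e-8) {
      s <- setNames(s_new, names(kernels))
      converged <- TRUE
      break
    }
    s <- setNames(s_new, names(kernels))
    state <- state_new
    ll_old <- ll
  }
  if (!converged)
    stop("REML did not converge in ", max_iter,
         " iterations; log-likelihood trace: ",
         paste(sprintf("%.4f", utils::tail(trace, 5L)), collapse = ", "))
  V <- Reduce(`+`, Map(`*`, kernels, s))
  Vinv <- chol2inv(chol(V))
  VinvQ <- Vinv %*% Q
  QVQ_inv <- solve(crossprod(Q, VinvQ))
  alpha <- drop(QVQ_inv %*% crossprod(VinvQ, y))
  P <- Vinv - VinvQ %*% QVQ_inv %*% t(VinvQ)
  Py <- drop(P %*% y)
  u <- drop(s["u"] * kernels$u %*% Py)
  u_cds <- if (!is.null(G_cds)) drop(s["u_cds"] * kernels$u_cds %*% Py)
           else rep(0, n)
  fitted <- drop(Q %*% alpha) + u + u_cds
  structure(list(sigma2 = s, alpha = alpha, u = u, u_cds = u_cds,
                 fitted = fitted, residuals = y - fitted, y = y, Q = Q,
                 loglik = trace[length(trace)], trace = trace,
                 iterations = iter, two_kernel = !is.null(G_cds)),
            class = "picnc_gblup")
}

#' @export
print.picnc_gblup <- function(x, ...) {
  cat("Two-kernel GBLUP" , if (!x$two_kernel) " (single kernel)", "\n",
      sep = "")
  cat("  n = ", length(x$y), ", REML iterations = ", x$iterations,
      ", logLik = ", sprintf("%.3f", x$loglik), "\n", sep = "")
  vc <- x$sigma2
  cat("  variance components:\n")
  for (nm in names(vc))
    cat(sprintf("    sigma2_%-5s %.4g\n", nm, vc[nm]))
  invisible(x)
}

#' @export
summary.picnc_gblup <- function(object, ...) {
  vc <- object$sigma2
  h2 <- (sum(vc) - vc["e"]) / sum(vc)
  out <- list(sigma2 = vc, prop_genetic = unname(h2),
              alpha = object$alpha,
              fit_cor = stats::cor(object$fitted, object$y),
              iterations = object$iterations, loglik = object$loglik)
  class(out) <- "summary.picnc_gblup"
  out
}

#' @export
print.summary.picnc_gblup <- function(x, ...) {
  cat("GBLUP variance components:\n")
  print(round(x$sigma2, 5))
  cat(sprintf("genetic proportion of variance: %.3f\n", x$prop_genetic))
  cat(sprintf("in-sample cor(fitted, y): %.3f after %d REML iterations\n",
              x$fit_cor, x$iterations))
  invisible(x)
}

#' @export
coef.picnc_gblup <- function(object, ...) object$alpha

#' @export
fitted.picnc_gblup <- function(object, ...) object$fitted

#' @export
residuals.picnc_gblup <- function(object, ...) object$residuals

#' Predict phenotypes of new individuals from joint kernels
#'
#' Conditional BLUP: with kernels computed jointly over training and
#' validation individuals (shared SNP set and allele frequencies), the
#' validation breeding values are
#' `u_val = G[val, train] (G[train, train] + eps I)^-1 u_train` per kernel,
#' and `y_val = Q_val alpha + u_val + u_cds_val`.
#'
#' @param object A `picnc_gblup` fitted on the training rows.
#' @param G_full Joint genome-wide kernel over train + validation rows.
#' @param Q_val Fixed-effect design of the validation rows.
#' @param train_idx,val_idx Row indices of the two panels in the joint
#'   kernels.
#' @param G_cds_full Joint coding-SNP kernel (required for two-kernel
#'   fits).
#' @param eps Ridge jitter applied to the training block before inversion.
#' @param ... Unused.
#' @return Numeric vector of predicted phenotypes.
#' @export
predict.picnc_gblup <- function(object, G_full, Q_val, train_idx, val_idx,
                                G_cds_full = NULL, eps = 1e-8, ...) {
  stopifnot(length(train_idx) == length(object$y))
  carry <- function(K, u_train) {
    A <- K[train_idx, train_idx, drop = FALSE]
    drop(K[val_idx, train_idx, drop = FALSE] %*%
           solve(A + diag(eps, nrow(A)), u_train))
  }
  out <- drop(as.matrix(Q_val) %*% object$alpha) +
    carry(G_full, object$u)
  if (object$two_kernel) {
    if (is.null(G_cds_full))
      stop("G_cds_full is required for a two-kernel model")
    out <- out + carry(G_cds_full, object$u_cds)
  }
  out
}

#' Genomic prediction accuracy
#'
#' Pearson correlation between predicted and observed phenotypes.
#'
#' @param y_hat,y Predicted and observed phenotype vectors (at least 3
#'   pairs, both with nonzero variance).
#' @return Correlation coefficient.
#' @export
prediction_accuracy <- function(y_hat, y) {
  stopifnot(length(y_hat) == length(y), length(y) >= 3L)
  if (stats::sd(y_hat) == 0 || stats::sd(y) == 0)
    stop("prediction accuracy undefined: zero variance")
  stats::cor(y_hat, y)
}

#' Permutation significance test for SNP weights
#'
#' Compares the genomic prediction accuracy obtained with the actual SNP
#' weights against the accuracies from `B` random permutations of the
#' weights (each permuted vector passes through the same truncation). The
#' improvement is significant (P < 0.05 for B = 20) when the observed
#' accuracy strictly exceeds every permuted accuracy.
#'
#' @param pipeline Function taking a weight vector and returning a
#'   prediction accuracy (it should rebuild the weighted kernel, refit and
#'   score).
#' @param w SNP weight vector.
#' @param q Truncation percentile applied to actual and permuted weights.
#' @param B Number of permutations (default 20).
#' @param seed Integer seed for the permutations.
#' @return List of class `picnc_permutation`: `observed`, `permuted`,
#'   `significant`.
#' @export
permutation_test <- function(pipeline, w, q = 0, B = 20L, seed = 1L) {
  observed <- pipeline(truncate_weights(w, q))
  permuted <- with_seed(seed, {
    vapply(seq_len(B), function(b)
      pipeline(truncate_weights(sample(w), q)), 0)
  })
  structure(list(observed = observed, permuted = permuted,
                 significant = all(observed > permuted), B = B),
            class = "picnc_permutation")
}

#' @export
print.picnc_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (B = %d)\n", x$B))
  cat(sprintf("  observed accuracy: %.4f\n", x$observed))
  cat(sprintf("  permuted range: [%.4f, %.4f]\n", min(x$permuted),
              max(x$permuted)))
  cat("  significant (observed > all permuted): ", x$significant, "\n",
      sep = "")
  invisible(x)
}

#' Leave-one-family-out genomic prediction
#'
#' For each family, fits the model on all other families and predicts the
#' held-out family from the joint kernels. Accuracy is pooled over the
#' concatenated held-out predictions; per-family accuracies are reported
#' alongside. Families smaller than 3 are skipped with a warning.
#'
#' @param y Phenotypes over the whole panel.
#' @param Q Fixed-effect design over the whole panel.
#' @param G Genome-wide kernel over the whole panel.
#' @param families Family label per individual.
#' @param G_cds Optional coding-SNP kernel.
#' @param ... Passed to [picnc_gblup()].
#' @return List: `pooled_accuracy`, `per_family`, `predictions`.
#' @export
leave_one_family_out <- function(y, Q, G, families, G_cds = NULL, ...) {
  families <- as.character(families)
  sizes <- table(families)
  usable <- names(sizes)[sizes >= 3L]
  skipped <- setdiff(names(sizes), usable)
  if (length(skipped))
    warning("skipping families of size < 3: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (length(usable) < 2L)
    stop("leave-one-family-out requires at least 2 usable families")
  pred <- rep(NA_real_, length(y))
  per_family <- setNames(numeric(length(usable)), usable)
  for (f in usable) {
    val <- which(families == f)
    train <- which(families != f)
    fit <- picnc_gblup(y[train], Q[train, , drop = FALSE],
                       G[train, train, drop = FALSE],
                       if (!is.null(G_cds))
                         G_cds[train, train, drop = FALSE],
                       ...)
    pred[val] <- predict(fit, G, Q[val, , drop = FALSE], train, val,
                         G_cds_full = G_cds)
    per_family[f] <- stats::cor(pred[val], y[val])
  }
  keep <- !is.na(pred)
  list(pooled_accuracy = prediction_accuracy(pred[keep], y[keep]),
       per_family = per_family, predictions = pred)
}
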