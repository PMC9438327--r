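#' Probability-forest configuration
#'
#' Defaults follow the training protocol used for genome-scale runs: 1000
#' trees, 50,000 sites per tree sampled with replacement, at least 100 sites
#' per terminal node, and one third of the non-baseline annotations sampled
#' per tree. Mutation type, SIFT score and SIFT class are always included as
#' baseline predictors.
#'
#' @param n_trees Number of trees per forest.
#' @param p_variables Fraction of non-baseline features sampled per tree.
#' @param bootstrap_size Observations drawn (with replacement) per tree;
#'   capped at the training size when smaller.
#' @param min_node_size Minimum terminal node size.
#' @param baseline_features Feature names always included.
#' @param sampling `"per_tree"` (default) draws one feature subset per tree
#'   with all subset features available at every split; `"per_split"`
#'   delegates subsetting to the split level (mtry).
#' @param max_depth Optional tree depth cap (`NULL` = unlimited).
#' @param bootstrap Draw bootstrap samples per tree (default). `FALSE`
#'   grows every tree on the full training set (diagnostic use, e.g.
#'   comparing a single tree against an exhaustive split search).
#' @param seed Integer seed; the forest is deterministic given it.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 1000L, p_variables = 1 / 3,
                          bootstrap_size = 50000L, min_node_size = 100L,
                          baseline_features = c("mutation_type",
                                                "sift_score", "sift_class"),
                          sampling = c("per_tree", "per_split"),
                          max_depth = NULL, bootstrap = TRUE, seed = 1L) {
  stopifnot(p_variables > 0, p_variables <= 1, min_node_size >= 1)
  structure(list(n_trees = as.integer(n_trees), p_variables = p_variables,
                 bootstrap_size = as.integer(bootstrap_size),
                 min_node_size = as.integer(min_node_size),
                 baseline_features = baseline_features,
                 sampling = match.arg(sampling), max_depth = max_depth,
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "forest_config")
}

#' Balanced sample weights by label and chromosome
#'
#' Each observation is weighted by the inverse of the size of its
#' (label, chromosome) class, so every class contributes total weight 1 and
#' imbalance with respect to conservation or chromosome does not dominate
#' training or accuracy estimates.
#'
#' @param labels Vector of 0/1 labels.
#' @param chromosomes Optional chromosome of each observation; omitted, all
#'   observations share one stratum per label.
#' @return Numeric weight vector.
#' @export
compute_sample_weights <- function(labels, chromosomes = NULL) {
  stopifnot(all(labels %in% c(0, 1)))
  if (is.null(chromosomes)) chromosomes <- rep("all", length(labels))
  key <- paste(labels, chromosomes)
  1 / as.numeric(table(key)[key])
}

# Coerce predictor columns to the types ranger expects and record the
# factor levels so prediction data can be aligned to the training schema.
prepare_features <- function(X, schema = NULL) {
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  if (is.null(schema)) {
    levels <- lapply(X, function(col)
      if (is.character(col) || is.factor(col)) sort(unique(as.character(col))))
    schema <- list(columns = names(X), levels = levels)
  } else {
    missing <- setdiff(schema$columns, names(X))
    if (length(missing))
      stop("prediction data lacks training columns: ",
           paste(missing, collapse = ", "))
    X <- X[schema$columns]
  }
  for (nm in names(X)) {
    lv <- schema$levels[[nm]]
    if (!is.null(lv)) X[[nm]] <- factor(as.character(X[[nm]]), levels = lv)
    else if (is.logical(X[[nm]])) X[[nm]] <- as.numeric(X[[nm]])
  }
  if (anyNA(X)) stop("missing values in predictors; only SIFT may be ",
                     "missing and must be imputed to 1 upstream")
  list(X = X, schema = schema)
}

#' Fit a probability random forest
#'
#' Trains an ensemble of probability trees on labeled sites. Each tree is
#' grown on `bootstrap_size` observations drawn with replacement with
#' probability proportional to the sample weights, using the baseline
#' features plus a per-tree random subset of
#' `ceiling(p_variables * n_nonbaseline)` remaining features (or per-split
#' subsetting when configured). Leaves store the class-1 proportion and the
#' forest prediction is the mean over trees. Variable importance is the
#' corrected impurity measure (impurity reduction debiased against permuted
#' shadow copies), accumulated over trees.
#'
#' @param X Data frame of annotations (no missing values).
#' @param w 0/1 conservation labels.
#' @param weights Sample weights; defaults to
#'   [compute_sample_weights()] over `w` and `chromosomes`.
#' @param config A [forest_config()].
#' @param chromosomes Optional chromosome vector used for default weights.
#' @return An object of class `picnc_forest`.
#' @export
picnc_forest <- function(X, w, weights = NULL, config = forest_config(),
                         chromosomes = NULL) {
  if (length(unique(w)) < 2L)
    stop("degenerate labels: training data contains a single class")
  stopifnot(all(w %in% c(0, 1)), nrow(X) == length(w))
  if (is.null(weights)) weights <- compute_sample_weights(w, chromosomes)
  prep <- prepare_features(X)
  X <- prep$X
  y <- factor(w, levels = c(0, 1))
  n <- nrow(X)
  # when the training set is smaller than bootstrap_size, sample n with
  # replacement and flag the cap on the returned object
  capped <- config$bootstrap_size > n
  replace <- config$bootstrap
  frac <- if (replace) min(config$bootstrap_size, n) / n else 1
  baseline <- intersect(config$baseline_features, names(X))
  nonbase <- setdiff(names(X), baseline)
  imp <- setNames(numeric(ncol(X)), names(X))
  grow <- function(X_t, seed, importance = "none") {
    ranger::ranger(x = X_t, y = y, num.trees = 1L, probability = TRUE,
                   mtry = ncol(X_t), max.depth = config$max_depth,
                   min.node.size = config$min_node_size,
                   case.weights = weights, sample.fraction = frac,
                   replace = replace, importance = importance,
                   respect.unordered.factors = "order", seed = seed,
                   num.threads = 1L, verbose = FALSE)
  }
  if (config$sampling == "per_tree") {
    n_sub <- min(length(nonbase),
                 ceiling(config$p_variables * length(nonbase)))
    trees <- vector("list", config$n_trees)
    subsets <- vector("list", config$n_trees)
    for (t in seq_len(config$n_trees)) {
      sub <- with_seed(config$seed + t,
                       sort(sample(nonbase, n_sub)))
      feats <- c(baseline, sub)
      trees[[t]] <- grow(X[feats], config$seed + t)
      subsets[[t]] <- feats
      # corrected impurity importance: grow a parallel tree on the subset
      # plus permuted shadow copies and subtract the shadow importances,
      # so the prediction trees themselves stay free of shadow splits
      shadow <- with_seed(config$seed * 2L + t, {
        sh <- lapply(X[feats], sample)
        names(sh) <- paste0(".shadow.", feats)
        as.data.frame(sh, optional = TRUE)
      })
      imp_fit <- grow(cbind(X[feats], shadow), config$seed + t,
                      importance = "impurity")
      vi <- imp_fit$variable.importance
      imp[feats] <- imp[feats] + vi[feats] -
        vi[paste0(".shadow.", feats)]
    }
  } else {
    mtry <- max(1L, ceiling(config$p_variables * length(nonbase)))
    full <- function(X_t, mtry_t, importance, always) {
      ranger::ranger(x = X_t, y = y, num.trees = config$n_trees,
                     probability = TRUE, mtry = mtry_t,
                     max.depth = config$max_depth,
                     min.node.size = config$min_node_size,
                     case.weights = weights, sample.fraction = frac,
                     replace = replace, importance = importance,
                     always.split.variables = always,
                     respect.unordered.factors = "order",
                     seed = config$seed, num.threads = 1L,
                     verbose = FALSE)
    }
    always <- if (length(baseline)) baseline else NULL
    trees <- full(X, mtry, "none", always)
    subsets <- NULL
    shadow <- with_seed(config$seed * 2L + 1L, {
      sh <- lapply(X, sample)
      names(sh) <- paste0(".shadow.", names(X))
      as.data.frame(sh, optional = TRUE)
    })
    imp_fit <- full(cbind(X, shadow), mtry, "impurity", always)
    vi <- imp_fit$variable.importance
    imp <- vi[names(imp)] - vi[paste0(".shadow.", names(imp))]
    names(imp) <- colnames(X)
  }
  structure(list(trees = trees, subsets = subsets, schema = prep$schema,
                 importance = imp, config = config, capped = capped,
                 n_train = n),
            class = "picnc_forest")
}

#' Predict conservation probabilities
#'
#' @param object A fitted [picnc_forest()].
#' @param newdata Data frame with (at least) the training columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities `P(w = 1)` in \[0, 1\].
#' @export
predict.picnc_forest <- function(object, newdata, ...) {
  prep <- prepare_features(newdata, schema = object$schema)
  X <- prep$X
  if (object$config$sampling == "per_tree") {
    acc <- numeric(nrow(X))
    for (t in seq_along(object$trees))
      acc <- acc + stats::predict(object$trees[[t]],
                                  data = X[object$subsets[[t]]],
                                  num.threads = 1L,
                                  verbose = FALSE)$predictions[, "1"]
    acc / length(object$trees)
  } else {
    stats::predict(object$trees, data = X, num.threads = 1L,
                   verbose = FALSE)$predictions[, "1"]
  }
}

#' @export
print.picnc_forest <- function(x, ...) {
  cat("Probability random forest (", x$config$n_trees, " trees, ",
      x$config$sampling, " feature sampling)\n", sep = "")
  cat("  training sites: ", x$n_train, "\n", sep = "")
  cat("  features: ", length(x$schema$columns), " (baseline: ",
      paste(intersect(x$config$baseline_features, x$schema$columns),
            collapse = ", "), ")\n", sep = "")
  top <- sort(x$importance, decreasing = TRUE)
  top <- top[seq_len(min(5L, length(top)))]
  cat("  top importance: ",
      paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Corrected-impurity variable importance
#'
#' @param forest A fitted [picnc_forest()].
#' @return Named numeric vector over all training features (zero for
#'   features never sampled or never split).
#' @export
variable_importance <- function(forest) {
  stopifnot(inherits(forest, "picnc_forest"))
  forest$importance
}

#' Class-weighted classification accuracy
#'
#' Fraction of sites whose rounded predicted probability equals the
#' observed label, weighted by the sample weights. Probabilities of exactly
#' 0.5 round up to class 1.
#'
#' @param w_hat Predicted probabilities.
#' @param w Observed 0/1 labels.
#' @param weights Sample weights (default uniform).
#' @return Weighted accuracy in \[0, 1\].
#' @export
weighted_accuracy <- function(w_hat, w, weights = NULL) {
  stopifnot(length(w_hat) == length(w))
  if (is.null(weights)) weights <- rep(1, length(w))
  called <- as.integer(w_hat >= 0.5)
  sum(weights * (called == w)) / sum(weights)
}

chrom_parity <- function(chrom) {
  num <- suppressWarnings(as.integer(gsub("\\D", "", chrom)))
  if (anyNA(num)) num <- match(chrom, sort(unique(chrom)))
  num %% 2L
}

#' Leave-one-chromosome-out prediction
#'
#' For each chromosome carrying prediction (SNP) sites, scores those sites
#' with a forest trained on the labeled monomorphic sites of all other
#' chromosomes, so predictions on a chromosome never use training data from
#' it. The union of folds covers every prediction site exactly once.
#'
#' @param annotations Annotated mutation table (monomorphic and SNP rows;
#'   see [annotate_mutations()]).
#' @param labels Label vector aligned with `annotations` (see
#'   [label_sites()]); required for monomorphic rows only.
#' @param config A [forest_config()].
#' @return Data frame `chrom`, `pos`, `ref`, `alt`, `w_hat`, with the
#'   per-fold training chromosome sets in the `"folds"` attribute.
#' @export
loco_predict <- function(annotations, labels, config = forest_config()) {
  part <- partition_sites(annotations, labels)
  feats <- annotation_columns(annotations)
  train <- annotations[part$training, , drop = FALSE]
  w_train <- labels[part$training]
  pred <- annotations[part$prediction, , drop = FALSE]
  if (length(unique(annotations$chrom)) < 2L)
    stop("leave-one-chromosome-out requires at least 2 chromosomes")
  out <- pred[c("chrom", "pos", "ref", "alt")]
  rownames(out) <- NULL
  out$w_hat <- NA_real_
  folds <- list()
  for (k in unique(pred$chrom)) {
    in_fold <- pred$chrom == k
    use <- train$chrom != k
    if (!any(use))
      stop("no training data outside chromosome ", k)
    if (length(unique(w_train[use])) < 2L)
      stop("degenerate labels outside chromosome ", k)
    cfg <- config
    cfg$seed <- config$seed + match(k, unique(pred$chrom))
    fit <- picnc_forest(train[use, feats, drop = FALSE], w_train[use],
                        config = cfg, chromosomes = train$chrom[use])
    out$w_hat[in_fold] <- predict(fit, pred[in_fold, feats, drop = FALSE])
    folds[[k]] <- sort(unique(train$chrom[use]))
  }
  attr(out, "folds") <- folds
  out
}

#' Hyperparameter tuning for the left-out chromosome
#'
#' Grid search over tree counts and feature-sampling fractions. For each
#' grid point a forest is trained on the chromosomes of parity opposite to
#' the left-out chromosome `k` and validated (by class-weighted accuracy) on
#' the remaining chromosomes excluding `k`. Ties favour more trees, then a
#' smaller sampling fraction.
#'
#' @param X Data frame of annotations for labeled training sites.
#' @param w 0/1 labels.
#' @param chromosomes Chromosome of each site.
#' @param k The left-out chromosome (excluded from tuning entirely).
#' @param grid_trees,grid_p Candidate values for `n_trees` and
#'   `p_variables`.
#' @param config Base [forest_config()] providing the remaining settings.
#' @return The selected `forest_config`, with the accuracy grid in the
#'   `"grid"` attribute.
#' @export
tune_hyperparameters <- function(X, w, chromosomes, k,
                                 grid_trees = c(100L, 250L, 500L, 1000L),
                                 grid_p = c(1 / 12, 1 / 6, 1 / 3, 2 / 3),
                                 config = forest_config()) {
  if (!length(grid_trees) || !length(grid_p)) stop("empty tuning grid")
  chroms <- unique(chromosomes)
  if (length(chroms) < 3L)
    stop("tuning requires at least 3 chromosomes")
  par_k <- chrom_parity(k)
  parity <- chrom_parity(chromosomes)
  train_idx <- chromosomes != k & parity != par_k
  val_idx <- chromosomes != k & parity == par_k
  if (!any(train_idx) || !any(val_idx))
    stop("parity split leaves an empty training or validation set")
  grid <- expand.grid(n_trees = grid_trees, p_variables = grid_p)
  grid$accuracy <- NA_real_
  w_val <- w[val_idx]
  val_weights <- compute_sample_weights(w_val, chromosomes[val_idx])
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$n_trees <- as.integer(grid$n_trees[i])
    cfg$p_variables <- grid$p_variables[i]
    fit <- picnc_forest(X[train_idx, , drop = FALSE], w[train_idx],
                        config = cfg,
                        chromosomes = chromosomes[train_idx])
    grid$accuracy[i] <- weighted_accuracy(
      predict(fit, X[val_idx, , drop = FALSE]), w_val, val_weights)
  }
  ord <- order(-grid$accuracy, -grid$n_trees, grid$p_variables)
  best <- grid[ord[1L], ]
  out <- config
  out$n_trees <- as.integer(best$n_trees)
  out$p_variables <- best$p_variables
  attr(out, "grid") <- grid
  out
}
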