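# Split protocol, the five classification meta-algorithms, multiclass
# performance indices, and pattern scoring over the split x seed grid.

ALGORITHMS <- c("extra_trees", "decision_tree", "cat_boost",
                "gradient_boosting", "ada_boost")

#' Repeated random split-and-seed evaluation protocol
#'
#' Defines how a pattern is scored: the cohort is split `n_splits` times
#' into train/test at `train_fraction` (default 80/20, the floor rule, so a
#' 564-record cohort gives 451/113), and each split is fitted with
#' `n_seeds` model seeds; the full crossed grid of
#' `n_splits * n_seeds` evaluations is aggregated.  The study protocol is
#' 25 splits x 101 seeds; scaled-down grids are used for interactive work
#' and testing.
#'
#' @param train_fraction Fraction of records in the training partition.
#' @param n_splits Number of random train/test splits.
#' @param n_seeds Number of model seeds per split.
#' @param stratified Stratify splits by outcome class (default TRUE).
#' @param master_seed Integer from which split seeds (`master_seed + i`)
#'   and model seeds (`master_seed + j`) are derived.
#' @return An object of class `derga_protocol`.
#' @export
split_protocol <- function(train_fraction = 0.8, n_splits = 25,
                           n_seeds = 101, stratified = TRUE,
                           master_seed = 42) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            n_splits >= 1, n_seeds >= 1)
  structure(list(train_fraction = train_fraction,
                 n_splits = as.integer(n_splits),
                 n_seeds = as.integer(n_seeds),
                 stratified = isTRUE(stratified),
                 master_seed = as.integer(master_seed)),
            class = "derga_protocol")
}

#' @export
print.derga_protocol <- function(x, ...) {
  cat(sprintf(
    "Split protocol: %g/%g%% %s splits x %d, model seeds x %d (master seed %d)\n",
    100 * x$train_fraction, 100 * (1 - x$train_fraction),
    if (x$stratified) "stratified" else "unstratified",
    x$n_splits, x$n_seeds, x$master_seed))
  invisible(x)
}

#' Build the train/test splits of a protocol
#'
#' Training size follows the floor rule `|train| = floor(train_fraction * n)`.
#' Stratified splits allocate per-class training counts proportionally
#' (largest-remainder rounding), so each class's training share differs from
#' its cohort share by at most one record.  Split `i` uses RNG seed
#' `master_seed + i`.
#'
#' @param n_records Number of records.
#' @param labels Outcome labels (used when stratifying).
#' @param protocol A `derga_protocol`.
#' @return List of `n_splits` lists with `train`, `test` (integer index
#'   vectors) and `split_seed`.
#' @export
make_splits <- function(n_records, labels = NULL, protocol = split_protocol()) {
  stopifnot(n_records >= 5)
  n_train <- floor(protocol$train_fraction * n_records)
  if (n_train < 1 || n_train >= n_records) {
    stop("train fraction leaves an empty partition")
  }
  stratified <- protocol$stratified && !is.null(labels)
  if (stratified) {
    labels <- factor(labels)
    stopifnot(length(labels) == n_records)
  }
  lapply(seq_len(protocol$n_splits), function(i) {
    seed <- protocol$master_seed + i
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    if (stratified) {
      counts <- table(labels)
      exact <- protocol$train_fraction * as.numeric(counts)
      base <- floor(exact)
      rem <- n_train - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      } else if (rem < 0) {
        cut <- order(exact - base, decreasing = FALSE)
        k <- 0
        for (j in cut) {
          if (k == -rem) break
          if (base[j] > 0) { base[j] <- base[j] - 1; k <- k + 1 }
        }
      }
      train <- integer(0)
      for (j in seq_along(base)) {
        idx <- which(as.integer(labels) == j)
        if (base[j] > length(idx)) stop("class too small to stratify")
        train <- c(train, sample(idx, base[j]))
      }
      train <- sort(train)
    } else {
      train <- sort(sample.int(n_records, n_train))
    }
    test <- setdiff(seq_len(n_records), train)
    if (!is.null(labels) && length(unique(labels[train])) < 2) {
      stop("a training partition holds a single outcome class")
    }
    list(train = train, test = test, split_seed = seed)
  })
}

# --- frozen hyperparameters ------------------------------------------------

#' Frozen default hyperparameters of the five meta-algorithms
#'
#' The source protocol leaves the learners' hyperparameters unstated; this
#' package freezes one documented set so results do not drift with library
#' defaults: 100 trees for the tree ensembles, conventional boosting depths
#' and learning rates, fully-grown single decision trees.  Every report logs
#' the set in force.
#'
#' @return Named list, one sublist per algorithm identifier.
#' @export
default_hyper <- function() {
  list(
    extra_trees = list(num_trees = 100, mtry = NULL,  # NULL -> floor(sqrt(p))
                       min_node_size = 1, num_random_splits = 1),
    decision_tree = list(cp = 0, minsplit = 2, minbucket = 1,
                         maxdepth = 30),
    cat_boost = list(nrounds = 100, max_depth = 6, eta = 0.1),
    gradient_boosting = list(nrounds = 100, max_depth = 3, eta = 0.1),
    ada_boost = list(n_estimators = 50, max_depth = 1)
  )
}

# --- learners --------------------------------------------------------------

fit_learner <- function(algorithm, x, y, hyper, model_seed) {
  hp <- hyper[[algorithm]]
  switch(algorithm,
    extra_trees = {
      mtry <- if (is.null(hp$mtry)) max(1, floor(sqrt(ncol(x)))) else hp$mtry
      fit <- ranger::ranger(
        x = as.data.frame(x), y = y,
        num.trees = hp$num_trees, mtry = min(mtry, ncol(x)),
        min.node.size = hp$min_node_size,
        splitrule = "extratrees", num.random.splits = hp$num_random_splits,
        replace = FALSE, sample.fraction = 1,
        seed = model_seed, num.threads = 1, verbose = FALSE)
      list(kind = algorithm, fit = fit, classes = levels(y),
           seed = model_seed)
    },
    decision_tree = {
      d <- data.frame(.y = y, as.data.frame(x))
      fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                          control = rpart::rpart.control(
                            cp = hp$cp, minsplit = hp$minsplit,
                            minbucket = hp$minbucket,
                            maxdepth = hp$maxdepth, xval = 0))
      list(kind = algorithm, fit = fit, classes = levels(y))
    },
    cat_boost = ,
    gradient_boosting = {
      fit <- xgboost_fit(x, y, hp, model_seed)
      list(kind = algorithm, fit = fit, classes = levels(y))
    },
    ada_boost = {
      fit <- adaboost_fit(x, y, n_estimators = hp$n_estimators,
                          max_depth = hp$max_depth, seed = model_seed)
      list(kind = algorithm, fit = fit, classes = levels(y))
    },
    stop("unknown algorithm: ", algorithm)
  )
}

predict_learner <- function(model, x) {
  cls <- model$classes
  pred <- switch(model$kind,
    # the prediction seed pins ranger's vote tie-breaking, so evaluation
    # is a pure function of (data, hyper, model seed)
    extra_trees = as.character(stats::predict(
      model$fit, data = as.data.frame(x), num.threads = 1,
      seed = model$seed)$predictions),
    decision_tree = {
      p <- stats::predict(model$fit, newdata = as.data.frame(x),
                          type = "class")
      as.character(p)
    },
    cat_boost = ,
    gradient_boosting = xgboost_predict(model$fit, x, cls),
    ada_boost = adaboost_predict(model$fit, x, cls)
  )
  factor(pred, levels = cls)
}

xgboost_fit <- function(x, y, hp, model_seed) {
  k <- nlevels(y)
  dtrain <- xgboost::xgb.DMatrix(data = x, label = as.integer(y) - 1L)
  params <- list(objective = "multi:softprob", num_class = k,
                 max_depth = hp$max_depth, eta = hp$eta,
                 nthread = 1, seed = model_seed,
                 subsample = 1, colsample_bytree = 1)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hp$nrounds, verbose = 0)
}

xgboost_predict <- function(fit, x, classes) {
  p <- stats::predict(fit, newdata = xgboost::xgb.DMatrix(x))
  if (!is.matrix(p)) p <- matrix(p, ncol = length(classes), byrow = TRUE)
  classes[max.col(p, ties.method = "first")]
}

# Multiclass AdaBoost (SAMME) over shallow rpart stumps: reweight records
# by exponential loss, stop early when a stump is no better than chance or
# perfectly separates the weighted sample.
adaboost_fit <- function(x, y, n_estimators = 50, max_depth = 1, seed = 0) {
  n <- nrow(x); k <- nlevels(y)
  w <- rep(1 / n, n)
  d <- data.frame(.y = y, as.data.frame(x))
  stumps <- list()
  alphas <- numeric(0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = -1, minsplit = 2,
                          minbucket = 1, xval = 0))
    pred <- stats::predict(fit, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / k) break          # no better than chance
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break              # perfect weighted fit
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {             # degenerate: majority class
    stumps <- list(NULL)
    alphas <- 1
    attr(stumps, "majority") <- levels(y)[which.max(tabulate(y, k))]
  }
  list(stumps = stumps, alphas = alphas, classes = levels(y))
}

adaboost_predict <- function(fit, x, classes) {
  if (!is.null(attr(fit$stumps, "majority"))) {
    return(rep(attr(fit$stumps, "majority"), nrow(x)))
  }
  votes <- matrix(0, nrow(x), length(classes),
                  dimnames = list(NULL, classes))
  nd <- as.data.frame(x)
  for (m in seq_along(fit$stumps)) {
    pred <- as.character(stats::predict(fit$stumps[[m]], newdata = nd,
                                        type = "class"))
    votes[cbind(seq_len(nrow(x)), match(pred, classes))] <-
      votes[cbind(seq_len(nrow(x)), match(pred, classes))] + fit$alphas[m]
  }
  classes[max.col(votes, ties.method = "first")]
}

# --- performance indices ---------------------------------------------------

#' Multiclass performance indices from predictions
#'
#' Computes the 3 x 3 confusion matrix, overall accuracy, and per-class
#' one-vs-rest precision, recall and F1 with their macro (unweighted)
#' averages.  A per-class precision or recall with an empty denominator is
#' 0; F1 is the harmonic mean of that class's precision and recall (0 when
#' both are 0).
#'
#' @param truth Factor of true labels.
#' @param pred Factor of predicted labels on the same levels.
#' @return An object of class `derga_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f1` (macro), `per_class` (data frame) and
#'   `confusion`.
#' @export
multiclass_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  lev <- levels(truth)
  pred <- factor(pred, levels = lev)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    accuracy = sum(tp) / sum(cm),
    precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    per_class = data.frame(class = lev, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1)),
    confusion = cm), class = "derga_metrics")
}

#' @export
print.derga_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | macro precision %.4f recall %.4f F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Fit one learner on one split and evaluate on its test partition
#'
#' @param algorithm One of `"extra_trees"`, `"decision_tree"`,
#'   `"cat_boost"`, `"gradient_boosting"`, `"ada_boost"`.
#' @param table A `cohort`.
#' @param pattern Feature names to use.
#' @param split One element of [make_splits()].
#' @param model_seed Integer seed for the learner's randomness.
#' @param hyper Hyperparameter list (default [default_hyper()]).
#' @return List with `algorithm`, `pattern`, `split_seed`, `model_seed` and
#'   `metrics` (a `derga_metrics` computed on the test partition only).
#' @export
train_and_evaluate <- function(algorithm, table, pattern, split,
                               model_seed, hyper = default_hyper()) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  enc <- encode_cohort(table, pattern)
  ytr <- droplevels(enc$y[split$train])
  if (nlevels(ytr) < 2) stop("degenerate training labels (single class)")
  model <- fit_learner(algorithm, enc$x[split$train, , drop = FALSE],
                       droplevels(enc$y[split$train]), hyper, model_seed)
  pred <- predict_learner(model, enc$x[split$test, , drop = FALSE])
  pred <- factor(as.character(pred), levels = levels(enc$y))
  list(algorithm = algorithm, pattern = enc$feature_names,
       split_seed = split$split_seed, model_seed = model_seed,
       metrics = multiclass_metrics(enc$y[split$test], pred))
}

#' Score a feature pattern over the full split x seed grid
#'
#' Runs `n_splits * n_seeds` train/evaluate cycles for one algorithm and
#' pattern and aggregates test accuracy.  Both the mean (the default
#' selection statistic) and the best single evaluation are reported.
#'
#' @inheritParams train_and_evaluate
#' @param protocol A `derga_protocol`.
#' @param splits Optional precomputed [make_splits()] result (so the same
#'   splits are reused across patterns).
#' @return An object of class `derga_score`: list with `mean`, `sd`, `max`
#'   of test accuracy, `n_evaluations`, and `best` (the best evaluation's
#'   details).
#' @export
score_pattern <- function(algorithm, table, pattern,
                          protocol = split_protocol(),
                          hyper = default_hyper(), splits = NULL) {
  if (is.null(splits)) {
    splits <- make_splits(nrow(table), table$outcome, protocol)
  }
  model_seeds <- protocol$master_seed + seq_len(protocol$n_seeds)
  accs <- numeric(0)
  best <- NULL
  for (sp in splits) {
    for (ms in model_seeds) {
      ev <- train_and_evaluate(algorithm, table, pattern, sp, ms, hyper)
      accs <- c(accs, ev$metrics$accuracy)
      if (is.null(best) || ev$metrics$accuracy > best$metrics$accuracy) {
        best <- ev
      }
    }
  }
  structure(list(mean = mean(accs), sd = stats::sd(accs), max = max(accs),
                 n_evaluations = length(accs), best = best),
            class = "derga_score")
}

#' @export
print.derga_score <- function(x, ...) {
  cat(sprintf("pattern score: mean acc %.4f (sd %.4f), best %.4f over %d evaluations\n",
              x$mean, if (is.na(x$sd)) 0 else x$sd, x$max, x$n_evaluations))
  invisible(x)
}
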