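# DERGA: greedy backward feature elimination over a classification
# meta-algorithm, with pattern-count accounting, optimal-pattern selection
# and parameter influence ranking.

#' Pattern counts of an exhaustive subset search
#'
#' Number of parameter combinations an exhaustive search over an
#' n-parameter database would examine, by the published closed form
#' `2 * (2^n - 1)` (twice the number of non-empty subsets).
#'
#' @param n Number of parameters (>= 1).
#' @return Integer-valued numeric.
#' @export
count_exhaustive_patterns <- function(n) {
  stopifnot(length(n) == 1, n >= 1, n == floor(n))
  2 * (2^n - 1)
}

#' Pattern counts of a DERGA run
#'
#' Number of distinct feature patterns the greedy backward-elimination pass
#' scores when run from all `n` parameters down to a single one:
#' `n * (n + 1) / 2` (the full pattern plus every leave-one-out candidate
#' at each elimination step).  For n = 18 this is 171.
#'
#' @param n Number of parameters (>= 1).
#' @return Integer-valued numeric.
#' @export
count_derga_patterns <- function(n) {
  stopifnot(length(n) == 1, n >= 1, n == floor(n))
  n * (n + 1) / 2
}

#' Total models trained by a DERGA run under a protocol
#'
#' `count_derga_patterns(n) * n_splits * n_seeds`; with 18 parameters and
#' the 25-split x 101-seed study protocol this is 431,775 models per
#' meta-algorithm.
#'
#' @param n Number of parameters.
#' @param protocol A `derga_protocol`.
#' @return Integer-valued numeric.
#' @export
count_trained_models <- function(n, protocol = split_protocol()) {
  count_derga_patterns(n) * protocol$n_splits * protocol$n_seeds
}

pattern_key <- function(pattern) paste(sort(pattern), collapse = "|")

score_stat <- function(score, statistic) {
  if (statistic == "best") score$max else score$mean
}

# score with per-run memoisation (the greedy path never revisits a pattern,
# but the exhaustive oracle and the ranking step do)
score_cached <- function(cache, algorithm, table, pattern, protocol, hyper,
                         splits) {
  key <- pattern_key(pattern)
  if (!is.null(cache[[key]])) return(cache[[key]])
  s <- score_pattern(algorithm, table, pattern, protocol, hyper, splits)
  cache[[key]] <- s
  s
}

#' Run the DERGA elimination loop
#'
#' Starting from the full pattern, each step scores every leave-one-out
#' candidate of the current pattern over the split x seed grid and
#' eliminates one feature, until `stop_at` features remain.  Under the
#' default `"backward"` policy the eliminated feature is the one whose
#' exclusion yields the HIGHEST selection statistic — i.e. the feature the
#' model misses least, standard backward elimination.  The `"literal"`
#' policy instead eliminates the feature whose exclusion scores worst; it
#' is provided for auditability and collapses accuracy early, since it
#' removes the most informative feature first.  Candidate ties break by
#' schema order of the excluded feature.
#'
#' @param table A `cohort`.
#' @param algorithm One of the five meta-algorithm identifiers.
#' @param protocol A `derga_protocol`.
#' @param hyper Hyperparameters ([default_hyper()]).
#' @param features Initial pattern (default: all schema features).
#' @param stop_at Stop when this many features remain (default 1, which
#'   makes the number of distinct patterns scored `n (n + 1) / 2`).
#' @param elimination `"backward"` (default) or `"literal"`.
#' @param statistic Selection statistic: `"mean"` (default) or `"best"`
#'   test accuracy over the grid.
#' @return An object of class `derga_trajectory`: list with `steps` (each
#'   holding `step_index`, `incoming`, `candidate_scores`, `eliminated`,
#'   `outgoing`, `outgoing_score`), `baseline_score`, `algorithm`,
#'   `features`, `statistic`, `n_patterns_scored` and the score `cache`.
#' @export
run_derga <- function(table, algorithm = "extra_trees",
                      protocol = split_protocol(), hyper = default_hyper(),
                      features = NULL, stop_at = 1,
                      elimination = c("backward", "literal"),
                      statistic = c("mean", "best")) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  elimination <- match.arg(elimination)
  statistic <- match.arg(statistic)
  stopifnot(inherits(table, "cohort"), stop_at >= 1)
  schema <- attr(table, "schema")
  fn <- schema_feature_names(schema)
  if (is.null(features)) features <- fn
  features <- fn[fn %in% features]       # canonical schema order
  stopifnot(length(features) >= 1, stop_at <= length(features))
  if (nlevels(droplevels(table$outcome)) < 2) {
    stop("cohort must hold at least 2 distinct outcome labels")
  }

  splits <- make_splits(nrow(table), table$outcome, protocol)
  cache <- new.env(parent = emptyenv())
  baseline <- score_cached(cache, algorithm, table, features, protocol,
                           hyper, splits)
  steps <- list()
  pattern <- features
  step_index <- 0L
  while (length(pattern) > stop_at) {
    step_index <- step_index + 1L
    cand <- lapply(pattern, function(f) {
      score_cached(cache, algorithm, table, setdiff(pattern, f), protocol,
                   hyper, splits)
    })
    names(cand) <- pattern
    vals <- vapply(cand, score_stat, 0, statistic = statistic)
    pick <- if (elimination == "backward") {
      which(vals == max(vals))[1]        # ties -> schema order
    } else {
      which(vals == min(vals))[1]
    }
    eliminated <- pattern[pick]
    outgoing <- setdiff(pattern, eliminated)
    steps[[step_index]] <- list(
      step_index = step_index, incoming = pattern,
      candidate_scores = cand, eliminated = eliminated,
      outgoing = outgoing, outgoing_score = cand[[pick]])
    pattern <- outgoing
  }
  structure(list(steps = steps, baseline_score = baseline,
                 algorithm = algorithm, features = features,
                 protocol = protocol, hyper = hyper,
                 statistic = statistic, elimination = elimination,
                 n_patterns_scored = length(ls(cache)),
                 cache = cache, splits = splits),
            class = "derga_trajectory")
}

#' Select the optimal pattern of a trajectory
#'
#' The optimal pattern is the argmax of the selection statistic over the
#' baseline pattern and every step's outgoing pattern; ties break toward
#' fewer features, then the earlier step.  Under `tie_break = "exact"`
#' (the default) only exactly equal scores are tied.  Under
#' `tie_break = "one_se"` every pattern whose score lies within one
#' standard error of the top score (the SE of the top pattern's mean over
#' its evaluation grid) counts as tied — the classical one-SE parsimony
#' rule, appropriate for scaled-down grids whose per-pattern scores carry
#' visible sampling noise; the full study-size grid makes the two rules
#' coincide for all practical purposes.
#'
#' @param trajectory A `derga_trajectory`.
#' @param statistic Override of the trajectory's selection statistic.
#' @param tie_break `"exact"` or `"one_se"`.
#' @return List with `pattern`, `score` (`derga_score`), `statistic_value`,
#'   `step_index` (0 = the full baseline pattern) and `algorithm`.
#' @export
select_optimal <- function(trajectory, statistic = NULL,
                           tie_break = c("exact", "one_se")) {
  stopifnot(inherits(trajectory, "derga_trajectory"))
  statistic <- statistic %||% trajectory$statistic
  tie_break <- match.arg(tie_break)
  cands <- c(list(list(pattern = trajectory$features,
                       score = trajectory$baseline_score, step_index = 0L)),
             lapply(trajectory$steps, function(s) {
               list(pattern = s$outgoing, score = s$outgoing_score,
                    step_index = s$step_index)
             }))
  vals <- vapply(cands, function(c) score_stat(c$score, statistic), 0)
  sizes <- vapply(cands, function(c) length(c$pattern), 0L)
  steps <- vapply(cands, function(c) c$step_index, 0L)
  top <- order(-vals, sizes, steps)[1]
  if (tie_break == "one_se") {
    s <- cands[[top]]$score
    se <- if (is.na(s$sd) || s$n_evaluations < 2) 0 else {
      s$sd / sqrt(s$n_evaluations)
    }
    tied <- which(vals >= vals[top] - se)
    best <- tied[order(sizes[tied], steps[tied])[1]]
  } else {
    best <- top
  }
  c(cands[[best]], list(statistic = statistic, statistic_value = vals[best],
                        algorithm = trajectory$algorithm))
}

#' Rank parameters by influence
#'
#' Features inside the optimal pattern rank first, ordered by the drop in
#' the selection statistic when each is excluded at the optimal step
#' (largest drop = most influential; "loo-drop" rank method); eliminated
#' features follow in reverse elimination order (the last-eliminated is the
#' most influential of the eliminated).
#'
#' @param trajectory A `derga_trajectory`.
#' @param optimal Result of [select_optimal()] on that trajectory.
#' @param table The cohort, needed only when the optimal pattern's
#'   leave-one-out candidates were not scored during the run (i.e. the
#'   optimum is the final pattern of a `stop_at > 1` run).
#' @return List with `ranking` (feature names, most to least influential),
#'   `loo_drop` (named numeric over the optimal pattern) and
#'   `rank_method = "loo-drop"`.
#' @export
rank_parameters <- function(trajectory, optimal = select_optimal(trajectory),
                            table = NULL) {
  opt <- optimal$pattern
  eliminated <- vapply(trajectory$steps, `[[`, "", "eliminated")
  # scores of the optimum's leave-one-out candidates: reuse the step that
  # had the optimal pattern as its incoming pattern, if any
  incoming_keys <- vapply(trajectory$steps, function(s) pattern_key(s$incoming), "")
  hit <- match(pattern_key(opt), incoming_keys)
  if (length(opt) == 1) {
    loo <- stats::setNames(numeric(1), opt)
    loo[1] <- optimal$statistic_value    # sole feature carries all signal
  } else if (!is.na(hit)) {
    cand <- trajectory$steps[[hit]]$candidate_scores
    loo <- optimal$statistic_value -
      vapply(cand[opt], score_stat, 0, statistic = optimal$statistic)
  } else {
    if (is.null(table)) {
      stop("leave-one-out scores of the optimal pattern are not in the ",
           "trajectory; supply the cohort via `table`")
    }
    loo <- vapply(opt, function(f) {
      s <- score_cached(trajectory$cache, trajectory$algorithm, table,
                        setdiff(opt, f), trajectory$protocol,
                        trajectory$hyper, trajectory$splits)
      optimal$statistic_value - score_stat(s, optimal$statistic)
    }, 0)
  }
  in_rank <- opt[order(-loo, match(opt, trajectory$features))]
  out_rank <- rev(eliminated[!(eliminated %in% opt)])
  list(ranking = c(in_rank, out_rank),
       loo_drop = loo[in_rank], rank_method = "loo-drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a DERGA feature-selection model
#'
#' The main fitting function: runs greedy backward elimination
#' ([run_derga()]) for one classification meta-algorithm, selects the
#' optimal feature pattern ([select_optimal()]) and ranks the parameters by
#' influence ([rank_parameters()]).
#'
#' @inheritParams run_derga
#' @inheritParams select_optimal
#' @return An object of class `derga`: the trajectory plus `optimal`,
#'   `ranking`, `loo_drop`, `n_records` and `call`.  Methods: `print`,
#'   `summary`, `coef` (leave-one-out accuracy drops of the optimal
#'   pattern), `predict` (refit the optimal model and classify new
#'   records), `plot` (selection statistic along the elimination path).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(200, seed = 1, constraint = NULL)
#' fit <- derga(cohort, algorithm = "decision_tree",
#'              protocol = split_protocol(n_splits = 2, n_seeds = 1),
#'              features = c("age", "crea_day2", "agvhd", "gender"))
#' print(fit)
#' coef(fit)
#' }
#' @export
derga <- function(table, algorithm = "extra_trees",
                  protocol = split_protocol(), hyper = default_hyper(),
                  features = NULL, stop_at = 1,
                  elimination = c("backward", "literal"),
                  statistic = c("mean", "best"),
                  tie_break = c("exact", "one_se")) {
  cl <- match.call()
  traj <- run_derga(table, algorithm, protocol, hyper, features, stop_at,
                    elimination, statistic)
  optimal <- select_optimal(traj, tie_break = tie_break)
  ranking <- rank_parameters(traj, optimal, table)
  obj <- traj
  obj$optimal <- optimal
  obj$ranking <- ranking$ranking
  obj$loo_drop <- ranking$loo_drop
  obj$rank_method <- ranking$rank_method
  obj$n_records <- nrow(table)
  obj$provenance <- attr(table, "provenance")
  obj$call <- cl
  class(obj) <- c("derga", "derga_trajectory")
  obj
}

#' @export
print.derga <- function(x, ...) {
  cat("DERGA fit (", x$algorithm, ", ", x$statistic,
      " test accuracy over ", x$protocol$n_splits, " splits x ",
      x$protocol$n_seeds, " seeds)\n", sep = "")
  cat(sprintf("  records: %d | initial features: %d | patterns scored: %d\n",
              x$n_records, length(x$features), x$n_patterns_scored))
  cat(sprintf("  optimal pattern (%d features, %s accuracy %.4f):\n",
              length(x$optimal$pattern), x$statistic,
              x$optimal$statistic_value))
  cat("   ", paste(x$optimal$pattern, collapse = ", "), "\n")
  cat("  ranking (most -> least influential):\n   ",
      paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' @export
summary.derga <- function(object, ...) {
  path <- data.frame(
    step = c(0, vapply(object$steps, `[[`, 0L, "step_index")),
    n_features = c(length(object$features),
                   vapply(object$steps, function(s) length(s$outgoing), 0L)),
    eliminated = c(NA, vapply(object$steps, `[[`, "", "eliminated")),
    mean_accuracy = c(object$baseline_score$mean,
                      vapply(object$steps, function(s) s$outgoing_score$mean, 0)),
    best_accuracy = c(object$baseline_score$max,
                      vapply(object$steps, function(s) s$outgoing_score$max, 0)))
  structure(list(path = path, optimal = object$optimal,
                 ranking = object$ranking, loo_drop = object$loo_drop,
                 rank_method = object$rank_method,
                 algorithm = object$algorithm, statistic = object$statistic,
                 n_records = object$n_records,
                 n_patterns_scored = object$n_patterns_scored),
            class = "summary.derga")
}

#' @export
print.summary.derga <- function(x, ...) {
  cat("DERGA elimination path (", x$algorithm, ")\n", sep = "")
  print(x$path, row.names = FALSE, digits = 4)
  cat(sprintf("\noptimal: %d features at step %d, %s accuracy %.4f\n",
              length(x$optimal$pattern), x$optimal$step_index,
              x$statistic, x$optimal$statistic_value))
  cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  cat("in-pattern leave-one-out accuracy drops (rank method:",
      x$rank_method, "):\n")
  print(round(x$loo_drop, 4))
  invisible(x)
}

#' @export
coef.derga <- function(object, ...) {
  object$loo_drop
}

#' @export
plot.derga <- function(x, ...) {
  s <- summary(x)
  graphics::plot(s$path$n_features, s$path$mean_accuracy, type = "b",
                 pch = 19, xlim = rev(range(s$path$n_features)),
                 xlab = "features remaining",
                 ylab = paste(x$statistic, "test accuracy"),
                 main = paste("DERGA elimination path:", x$algorithm), ...)
  opt_n <- length(x$optimal$pattern)
  graphics::abline(v = opt_n, lty = 2, col = "grey40")
  graphics::points(opt_n, x$optimal$statistic_value, col = "red", pch = 19,
                   cex = 1.4)
  invisible(x)
}

#' @export
predict.derga <- function(object, newdata, table, ...) {
  if (missing(table)) {
    stop("supply the training cohort via `table` (the fit stores no data)")
  }
  enc <- encode_cohort(table, object$optimal$pattern)
  model <- fit_learner(object$algorithm, enc$x, enc$y, object$hyper,
                       object$protocol$master_seed)
  if (inherits(newdata, "cohort")) newdata <- as.data.frame(newdata)
  nx <- as.matrix(newdata[, enc$feature_names, drop = FALSE])
  storage.mode(nx) <- "double"
  predict_learner(model, nx)
}

#' Exhaustive subset search (brute-force oracle)
#'
#' Scores every non-empty subset of the given features and returns the best
#' under the selection statistic.  Intended as the oracle that greedy
#' elimination is compared against on small feature sets; guarded to at
#' most 20 features.
#'
#' @inheritParams run_derga
#' @return List with `best_pattern`, `best_score`, `statistic_value` and
#'   `all_scores` (named statistic values keyed by sorted pattern).
#' @export
derga_exhaustive <- function(table, algorithm = "extra_trees",
                             protocol = split_protocol(),
                             hyper = default_hyper(), features = NULL,
                             statistic = c("mean", "best")) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  statistic <- match.arg(statistic)
  schema <- attr(table, "schema")
  fn <- schema_feature_names(schema)
  if (is.null(features)) features <- fn
  features <- fn[fn %in% features]
  n <- length(features)
  if (n > 20) stop("exhaustive search is guarded to at most 20 features")
  splits <- make_splits(nrow(table), table$outcome, protocol)
  cache <- new.env(parent = emptyenv())
  best <- NULL; best_val <- -Inf; all_vals <- numeric(0)
  for (mask in seq_len(2^n - 1)) {
    pattern <- features[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    s <- score_cached(cache, algorithm, table, pattern, protocol, hyper,
                      splits)
    v <- score_stat(s, statistic)
    all_vals[pattern_key(pattern)] <- v
    # ties toward fewer features, then enumeration order
    if (v > best_val + 1e-12 ||
        (abs(v - best_val) <= 1e-12 && !is.null(best) &&
         length(pattern) < length(best$pattern))) {
      best <- list(pattern = pattern, score = s)
      best_val <- v
    }
  }
  list(best_pattern = best$pattern, best_score = best$score,
       statistic_value = best_val, statistic = statistic,
       all_scores = all_vals)
}

#' Run DERGA under every meta-algorithm (the ensemble sweep)
#'
#' Fits [derga()] once per algorithm and reports each algorithm's optimal
#' model plus the overall winner by selection statistic.  Per-algorithm
#' failures are recorded and the sweep continues; it errors only if every
#' algorithm fails.
#'
#' @inheritParams run_derga
#' @param algorithms Algorithm identifiers (default: all five).
#' @return An object of class `derga_ensemble`: list with `fits` (named
#'   `derga` objects), `failures` (named error messages), `winner` (name of
#'   the best algorithm) and `best` (its `derga` fit).
#' @export
derga_ensemble <- function(table, algorithms = ALGORITHMS,
                           protocol = split_protocol(),
                           hyper = default_hyper(), features = NULL,
                           stop_at = 1,
                           elimination = c("backward", "literal"),
                           statistic = c("mean", "best"),
                           tie_break = c("exact", "one_se")) {
  stopifnot(length(algorithms) >= 1)
  algorithms <- vapply(algorithms, match.arg, "", choices = ALGORITHMS)
  fits <- list(); failures <- character(0)
  for (alg in algorithms) {
    res <- tryCatch(
      derga(table, alg, protocol, hyper, features, stop_at, elimination,
            statistic, tie_break),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[alg] <- conditionMessage(res)
    } else {
      fits[[alg]] <- res
    }
  }
  if (length(fits) == 0) {
    stop("every algorithm failed; first error: ", failures[1])
  }
  vals <- vapply(fits, function(f) f$optimal$statistic_value, 0)
  winner <- names(fits)[which.max(vals)]
  structure(list(fits = fits, failures = failures, winner = winner,
                 best = fits[[winner]]),
            class = "derga_ensemble")
}

#' @export
print.derga_ensemble <- function(x, ...) {
  cat("DERGA ensemble over", length(x$fits), "meta-algorithm(s)\n")
  for (alg in names(x$fits)) {
    f <- x$fits[[alg]]
    cat(sprintf("  %-18s %s acc %.4f with %d features%s\n", alg,
                f$statistic, f$optimal$statistic_value,
                length(f$optimal$pattern),
                if (alg == x$winner) "  <- winner" else ""))
  }
  if (length(x$failures) > 0) {
    cat("  failed:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.derga_ensemble <- function(object, ...) {
  df <- do.call(rbind, lapply(names(object$fits), function(alg) {
    f <- object$fits[[alg]]
    data.frame(algorithm = alg, n_features = length(f$optimal$pattern),
               statistic_value = f$optimal$statistic_value,
               best_accuracy = f$optimal$score$max,
               pattern = paste(f$optimal$pattern, collapse = ","))
  }))
  df[order(-df$statistic_value), ]
}
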