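# Brute-force subset counts used as the independent oracle for the closed
# forms: enumerate every non-empty subset of n items.
enumerate_subsets <- function(n) {
  unlist(lapply(seq_len(n), function(k) utils::combn(n, k, simplify = FALSE)),
         recursive = FALSE)
}

test_that("pattern-count closed forms agree with subset enumeration", {
  for (n in 1:6) {
    expect_equal(count_exhaustive_patterns(n),
                 2 * length(enumerate_subsets(n)))
  }
  expect_equal(count_exhaustive_patterns(18), 524286)
  expect_equal(count_derga_patterns(18), 171)
  expect_equal(count_derga_patterns(1), 1)
  expect_equal(count_derga_patterns(4), 10)
  expect_error(count_exhaustive_patterns(0))
  expect_error(count_derga_patterns(0))
})

test_that("trained-model accounting multiplies patterns by the grid", {
  paper <- split_protocol(n_splits = 25, n_seeds = 101)
  expect_equal(count_trained_models(18, paper), 431775)
  expect_equal(5 * count_trained_models(18, paper), 2158875)
  expect_equal(count_trained_models(1, split_protocol(n_splits = 1,
                                                      n_seeds = 1)), 1)
  # property: product identity under random protocols
  set.seed(7)
  for (i in 1:10) {
    n <- sample(1:25, 1); s <- sample(1:30, 1); k <- sample(1:120, 1)
    expect_equal(count_trained_models(n, split_protocol(n_splits = s,
                                                        n_seeds = k)),
                 count_derga_patterns(n) * s * k)
  }
})

test_that("the elimination trajectory is nested and conserves the feature set", {
  co <- generate_cohort(250, seed = 17, constraint = NULL)
  feats <- schema_feature_names()[c(2, 4, 9, 11, 14, 16)]
  traj <- run_derga(co, "decision_tree", fast_protocol(), features = feats)
  n <- length(feats)
  expect_length(traj$steps, n - 1)
  expect_equal(traj$n_patterns_scored, count_derga_patterns(n))
  for (s in traj$steps) {
    expect_length(s$candidate_scores, length(s$incoming))
    expect_setequal(s$outgoing, setdiff(s$incoming, s$eliminated))
    expect_true(all(s$outgoing %in% s$incoming))
  }
  # elimination order plus final pattern partitions the initial features
  elim <- vapply(traj$steps, `[[`, "", "eliminated")
  final <- traj$steps[[length(traj$steps)]]$outgoing
  expect_setequal(c(elim, final), feats)
  expect_false(anyDuplicated(c(elim, final)) > 0)
})

test_that("optimal-pattern selection is the argmax with parsimony tie-breaks", {
  fake_score <- function(acc) structure(list(mean = acc, sd = 0, max = acc,
                                             n_evaluations = 1L),
                                        class = "derga_score")
  fake_traj <- function(accs) {
    feats <- LETTERS[1:4]
    steps <- lapply(seq_along(accs[-1]), function(i) {
      list(step_index = i, incoming = feats[1:(5 - i)],
           candidate_scores = setNames(rep(list(fake_score(accs[i + 1])),
                                           5 - i), feats[1:(5 - i)]),
           eliminated = feats[5 - i], outgoing = feats[1:(4 - i)],
           outgoing_score = fake_score(accs[i + 1]))
    })
    structure(list(steps = steps, baseline_score = fake_score(accs[1]),
                   algorithm = "decision_tree", features = feats,
                   statistic = "mean", elimination = "backward"),
              class = "derga_trajectory")
  }
  # rising then falling accuracy: the third scored pattern wins
  opt <- select_optimal(fake_traj(c(0.80, 0.85, 0.93, 0.90)))
  expect_identical(opt$step_index, 2L)
  expect_identical(opt$pattern, c("A", "B"))
  expect_equal(opt$statistic_value, 0.93)
  # all equal: the smallest pattern wins
  opt <- select_optimal(fake_traj(c(0.9, 0.9, 0.9, 0.9)))
  expect_identical(opt$pattern, "A")
})

test_that("ranking places optimal-pattern features first, then reverse elimination", {
  co <- separable_cohort(n = 300, seed = 23)
  feats <- c("dri", "gender", "age")
  fit <- derga(co, "decision_tree", fast_protocol(), features = feats)
  # the DRI code alone decides the outcome, so it must lead the ranking
  expect_identical(fit$ranking[1], "dri")
  expect_setequal(fit$ranking, feats)
  # eliminated features appear in reverse elimination order
  elim <- vapply(fit$steps, `[[`, "", "eliminated")
  out_rank <- fit$ranking[!(fit$ranking %in% fit$optimal$pattern)]
  expect_identical(out_rank, rev(elim[!(elim %in% fit$optimal$pattern)]))
  expect_identical(fit$rank_method, "loo-drop")
  expect_named(coef(fit))
})

test_that("greedy elimination matches the exhaustive oracle on separable data", {
  co <- separable_cohort(n = 300, seed = 29)
  feats <- c("dri", "gender", "age", "cd34")
  pr <- fast_protocol()
  fit <- derga(co, "decision_tree", pr, features = feats)
  oracle <- derga_exhaustive(co, "decision_tree", pr, features = feats)
  expect_length(oracle$all_scores, 15)       # 2^4 - 1 subsets
  expect_equal(fit$optimal$statistic_value, oracle$statistic_value,
               tolerance = 1e-9)
  expect_equal(fit$optimal$statistic_value, 1.0)
  # on any data, greedy explores a subset of patterns, so it cannot beat
  # the oracle
  noisy <- generate_cohort(200, seed = 31, constraint = NULL)
  gfit <- derga(noisy, "decision_tree", pr, features = feats)
  gorc <- derga_exhaustive(noisy, "decision_tree", pr, features = feats)
  expect_lte(gfit$optimal$statistic_value, gorc$statistic_value + 1e-12)
})

test_that("ranking can re-score the optimum when elimination stops early", {
  co <- separable_cohort(n = 250, seed = 61)
  feats <- c("dri", "gender", "age", "cd34")
  traj <- run_derga(co, "decision_tree", fast_protocol(), features = feats,
                    stop_at = 3)
  expect_length(traj$steps, 1)
  opt <- select_optimal(traj)
  rk <- rank_parameters(traj, opt, table = co)
  expect_setequal(rk$ranking, feats)
  expect_identical(rk$ranking[1], "dri")
  # without the cohort the leave-one-out scores cannot be recomputed
  if (length(opt$pattern) == 3 && is.na(match(
        paste(sort(opt$pattern), collapse = "|"),
        vapply(traj$steps, function(s) paste(sort(s$incoming), collapse = "|"), "")))) {
    expect_error(rank_parameters(traj, opt), "supply the cohort")
  }
})

test_that("literal elimination removes the most informative feature first", {
  co <- separable_cohort(n = 300, seed = 37)
  feats <- c("dri", "gender", "age")
  lit <- run_derga(co, "decision_tree", fast_protocol(), features = feats,
                   elimination = "literal")
  # dropping `dri` destroys the signal, so the literal policy drops it first
  expect_identical(lit$steps[[1]]$eliminated, "dri")
  bwd <- run_derga(co, "decision_tree", fast_protocol(), features = feats)
  expect_false(identical(bwd$steps[[1]]$eliminated, "dri"))
})

test_that("the ensemble sweep reports per-algorithm optima and a winner", {
  co <- separable_cohort(n = 250, seed = 41)
  feats <- c("dri", "gender")
  ens <- derga_ensemble(co, c("decision_tree", "ada_boost"),
                        fast_protocol(), features = feats)
  expect_named(ens$fits, c("decision_tree", "ada_boost"))
  expect_true(ens$winner %in% names(ens$fits))
  expect_equal(ens$best$optimal$statistic_value,
               max(vapply(ens$fits, function(f) f$optimal$statistic_value, 0)))
  # degenerate single-algorithm ensemble equals the plain fit
  one <- derga_ensemble(co, "decision_tree", fast_protocol(),
                        features = feats)
  fit <- derga(co, "decision_tree", fast_protocol(), features = feats)
  expect_identical(one$best$optimal$pattern, fit$optimal$pattern)
  expect_equal(one$best$optimal$statistic_value,
               fit$optimal$statistic_value)
})

test_that("derga fits expose coherent methods", {
  co <- separable_cohort(n = 250, seed = 43)
  fit <- derga(co, "decision_tree", fast_protocol(),
               features = c("dri", "gender", "cd34"))
  expect_s3_class(fit, "derga")
  expect_output(print(fit), "optimal pattern")
  s <- summary(fit)
  expect_equal(nrow(s$path), 3)            # baseline + 2 steps
  expect_output(print(s), "elimination path")
  # selection statistic of the optimum is never below the full baseline
  expect_gte(fit$optimal$statistic_value, fit$baseline_score$mean)
  # prediction on the training records recovers the deterministic rule
  pred <- predict(fit, as.data.frame(co)[1:20, ], table = co)
  expect_identical(as.character(pred), as.character(co$outcome[1:20]))
})
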