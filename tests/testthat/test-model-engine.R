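test_that("split arithmetic follows the floor rule", {
  labs <- factor(rep(c("alive", "dead", "alive_lt24"), c(280, 170, 114)))
  sp <- make_splits(564, labs, fast_protocol())[[1]]
  expect_length(sp$train, 451)
  expect_length(sp$test, 113)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:564)

  sp10 <- make_splits(10, factor(rep(c("a", "b"), 5)),
                      fast_protocol())[[1]]
  expect_length(sp10$train, 8)
  expect_length(sp10$test, 2)
})

test_that("stratified splits keep per-class proportions within one record", {
  labs <- factor(rep(c("alive", "dead", "alive_lt24"), c(280, 170, 114)))
  splits <- make_splits(564, labs, fast_protocol(n_splits = 5))
  for (sp in splits) {
    got <- table(labs[sp$train])
    want <- 0.8 * table(labs)
    expect_true(all(abs(as.numeric(got) - as.numeric(want)) <= 1))
  }
  # determinism: the same protocol reproduces identical index sets
  again <- make_splits(564, labs, fast_protocol(n_splits = 5))
  expect_identical(splits, again)
})

test_that("performance indices match an independent hand computation", {
  set.seed(42)
  lev <- c("alive", "dead", "alive_lt24")
  for (rep in 1:5) {
    truth <- factor(sample(lev, 200, TRUE, prob = c(0.5, 0.3, 0.2)),
                    levels = lev)
    pred <- factor(sample(lev, 200, TRUE), levels = lev)
    m <- multiclass_metrics(truth, pred)

    # independent oracle: naive loops over classes
    acc <- mean(truth == pred)
    prc <- rec <- f1c <- numeric(3)
    for (i in seq_along(lev)) {
      tp <- sum(truth == lev[i] & pred == lev[i])
      prc[i] <- if (sum(pred == lev[i]) > 0) tp / sum(pred == lev[i]) else 0
      rec[i] <- if (sum(truth == lev[i]) > 0) tp / sum(truth == lev[i]) else 0
      f1c[i] <- if (prc[i] + rec[i] > 0) {
        2 * prc[i] * rec[i] / (prc[i] + rec[i])
      } else 0
    }
    expect_equal(m$accuracy, acc)
    expect_equal(m$precision, mean(prc))
    expect_equal(m$recall, mean(rec))
    expect_equal(m$f1, mean(f1c))
    expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion))

    # macro F1 is invariant under a permutation of class labels
    map <- setNames(lev[c(3, 1, 2)], lev)
    m2 <- multiclass_metrics(factor(map[as.character(truth)], levels = lev),
                             factor(map[as.character(pred)], levels = lev))
    expect_equal(m2$f1, m$f1)
    expect_equal(m2$accuracy, m$accuracy)
  }
})

test_that("a constant single-class prediction yields the degenerate macro values", {
  lev <- c("alive", "dead", "alive_lt24")
  truth <- factor(rep(lev, c(10, 6, 4)), levels = lev)
  pred <- factor(rep("alive", 20), levels = lev)
  m <- multiclass_metrics(truth, pred)
  expect_equal(m$recall, (1 + 0 + 0) / 3)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$per_class$f1[2:3], c(0, 0))
})

test_that("a perfectly separable outcome is learnt exactly on held-out data", {
  co <- separable_cohort()
  sp <- make_splits(nrow(co), co$outcome, fast_protocol())[[1]]
  ev <- train_and_evaluate("decision_tree", co, "dri", sp, model_seed = 1)
  expect_equal(ev$metrics$accuracy, 1.0)
  for (alg in c("extra_trees", "gradient_boosting", "cat_boost")) {
    ev <- train_and_evaluate(alg, co, "dri", sp, model_seed = 1)
    expect_gte(ev$metrics$accuracy, 0.99)
  }
  # depth-1 stumps cannot carve three classes out of one code; depth 2 can
  hp <- default_hyper(); hp$ada_boost$max_depth <- 2
  ev <- train_and_evaluate("ada_boost", co, "dri", sp, 1, hyper = hp)
  expect_equal(ev$metrics$accuracy, 1.0)
})

test_that("shuffled labels collapse accuracy to the majority-class share", {
  co <- generate_cohort(600, seed = 13, constraint = NULL)
  df <- as.data.frame(co)
  set.seed(99)
  df$outcome <- sample(as.character(df$outcome))
  coshuf <- as_cohort(df)
  p <- as.numeric(table(coshuf$outcome)) / nrow(coshuf)
  share <- max(p)                 # majority-vote ceiling under the null
  floorp <- sum(p^2)              # label-memorisation floor under the null
  sc <- score_pattern("extra_trees", coshuf, c("age", "ldh_day2", "cd34"),
                      fast_protocol(n_splits = 3, n_seeds = 2))
  se <- sc$sd / sqrt(sc$n_evaluations)
  expect_lt(sc$mean, share + 3 * se + 0.02)
  expect_gt(sc$mean, floorp - 3 * se - 0.02)
})

test_that("pattern scoring runs the full grid deterministically", {
  co <- generate_cohort(150, seed = 14, constraint = NULL)
  pr <- fast_protocol(n_splits = 3, n_seeds = 2, master_seed = 4)
  s1 <- score_pattern("decision_tree", co, c("age", "crea_day2"), pr)
  expect_identical(s1$n_evaluations, 6L)
  s2 <- score_pattern("decision_tree", co, c("age", "crea_day2"), pr)
  expect_identical(s1$mean, s2$mean)
  expect_identical(s1$max, s2$max)
  expect_gte(s1$max, s1$mean)
  # the retained best evaluation is one of the grid's cells
  expect_true(s1$best$split_seed %in% (pr$master_seed + 1:3))
  expect_true(s1$best$model_seed %in% (pr$master_seed + 1:2))
})

test_that("degenerate training labels abort evaluation", {
  df <- tiny_cohort_df()[c(1, 1, 1, 2, 2, 2), ]
  df$outcome <- c("alive", "alive", "alive", "dead", "dead", "dead")
  co <- as_cohort(df)
  split <- list(train = 1:3, test = 4:6, split_seed = 1)
  expect_error(train_and_evaluate("decision_tree", co, "age", split, 1),
               "single class")
})
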