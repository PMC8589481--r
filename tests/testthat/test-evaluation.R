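test_that("recall@K matches hand counts and brute-force intersection", {
  ## perfect retrieval
  expect_equal(recall_at_k(list(u = "a"), list(u = "a"), 1), 1.0)
  ## one of two relevant retrieved
  expect_equal(recall_at_k(list(u = c("a", "c")), list(u = c("a", "b")), 2),
               0.5)
  ## users without relevant items are excluded from the mean
  expect_equal(recall_at_k(list(u1 = c("a", "c"), u2 = c("x", "y")),
                           list(u1 = c("a", "b"), u2 = character(0)), 2),
               0.5)
  expect_error(recall_at_k(list(u = "a"), list(u = character(0)), 1),
               "no user has relevant")
  expect_error(recall_at_k(list(u = c("a", "a")), list(u = "a"), 1),
               "duplicates")

  ## nondecreasing in K; brute force agreement on random instances
  set.seed(4)
  for (rep in 1:10) {
    items <- sprintf("i%02d", 1:20)
    ranked <- list(u1 = sample(items), u2 = sample(items))
    relevant <- list(u1 = sample(items, 4), u2 = sample(items, 6))
    vals <- vapply(1:20, function(k) recall_at_k(ranked, relevant, k),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
    for (k in c(1, 5, 20)) {
      brute <- mean(c(
        sum(ranked$u1[seq_len(k)] %in% relevant$u1) / length(relevant$u1),
        sum(ranked$u2[seq_len(k)] %in% relevant$u2) / length(relevant$u2)))
      expect_equal(recall_at_k(ranked, relevant, k), brute)
    }
  }
})

test_that("AUC equals the pairwise ordering probability with half ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  ## 4-point case: 3 of 4 positive-negative pairs correctly ordered
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")

  ## brute-force pair counting on random instances
  set.seed(5)
  for (rep in 1:10) {
    s <- round(runif(30), 2)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(auc_score(s, y), brute)
  }
})

test_that("splits are disjoint, user-stratified and seed-stable", {
  w <- small_world()
  sp <- split_interactions(w$interactions, seed = 3)
  idx <- lapply(sp, function(d) paste(d$user, d$item, seq_len(nrow(d))))
  expect_equal(nrow(sp$train) + nrow(sp$valid) + nrow(sp$test),
               nrow(w$interactions))
  ## row-level disjointness via rownames of the original frame
  rn <- lapply(sp, rownames)
  expect_length(intersect(rn$train, rn$test), 0)
  expect_length(intersect(rn$train, rn$valid), 0)
  ## stratification: every user appears in every part (30 records each)
  expect_setequal(unique(sp$train$user), unique(w$interactions$user))
  expect_setequal(unique(sp$test$user), unique(w$interactions$user))
  ## 6:2:2 proportions per user
  expect_equal(unname(table(sp$train$user))[1], 18)
  expect_equal(unname(table(sp$test$user))[1], 6)
  expect_identical(sp, split_interactions(w$interactions, seed = 3))
  expect_false(identical(sp$train, split_interactions(w$interactions,
                                                      seed = 4)$train))
})

test_that("evaluate_model ranks held-out positives against non-consumed
           items", {
  m <- small_kgmr()
  sp <- split_interactions(small_world()$interactions, seed = 11)
  ev <- evaluate_model(m, sp, k = 10)
  expect_true(ev$recall_at_k >= 0 && ev$recall_at_k <= 1)
  expect_true(ev$auc >= 0 && ev$auc <= 1)
  expect_gt(ev$n_users, 0)
})

test_that("the ablation harness is deterministic with one row per
           configuration", {
  w <- small_world()
  cfg <- kgmr_config(epochs = 2L, kg_pretrain_epochs = 10L, sg_epochs = 5L)
  ab <- run_ablation(w, configs = list(base = character(0),
                                       also_base = character(0),
                                       full = c("text", "image")),
                     seeds = 1:3, config = cfg)
  expect_equal(nrow(ab$table), 3L)
  expect_equal(nrow(ab$per_seed), 9L)
  ## identical configurations produce identical per-seed metrics
  expect_equal(ab$per_seed$recall[ab$per_seed$model == "base"],
               ab$per_seed$recall[ab$per_seed$model == "also_base"])
  expect_output(print(ab), "Model\\s+Recall")

  expect_error(run_ablation(w, configs = list(a = character(0)),
                            seeds = 1:3), "at least 2")
  expect_error(run_ablation(w, seeds = 1:2), "at least 3")
  expect_error(run_ablation(w, configs = list(a = character(0), b = "video"),
                            seeds = 1:3), "harness error")
})
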