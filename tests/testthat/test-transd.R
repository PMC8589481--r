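test_that("mapping matrix is the outer product plus a diagonal identity", {
  ## zero relation projection: plain (possibly rectangular) identity
  expect_equal(mapping_matrix(c(0, 0), c(0, 0)), diag(2))
  M <- mapping_matrix(c(0, 0, 0), c(0, 0))        # m = 3, n = 2
  expect_equal(M, rbind(diag(2), 0))

  ## hand-worked 2x2 case
  expect_equal(mapping_matrix(c(1, 0), c(0, 1)),
               matrix(c(1, 0, 1, 1), 2, 2))

  ## algebraic identity M h = pad(h) + r_p (e_p . h)
  set.seed(1)
  for (i in 1:20) {
    inst <- random_transd_instance(sample(2:8, 1), sample(2:8, 1))
    lhs <- drop(mapping_matrix(inst$r_p, inst$e_p) %*% inst$e)
    rhs <- transd_project(inst$e, inst$e_p, inst$r_p)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("vector-form projection equals the explicit matrix product", {
  ## identity mapping when the relation projection vanishes
  h <- c(1, 1)
  expect_equal(transd_project(h, c(1, 0), c(0, 0)), h)

  ## hand evaluation: h + r_p (h_p . h)
  expect_equal(transd_project(c(1, 1), c(1, 0), c(2, 0)), c(3, 1))

  ## brute-force matrix oracle on 100 random small instances
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    inst <- random_transd_instance(sample(1:8, 1), sample(1:8, 1))
    explicit <- drop(mapping_matrix(inst$r_p, inst$e_p) %*% inst$e)
    vecform <- transd_project(inst$e, inst$e_p, inst$r_p)
    worst <- max(worst, max(abs(explicit - vecform)))
  }
  expect_lt(worst, 1e-10)

  expect_error(transd_project(1:3, 1:2, 1:2), "shape error")
})

test_that("distance score is squared L2, zero iff exact translation", {
  expect_equal(transd_score(c(1, 0), c(0, 1), c(1, 1)), 0)
  expect_equal(transd_score(c(0, 0), c(3, 4), c(0, 0)), 25)
  ## permutation invariance
  set.seed(2)
  h <- rnorm(5); r <- rnorm(5); t <- rnorm(5); p <- sample(5)
  expect_equal(transd_score(h[p], r[p], t[p]), transd_score(h, r, t))
  ## nonnegativity on random inputs
  for (i in 1:20) {
    s <- transd_score(rnorm(4), rnorm(4), rnorm(4))
    expect_gte(s, 0)
  }
})

test_that("margin loss is the pairwise hinge with the stated properties", {
  tr <- generate_kg(tiny_schema(3, 4), 1, seed = 1)
  params <- transd_params(tr, 4, 4, margin = 1, seed = 1)

  ## hand-worked single pair: max(0, 1 + 1 - 0) = 2
  ## (construct params scoring pos = 1, neg = 0 via direct surgery)
  p2 <- params
  p2$ent[] <- 0; p2$ent_p[] <- 0; p2$rel_p[] <- 0
  p2$rel["has_symptom", ] <- c(1, 0, 0, 0)
  pos <- tr[1, ]
  neg <- pos; neg$tail <- setdiff(unique(tr$tail), pos$tail)[1]
  p2$ent[neg$tail, ] <- c(1, 0, 0, 0)   # f(pos) = 1, f(neg) = 0
  expect_equal(transd_margin_loss(pos, neg, p2), 2)

  ## fully separated batches give exactly zero
  p3 <- p2
  p3$ent[neg$tail, ] <- 0                    # undo: f(symptom02) back to 1
  p3$ent["symptom01", ] <- c(1, 0, 0, 0)     # (h, r, symptom01) scores 0
  pos3 <- data.frame(head = "disease01", relation = "has_symptom",
                     tail = "symptom01")
  neg3 <- data.frame(head = "disease01", relation = "has_symptom",
                     tail = "symptom02")     # scores 1 = 0 + margin
  expect_identical(transd_margin_loss(pos3, neg3, p3), 0)

  ## monotone nondecreasing in the margin, scores held fixed
  losses <- vapply(c(0.5, 1, 2, 4), function(g) {
    pg <- p2; pg$margin <- g
    transd_margin_loss(tr, tr[sample(nrow(tr)), ], pg)
  }, numeric(1))
  expect_true(all(diff(losses) >= 0))

  expect_error(transd_margin_loss(tr[0, ], tr[0, ], params), "nonempty")
  expect_error(transd_margin_loss(tr[1:2, ], tr[1, ], params), "matched")
})

test_that("corruption replaces exactly one end with a same-type entity", {
  tr <- generate_kg(tiny_schema(4, 2), 1, seed = 1)
  vocab <- unique(c(tr$head, tr$tail))

  ## forced choice with two tails: corruption is the other tail (when the
  ## tail side is chosen) or another disease
  set.seed(1)
  for (i in 1:50) {
    out <- corrupt_triple(tr[1, ], vocab)
    changed_head <- out$head != tr$head[1]
    changed_tail <- out$tail != tr$tail[1]
    expect_true(xor(changed_head, changed_tail))
    if (changed_tail) expect_equal(out$tail, setdiff(c("symptom01",
                                                       "symptom02"),
                                                     tr$tail[1]))
  }

  ## head-vs-tail frequency is a fair coin
  set.seed(7)
  n <- 10000L
  heads <- 0L
  for (i in seq_len(n)) {
    out <- corrupt_triple(tr[1, ], vocab)
    if (out$head != tr$head[1]) heads <- heads + 1L
  }
  expect_lt(abs(heads / n - 0.5), 3 * sqrt(0.25 / n))

  ## impossible corruption errors out
  one <- data.frame(head = "disease01", relation = "has_symptom",
                    tail = "symptom01")
  expect_error(corrupt_triple(one, c("disease01", "symptom01")),
               "sampling error")
})

test_that("training drives the hinge to zero on a separable instance", {
  one <- data.frame(head = "disease01", relation = "has_symptom",
                    tail = "symptom01", stringsAsFactors = FALSE)
  two <- rbind(one, data.frame(head = "disease01",
                               relation = "has_symptom",
                               tail = "symptom02"))
  fit <- transd(two[1, ], dim = 8, epochs = 50, seed = 2)
  expect_equal(utils::tail(fit$trace, 1), 0)
})

test_that("zero learning rate is a no-op and training is deterministic", {
  tr <- generate_kg(tiny_schema(4, 6), 0.8, seed = 1)
  f0 <- transd(tr, dim = 8, epochs = 3, lr = 0, seed = 5)
  init <- transd_params(tr, 8, 8, 1, seed = 5)
  expect_equal(f0$params$ent, init$ent)
  expect_equal(f0$params$rel, init$rel)
  expect_equal(length(unique(round(f0$trace, 12))), 1L)

  f1 <- transd(tr, dim = 8, epochs = 5, seed = 6)
  f2 <- transd(tr, dim = 8, epochs = 5, seed = 6)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$params, f2$params)
})

test_that("link prediction ranks candidates and reduces mean rank", {
  tr <- generate_kg(tiny_schema(6, 8), 0.5, seed = 2)

  ## single candidate is a forced hit
  fit <- transd(tr, dim = 8, epochs = 5, seed = 1)
  lp1 <- link_predict(fit, tr[1, ], candidates = tr$tail[1], k = 1)
  expect_equal(lp1$hits_at_k, 1.0)

  ## untrained seeded params rank ~uniformly: hits@10 ~ 10/N
  big <- generate_kg(tiny_schema(20, 30), 0.4, seed = 3)
  p0 <- transd_params(big, 8, 8, 1, seed = 9)
  qs <- big[rep(seq_len(nrow(big)), length.out = 250), ]
  lp0 <- link_predict(p0, qs, k = 10)
  expected <- 10 / lp0$n_candidates
  se <- sqrt(expected * (1 - expected) / nrow(qs))
  expect_lt(abs(lp0$hits_at_k - expected), 3 * se)

  ## training reduces the mean rank of true tails relative to epoch 0
  fit2 <- transd(tr, dim = 16, epochs = 60, seed = 4)
  before <- link_predict(transd_params(tr, 16, 16, 1, seed = 4), tr,
                         known = tr)
  after <- link_predict(fit2, tr)
  expect_lt(after$mean_rank, before$mean_rank)

  ## the filtered setting never worsens the rank of the true tail
  raw <- link_predict(fit2, tr, filtered = FALSE)
  fil <- link_predict(fit2, tr, filtered = TRUE)
  expect_true(all(fil$ranks <= raw$ranks))

  ## unknown ids raise vocabulary errors
  bad <- data.frame(head = "nope01", relation = "has_symptom",
                    tail = "symptom01")
  expect_error(link_predict(fit, bad), "vocabulary error")
  expect_error(rank_tails(fit, "nope01", "has_symptom"), "vocabulary error")

  ## rank_tails orders by ascending distance score
  rt <- rank_tails(fit2, tr$head[1], "has_symptom")
  expect_false(is.unsorted(rt$score))
})

test_that("fitted embeddings round-trip through the TSV writer", {
  tr <- generate_kg(tiny_schema(3, 3), 1, seed = 1)
  fit <- transd(tr, dim = 4, epochs = 2, seed = 1)
  d <- withr::local_tempdir()
  write_transd(fit, d)
  ent <- read_vectors(file.path(d, "entity.tsv"))
  expect_equal(unname(ent), unname(fit$params$ent), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(ent, "meta")$margin, 1)
})
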