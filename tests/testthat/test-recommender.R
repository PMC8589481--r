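random_cross_params <- function(d) {
  list(w_vv = rnorm(d), w_ev = rnorm(d), w_ve = rnorm(d), w_ee = rnorm(d),
       b_v = rnorm(d), b_e = rnorm(d))
}

test_that("cross-compression matches hand arithmetic and the elementwise
           oracle", {
  ## hand-worked case: C = v e^T, only w_vv nonzero
  p <- list(w_vv = c(1, 0), w_ev = c(0, 0), w_ve = c(0, 0), w_ee = c(0, 0),
            b_v = c(0, 0), b_e = c(0, 0))
  out <- cross_compress(c(1, 2), c(3, 4), p)
  expect_equal(out$v, c(3, 6))
  expect_equal(out$e, c(0, 0))

  ## zero entity vector annihilates C: outputs are the biases
  p2 <- random_cross_params(3)
  out2 <- cross_compress(c(1, -2, 3), c(0, 0, 0), p2)
  expect_equal(out2$v, p2$b_v)
  expect_equal(out2$e, p2$b_e)

  ## brute-force oracle on 50 random instances, d <= 8
  set.seed(10)
  worst <- 0
  for (i in 1:50) {
    d <- sample(2:8, 1)
    p3 <- random_cross_params(d)
    v <- rnorm(d); e <- rnorm(d)
    C <- matrix(0, d, d)
    for (a in seq_len(d)) for (b in seq_len(d)) C[a, b] <- v[a] * e[b]
    ora_v <- drop(C %*% p3$w_vv) + drop(t(C) %*% p3$w_ev) + p3$b_v
    ora_e <- drop(C %*% p3$w_ve) + drop(t(C) %*% p3$w_ee) + p3$b_e
    out3 <- cross_compress(v, e, p3)
    worst <- max(worst, max(abs(out3$v - ora_v)), max(abs(out3$e - ora_e)))
  }
  expect_lt(worst, 1e-10)

  expect_error(cross_compress(1:3, 1:2, p), "shape error")
})

test_that("click prediction is a proper probability with the sigmoid
           fixed points", {
  m <- small_kgmr()

  ## zero final layer: sigmoid(0) = 0.5 exactly
  m0 <- m
  m0$params$w_c2[] <- 0
  m0$params$b_c2 <- 0
  expect_identical(predict_click(m0, m$users[1], kg_items_of(m)[1]), 0.5)

  ## determinism and range over many pairs
  set.seed(1)
  us <- sample(m$users, 1000, replace = TRUE)
  is <- sample(kg_items_of(m), 1000, replace = TRUE)
  p1 <- predict(m, data.frame(user = us, item = is))
  p2 <- predict(m, data.frame(user = us, item = is))
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))

  expect_error(predict_click(m, "ghost", kg_items_of(m)[1]),
               "vocabulary error")
})

test_that("tail prediction scores by sigmoid inner-product similarity", {
  expect_equal(tail_similarity(c(1, 0), c(1, 0)), plogis(1))
  expect_equal(tail_similarity(c(1, 0), c(0, 1)), 0.5)

  ## strictly increasing in the inner product
  sims <- vapply(seq(-3, 3, by = 0.5),
                 function(a) tail_similarity(c(a, 0), c(1, 0)), numeric(1))
  expect_true(all(diff(sims) > 0))

  m <- small_kgmr()
  v <- predict_tail(m, m$entities[1], m$relations[1])
  expect_length(v, m$config$d)
  expect_error(predict_tail(m, "ghost", m$relations[1]), "vocabulary error")
})

test_that("joint loss decomposes exactly into its three printed terms", {
  m <- small_kgmr()
  w <- small_world()
  tri <- w$triples[1:40, ]
  set.seed(2)
  neg <- tri
  neg$tail <- sample(neg$tail)
  neg <- neg[neg$tail != tri$tail, ][1:20, ]
  pos <- tri[seq_len(nrow(neg)), ]
  jl <- joint_loss(m, w$interactions[1:80, ], pos, neg)
  expect_identical(jl$total, jl$L_RS + jl$L_KG + jl$L_REG)
  expect_gte(jl$L_REG, 0)

  ## lambda2 scaling is linear in the regularizer
  jl2 <- joint_loss(m, w$interactions[1:80, ], pos, neg,
                    lambda2 = 2 * jl$lambda2)
  expect_equal(jl2$L_REG, 2 * jl$L_REG)

  ## lambda1 = lambda2 = 0 leaves only the cross-entropy
  jl0 <- joint_loss(m, w$interactions[1:80, ], pos, neg, lambda1 = 0,
                    lambda2 = 0)
  expect_equal(jl0$total, jl0$L_RS)
  expect_error(joint_loss(m, w$interactions[0, ], pos, neg), "nonempty")
})

test_that("task steps touch disjoint parameter blocks", {
  m <- small_kgmr()
  w <- small_world()
  tri <- w$triples[1:30, ]
  ents <- unique(c(w$triples$head, w$triples$tail))
  set.seed(3)
  neg <- kgmedrec:::corrupt_batch(tri, ents, character())

  kg <- kgmr_step(m, "kg", tri, neg)
  expect_identical(kg$params$user_emb, m$params$user_emb)
  expect_identical(kg$params$W_u1, m$params$W_u1)
  expect_identical(kg$params$W_u2, m$params$W_u2)
  expect_identical(kg$params$W_c1, m$params$W_c1)
  expect_identical(kg$params$w_c2, m$params$w_c2)
  expect_false(identical(kg$params$item_emb, m$params$item_emb))
  expect_false(identical(kg$params$rel_emb, m$params$rel_emb))
  expect_false(identical(kg$params$W_t, m$params$W_t))

  rs <- kgmr_step(m, "rs", w$interactions[1:60, ])
  expect_identical(rs$params$rel_emb, m$params$rel_emb)
  expect_identical(rs$params$W_r, m$params$W_r)
  expect_identical(rs$params$W_t, m$params$W_t)
  expect_false(identical(rs$params$user_emb, m$params$user_emb))
  expect_false(identical(rs$params$W_c1, m$params$W_c1))
})

test_that("joint training is reproducible and reduces the click loss", {
  w <- small_world()
  feats <- small_features()
  cfg <- kgmr_config(epochs = 5L)
  f1 <- kgmr(w, config = cfg, seed = 17, features = feats)
  f2 <- kgmr(w, config = cfg, seed = 17, features = feats)
  expect_identical(f1$trace, f2$trace)
  expect_lt(utils::tail(f1$trace$L_RS, 1), f1$trace$L_RS[1])
  ## reported totals recompose exactly every epoch
  expect_equal(f1$trace$total, f1$trace$L_RS + f1$trace$L_KG +
                 f1$trace$L_REG)
})

test_that("interactions outside the KG are rejected as a configuration
           error", {
  w <- small_world()
  bad <- w$interactions
  bad$item[1] <- "unlisted99"
  expect_error(kgmr(w, interactions = bad, features = small_features()),
               "configuration error")
})
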