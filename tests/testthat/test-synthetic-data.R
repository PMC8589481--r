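test_that("schema validation enforces typed relations and counts", {
  expect_error(kg_schema(c("disease"),
                         data.frame(name = "has_symptom",
                                    head_type = "disease",
                                    tail_type = "symptom"),
                         c(disease = 1)),
               "schema error")
  expect_error(kg_schema(c("disease", "symptom"),
                         data.frame(name = "has_symptom",
                                    head_type = "disease",
                                    tail_type = "symptom"),
                         c(disease = 1, symptom = 0)),
               "schema error")
  expect_s3_class(default_schema(), "kg_schema")
})

test_that("generate_kg honours density, coverage and determinism", {
  ## one disease, one symptom, density 1: the single forced triple
  tr <- generate_kg(tiny_schema(1, 1), density = 1, seed = 3)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$head, "disease01")
  expect_equal(tr$relation, "has_symptom")
  expect_equal(tr$tail, "symptom01")

  ## exhaustive pairing at density 1
  tr2 <- generate_kg(tiny_schema(10, 20), density = 1, seed = 3)
  expect_equal(nrow(tr2), 200L)
  expect_false(anyDuplicated(tr2) > 0)

  ## every head linked at least once even at low density
  tr3 <- generate_kg(tiny_schema(10, 20), density = 0.05, seed = 3)
  expect_setequal(unique(tr3$head), sprintf("disease%02d", 1:10))

  ## deterministic per seed; sensitive to seed
  expect_identical(tr3, generate_kg(tiny_schema(10, 20), 0.05, seed = 3))
  expect_false(identical(tr3, generate_kg(tiny_schema(10, 20), 0.05, seed = 4)))

  expect_error(generate_kg(tiny_schema(), density = 0), "density")
  expect_error(generate_kg(list(), density = 1), "schema error")
})

test_that("interaction labels follow the KG-dependent logistic model", {
  tr <- generate_kg(default_schema(), 0.6, seed = 1)

  ## count contract
  it <- generate_interactions(tr, n_users = 2, n_per_user = 3, seed = 1)
  expect_equal(nrow(it), 6L)
  expect_true(all(it$label %in% c(0L, 1L)))

  ## items are KG entities of item-eligible types
  ents <- unique(c(tr$head, tr$tail))
  expect_true(all(it$item %in% ents))

  ## kg_weight 0, noise 0.5: positive rate ~ 0.5 within 3 binomial s.e.
  it0 <- generate_interactions(tr, 100, 30, kg_weight = 0, noise = 0.5,
                               seed = 2)
  n <- nrow(it0)
  expect_lt(abs(mean(it0$label) - 0.5), 3 * sqrt(0.25 / n))

  ## large kg_weight, noise 0: adjacent items strictly preferred
  it1 <- generate_interactions(tr, 100, 30, kg_weight = 10, noise = 0,
                               seed = 2)
  adj <- attr(it1, "adjacency")
  pref <- attr(it1, "preferred_disease")
  is_adj <- adj[cbind(match(pref[it1$user], rownames(adj)),
                      match(it1$item, colnames(adj)))]
  expect_gt(mean(it1$label[is_adj]), mean(it1$label[!is_adj]))

  ## per-user positive rate strictly inside (0, 1)
  rates <- tapply(it1$label, it1$user, mean)
  expect_true(all(rates > 0 & rates < 1))

  expect_error(generate_interactions(tr[0, ], 2, 3), "nonempty")
})

test_that("adjacency/label association increases with kg_weight", {
  tr <- generate_kg(default_schema(), 0.6, seed = 1)
  odds_ratio <- function(kw) {
    it <- generate_interactions(tr, 150, 30, kg_weight = kw, noise = 0.1,
                                seed = 5)
    adj <- attr(it, "adjacency")
    pref <- attr(it, "preferred_disease")
    a <- adj[cbind(match(pref[it$user], rownames(adj)),
                   match(it$item, colnames(adj)))]
    tab <- table(a, it$label) + 0.5
    (tab["TRUE", "1"] * tab["FALSE", "0"]) /
      (tab["TRUE", "0"] * tab["FALSE", "1"])
  }
  ors <- vapply(c(0, 2, 10), odds_ratio, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("documents follow per-disease topic distributions", {
  tr <- generate_kg(tiny_schema(2, 3), 1, seed = 1)

  docs <- generate_documents(tr, vocab_size = 2, doc_len = 4, seed = 1)
  toks <- strsplit(unlist(docs), " ")
  expect_true(all(lengths(toks) == 4L))
  expect_true(all(unlist(toks) %in% c("w001", "w002")))

  ## disjoint topic supports -> zero shared tokens
  docs2 <- generate_documents(tr, vocab_size = 20, doc_len = 50, seed = 1,
                              shared_frac = 0)
  expect_length(intersect(strsplit(docs2[[1]], " ")[[1]],
                          strsplit(docs2[[2]], " ")[[1]]), 0)

  expect_identical(docs2, generate_documents(tr, 20, 50, seed = 1,
                                             shared_frac = 0))
  expect_error(generate_documents(tr, 20, doc_len = 0), "doc_len")
  expect_error(generate_documents(tr, vocab_size = 1, doc_len = 5),
               "vocab_size")
})

test_that("images carry a blob-count class signal within [0,1]", {
  tr <- generate_kg(tiny_schema(6, 2), 1, seed = 1)
  imgs <- generate_images(tr, size = 16, seed = 1)
  expect_length(imgs, 6L)
  expect_true(all(vapply(imgs, function(m) all(m >= 0 & m <= 1), TRUE)))
  expect_identical(imgs, generate_images(tr, 16, seed = 1))

  ## more blobs -> higher mean intensity at equal radius
  pr <- attr(imgs, "params")
  m1 <- mean(vapply(pr$key[pr$n_blobs == 1], function(k) mean(imgs[[k]]),
                    numeric(1)))
  m3 <- mean(vapply(pr$key[pr$n_blobs == 3], function(k) mean(imgs[[k]]),
                    numeric(1)))
  expect_gt(m3, m1)

  expect_error(generate_images(tr, size = 4), "size")
})

test_that("synthetic_world is internally consistent and reproducible", {
  w <- synthetic_world(n_users = 10, seed = 21)
  ents <- unique(c(w$triples$head, w$triples$tail))
  expect_true(all(w$interactions$item %in% ents))
  expect_true(all(names(w$documents) %in% ents))
  w2 <- synthetic_world(n_users = 10, seed = 21)
  expect_identical(w$triples, w2$triples)
  expect_identical(w$interactions, w2$interactions)
  expect_identical(w$documents, w2$documents)
  expect_identical(w$images, w2$images)
  expect_output(print(w), "Synthetic medical KG world")
})
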