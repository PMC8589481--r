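## Translation-distance KG embedding with dynamic mapping matrices. Every
## entity e carries a meaning vector e and a projection vector e_p; every
## relation r carries r and r_p. The relation-and-entity-specific mapping
## matrix M = r_p e_p^T + I projects entities into the relation space
## before the translation h_perp + r ~ t_perp is scored by squared L2
## distance. The projection is computed in vector form, never
## materializing M: M e = pad(e) + r_p (e_p . e).

## pad or truncate the columns of a matrix (or length of a vector) to m:
## the action of the rectangular principal-diagonal identity.
pad_cols <- function(x, m) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (n == m) return(x)
  if (n > m) return(x[, seq_len(m), drop = FALSE])
  cbind(x, matrix(0, nrow(x), m - n))
}

#' Dynamic mapping matrix of a (relation, entity) pair
#'
#' Returns `r_p %o% e_p + I` where `I` is the (possibly rectangular)
#' principal-diagonal identity, so relation and entity dimensions may
#' differ.
#'
#' @param rel_proj relation projection vector, length m.
#' @param ent_proj entity projection vector, length n.
#' @return an m x n matrix.
#' @export
mapping_matrix <- function(rel_proj, ent_proj) {
  stopifnot(all(is.finite(rel_proj)), all(is.finite(ent_proj)))
  m <- length(rel_proj); n <- length(ent_proj)
  M <- outer(rel_proj, ent_proj)
  d <- seq_len(min(m, n))
  M[cbind(d, d)] <- M[cbind(d, d)] + 1
  M
}

#' Project an entity vector into a relation's space
#'
#' Vector-form evaluation of `mapping_matrix(rel_proj, ent_proj) %*%
#' ent_vec`, i.e. `pad(ent_vec) + rel_proj * (ent_proj . ent_vec)`,
#' without materializing the matrix.
#'
#' @param ent_vec entity meaning vector, length n.
#' @param ent_proj entity projection vector, length n.
#' @param rel_proj relation projection vector, length m.
#' @return projected vector of length m.
#' @export
transd_project <- function(ent_vec, ent_proj, rel_proj) {
  if (length(ent_vec) != length(ent_proj))
    stop_value("shape error: ent_vec and ent_proj lengths differ")
  drop(pad_cols(ent_vec, length(rel_proj))) +
    rel_proj * sum(ent_proj * ent_vec)
}

## batch projection: rows of E (B x n), Ep (B x n), Rp (B x m) -> B x m
project_rows <- function(E, Ep, Rp) {
  pad_cols(E, ncol(Rp)) + Rp * rowSums(Ep * E)
}

#' Translation-distance score of a projected triple
#'
#' Squared Euclidean distance `||h_perp + r - t_perp||^2`; lower means a
#' more plausible fact, 0 iff the translation is exact.
#'
#' @param h_perp,t_perp projected head and tail vectors.
#' @param r relation meaning vector.
#' @return nonnegative scalar.
#' @export
transd_score <- function(h_perp, r, t_perp) {
  d <- h_perp + r - t_perp
  sum(d * d)
}

## vocabulary + parameter container ------------------------------------

transd_vocab <- function(triples) {
  list(entities = kg_entities(triples),
       relations = sort(unique(triples$relation)))
}

#' Initialize TransD parameters for a triple set
#'
#' @param triples KG triples.
#' @param dim_entity,dim_relation embedding dimensions n and m.
#' @param margin ranking margin gamma, > 0.
#' @param seed integer seed.
#' @return object of class `transd_params` holding entity/relation meaning
#'   and projection matrices (rows named by id) and the margin.
#' @export
transd_params <- function(triples, dim_entity = 32L, dim_relation = dim_entity,
                          margin = 1, seed = 1L) {
  stopifnot(margin > 0)
  voc <- transd_vocab(triples)
  with_seed(derive_seed(seed, "transd-init"), {
    init <- function(ids, d) {
      m <- matrix(stats::runif(length(ids) * d, -6 / sqrt(d), 6 / sqrt(d)) / d,
                  length(ids), d, dimnames = list(ids, NULL))
      m / pmax(sqrt(rowSums(m^2)), 1)
    }
    structure(list(
      ent = init(voc$entities, dim_entity),
      ent_p = init(voc$entities, dim_entity),
      rel = init(voc$relations, dim_relation),
      rel_p = init(voc$relations, dim_relation),
      margin = margin, dim_entity = as.integer(dim_entity),
      dim_relation = as.integer(dim_relation)),
      class = "transd_params")
  })
}

## score a data.frame of triples under params (vectorized over rows)
score_triples <- function(params, triples) {
  if (!all(triples$head %in% rownames(params$ent)) ||
      !all(triples$tail %in% rownames(params$ent)) ||
      !all(triples$relation %in% rownames(params$rel)))
    stop_value("vocabulary error: unknown entity or relation id")
  H <- params$ent[triples$head, , drop = FALSE]
  Hp <- params$ent_p[triples$head, , drop = FALSE]
  T_ <- params$ent[triples$tail, , drop = FALSE]
  Tp <- params$ent_p[triples$tail, , drop = FALSE]
  R <- params$rel[triples$relation, , drop = FALSE]
  Rp <- params$rel_p[triples$relation, , drop = FALSE]
  d <- project_rows(H, Hp, Rp) + R - project_rows(T_, Tp, Rp)
  rowSums(d * d)
}

#' Margin-ranking loss over matched positive/negative triples
#'
#' `sum over pairs of max(0, f(pos) + margin - f(neg))`: observed facts
#' must score at least `margin` lower (better) than their corruptions.
#'
#' @param positives,negatives matched data.frames of triples (equal rows).
#' @param params a [transd_params()] object.
#' @return nonnegative scalar.
#' @export
transd_margin_loss <- function(positives, negatives, params) {
  if (nrow(positives) == 0L || nrow(negatives) == 0L)
    stop_value("positive/negative batches must be nonempty")
  if (nrow(positives) != nrow(negatives))
    stop_value("positives and negatives must be matched pairwise")
  sum(pmax(0, score_triples(params, positives) + params$margin -
             score_triples(params, negatives)))
}

#' Corrupt a triple by replacing its head or tail
#'
#' Flips a fair coin to pick head or tail, then substitutes a uniformly
#' drawn entity of the same type. Resamples (bounded) so the corruption is
#' not itself an observed triple. Uses the current RNG state.
#'
#' @param triple one-row data.frame or list with `head`, `relation`, `tail`.
#' @param entity_vocab character vector of candidate entity ids.
#' @param observed optional character vector of observed `"h|r|t"` keys to
#'   avoid.
#' @param max_tries resampling bound.
#' @return the corrupted triple as a one-row data.frame.
#' @export
corrupt_triple <- function(triple, entity_vocab, observed = character(),
                           max_tries = 50L) {
  h <- triple$head; r <- triple$relation; t <- triple$tail
  for (i in seq_len(max_tries)) {
    corrupt_head <- stats::runif(1) < 0.5
    type <- entity_type_of(if (corrupt_head) h else t)
    pool <- entity_vocab[entity_type_of(entity_vocab) == type]
    pool <- setdiff(pool, if (corrupt_head) h else t)
    if (length(pool) == 0L) next
    e <- pool[sample.int(length(pool), 1L)]
    cand <- if (corrupt_head) data.frame(head = e, relation = r, tail = t,
                                         stringsAsFactors = FALSE)
            else data.frame(head = h, relation = r, tail = e,
                            stringsAsFactors = FALSE)
    if (!(paste(cand$head, cand$relation, cand$tail, sep = "|") %in% observed))
      return(cand)
  }
  stop_value("sampling error: no valid corruption found")
}

## batch corruption used by the trainers: fair head/tail coin, replacement
## drawn from the same entity type with probability type_preserve_prob and
## from the whole vocabulary otherwise, avoiding observed triples.
## Untyped corruptions are what teach the model to rank entities of the
## wrong type below plausible tails.
corrupt_batch <- function(batch, entity_vocab, observed, max_tries = 50L,
                          type_preserve_prob = 1) {
  n <- nrow(batch)
  pools <- split(entity_vocab, entity_type_of(entity_vocab))
  pools$.all <- entity_vocab
  corrupt_head <- logical(n)
  cur <- batch$head
  types <- entity_type_of(cur)
  new <- cur
  todo <- seq_len(n)
  for (iter in seq_len(max_tries)) {
    if (length(todo) == 0L) break
    ## the coin is re-flipped on every attempt: a triple may admit
    ## corruption on only one side
    corrupt_head[todo] <- stats::runif(length(todo)) < 0.5
    cur[todo] <- ifelse(corrupt_head[todo], batch$head[todo],
                        batch$tail[todo])
    types[todo] <- ifelse(stats::runif(length(todo)) < type_preserve_prob,
                          entity_type_of(cur[todo]), ".all")
    for (ty in unique(types[todo])) {
      rows <- todo[types[todo] == ty]
      pool <- pools[[ty]]
      new[rows] <- pool[sample.int(length(pool), length(rows),
                                   replace = TRUE)]
    }
    h2 <- ifelse(corrupt_head[todo], new[todo], batch$head[todo])
    t2 <- ifelse(corrupt_head[todo], batch$tail[todo], new[todo])
    bad <- new[todo] == cur[todo] |
      paste(h2, batch$relation[todo], t2, sep = "|") %in% observed
    todo <- todo[bad]
  }
  ## rows still stuck (nearly saturated neighborhoods): enumerate the
  ## valid corruptions exactly and sample uniformly from them
  for (i in todo) {
    h <- batch$head[i]; r <- batch$relation[i]; t <- batch$tail[i]
    hp <- setdiff(pools[[entity_type_of(h)]], h)
    tp <- setdiff(pools[[entity_type_of(t)]], t)
    hp <- hp[!(paste(hp, r, t, sep = "|") %in% observed)]
    tp <- tp[!(paste(h, r, tp, sep = "|") %in% observed)]
    sides <- c(if (length(hp) > 0L) "head", if (length(tp) > 0L) "tail")
    if (length(sides) == 0L)
      stop_value("sampling error: no valid corruption found")
    side <- sides[sample.int(length(sides), 1L)]
    corrupt_head[i] <- side == "head"
    new[i] <- if (side == "head") hp[sample.int(length(hp), 1L)]
              else tp[sample.int(length(tp), 1L)]
  }
  out <- batch
  out$head <- ifelse(corrupt_head, new, batch$head)
  out$tail <- ifelse(corrupt_head, batch$tail, new)
  out
}

#' Fit TransD embeddings by minibatch margin-ranking SGD
#'
#' Minimizes the hinge objective `sum max(0, f(pos) + margin - f(neg))`
#' over observed triples and type-preserving corruptions, with entity
#' meaning vectors projected back onto the unit ball after every update.
#' The reported trace is the full-data margin loss against one fixed,
#' seeded negative sample, evaluated after each epoch.
#'
#' @param triples KG triples (data.frame `head`, `relation`, `tail`).
#' @param dim embedding dimension (entities and relations).
#' @param margin ranking margin gamma.
#' @param lr SGD learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling init, shuffling and negatives.
#' @param type_preserve_prob probability that a training corruption draws
#'   its replacement from the same entity type (the remainder draw from
#'   the whole vocabulary, teaching cross-type separation).
#' @return object of class `transd`: the fitted `transd_params` plus
#'   `trace` (per-epoch loss), `triples`, and the call configuration.
#' @export
transd <- function(triples, dim = 32L, margin = 1, lr = 0.05, epochs = 200L,
                   batch_size = 128L, seed = 1L, type_preserve_prob = 0.5) {
  if (is.null(triples) || nrow(triples) == 0L)
    stop_value("triples must be nonempty")
  params <- transd_params(triples, dim, dim, margin, seed)
  voc <- transd_vocab(triples)
  observed <- paste(triples$head, triples$relation, triples$tail, sep = "|")
  n <- nrow(triples)
  trace <- numeric(epochs)
  with_seed(derive_seed(seed, "transd-train"), {
    eval_neg <- corrupt_batch(triples, voc$entities, observed,
                              type_preserve_prob = type_preserve_prob)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        pos <- triples[idx, ]
        neg <- corrupt_batch(pos, voc$entities, observed,
                             type_preserve_prob = type_preserve_prob)
        params <- transd_sgd_step(params, pos, neg, lr)
      }
      trace[ep] <- transd_margin_loss(triples, eval_neg, params) / n
      if (!is.finite(trace[ep]))
        stop_value("divergence error at epoch ", ep, ": non-finite loss")
    }
  })
  structure(list(params = params, trace = trace, triples = triples,
                 config = list(dim = dim, margin = margin, lr = lr,
                               epochs = epochs, batch_size = batch_size,
                               seed = seed)),
            class = "transd")
}

## one SGD step on a matched (pos, neg) minibatch; analytic gradients of
## the hinge through the vector-form projection.
transd_sgd_step <- function(params, pos, neg, lr) {
  f_pos <- score_triples(params, pos)
  f_neg <- score_triples(params, neg)
  active <- which(f_pos + params$margin - f_neg > 0)
  if (length(active) == 0L) return(params)
  grads <- list(ent = NULL, ent_p = NULL, rel = NULL, rel_p = NULL)
  add_triple_grads <- function(acc, batch, sign) {
    H <- params$ent[batch$head, , drop = FALSE]
    Hp <- params$ent_p[batch$head, , drop = FALSE]
    T_ <- params$ent[batch$tail, , drop = FALSE]
    Tp <- params$ent_p[batch$tail, , drop = FALSE]
    R <- params$rel[batch$relation, , drop = FALSE]
    Rp <- params$rel_p[batch$relation, , drop = FALSE]
    delta <- project_rows(H, Hp, Rp) + R - project_rows(T_, Tp, Rp)
    g <- sign * 2 * delta                           # d loss / d h_perp
    rg <- rowSums(Rp * g)                           # (r_p . g) per row
    n_e <- ncol(H)
    g_h <- pad_cols(g, n_e) + Hp * rg
    g_hp <- H * rg
    g_t <- -(pad_cols(g, n_e) + Tp * rg)
    g_tp <- -(T_ * rg)
    g_r <- g
    g_rp <- g * rowSums(Hp * H) - g * rowSums(Tp * T_)
    list(
      ent = rbind_pairs(acc$ent, cbind_id(batch$head, g_h),
                        cbind_id(batch$tail, g_t)),
      ent_p = rbind_pairs(acc$ent_p, cbind_id(batch$head, g_hp),
                          cbind_id(batch$tail, g_tp)),
      rel = rbind_pairs(acc$rel, cbind_id(batch$relation, g_r)),
      rel_p = rbind_pairs(acc$rel_p, cbind_id(batch$relation, g_rp)))
  }
  grads <- add_triple_grads(grads, pos[active, ], +1)
  grads <- add_triple_grads(grads, neg[active, ], -1)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    agg <- rowsum(g$mat, g$id)
    rows <- rownames(agg)
    params[[nm]][rows, ] <- params[[nm]][rows, , drop = FALSE] - lr * agg
  }
  ## norm constraint: meaning vectors back onto the unit ball
  nrm <- sqrt(rowSums(params$ent^2))
  scale <- pmax(nrm, 1)
  params$ent <- params$ent / scale
  params
}

## helper: pair an id vector with a gradient block for rowsum() aggregation
cbind_id <- function(id, mat) list(id = id, mat = mat)

## combine (id, mat) gradient pairs, dropping NULLs
rbind_pairs <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  list(id = unlist(lapply(parts, `[[`, "id")),
       mat = do.call(rbind, lapply(parts, `[[`, "mat")))
}

#' Rank candidate tails for (head, relation) queries
#'
#' Scores every candidate entity as tail of each query triple and reports
#' the rank of the true tail, hits@k and mean rank. In the filtered
#' setting, candidates that form other known-true triples with the query
#' head and relation are removed before ranking.
#'
#' @param object a fitted [transd()] model or a `transd_params`.
#' @param queries data.frame of test triples (`head`, `relation`, `tail`).
#' @param candidates candidate tail entity ids; default all entities.
#' @param k cutoff for hits@k.
#' @param filtered logical; remove other known-true tails.
#' @param known triples defining the known-true set for filtering (default:
#'   the model's training triples).
#' @return list with `ranks`, `hits_at_k`, `mean_rank`, `k`, `n_candidates`.
#' @export
link_predict <- function(object, queries, candidates = NULL, k = 10L,
                         filtered = FALSE, known = NULL) {
  params <- if (inherits(object, "transd")) object$params else object
  if (!inherits(params, "transd_params"))
    stop_value("object must be a transd fit or transd_params")
  if (is.null(known) && inherits(object, "transd")) known <- object$triples
  if (is.null(candidates)) candidates <- rownames(params$ent)
  if (!all(queries$head %in% rownames(params$ent)) ||
      !all(queries$relation %in% rownames(params$rel)))
    stop_value("vocabulary error: unknown id in queries")
  if (!all(candidates %in% rownames(params$ent)))
    stop_value("vocabulary error: unknown candidate id")
  known_key <- if (!is.null(known))
    paste(known$head, known$relation, known$tail, sep = "|") else character()
  Tm <- params$ent[candidates, , drop = FALSE]
  Tp <- params$ent_p[candidates, , drop = FALSE]
  ts <- rowSums(Tp * Tm)
  ranks <- numeric(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    h <- queries$head[i]; r <- queries$relation[i]; t <- queries$tail[i]
    rp <- params$rel_p[r, ]
    h_perp <- transd_project(params$ent[h, ], params$ent_p[h, ], rp)
    pred <- h_perp + params$rel[r, ]
    T_perp <- pad_cols(Tm, length(rp)) + outer(ts, rp)
    d <- sweep(T_perp, 2L, pred)
    sc <- rowSums(d * d)
    keep <- rep(TRUE, length(candidates))
    if (filtered) {
      other <- paste(h, r, candidates, sep = "|") %in% known_key &
        candidates != t
      keep <- !other
    }
    ti <- which(candidates == t)
    if (length(ti) != 1L) stop_value("vocabulary error: true tail not a candidate")
    s_true <- sc[ti]
    s_others <- sc[keep]
    ranks[i] <- 1 + sum(s_others < s_true) +
      (sum(s_others == s_true) - 1) / 2
  }
  list(ranks = ranks, hits_at_k = mean(ranks <= k), mean_rank = mean(ranks),
       k = as.integer(k), n_candidates = length(candidates))
}

#' Rank candidates for a single (head, relation) query
#'
#' @inheritParams link_predict
#' @param head,relation query ids.
#' @return data.frame of candidates sorted by ascending distance score.
#' @export
rank_tails <- function(object, head, relation, candidates = NULL) {
  params <- if (inherits(object, "transd")) object$params else object
  if (is.null(candidates)) candidates <- rownames(params$ent)
  if (!(head %in% rownames(params$ent)) ||
      !(relation %in% rownames(params$rel)))
    stop_value("vocabulary error: unknown head or relation id")
  rp <- params$rel_p[relation, ]
  h_perp <- transd_project(params$ent[head, ], params$ent_p[head, ], rp)
  pred <- h_perp + params$rel[relation, ]
  Tm <- params$ent[candidates, , drop = FALSE]
  Tp <- params$ent_p[candidates, , drop = FALSE]
  T_perp <- pad_cols(Tm, length(rp)) + outer(rowSums(Tp * Tm), rp)
  d <- sweep(T_perp, 2L, pred)
  sc <- rowSums(d * d)
  out <- data.frame(tail = candidates, score = sc, stringsAsFactors = FALSE)
  out[order(out$score, out$tail), ]
}

#' @export
print.transd <- function(x, ...) {
  cat("TransD embedding fit\n")
  cat("  entities: ", nrow(x$params$ent), ", relations: ",
      nrow(x$params$rel), ", dim: ", x$config$dim, "\n", sep = "")
  cat("  margin: ", x$params$margin, ", epochs: ", x$config$epochs,
      "\n", sep = "")
  cat("  final loss: ", format(utils::tail(x$trace, 1L), digits = 4),
      " (from ", format(x$trace[1L], digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
predict.transd <- function(object, newdata, ...) {
  score_triples(object$params, newdata)
}

#' @export
plot.transd <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", xlab = "epoch",
       ylab = "margin loss / triple", main = "TransD training", ...)
  invisible(x)
}

#' Write fitted embeddings to vector TSV files
#'
#' @param object a fitted [transd()] model.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_transd <- function(object, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(dim_entity = object$params$dim_entity,
               dim_relation = object$params$dim_relation,
               margin = object$params$margin,
               epochs = object$config$epochs)
  write_vectors(object$params$ent, file.path(dir, "entity.tsv"), meta)
  write_vectors(object$params$ent_p, file.path(dir, "entity_proj.tsv"), meta)
  write_vectors(object$params$rel, file.path(dir, "relation.tsv"), meta)
  write_vectors(object$params$rel_p, file.path(dir, "relation_proj.tsv"), meta)
  invisible(dir)
}
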