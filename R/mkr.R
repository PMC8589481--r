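## The coupled two-task model: a click-through head (user MLP + item
## stream -> combining MLP -> sigmoid probability) and a KG head (head
## entity + relation MLP -> predicted tail vector, scored against the
## actual tail by a sigmoid inner-product similarity), sharing low-level
## item/entity features through cross-compression units. Items are KG
## entities; the entity-side input of the cross unit is the fused
## multimodal representation. The joint objective is
##   L = L_RS + L_KG + L_REG
##     = cross-entropy(click) - lambda1 (score(pos) - score(neg))
##       + lambda2 ||W||^2.

#' Cross-compression of an item vector and its entity vector
#'
#' Forms the outer product `C = v e^T` and compresses it back into updated
#' item and entity vectors:
#' `v' = C w_vv + C^T w_ev + b_v`, `e' = C w_ve + C^T w_ee + b_e`.
#' Computed in vector form (`C w = v (e . w)`, `C^T w = e (v . w)`)
#' without materializing C.
#'
#' @param v item vector, length d.
#' @param e entity vector, length d.
#' @param params list with weight vectors `w_vv`, `w_ev`, `w_ve`, `w_ee`
#'   and biases `b_v`, `b_e`, all length d.
#' @return list with updated vectors `v` and `e`.
#' @export
cross_compress <- function(v, e, params) {
  if (length(v) != length(e)) stop_value("shape error: v and e lengths differ")
  list(v = v * sum(e * params$w_vv) + e * sum(v * params$w_ev) + params$b_v,
       e = v * sum(e * params$w_ve) + e * sum(v * params$w_ee) + params$b_e)
}

cross_layer_init <- function(d) {
  list(w_vv = stats::runif(d, -0.5, 0.5) / sqrt(d),
       w_ev = stats::runif(d, -0.5, 0.5) / sqrt(d),
       w_ve = stats::runif(d, -0.5, 0.5) / sqrt(d),
       w_ee = stats::runif(d, -0.5, 0.5) / sqrt(d),
       b_v = numeric(d), b_e = numeric(d))
}

## batch cross-compression: V, E are B x d
cross_forward_batch <- function(layer, V, E) {
  list(V = V * drop(E %*% layer$w_vv) + E * drop(V %*% layer$w_ev) +
         matrix(layer$b_v, nrow(V), length(layer$b_v), byrow = TRUE),
       E = V * drop(E %*% layer$w_ve) + E * drop(V %*% layer$w_ee) +
         matrix(layer$b_e, nrow(V), length(layer$b_e), byrow = TRUE))
}

## backward through one cross layer; dVo/dEo are gradients w.r.t. outputs
cross_backward_batch <- function(layer, V, E, dVo, dEo) {
  sv_vv <- drop(E %*% layer$w_vv); sv_ev <- drop(V %*% layer$w_ev)
  sv_ve <- drop(E %*% layer$w_ve); sv_ee <- drop(V %*% layer$w_ee)
  dV <- dVo * sv_vv + rep_row(layer$w_ev, nrow(V)) * rowSums(dVo * E) +
    dEo * sv_ve + rep_row(layer$w_ee, nrow(V)) * rowSums(dEo * E)
  dE <- rep_row(layer$w_vv, nrow(V)) * rowSums(dVo * V) + dVo * sv_ev +
    rep_row(layer$w_ve, nrow(V)) * rowSums(dEo * V) + dEo * sv_ee
  list(dV = dV, dE = dE,
       g = list(w_vv = colSums(E * rowSums(dVo * V)),
                w_ev = colSums(V * rowSums(dVo * E)),
                w_ve = colSums(E * rowSums(dEo * V)),
                w_ee = colSums(V * rowSums(dEo * E)),
                b_v = colSums(dVo), b_e = colSums(dEo)))
}

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' Default configuration of the multitask recommender
#'
#' @param d shared stream dimension of the user/item/entity/relation MLPs
#'   and the cross-compression unit.
#' @param cross_layers number of low-level cross-compression layers.
#' @param t_rs recommendation steps per KG step in the alternating
#'   schedule.
#' @param lambda1,lambda2 joint-loss equilibrium constants (KG term and
#'   L2 regularizer).
#' @param lr learning rate.
#' @param epochs joint-training epochs.
#' @param batch_rs,batch_kg minibatch sizes.
#' @param struct_dim,text_dim,image_dim modality input dimensions.
#' @param kg_pretrain_epochs TransD pretraining epochs for the structural
#'   vectors.
#' @param sg_epochs skip-gram pretraining epochs for the word vectors.
#' @return a named list of settings.
#' @export
kgmr_config <- function(d = 16L, cross_layers = 1L, t_rs = 3L,
                        lambda1 = 0.5, lambda2 = 1e-6, lr = 0.05,
                        epochs = 25L, batch_rs = 256L, batch_kg = 128L,
                        struct_dim = 32L, text_dim = 32L, image_dim = 32L,
                        kg_pretrain_epochs = 30L, sg_epochs = 15L) {
  as.list(environment())
}

#' Precompute the modality feature tables for a world
#'
#' Pretrains TransD for structural vectors, skip-gram + GRU sentence
#' encoding for textual vectors, and a seeded residual encoder for visual
#' vectors. Computing these once lets several model configurations share
#' identical inputs.
#'
#' @param world a [synthetic_world()] (or compatible list).
#' @param config a [kgmr_config()].
#' @param seed integer seed.
#' @param standardize center and scale the text/image tables per dimension
#'   across entities (then rescale to unit-norm-order rows). Raw encoder
#'   outputs carry large constant offsets that would otherwise saturate
#'   the fusion nonlinearity and bury the entity-specific signal.
#' @return list with `structural`, `text`, `image` matrices and the fitted
#'   `transd` model.
#' @export
kgmr_features <- function(world, config = kgmr_config(), seed = 1L,
                          standardize = TRUE) {
  td <- transd(world$triples, dim = config$struct_dim,
               epochs = config$kg_pretrain_epochs,
               seed = derive_seed(seed, "feat-transd"))
  text <- NULL
  if (length(world$documents) > 0L) {
    wm <- skipgram(world$documents, dim = 16L,
                   epochs = config$sg_epochs,
                   seed = derive_seed(seed, "feat-text"))
    enc <- sentence_encoder(wm, hidden = config$text_dim, mode = "gru",
                            seed = derive_seed(seed, "feat-gru"))
    text <- encode_documents(world$documents, wm, enc)
  }
  image <- NULL
  if (length(world$images) > 0L) {
    rn <- resnet(feature_dim = config$image_dim,
                 seed = derive_seed(seed, "feat-image"))
    image <- encode_images(world$images, rn)
    rownames(image) <- sub("\\.v[0-9]+$", "", rownames(image))
  }
  if (standardize) {
    text <- standardize_features(text)
    image <- standardize_features(image)
  }
  list(structural = td$params$ent, text = text, image = image, transd = td)
}

## z-score each column across entities, then scale rows to unit-norm order
## so all modalities enter fusion at comparable magnitude
standardize_features <- function(x, eps = 1e-8) {
  if (is.null(x) || nrow(x) < 2L) return(x)
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  sweep(sweep(x, 2L, mu), 2L, pmax(sd_, eps), "/") / sqrt(ncol(x))
}

kgmr_init <- function(users, entities, relations, config, seed) {
  d <- config$d
  with_seed(derive_seed(seed, "kgmr-init"), {
    emb <- function(ids, dd) matrix(stats::runif(length(ids) * dd, -0.5, 0.5) /
                                      sqrt(dd),
                                    length(ids), dd, dimnames = list(ids, NULL))
    list(
      user_emb = emb(users, d), item_emb = emb(entities, d),
      rel_emb = emb(relations, d),
      Wf = rand_mat(config$struct_dim + config$text_dim + config$image_dim, d),
      bf = numeric(d),
      def_text = stats::runif(config$text_dim, -0.1, 0.1),
      def_vis = stats::runif(config$image_dim, -0.1, 0.1),
      cross = lapply(seq_len(config$cross_layers),
                     function(i) cross_layer_init(d)),
      W_u1 = rand_mat(d, d), b_u1 = numeric(d),
      W_u2 = rand_mat(d, d), b_u2 = numeric(d),
      W_c1 = rand_mat(2L * d, d), b_c1 = numeric(d),
      w_c2 = rand_mat(d, 1L), b_c2 = 0,
      W_r = rand_mat(d, d), b_r = numeric(d),
      W_t = rand_mat(2L * d, d), b_t = numeric(d))
  })
}

## regularized transformation weights (embeddings and biases excluded)
kgmr_reg_sq <- function(params) {
  s <- sum(params$Wf^2) + sum(params$W_u1^2) + sum(params$W_u2^2) +
    sum(params$W_c1^2) + sum(params$w_c2^2) + sum(params$W_r^2) +
    sum(params$W_t^2)
  for (l in params$cross)
    s <- s + sum(l$w_vv^2) + sum(l$w_ev^2) + sum(l$w_ve^2) + sum(l$w_ee^2)
  s
}

## fused entity representations for entity row indices, with cache
kgmr_fused <- function(model, idx) {
  p <- model$params
  S <- model$inputs$S[idx, , drop = FALSE]
  Tx <- model$inputs$Tx[idx, , drop = FALSE]
  Vx <- model$inputs$Vx[idx, , drop = FALSE]
  missT <- !model$inputs$has_text[idx]
  missV <- !model$inputs$has_vis[idx]
  if (any(missT)) Tx[missT, ] <- rep_row(p$def_text, sum(missT))
  if (any(missV)) Vx[missV, ] <- rep_row(p$def_vis, sum(missV))
  Zf <- cbind(S, Tx, Vx)
  E0 <- tanh(Zf %*% p$Wf + rep_row(p$bf, length(idx)))
  list(idx = idx, Zf = Zf, E0 = E0, missT = missT, missV = missV)
}

## backward through the fusion layer for stacked caches; returns grads
kgmr_fused_backward <- function(model, caches, dE0s) {
  p <- model$params
  Zf <- do.call(rbind, lapply(caches, `[[`, "Zf"))
  E0 <- do.call(rbind, lapply(caches, `[[`, "E0"))
  dE0 <- do.call(rbind, dE0s)
  missT <- unlist(lapply(caches, `[[`, "missT"))
  missV <- unlist(lapply(caches, `[[`, "missV"))
  dPre <- dE0 * (1 - E0^2)
  dZf <- dPre %*% t(p$Wf)
  ds <- ncol(model$inputs$S); dt <- ncol(model$inputs$Tx)
  dv <- ncol(model$inputs$Vx)
  dT <- dZf[, ds + seq_len(dt), drop = FALSE]
  dV <- dZf[, ds + dt + seq_len(dv), drop = FALSE]
  list(Wf = crossprod(Zf, dPre), bf = colSums(dPre),
       def_text = if (any(missT)) colSums(dT[missT, , drop = FALSE])
                  else numeric(dt),
       def_vis = if (any(missV)) colSums(dV[missV, , drop = FALSE])
                 else numeric(dv))
}

## item-stream + entity-stream pass through the cross layers, with cache
kgmr_cross <- function(model, V0, E0) {
  Vs <- list(V0); Es <- list(E0)
  for (l in seq_along(model$params$cross)) {
    o <- cross_forward_batch(model$params$cross[[l]], Vs[[l]], Es[[l]])
    Vs[[l + 1L]] <- o$V; Es[[l + 1L]] <- o$E
  }
  list(Vs = Vs, Es = Es, V = Vs[[length(Vs)]], E = Es[[length(Es)]])
}

kgmr_cross_backward <- function(model, cache, dV, dE) {
  L <- length(model$params$cross)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    b <- cross_backward_batch(model$params$cross[[l]], cache$Vs[[l]],
                              cache$Es[[l]], dV, dE)
    dV <- b$dV; dE <- b$dE
    grads[[l]] <- b$g
  }
  list(dV0 = dV, dE0 = dE, grads = grads)
}

## forward pass of the recommendation head; cache for backward
kgmr_forward_rs <- function(model, users, items) {
  p <- model$params
  ui <- match(users, model$users)
  ii <- match(items, model$entities)
  if (anyNA(ui) || anyNA(ii))
    stop_value("vocabulary error: unknown user or item id")
  U0 <- p$user_emb[ui, , drop = FALSE]
  A1 <- U0 %*% p$W_u1 + rep_row(p$b_u1, length(ui)); U1 <- relu(A1)
  A2 <- U1 %*% p$W_u2 + rep_row(p$b_u2, length(ui)); U2 <- relu(A2)
  fc <- kgmr_fused(model, ii)
  V0 <- p$item_emb[ii, , drop = FALSE]
  cr <- kgmr_cross(model, V0, fc$E0)
  Z <- cbind(U2, cr$V)
  A3 <- Z %*% p$W_c1 + rep_row(p$b_c1, length(ui)); H <- relu(A3)
  logit <- drop(H %*% p$w_c2) + p$b_c2
  list(p = sigmoid(logit), logit = logit, ui = ui, ii = ii, U0 = U0,
       A1 = A1, U1 = U1, A2 = A2, U2 = U2, fc = fc, V0 = V0, cr = cr,
       Z = Z, A3 = A3, H = H)
}

## forward pass of the KG head on a batch of triples; cache for backward
kgmr_forward_kg <- function(model, triples) {
  p <- model$params
  hi <- match(triples$head, model$entities)
  ti <- match(triples$tail, model$entities)
  ri <- match(triples$relation, model$relations)
  if (anyNA(hi) || anyNA(ti) || anyNA(ri))
    stop_value("vocabulary error: unknown id in triples")
  fch <- kgmr_fused(model, hi)
  Vh0 <- p$item_emb[hi, , drop = FALSE]
  cr <- kgmr_cross(model, Vh0, fch$E0)
  R0 <- p$rel_emb[ri, , drop = FALSE]
  Ar <- R0 %*% p$W_r + rep_row(p$b_r, length(ri)); R1 <- relu(Ar)
  Tcat <- cbind(cr$E, R1)
  Tpred <- Tcat %*% p$W_t + rep_row(p$b_t, length(ri))
  fct <- kgmr_fused(model, ti)
  inner <- rowSums(Tpred * fct$E0)
  list(score = sigmoid(inner), inner = inner, hi = hi, ti = ti, ri = ri,
       fch = fch, Vh0 = Vh0, cr = cr, R0 = R0, Ar = Ar, R1 = R1,
       Tcat = Tcat, Tpred = Tpred, fct = fct)
}

## apply accumulated gradients with Adagrad (per-parameter adaptive step)
## plus per-step L2 decay on the transformation weights involved in the
## step. `emb` entries are (id, mat) pairs for the sparse embedding rows.
kgmr_apply <- function(model, grads, emb = list(), lr, lambda2, reg_names) {
  eps <- 1e-8
  params <- model$params
  opt <- model$opt
  for (nm in names(grads)) {
    if (nm == "cross") next
    g <- grads[[nm]]
    if (nm %in% reg_names) g <- g + 2 * lambda2 * params[[nm]]
    opt[[nm]] <- opt[[nm]] + g^2
    params[[nm]] <- params[[nm]] - lr * g / sqrt(opt[[nm]] + eps)
  }
  if (!is.null(grads$cross)) {
    for (l in seq_along(grads$cross)) {
      for (w in names(grads$cross[[l]])) {
        g <- grads$cross[[l]][[w]]
        if (startsWith(w, "w_")) g <- g + 2 * lambda2 * params$cross[[l]][[w]]
        opt$cross[[l]][[w]] <- opt$cross[[l]][[w]] + g^2
        params$cross[[l]][[w]] <- params$cross[[l]][[w]] -
          lr * g / sqrt(opt$cross[[l]][[w]] + eps)
      }
    }
  }
  for (nm in names(emb)) {
    pair <- emb[[nm]]
    if (is.null(pair)) next
    g <- rowsum(pair$mat, pair$id)
    rows <- as.integer(rownames(g))
    opt[[nm]][rows, ] <- opt[[nm]][rows, , drop = FALSE] + g^2
    params[[nm]][rows, ] <- params[[nm]][rows, , drop = FALSE] -
      lr * g / sqrt(opt[[nm]][rows, , drop = FALSE] + eps)
  }
  model$params <- params
  model$opt <- opt
  model
}

## zero Adagrad accumulators mirroring the parameter shapes
kgmr_opt_init <- function(params) {
  z <- function(p) if (is.list(p)) lapply(p, z) else p * 0
  lapply(params, z)
}

#' One optimization step of the multitask model
#'
#' `type = "rs"` takes a gradient step on the click cross-entropy for a
#' batch of interactions (touching user, item, cross, fusion and combining
#' parameters only); `type = "kg"` takes a step on the KG scoring term for
#' matched positive/negative triple batches (touching entity-side, cross,
#' fusion, relation and tail parameters only).
#'
#' @param model a `kgmr` model.
#' @param type `"rs"` or `"kg"`.
#' @param batch interactions data.frame (rs) or positive triples (kg).
#' @param negatives matched corrupted triples (kg only).
#' @param lr learning rate override (default: model config).
#' @return the updated model.
#' @export
kgmr_step <- function(model, type = c("rs", "kg"), batch, negatives = NULL,
                      lr = NULL) {
  type <- match.arg(type)
  lr <- lr %||% model$config$lr
  l2 <- model$config$lambda2
  if (type == "rs") {
    fw <- kgmr_forward_rs(model, batch$user, batch$item)
    B <- nrow(batch)
    dlogit <- (fw$p - batch$label) / B
    g <- list()
    g$w_c2 <- crossprod(fw$H, dlogit)
    g$b_c2 <- sum(dlogit)
    dH <- tcrossprod(dlogit, drop(model$params$w_c2)) * (fw$A3 > 0)
    g$W_c1 <- crossprod(fw$Z, dH); g$b_c1 <- colSums(dH)
    dZ <- dH %*% t(model$params$W_c1)
    d <- model$config$d
    dU2 <- dZ[, seq_len(d), drop = FALSE] * (fw$A2 > 0)
    g$W_u2 <- crossprod(fw$U1, dU2); g$b_u2 <- colSums(dU2)
    dU1 <- dU2 %*% t(model$params$W_u2) * (fw$A1 > 0)
    g$W_u1 <- crossprod(fw$U0, dU1); g$b_u1 <- colSums(dU1)
    dU0 <- dU1 %*% t(model$params$W_u1)
    dVL <- dZ[, d + seq_len(d), drop = FALSE]
    cb <- kgmr_cross_backward(model, fw$cr, dVL, 0 * dVL)
    g$cross <- cb$grads
    fb <- kgmr_fused_backward(model, list(fw$fc), list(cb$dE0))
    g$Wf <- fb$Wf; g$bf <- fb$bf
    g$def_text <- fb$def_text; g$def_vis <- fb$def_vis
    model <- kgmr_apply(model, g,
                        emb = list(user_emb = cbind_id(fw$ui, dU0),
                                   item_emb = cbind_id(fw$ii, cb$dV0)),
                        lr, l2, c("W_c1", "w_c2", "W_u1", "W_u2", "Wf"))
  } else {
    if (is.null(negatives)) stop_value("kg step needs matched negatives")
    lam1 <- model$config$lambda1
    g_item <- NULL; g_rel <- NULL
    g <- list()
    caches <- list(); dE0s <- list()
    for (piece in list(list(b = batch, s = -lam1 / nrow(batch)),
                       list(b = negatives, s = +lam1 / nrow(negatives)))) {
      fw <- kgmr_forward_kg(model, piece$b)
      dinner <- piece$s * fw$score * (1 - fw$score)
      dTpred <- fw$fct$E0 * dinner
      dTact <- fw$Tpred * dinner
      g$W_t <- (g$W_t %||% 0) + crossprod(fw$Tcat, dTpred)
      g$b_t <- (g$b_t %||% 0) + colSums(dTpred)
      dTcat <- dTpred %*% t(model$params$W_t)
      d <- model$config$d
      dEhL <- dTcat[, seq_len(d), drop = FALSE]
      dR1 <- dTcat[, d + seq_len(d), drop = FALSE] * (fw$Ar > 0)
      g$W_r <- (g$W_r %||% 0) + crossprod(fw$R0, dR1)
      g$b_r <- (g$b_r %||% 0) + colSums(dR1)
      dR0 <- dR1 %*% t(model$params$W_r)
      g_rel <- rbind_pairs(g_rel, cbind_id(fw$ri, dR0))
      cb <- kgmr_cross_backward(model, fw$cr, 0 * dEhL, dEhL)
      if (is.null(g$cross)) g$cross <- cb$grads
      else for (l in seq_along(cb$grads))
        for (w in names(cb$grads[[l]]))
          g$cross[[l]][[w]] <- g$cross[[l]][[w]] + cb$grads[[l]][[w]]
      g_item <- rbind_pairs(g_item, cbind_id(fw$hi, cb$dV0))
      caches <- c(caches, list(fw$fch, fw$fct))
      dE0s <- c(dE0s, list(cb$dE0, dTact))
    }
    fb <- kgmr_fused_backward(model, caches, dE0s)
    g$Wf <- fb$Wf; g$bf <- fb$bf
    g$def_text <- fb$def_text; g$def_vis <- fb$def_vis
    model <- kgmr_apply(model, g,
                        emb = list(item_emb = g_item, rel_emb = g_rel),
                        lr, l2, c("W_t", "W_r", "Wf"))
  }
  model
}

#' Decomposed joint loss on given batches
#'
#' `L_RS` is the mean click cross-entropy, `L_KG` is
#' `-lambda1 (mean score(pos) - mean score(neg))` with the sigmoid
#' inner-product tail similarity as score (higher = better), and `L_REG`
#' is `lambda2` times the squared L2 norm of the transformation weights.
#'
#' @param model a `kgmr` model.
#' @param batch_rs interactions data.frame.
#' @param batch_kg_pos,batch_kg_neg matched positive/corrupted triples.
#' @param lambda1,lambda2 overrides of the model's equilibrium constants.
#' @return list of class `joint_loss_report` with `L_RS`, `L_KG`, `L_REG`,
#'   `total`, `lambda1`, `lambda2`.
#' @export
joint_loss <- function(model, batch_rs, batch_kg_pos, batch_kg_neg,
                       lambda1 = NULL, lambda2 = NULL) {
  if (nrow(batch_rs) == 0L || nrow(batch_kg_pos) == 0L)
    stop_value("batches must be nonempty")
  lambda1 <- lambda1 %||% model$config$lambda1
  lambda2 <- lambda2 %||% model$config$lambda2
  p <- kgmr_forward_rs(model, batch_rs$user, batch_rs$item)$p
  if (any(p <= 0) || any(p >= 1)) stop_value("numeric error: p outside (0,1)")
  y <- batch_rs$label
  L_RS <- -mean(y * log(p) + (1 - y) * log(1 - p))
  s_pos <- kgmr_forward_kg(model, batch_kg_pos)$score
  s_neg <- kgmr_forward_kg(model, batch_kg_neg)$score
  L_KG <- -lambda1 * (mean(s_pos) - mean(s_neg))
  L_REG <- lambda2 * kgmr_reg_sq(model$params)
  structure(list(L_RS = L_RS, L_KG = L_KG, L_REG = L_REG,
                 total = L_RS + L_KG + L_REG,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "joint_loss_report")
}

#' @export
print.joint_loss_report <- function(x, ...) {
  cat(sprintf("joint loss: total %.6f = L_RS %.6f + L_KG %+.6f + L_REG %.2e\n",
              x$total, x$L_RS, x$L_KG, x$L_REG))
  invisible(x)
}

#' Fit the multitask knowledge-graph recommender
#'
#' Trains the coupled click-prediction and KG-embedding tasks by an
#' alternating schedule (`t_rs` recommendation minibatches per KG
#' minibatch), with cross-compression sharing at the low layers and a
#' fused multimodal entity representation. Modalities are toggled purely
#' by which input tables are supplied: `modalities = character(0)` is the
#' structural-only base model; adding `"text"` and/or `"image"` enables
#' the corresponding feature table with no code-path change.
#'
#' @param world a [synthetic_world()] or list with `triples`,
#'   `interactions`, `documents`, `images`.
#' @param modalities character subset of `c("text", "image")`.
#' @param config a [kgmr_config()].
#' @param seed integer seed (initialization, batching, negatives).
#' @param features optional precomputed [kgmr_features()] (shared across
#'   ablation configurations).
#' @param interactions optional interactions override (e.g. a training
#'   split); defaults to `world$interactions`.
#' @return object of class `kgmr` with `params`, `trace` (per-epoch
#'   [joint_loss()] decomposition), vocabularies and config.
#' @export
kgmr <- function(world, modalities = c("text", "image"),
                 config = kgmr_config(), seed = 1L, features = NULL,
                 interactions = NULL) {
  interactions <- interactions %||% world$interactions
  triples <- world$triples
  entities <- kg_entities(triples)
  if (!all(interactions$item %in% entities))
    stop_value("configuration error: interaction items must be KG entities")
  if (length(intersect(interactions$item, entities)) == 0L)
    stop_value("configuration error: no item/entity overlap")
  modalities <- intersect(modalities, c("text", "image"))
  if (is.null(features)) features <- kgmr_features(world, config, seed)
  users <- sort(unique(interactions$user))
  relations <- sort(unique(triples$relation))
  params <- kgmr_init(users, entities, relations, config, seed)
  S <- features$structural[entities, , drop = FALSE]
  Tx <- matrix(0, length(entities), config$text_dim,
               dimnames = list(entities, NULL))
  Vx <- matrix(0, length(entities), config$image_dim,
               dimnames = list(entities, NULL))
  has_text <- stats::setNames(rep(FALSE, length(entities)), entities)
  has_vis <- has_text
  if ("text" %in% modalities && !is.null(features$text)) {
    ids <- intersect(rownames(features$text), entities)
    Tx[ids, ] <- features$text[ids, , drop = FALSE]
    has_text[ids] <- TRUE
  }
  if ("image" %in% modalities && !is.null(features$image)) {
    ids <- intersect(rownames(features$image), entities)
    Vx[ids, ] <- features$image[ids, , drop = FALSE]
    has_vis[ids] <- TRUE
  }
  model <- structure(list(
    params = params, opt = kgmr_opt_init(params),
    users = users, entities = entities,
    relations = relations, config = config, modalities = modalities,
    inputs = list(S = S, Tx = Tx, Vx = Vx, has_text = unname(has_text),
                  has_vis = unname(has_vis)),
    seed = as.integer(seed)), class = "kgmr")
  n_rs <- nrow(interactions); n_kg <- nrow(triples)
  observed <- paste(triples$head, triples$relation, triples$tail, sep = "|")
  trace <- NULL
  with_seed(derive_seed(seed, "kgmr-train"), {
    eval_neg <- corrupt_batch(triples, entities, observed)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_rs)
      rs_starts <- seq(1L, n_rs, by = config$batch_rs)
      kg_ord <- sample.int(n_kg)
      kg_pos <- 1L
      for (bi in seq_along(rs_starts)) {
        idx <- ord[rs_starts[bi]:min(rs_starts[bi] + config$batch_rs - 1L,
                                     n_rs)]
        model <- kgmr_step(model, "rs", interactions[idx, ])
        if (bi %% config$t_rs == 0L) {
          kend <- min(kg_pos + config$batch_kg - 1L, n_kg)
          kidx <- kg_ord[kg_pos:kend]
          kg_pos <- if (kend >= n_kg) 1L else kend + 1L
          pos <- triples[kidx, ]
          neg <- corrupt_batch(pos, entities, observed)
          model <- kgmr_step(model, "kg", pos, neg)
        }
      }
      rep_ <- joint_loss(model, interactions, triples, eval_neg)
      trace <- rbind(trace, data.frame(epoch = ep, L_RS = rep_$L_RS,
                                       L_KG = rep_$L_KG, L_REG = rep_$L_REG,
                                       total = rep_$total))
      if (!all(is.finite(unlist(rep_[1:4]))))
        stop_value("divergence error at epoch ", ep)
    }
  })
  model$trace <- trace
  model$interactions <- interactions
  model
}

#' Predicted click probability for a (user, item) pair
#'
#' @param model a fitted [kgmr()] model.
#' @param user_id,item_id known ids.
#' @return probability in (0, 1).
#' @export
predict_click <- function(model, user_id, item_id) {
  unname(drop(kgmr_forward_rs(model, user_id, item_id)$p))
}

#' Predicted tail vector for a (head, relation) query
#'
#' @param model a fitted [kgmr()] model.
#' @param head_id,relation_id known ids.
#' @return predicted tail vector of length `config$d`.
#' @export
predict_tail <- function(model, head_id, relation_id) {
  fw <- kgmr_forward_kg(model, data.frame(
    head = head_id, relation = relation_id,
    tail = model$entities[1L], stringsAsFactors = FALSE))
  drop(fw$Tpred)
}

#' Sigmoid inner-product similarity between tail vectors
#'
#' @param predicted,actual vectors of equal length.
#' @return similarity in (0, 1); 0.5 for orthogonal vectors, increasing in
#'   the inner product.
#' @export
tail_similarity <- function(predicted, actual) {
  sigmoid(sum(predicted * actual))
}

#' @export
predict.kgmr <- function(object, newdata, type = c("click", "tail"), ...) {
  type <- match.arg(type)
  if (type == "click")
    kgmr_forward_rs(object, newdata$user, newdata$item)$p
  else
    kgmr_forward_kg(object, newdata)$Tpred
}

#' @export
print.kgmr <- function(x, ...) {
  cat("Multitask KG recommender (kgmr)\n")
  cat("  users: ", length(x$users), ", entities: ", length(x$entities),
      ", relations: ", length(x$relations), "\n", sep = "")
  cat("  modalities: base",
      if (length(x$modalities)) paste0(" + ", paste(x$modalities,
                                                    collapse = " + ")),
      "; d = ", x$config$d, "\n", sep = "")
  if (!is.null(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  after %d epochs: L_RS %.4f, L_KG %+.4f, total %.4f\n",
                last$epoch, last$L_RS, last$L_KG, last$total))
  }
  invisible(x)
}

#' @export
summary.kgmr <- function(object, ...) {
  cat("Multitask KG recommender\n")
  print(object)
  if (!is.null(object$trace)) {
    cat("\nLoss trace (per epoch):\n")
    print(object$trace, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
plot.kgmr <- function(x, ...) {
  if (is.null(x$trace)) stop_value("no trace to plot")
  plot(x$trace$epoch, x$trace$L_RS, type = "l", xlab = "epoch",
       ylab = "loss", main = "Joint training", ...)
  graphics::lines(x$trace$epoch, x$trace$total, lty = 2)
  graphics::legend("topright", c("L_RS", "total"), lty = c(1, 2), bty = "n")
  invisible(x)
}
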