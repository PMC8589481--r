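## GRU sentence encoder in the skip-thought style: a document's tokens are
## mapped to word vectors and run through a single GRU layer; the final
## hidden state is the document vector. Optional pretraining attaches two
## GRU decoders that reconstruct the previous and next sentence of a
## document stream from the encoded state. A mean-pooling fallback encoder
## is also provided and flagged in the output metadata.

gru_cell_init <- function(d_in, d_h, seed) {
  with_seed(seed, {
    g <- function() rand_mat(d_h, d_in)
    u <- function() rand_mat(d_h, d_h)
    list(Wz = g(), Uz = u(), bz = numeric(d_h),
         Wr = g(), Ur = u(), br = numeric(d_h),
         Wh = g(), Uh = u(), bh = numeric(d_h))
  })
}

## one GRU step; returns new hidden plus the intermediates needed for BPTT
gru_step <- function(cell, x, h) {
  z <- sigmoid(drop(cell$Wz %*% x + cell$Uz %*% h) + cell$bz)
  r <- sigmoid(drop(cell$Wr %*% x + cell$Ur %*% h) + cell$br)
  hh <- tanh(drop(cell$Wh %*% x + cell$Uh %*% (r * h)) + cell$bh)
  list(h = (1 - z) * h + z * hh, z = z, r = r, hh = hh, x = x, h_prev = h)
}

gru_forward <- function(cell, X, h0 = NULL) {
  d_h <- length(cell$bz)
  h <- h0 %||% numeric(d_h)
  steps <- vector("list", nrow(X))
  for (t in seq_len(nrow(X))) {
    steps[[t]] <- gru_step(cell, X[t, ], h)
    h <- steps[[t]]$h
  }
  list(h = h, steps = steps)
}

## scale factor implementing global-norm gradient clipping
clip_scale <- function(grads, clip) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > clip) clip / nrm else 1
}

## backward through a forward pass. dh_steps: list of gradients w.r.t. each
## step's output hidden (NULL entries allowed); returns cell gradients and
## the gradient w.r.t. the initial hidden state.
gru_backward <- function(cell, steps, dh_steps) {
  grads <- lapply(cell, function(p) p * 0)
  dh <- numeric(length(cell$bz))
  for (t in rev(seq_along(steps))) {
    s <- steps[[t]]
    if (!is.null(dh_steps[[t]])) dh <- dh + dh_steps[[t]]
    dz <- dh * (s$hh - s$h_prev)
    dhh <- dh * s$z
    dh_prev <- dh * (1 - s$z)
    dhh_pre <- dhh * (1 - s$hh^2)
    grads$Wh <- grads$Wh + outer(dhh_pre, s$x)
    grads$Uh <- grads$Uh + outer(dhh_pre, s$r * s$h_prev)
    grads$bh <- grads$bh + dhh_pre
    drh <- drop(crossprod(cell$Uh, dhh_pre))
    dr <- drh * s$h_prev
    dh_prev <- dh_prev + drh * s$r
    dz_pre <- dz * s$z * (1 - s$z)
    dr_pre <- dr * s$r * (1 - s$r)
    grads$Wz <- grads$Wz + outer(dz_pre, s$x)
    grads$Uz <- grads$Uz + outer(dz_pre, s$h_prev)
    grads$bz <- grads$bz + dz_pre
    grads$Wr <- grads$Wr + outer(dr_pre, s$x)
    grads$Ur <- grads$Ur + outer(dr_pre, s$h_prev)
    grads$br <- grads$br + dr_pre
    dh <- dh_prev + drop(crossprod(cell$Uz, dz_pre)) +
      drop(crossprod(cell$Ur, dr_pre))
  }
  list(grads = grads, dh0 = dh)
}

#' Build a sentence encoder over a fitted word-embedding model
#'
#' @param word_model a fitted [skipgram()] model supplying word vectors.
#' @param hidden GRU hidden size (the sentence-vector dimension for mode
#'   `"gru"`; mode `"mean"` returns word-vector-dimension means).
#' @param mode `"gru"` (final hidden state) or `"mean"` (mean pooling).
#' @param seed integer seed for GRU weight initialization.
#' @return object of class `sentence_encoder`.
#' @export
sentence_encoder <- function(word_model, hidden = 32L, mode = c("gru", "mean"),
                             seed = 1L) {
  mode <- match.arg(mode)
  structure(list(
    cell = gru_cell_init(word_model$dim, hidden,
                         derive_seed(seed, "gru-encoder")),
    hidden = as.integer(hidden), mode = mode, dim_in = word_model$dim,
    seed = as.integer(seed)),
    class = "sentence_encoder")
}

doc_matrix <- function(document, word_model) {
  toks <- tokenize(document)
  if (length(toks) == 0L) stop_value("empty document")
  word_model$W_in[sg_lookup(word_model$vocab, toks), , drop = FALSE]
}

#' Encode a document as a fixed-length vector
#'
#' Runs the document's word vectors through the encoder: the GRU's final
#' hidden state (mode `"gru"`, order-sensitive) or the mean word vector
#' (mode `"mean"`, order-invariant fallback). The mode used is attached as
#' attribute `"mode"`.
#'
#' @param document a text string.
#' @param word_model a fitted [skipgram()] model.
#' @param encoder a [sentence_encoder()].
#' @return numeric vector of the encoder's output dimension.
#' @export
encode_sentence <- function(document, word_model, encoder) {
  X <- doc_matrix(document, word_model)
  out <- if (encoder$mode == "mean") colMeans(X)
         else gru_forward(encoder$cell, X)$h
  attr(out, "mode") <- encoder$mode
  out
}

#' Encode a set of entity documents
#'
#' @param documents named list, entity id -> text.
#' @inheritParams encode_sentence
#' @return matrix, one row per entity id.
#' @export
encode_documents <- function(documents, word_model, encoder) {
  out <- t(vapply(documents, function(d) {
    v <- encode_sentence(d, word_model, encoder)
    attributes(v) <- NULL
    v
  }, numeric(if (encoder$mode == "mean") word_model$dim else encoder$hidden)))
  rownames(out) <- names(documents)
  out
}

#' Pretrain a GRU sentence encoder with the skip-thought objective
#'
#' Treats `documents` (in order) as a sentence stream. Each interior
#' sentence is encoded; two GRU decoders, initialized from the encoded
#' state, reconstruct the previous and the next sentence token-by-token
#' under teacher forcing with a softmax over the word vocabulary. Word
#' vectors stay frozen; encoder, decoders and the output layer train by
#' backpropagation through time.
#'
#' @param documents character vector / list of sentences in stream order
#'   (at least 3).
#' @param word_model a fitted [skipgram()] model.
#' @param encoder a [sentence_encoder()] with mode `"gru"`.
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param clip global gradient-norm clip per update (BPTT through long
#'   sentences is otherwise prone to exploding gradients).
#' @return the encoder with updated weights and a per-epoch NLL `trace`.
#' @export
train_skipthought <- function(documents, word_model, encoder, lr = 0.05,
                              epochs = 10L, seed = 1L, clip = 5) {
  if (encoder$mode != "gru") stop_value("skip-thought needs a GRU encoder")
  docs <- unlist(documents)
  if (length(docs) < 3L) stop_value("need at least 3 sentences in the stream")
  V <- word_model$vocab$size
  dh <- encoder$hidden
  with_seed(derive_seed(seed, "skipthought"), {
    dec_prev <- gru_cell_init(word_model$dim, dh, derive_seed(seed, "dec-prev"))
    dec_next <- gru_cell_init(word_model$dim, dh, derive_seed(seed, "dec-next"))
    W_vocab <- rand_mat(V, dh)
    b_vocab <- numeric(V)
    Xs <- lapply(docs, doc_matrix, word_model = word_model)
    ids <- lapply(docs, function(d) sg_lookup(word_model$vocab, tokenize(d)))
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      tot <- 0; ntok <- 0
      for (i in 2:(length(docs) - 1L)) {
        enc <- gru_forward(encoder$cell, Xs[[i]])
        dh0_total <- numeric(dh)
        for (side in c("prev", "next")) {
          cell <- if (side == "prev") dec_prev else dec_next
          j <- if (side == "prev") i - 1L else i + 1L
          Xt <- Xs[[j]]; yt <- ids[[j]]
          Tn <- nrow(Xt)
          ## teacher forcing: input at step t is the previous target token
          Xin <- rbind(numeric(word_model$dim),
                       Xt[-Tn, , drop = FALSE])
          fwd <- gru_forward(cell, Xin, h0 = enc$h)
          H <- t(vapply(fwd$steps, `[[`, numeric(dh), "h"))   # Tn x dh
          U <- H %*% t(W_vocab) + matrix(b_vocab, Tn, V, byrow = TRUE)
          P <- softmax_rows(U)
          tot <- tot - sum(log(pmax(P[cbind(seq_len(Tn), yt)], 1e-300)))
          ntok <- ntok + Tn
          G <- P
          G[cbind(seq_len(Tn), yt)] <- G[cbind(seq_len(Tn), yt)] - 1
          gW_vocab <- crossprod(G, H)
          gb_vocab <- colSums(G)
          dH <- G %*% W_vocab
          bwd <- gru_backward(cell, fwd$steps,
                              lapply(seq_len(Tn), function(t) dH[t, ]))
          sc <- clip_scale(c(bwd$grads, list(gW_vocab, gb_vocab)), clip)
          for (nm in names(cell))
            cell[[nm]] <- cell[[nm]] - lr * sc * bwd$grads[[nm]]
          W_vocab <- W_vocab - lr * sc * gW_vocab
          b_vocab <- b_vocab - lr * sc * gb_vocab
          dh0_total <- dh0_total + bwd$dh0
          if (side == "prev") dec_prev <- cell else dec_next <- cell
        }
        ## push the decoders' gradient into the encoder via its final state
        dh_steps <- vector("list", length(enc$steps))
        dh_steps[[length(enc$steps)]] <- dh0_total
        ebwd <- gru_backward(encoder$cell, enc$steps, dh_steps)
        sc <- clip_scale(ebwd$grads, clip)
        for (nm in names(encoder$cell))
          encoder$cell[[nm]] <- encoder$cell[[nm]] - lr * sc * ebwd$grads[[nm]]
      }
      trace[ep] <- tot / ntok
      if (!is.finite(trace[ep]))
        stop_value("divergence error at epoch ", ep, ": non-finite loss")
    }
    encoder$trace <- trace
    encoder
  })
}

#' @export
print.sentence_encoder <- function(x, ...) {
  cat("Sentence encoder (", x$mode, "), hidden = ", x$hidden,
      ", input dim = ", x$dim_in, "\n", sep = "")
  if (!is.null(x$trace))
    cat("  skip-thought NLL/token: ",
        format(utils::tail(x$trace, 1L), digits = 4), "\n", sep = "")
  invisible(x)
}
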