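## Skip-gram word embeddings with an exact full-softmax objective. The
## synthetic vocabularies are small by construction, so the softmax over
## the whole vocabulary is computed directly rather than approximated by
## negative sampling.

tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[[:space:]]+"))
  toks[nzchar(toks)]
}

#' Build a vocabulary from a corpus
#'
#' Tokens (whitespace-split, lowercased) with frequency at least
#' `min_count` are indexed deterministically: by decreasing frequency,
#' ties broken lexicographically.
#'
#' @param corpus character vector of documents, or named list of texts.
#' @param min_count minimum token frequency.
#' @return object of class `sg_vocab`: `index` (token -> 1-based id),
#'   `tokens`, `size`, `counts`.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  toks <- tokenize(paste(unlist(corpus), collapse = " "))
  if (length(toks) == 0L) stop_value("corpus is empty")
  tab <- table(toks)
  tab <- tab[tab >= min_count]
  if (length(tab) == 0L) stop_value("empty vocabulary after min_count filter")
  ord <- order(-as.integer(tab), names(tab))
  tokens <- names(tab)[ord]
  structure(list(index = stats::setNames(seq_along(tokens), tokens),
                 tokens = tokens, size = length(tokens),
                 counts = as.integer(tab)[ord]),
            class = "sg_vocab")
}

sg_lookup <- function(vocab, words) {
  idx <- vocab$index[words]
  if (anyNA(idx)) stop_value("vocabulary error: unknown token(s): ",
                             paste(words[is.na(idx)], collapse = ", "))
  unname(idx)
}

sg_init <- function(vocab, dim = 16L, window = 2L, seed = 1L) {
  with_seed(derive_seed(seed, "skipgram-init"), {
    structure(list(
      W_in = matrix(stats::runif(vocab$size * dim, -0.5, 0.5) / dim,
                    vocab$size, dim, dimnames = list(vocab$tokens, NULL)),
      W_out = matrix(0, dim, vocab$size, dimnames = list(NULL, vocab$tokens)),
      vocab = vocab, dim = as.integer(dim), window = as.integer(window)),
      class = "skipgram")
  })
}

## raw output scores u_j for one center word: 1 x V
sg_scores <- function(model, center) {
  drop(model$W_in[sg_lookup(model$vocab, center), , drop = FALSE] %*%
         model$W_out)
}

#' Softmax probability of a context word given a center word
#'
#' `exp(u_j) / sum_j' exp(u_j')` over the output scores `u` of the center
#' word: a proper distribution over the vocabulary.
#'
#' @param model a `skipgram` model.
#' @param input_word center word.
#' @param target_word context word whose probability is returned.
#' @return probability in (0, 1).
#' @export
context_prob <- function(model, input_word, target_word) {
  u <- sg_scores(model, input_word)
  p <- drop(softmax_rows(u))
  p[sg_lookup(model$vocab, target_word)]
}

#' Skip-gram negative log-likelihood of a context window
#'
#' `-sum_c u_{j*(c)} + |context| * log sum_j exp(u_j)`: the negative log
#' probability of the observed context words under the full softmax, which
#' equals `-sum_c log context_prob(center, context_c)`.
#'
#' @param model a `skipgram` model.
#' @param center_word center word.
#' @param context_words character vector, between 1 and 2*window words.
#' @return nonnegative scalar.
#' @export
skipgram_loss <- function(model, center_word, context_words) {
  nc <- length(context_words)
  if (nc < 1L || nc > 2L * model$window)
    stop_value("context size must be in [1, 2*window]")
  u <- sg_scores(model, center_word)
  j <- sg_lookup(model$vocab, context_words)
  mx <- max(u)
  lse <- mx + log(sum(exp(u - mx)))
  -sum(u[j]) + nc * lse
}

## (center, context) index pairs from a token stream with window C
sg_pairs <- function(ids, window) {
  n <- length(ids)
  ctr <- integer(0); ctx <- integer(0)
  for (off in seq_len(window)) {
    if (n > off) {
      ctr <- c(ctr, ids[seq_len(n - off)], ids[(off + 1L):n])
      ctx <- c(ctx, ids[(off + 1L):n], ids[seq_len(n - off)])
    }
  }
  cbind(center = ctr, context = ctx)
}

#' Fit skip-gram word embeddings by full-softmax SGD
#'
#' @param corpus character vector or named list of documents.
#' @param dim embedding dimension.
#' @param window context window size C.
#' @param min_count vocabulary frequency threshold.
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size (center/context pairs).
#' @param seed integer seed.
#' @return object of class `skipgram` with matrices `W_in` (V x d input
#'   embeddings, the word vectors), `W_out` (d x V), the `sg_vocab`, and a
#'   per-epoch mean-NLL `trace`.
#' @export
skipgram <- function(corpus, dim = 16L, window = 2L, min_count = 1L,
                     lr = 0.5, epochs = 30L, batch_size = 256L, seed = 1L) {
  vocab <- build_vocab(corpus, min_count)
  model <- sg_init(vocab, dim, window, seed)
  streams <- lapply(unlist(corpus), function(txt) {
    toks <- tokenize(txt)
    unname(vocab$index[toks[toks %in% names(vocab$index)]])
  })
  pairs <- do.call(rbind, lapply(streams, sg_pairs, window = window))
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop_value("corpus too short for window size")
  n <- nrow(pairs)
  trace <- numeric(epochs)
  with_seed(derive_seed(seed, "skipgram-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        ctr <- pairs[idx, 1L]; ctx <- pairs[idx, 2L]
        X <- model$W_in[ctr, , drop = FALSE]        # B x d
        U <- X %*% model$W_out                      # B x V
        P <- softmax_rows(U)
        B <- length(idx)
        tot <- tot - sum(log(pmax(P[cbind(seq_len(B), ctx)], 1e-300)))
        G <- P                                       # dU = P - onehot(ctx)
        G[cbind(seq_len(B), ctx)] <- G[cbind(seq_len(B), ctx)] - 1
        gW_out <- crossprod(X, G)                    # d x V
        gX <- G %*% t(model$W_out)                   # B x d
        model$W_out <- model$W_out - lr * gW_out / B
        gIn <- rowsum(gX, ctr)
        rows <- as.integer(rownames(gIn))
        model$W_in[rows, ] <- model$W_in[rows, , drop = FALSE] -
          lr * gIn / B
      }
      trace[ep] <- tot / n
      if (!is.finite(trace[ep]))
        stop_value("divergence error at epoch ", ep, ": non-finite loss")
    }
  })
  model$trace <- trace
  model
}

#' @export
print.skipgram <- function(x, ...) {
  cat("Skip-gram word embedding model\n")
  cat("  vocabulary: ", x$vocab$size, ", dim: ", x$dim, ", window: ",
      x$window, "\n", sep = "")
  if (!is.null(x$trace))
    cat("  final NLL/pair: ", format(utils::tail(x$trace, 1L), digits = 4),
        "\n", sep = "")
  invisible(x)
}

#' Word vectors of a fitted skip-gram model
#'
#' @param object a `skipgram` model.
#' @param ... unused.
#' @return V x d matrix of input embeddings, rows named by token.
#' @export
coef.skipgram <- function(object, ...) object$W_in
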