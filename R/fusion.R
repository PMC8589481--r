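## Multimodal entity encoder: the structural (TransD), textual (sentence)
## and visual (residual-encoder) vectors of an entity are concatenated --
## any absent modality replaced by a learned per-modality default vector --
## and passed through one dense layer with a nonlinearity to yield the
## entity representation consumed by both downstream tasks.

MODALITIES <- c("structural", "textual", "visual")

#' Initialize fusion weights
#'
#' @param dims named list/vector of input dimensions per modality, in the
#'   order `structural`, `textual`, `visual` (a modality may be omitted
#'   entirely to exclude it from the encoder).
#' @param out_dim fused entity dimension.
#' @param activation `"tanh"` or `"linear"`.
#' @param init `"random"` or `"identity"` (identity places an identity
#'   matrix on each modality block whose dimension equals `out_dim`;
#'   defaults and bias start at zero).
#' @param seed integer seed.
#' @return object of class `fusion_weights`: `W` (total_in x out_dim), `b`,
#'   per-modality `defaults`, `dims`, `activation`.
#' @export
fusion_weights <- function(dims, out_dim = 16L,
                           activation = c("tanh", "linear"),
                           init = c("random", "identity"), seed = 1L) {
  activation <- match.arg(activation)
  init <- match.arg(init)
  dims <- unlist(dims)
  dims <- dims[intersect(MODALITIES, names(dims))]
  if (length(dims) == 0L) stop_value("at least one modality dimension needed")
  tot <- sum(dims)
  with_seed(derive_seed(seed, "fusion"), {
    if (init == "identity") {
      W <- matrix(0, tot, out_dim)
      off <- 0L
      for (m in names(dims)) {
        if (dims[[m]] == out_dim)
          W[off + seq_len(out_dim), ] <- diag(out_dim)
        off <- off + dims[[m]]
      }
      defaults <- lapply(dims, numeric)
    } else {
      W <- rand_mat(tot, out_dim)
      defaults <- lapply(dims, function(d) stats::runif(d, -0.1, 0.1))
    }
    structure(list(W = W, b = numeric(out_dim), defaults = defaults,
                   dims = dims, out_dim = as.integer(out_dim),
                   activation = activation),
              class = "fusion_weights")
  })
}

fusion_act <- function(pre, activation) {
  if (activation == "tanh") tanh(pre) else pre
}

#' Fuse an entity's multimodal features into one vector
#'
#' Concatenates the present modality vectors (absent ones replaced by the
#' learned per-modality default), applies the dense layer and the
#' configured nonlinearity.
#'
#' @param features list with `entity_id` and any of `structural`,
#'   `textual`, `visual` vectors (NULL = absent).
#' @param weights a [fusion_weights()] object.
#' @return fused vector of length `weights$out_dim`.
#' @export
fuse <- function(features, weights) {
  present <- MODALITIES[vapply(MODALITIES,
                               function(m) !is.null(features[[m]]), TRUE)]
  present <- intersect(present, names(weights$dims))
  if (length(present) == 0L)
    stop_value("all modalities absent for entity ",
               features$entity_id %||% "?")
  z <- unlist(lapply(names(weights$dims), function(m) {
    v <- features[[m]] %||% weights$defaults[[m]]
    if (length(v) != weights$dims[[m]])
      stop_value("shape error: ", m, " vector has wrong dimension")
    v
  }))
  fusion_act(drop(z %*% weights$W) + weights$b, weights$activation)
}

#' Encode every KG entity into its fused representation
#'
#' @param entities character vector of entity ids.
#' @param structural matrix of structural vectors (rows named by entity;
#'   every entity must have one).
#' @param text_vectors,image_vectors optional matrices keyed by entity id;
#'   entities absent from a table use that modality's learned default. Ids
#'   not in `entities` raise a vocabulary error.
#' @param weights a [fusion_weights()] object.
#' @return matrix of fused vectors, one row per entity.
#' @export
encode_entities <- function(entities, structural, text_vectors = NULL,
                            image_vectors = NULL, weights) {
  for (tab in list(text_vectors, image_vectors))
    if (!is.null(tab) && !all(rownames(tab) %in% entities))
      stop_value("vocabulary error: unknown entity id in modality table")
  if (!all(entities %in% rownames(structural)))
    stop_value("vocabulary error: entity lacking structural vector")
  out <- t(vapply(entities, function(id) {
    fuse(list(
      entity_id = id,
      structural = structural[id, ],
      textual = if (!is.null(text_vectors) && id %in% rownames(text_vectors))
        text_vectors[id, ] else NULL,
      visual = if (!is.null(image_vectors) && id %in% rownames(image_vectors))
        image_vectors[id, ] else NULL), weights)
  }, numeric(weights$out_dim)))
  rownames(out) <- entities
  out
}
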