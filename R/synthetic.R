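#' Define a typed knowledge-graph schema
#'
#' A schema names the entity types of a medical knowledge graph, how many
#' entities of each type exist, and which directed relations connect them.
#' The default schema mirrors a small healthcare graph: diseases linked to
#' symptoms, treating drugs, recommended foods, responsible departments and
#' required examinations.
#'
#' @param entity_types character vector of entity type names.
#' @param relations data.frame with columns `name`, `head_type`, `tail_type`.
#' @param counts named integer vector, entities per type.
#' @return an object of class `kg_schema`.
#' @examples
#' sch <- kg_schema(c("disease", "symptom"),
#'   data.frame(name = "has_symptom", head_type = "disease",
#'              tail_type = "symptom"),
#'   c(disease = 2, symptom = 3))
#' @export
kg_schema <- function(entity_types, relations, counts) {
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "head_type", "tail_type") %in% names(relations)))
  if (!all(relations$head_type %in% entity_types) ||
      !all(relations$tail_type %in% entity_types))
    stop_value("schema error: relation endpoint type not in entity_types")
  touched <- unique(c(relations$head_type, relations$tail_type))
  if (!all(touched %in% names(counts)) || any(counts[touched] < 1))
    stop_value("schema error: every type touched by a relation needs count >= 1")
  counts <- vapply(counts, as.integer, integer(1))
  structure(list(entity_types = entity_types, relations = relations,
                 counts = counts), class = "kg_schema")
}

#' @rdname kg_schema
#' @export
default_schema <- function() {
  kg_schema(
    entity_types = c("disease", "symptom", "drug", "food", "department",
                     "examination"),
    relations = data.frame(
      name = c("has_symptom", "treated_by_drug", "recommended_food",
               "belongs_to_department", "requires_examination"),
      head_type = "disease",
      tail_type = c("symptom", "drug", "food", "department", "examination"),
      stringsAsFactors = FALSE),
    counts = c(disease = 12L, symptom = 16L, drug = 14L, food = 10L,
               department = 4L, examination = 9L))
}

entity_ids <- function(type, n) sprintf("%s%02d", type, seq_len(n))

## Entity ids are type-prefixed ("drug03"), so the type is recoverable from
## the id alone; this keeps triple files self-describing.
entity_type_of <- function(ids) sub("[0-9]+$", "", ids)

## Item-eligible types: entities a user can be recommended.
ITEM_TYPES <- c("drug", "food", "examination")

#' Generate a typed knowledge graph
#'
#' Samples triples per relation type: each eligible head--tail pair is
#' included independently with probability `density`, and every head is
#' guaranteed at least one tail of the correct type so no entity is
#' isolated within a relation. Output is deterministic per seed.
#'
#' @param schema a [kg_schema()].
#' @param density inclusion probability for each head--tail pair, in (0, 1].
#' @param seed integer seed.
#' @return data.frame with columns `head`, `relation`, `tail`; no duplicate
#'   rows. The schema is attached as attribute `"schema"`.
#' @export
generate_kg <- function(schema, density = 0.6, seed = 1L) {
  if (!inherits(schema, "kg_schema")) stop_value("schema error: not a kg_schema")
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop_value("density must lie in (0, 1]")
  with_seed(derive_seed(seed, "kg"), {
    out <- vector("list", nrow(schema$relations))
    for (i in seq_len(nrow(schema$relations))) {
      rel <- schema$relations[i, ]
      heads <- entity_ids(rel$head_type, schema$counts[[rel$head_type]])
      tails <- entity_ids(rel$tail_type, schema$counts[[rel$tail_type]])
      keep <- matrix(stats::runif(length(heads) * length(tails)) < density,
                     nrow = length(heads))
      ## guarantee: each head keeps at least one tail
      for (h in which(rowSums(keep) == 0L))
        keep[h, sample.int(length(tails), 1L)] <- TRUE
      idx <- which(keep, arr.ind = TRUE)
      out[[i]] <- data.frame(head = heads[idx[, 1L]], relation = rel$name,
                             tail = tails[idx[, 2L]],
                             stringsAsFactors = FALSE)
    }
    triples <- do.call(rbind, out)
    triples <- unique(triples)
    triples <- triples[order(triples$relation, triples$head, triples$tail), ]
    rownames(triples) <- NULL
    attr(triples, "schema") <- schema
    triples
  })
}

kg_entities <- function(triples) sort(unique(c(triples$head, triples$tail)))

kg_items <- function(triples) {
  ents <- kg_entities(triples)
  ents[entity_type_of(ents) %in% ITEM_TYPES]
}

## disease x item adjacency: TRUE when any triple links the disease (head)
## to the item (tail).
kg_adjacency <- function(triples) {
  diseases <- sort(unique(triples$head[entity_type_of(triples$head) == "disease"]))
  items <- kg_items(triples)
  adj <- matrix(FALSE, length(diseases), length(items),
                dimnames = list(diseases, items))
  hit <- triples$tail %in% items & triples$head %in% diseases
  if (any(hit))
    adj[cbind(match(triples$head[hit], diseases),
              match(triples$tail[hit], items))] <- TRUE
  adj
}

#' Generate user--item interactions whose labels depend on KG structure
#'
#' Each synthetic user holds latent taste factors and one preferred
#' disease. An item's positive-label probability is logistic in the latent
#' user--item affinity plus `kg_weight` times a centred indicator of KG
#' adjacency between the item and the preferred disease, so `kg_weight`
#' controls how much exploitable signal the knowledge graph carries. With
#' probability `noise` a label is replaced by a fair coin.
#'
#' @param triples KG triples from [generate_kg()].
#' @param n_users,n_per_user number of users and interactions per user.
#' @param kg_weight nonnegative strength of the KG adjacency effect.
#' @param noise label-noise probability in \[0, 1).
#' @param seed integer seed.
#' @param latent_dim dimension of the latent taste factors.
#' @return data.frame with columns `user`, `item`, `label` and attributes
#'   `user_factors`, `item_factors`, `preferred_disease`, `adjacency`.
#' @export
generate_interactions <- function(triples, n_users = 200L, n_per_user = 30L,
                                  kg_weight = 10, noise = 0.1, seed = 1L,
                                  latent_dim = 8L) {
  if (is.null(triples) || nrow(triples) == 0L)
    stop_value("triples must be nonempty")
  if (kg_weight < 0) stop_value("kg_weight must be >= 0")
  if (noise < 0 || noise >= 1) stop_value("noise must lie in [0, 1)")
  items <- kg_items(triples)
  if (length(items) == 0L) stop_value("no item-eligible entities in triples")
  adj <- kg_adjacency(triples)
  diseases <- rownames(adj)
  with_seed(derive_seed(seed, "interactions"), {
    users <- sprintf("u%03d", seq_len(n_users))
    uf <- matrix(stats::rnorm(n_users * latent_dim), n_users, latent_dim,
                 dimnames = list(users, NULL))
    itf <- matrix(stats::rnorm(length(items) * latent_dim), length(items),
                  latent_dim, dimnames = list(items, NULL))
    pref <- stats::setNames(sample(diseases, n_users, replace = TRUE), users)
    affinity <- uf %*% t(itf) / sqrt(latent_dim)          # users x items
    rec_user <- rep(users, each = n_per_user)
    rec_item <- items[unlist(lapply(seq_len(n_users), function(u)
      sample.int(length(items), n_per_user, replace = TRUE)))]
    ui <- cbind(match(rec_user, users), match(rec_item, items))
    adj_flag <- adj[cbind(match(pref[rec_user], diseases), ui[, 2L])]
    p <- sigmoid(affinity[ui] + kg_weight * (as.numeric(adj_flag) - 0.5))
    label <- as.integer(stats::runif(length(p)) < p)
    flip <- stats::runif(length(p)) < noise
    label[flip] <- as.integer(stats::runif(sum(flip)) < 0.5)
    ## per-user positive rate must be strictly inside (0,1): repair a
    ## degenerate user by flipping their least confident record
    for (u in seq_len(n_users)) {
      rows <- which(ui[, 1L] == u)
      m <- mean(label[rows])
      if (m == 0) label[rows[which.max(p[rows])]] <- 1L
      else if (m == 1) label[rows[which.min(p[rows])]] <- 0L
    }
    out <- data.frame(user = rec_user, item = rec_item, label = label,
                      stringsAsFactors = FALSE)
    attr(out, "user_factors") <- uf
    attr(out, "item_factors") <- itf
    attr(out, "preferred_disease") <- pref
    attr(out, "adjacency") <- adj
    out
  })
}

#' Generate symptom-description documents for disease entities
#'
#' Each disease draws `doc_len` tokens from a disease-specific topic
#' distribution over a shared vocabulary: a private token block per disease
#' plus a pool shared by all diseases (`shared_frac` of the vocabulary).
#' With `shared_frac = 0` and enough vocabulary, topic supports are
#' disjoint.
#'
#' @param triples KG triples; diseases are taken from their heads.
#' @param vocab_size vocabulary size, >= 2.
#' @param doc_len tokens per document, >= 1.
#' @param seed integer seed.
#' @param shared_frac fraction of the vocabulary shared across diseases.
#' @param private_mass probability mass a disease puts on its private block.
#' @return named list: entity id -> single whitespace-separated string.
#' @export
generate_documents <- function(triples, vocab_size = 60L, doc_len = 120L,
                               seed = 1L, shared_frac = 0.25,
                               private_mass = 0.8) {
  if (vocab_size < 2L) stop_value("vocab_size must be >= 2")
  if (doc_len < 1L) stop_value("doc_len must be >= 1")
  diseases <- sort(unique(c(triples$head, triples$tail)))
  diseases <- diseases[entity_type_of(diseases) == "disease"]
  vocab <- sprintf("w%03d", seq_len(vocab_size))
  n_shared <- floor(vocab_size * shared_frac)
  n_private <- (vocab_size - n_shared) %/% max(length(diseases), 1L)
  with_seed(derive_seed(seed, "documents"), {
    docs <- stats::setNames(vector("list", length(diseases)), diseases)
    for (i in seq_along(diseases)) {
      private <- if (n_private > 0L)
        vocab[seq.int((i - 1L) * n_private + 1L, i * n_private)] else character()
      shared <- if (n_shared > 0L) vocab[seq.int(vocab_size - n_shared + 1L,
                                                 vocab_size)] else character()
      support <- c(private, shared)
      if (length(support) == 0L) support <- vocab
      prob <- if (length(private) > 0L && length(shared) > 0L)
        c(rep(private_mass / length(private), length(private)),
          rep((1 - private_mass) / length(shared), length(shared)))
      else rep(1 / length(support), length(support))
      docs[[i]] <- paste(sample(support, doc_len, replace = TRUE, prob = prob),
                         collapse = " ")
    }
    docs
  })
}

#' Generate toy grayscale images for disease entities
#'
#' Each disease class carries a parametric blob pattern: disease `i` gets
#' `1 + (i - 1) mod 3` Gaussian blobs of fixed radius at seeded positions,
#' plus additive uniform noise, clamped to \[0, 1\]. Blob count is the
#' class signal a visual encoder can recover; the per-entity parameters are
#' attached as attribute `"params"` for test oracles.
#'
#' @param triples KG triples; diseases are taken from entity ids.
#' @param size image side length, >= 8.
#' @param seed integer seed.
#' @param noise additive noise amplitude.
#' @param n_variants images generated per disease (variants differ in blob
#'   placement; with `n_variants = 1` the map is entity id -> matrix,
#'   otherwise entity id gets suffixed variant keys).
#' @return named list: key -> size x size matrix in \[0, 1\].
#' @export
generate_images <- function(triples, size = 32L, seed = 1L, noise = 0.05,
                            n_variants = 1L) {
  if (size < 8L) stop_value("size must be >= 8")
  diseases <- sort(unique(c(triples$head, triples$tail)))
  diseases <- diseases[entity_type_of(diseases) == "disease"]
  radius <- size / 6
  with_seed(derive_seed(seed, "images"), {
    keys <- character(0); imgs <- list(); params <- NULL
    gx <- matrix(rep(seq_len(size), size), size)
    gy <- t(gx)
    for (i in seq_along(diseases)) {
      n_blobs <- 1L + (i - 1L) %% 3L
      for (v in seq_len(n_variants)) {
        img <- matrix(0, size, size)
        for (b in seq_len(n_blobs)) {
          cx <- stats::runif(1, radius, size - radius)
          cy <- stats::runif(1, radius, size - radius)
          img <- img + 0.9 * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * (radius / 2)^2))
        }
        if (noise > 0)
          img <- img + matrix(stats::runif(size * size, 0, noise), size)
        img <- pmin(pmax(img, 0), 1)
        key <- if (n_variants == 1L) diseases[i]
               else sprintf("%s.v%02d", diseases[i], v)
        keys <- c(keys, key)
        imgs[[key]] <- img
        params <- rbind(params, data.frame(key = key, entity = diseases[i],
                                           n_blobs = n_blobs, radius = radius,
                                           stringsAsFactors = FALSE))
      }
    }
    attr(imgs, "params") <- params
    imgs
  })
}

#' Generate a complete synthetic world
#'
#' Bundles the KG, interactions, documents and images produced from one
#' seed. These defaults are the package's reference study conditions.
#'
#' @inheritParams generate_kg
#' @inheritParams generate_interactions
#' @inheritParams generate_documents
#' @param image_size image side length.
#' @param image_noise image noise amplitude.
#' @return object of class `synthetic_world` with elements `triples`,
#'   `interactions`, `documents`, `images`, `schema`, `seed`, `params`.
#' @export
synthetic_world <- function(schema = default_schema(), density = 0.6,
                            n_users = 200L, n_per_user = 30L, kg_weight = 10,
                            noise = 0.1, vocab_size = 60L, doc_len = 120L,
                            image_size = 32L, image_noise = 0.05, seed = 1L) {
  triples <- generate_kg(schema, density, seed)
  inter <- generate_interactions(triples, n_users, n_per_user, kg_weight,
                                 noise, seed)
  docs <- generate_documents(triples, vocab_size, doc_len, seed)
  imgs <- generate_images(triples, image_size, seed, image_noise)
  ## referential integrity: interactions/documents/images only reference
  ## entities present in the KG
  ents <- kg_entities(triples)
  stopifnot(all(inter$item %in% ents), all(names(docs) %in% ents))
  structure(list(
    triples = triples, interactions = inter, documents = docs, images = imgs,
    schema = schema, seed = as.integer(seed),
    params = list(density = density, n_users = n_users,
                  n_per_user = n_per_user, kg_weight = kg_weight,
                  noise = noise, vocab_size = vocab_size, doc_len = doc_len,
                  image_size = image_size, image_noise = image_noise)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic medical KG world (seed ", x$seed, ")\n", sep = "")
  cat("  triples:      ", nrow(x$triples), " over ",
      length(kg_entities(x$triples)), " entities\n", sep = "")
  cat("  interactions: ", nrow(x$interactions), " (",
      length(unique(x$interactions$user)), " users, kg_weight = ",
      x$params$kg_weight, ", noise = ", x$params$noise, ")\n", sep = "")
  cat("  documents:    ", length(x$documents), " | images: ",
      length(x$images), "\n", sep = "")
  invisible(x)
}
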