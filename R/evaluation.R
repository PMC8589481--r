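## Recommendation and link-prediction metrics plus the ablation harness:
## base (structural only) vs base+text vs base+image vs full multimodal
## configurations trained on identical per-seed splits.

#' Recall at K over users
#'
#' Mean over users of `|top-K of ranking  intersect  relevant| / |relevant|`.
#' Users with no relevant items are excluded from the mean.
#'
#' @param ranked_items named list: user -> character vector of items in
#'   ranked order (no duplicates).
#' @param relevant_items named list: user -> character vector of relevant
#'   (held-out positive) items.
#' @param k cutoff, >= 1.
#' @return recall in \[0, 1\].
#' @export
recall_at_k <- function(ranked_items, relevant_items, k) {
  stopifnot(k >= 1L)
  users <- names(ranked_items)
  vals <- numeric(0)
  for (u in users) {
    rel <- unique(relevant_items[[u]])
    if (length(rel) == 0L) next
    rk <- ranked_items[[u]]
    if (anyDuplicated(rk)) stop_value("ranking contains duplicates")
    vals <- c(vals, length(intersect(utils::head(rk, k), rel)) / length(rel))
  }
  if (length(vals) == 0L) stop_value("no user has relevant items")
  mean(vals)
}

#' Area under the ROC curve
#'
#' Probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, ties counted one half (rank formulation).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop_value("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Split interactions into train/validation/test, stratified by user
#'
#' Each user's records are shuffled (seeded) and divided by the given
#' proportions; the three parts are disjoint and stable per seed.
#'
#' @param interactions interactions data.frame.
#' @param prop length-3 proportions (train, validation, test) summing to 1.
#' @param seed integer seed.
#' @return list with `train`, `valid`, `test` data.frames.
#' @export
split_interactions <- function(interactions, prop = c(0.6, 0.2, 0.2),
                               seed = 1L) {
  stopifnot(length(prop) == 3L, abs(sum(prop) - 1) < 1e-8)
  with_seed(derive_seed(seed, "split"), {
    parts <- list(train = integer(0), valid = integer(0), test = integer(0))
    for (rows in split(seq_len(nrow(interactions)), interactions$user)) {
      rows <- sample(rows)
      n <- length(rows)
      n_tr <- floor(prop[1L] * n); n_va <- floor(prop[2L] * n)
      parts$train <- c(parts$train, rows[seq_len(n_tr)])
      parts$valid <- c(parts$valid, rows[n_tr + seq_len(n_va)])
      parts$test <- c(parts$test, rows[-seq_len(n_tr + n_va)])
    }
    lapply(parts, function(ix) interactions[sort(ix), ])
  })
}

#' Held-out top-N and AUC evaluation of a fitted recommender
#'
#' For each test user the held-out positives are ranked against all items
#' the user has not already consumed (their train/validation positives are
#' removed from the candidate pool; a full ranking over the remaining
#' items). Reports per-user-averaged recall@K and AUC over test records.
#'
#' @param model a fitted [kgmr()] model.
#' @param split a [split_interactions()] result.
#' @param k recall cutoff.
#' @param items candidate item pool; defaults to all item-eligible
#'   entities (drug, food, examination) known to the model.
#' @return list with `recall_at_k`, `auc`, `k`, `n_users`.
#' @export
evaluate_model <- function(model, split, k = 10L, items = NULL) {
  if (is.null(items))
    items <- model$entities[entity_type_of(model$entities) %in% ITEM_TYPES]
  test <- split$test
  known <- rbind(split$train, split$valid)
  ranked <- list(); relevant <- list()
  for (u in unique(test$user)) {
    tu <- test[test$user == u, ]
    pos_known <- unique(known$item[known$user == u & known$label == 1L])
    rel <- setdiff(unique(tu$item[tu$label == 1L]), pos_known)
    if (length(rel) == 0L) next
    cand <- setdiff(items, pos_known)
    p <- kgmr_forward_rs(model, rep(u, length(cand)), cand)$p
    ranked[[u]] <- cand[order(-p, cand)]
    relevant[[u]] <- rel
  }
  rec <- recall_at_k(ranked, relevant, k)
  auc <- if (length(unique(test$label)) == 2L)
    auc_score(kgmr_forward_rs(model, test$user, test$item)$p, test$label)
  else NA_real_
  list(recall_at_k = rec, auc = auc, k = as.integer(k),
       n_users = length(ranked))
}

#' Run the ablation harness over model configurations and seeds
#'
#' Trains every configuration on identical per-seed train splits (one
#' world split and one set of pretrained modality features per seed) and
#' reports per-seed and median recall@K / AUC, mirroring a base vs
#' base+text vs base+image vs full comparison.
#'
#' @param world a [synthetic_world()].
#' @param configs named list of modality subsets of `c("text", "image")`;
#'   at least 2 configurations.
#' @param seeds integer vector of at least 3 seeds.
#' @param k recall cutoff.
#' @param config a [kgmr_config()] shared by all configurations.
#' @return object of class `kgmr_ablation`: `per_seed` data.frame and
#'   `table` of medians (model, recall, auc).
#' @export
run_ablation <- function(world,
                         configs = list(base = character(0),
                                        `base+text` = "text",
                                        `base+image` = "image",
                                        full = c("text", "image")),
                         seeds = 1:5, k = 10L, config = kgmr_config()) {
  if (length(configs) < 2L) stop_value("need at least 2 configurations")
  if (length(seeds) < 3L) stop_value("need at least 3 seeds")
  bad <- vapply(configs, function(m) !all(m %in% c("text", "image")), TRUE)
  if (any(bad)) stop_value("harness error: unknown modality in configs")
  per_seed <- NULL
  for (s in seeds) {
    split <- split_interactions(world$interactions, seed = s)
    features <- kgmr_features(world, config, seed = s)
    for (nm in names(configs)) {
      fit <- kgmr(world, modalities = configs[[nm]], config = config,
                  seed = s, features = features, interactions = split$train)
      ev <- evaluate_model(fit, split, k)
      per_seed <- rbind(per_seed, data.frame(
        model = nm, seed = s, recall = ev$recall_at_k, auc = ev$auc,
        stringsAsFactors = FALSE))
    }
  }
  med <- do.call(rbind, lapply(names(configs), function(nm) {
    rows <- per_seed[per_seed$model == nm, ]
    data.frame(model = nm, recall = stats::median(rows$recall),
               auc = stats::median(rows$auc), stringsAsFactors = FALSE)
  }))
  structure(list(per_seed = per_seed, table = med, k = as.integer(k),
                 seeds = seeds), class = "kgmr_ablation")
}

#' @export
print.kgmr_ablation <- function(x, ...) {
  cat("Ablation (median over ", length(x$seeds), " seeds, recall@",
      x$k, ")\n\n", sep = "")
  tab <- x$table
  w <- max(nchar(tab$model)) + 2L
  cat(sprintf(paste0("%-", w, "s %s\n"), "Model", "Recall"))
  for (i in seq_len(nrow(tab)))
    cat(sprintf(paste0("%-", w, "s %.4f\n"), tab$model[i], tab$recall[i]))
  invisible(x)
}

#' Write an ablation report as JSON plus an aligned-text table
#'
#' @param ablation a [run_ablation()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_ablation <- function(ablation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(list(per_seed = ablation$per_seed,
                            median = ablation$table, k = ablation$k,
                            seeds = ablation$seeds),
                       file.path(dir, "ablation.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  con <- file(file.path(dir, "ablation.txt"), "w")
  sink(con); print(ablation); sink()
  close(con)
  invisible(dir)
}
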