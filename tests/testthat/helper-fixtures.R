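## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## minimal two-type schema
tiny_schema <- function(n_disease = 1L, n_symptom = 1L) {
  kg_schema(c("disease", "symptom"),
            data.frame(name = "has_symptom", head_type = "disease",
                       tail_type = "symptom", stringsAsFactors = FALSE),
            c(disease = n_disease, symptom = n_symptom))
}

## a small but complete world shared by the slower model tests
small_world <- function() {
  fixture("small_world", function() synthetic_world(n_users = 30L, seed = 11L))
}

small_features <- function() {
  fixture("small_features", function()
    kgmr_features(small_world(), kgmr_config(kg_pretrain_epochs = 20L,
                                             sg_epochs = 8L), seed = 11L))
}

small_kgmr <- function() {
  fixture("small_kgmr", function()
    kgmr(small_world(), config = kgmr_config(epochs = 3L), seed = 11L,
         features = small_features()))
}

## item-eligible entities known to a fitted kgmr model
kg_items_of <- function(m) {
  m$entities[kgmedrec:::entity_type_of(m$entities) %in%
               c("drug", "food", "examination")]
}

## random TransD parameter draw for oracle checks
random_transd_instance <- function(m, n) {
  list(e = stats::rnorm(n), e_p = stats::rnorm(n), r_p = stats::rnorm(m))
}
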