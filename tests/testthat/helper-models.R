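# Trained models are expensive; build them once per test run and share.
# The small multi-seed study: 16 items over 6 slots (labels 2-5 phones),
# semantic 12 + visual 8 + lexical 120 -> hidden 140, cross-entropy
# objective at the standard hyperparameters (lr 0.4, momentum 0.4,
# Nesterov).

small_study_config <- function(seed) {
  list(synth = synth_config(n_items = 16L, n_categories = 4L,
                            length_range = c(2L, 5L), sem_dim = 12L,
                            vis_raw_dim = 40L, seed = seed),
       train = train_config(epochs = 6000L, eval_every = 200L,
                            seed = seed + 1L, loss_kind = "bce",
                            converge_k = 1L),
       vis_k = 8L, n_slots = 6L)
}

.study_cache <- new.env(parent = emptyenv())

# one trained run of the small study for a given seed
small_study_run <- function(seed) {
  key <- sprintf("run%d", seed)
  if (is.null(.study_cache[[key]])) {
    cfg <- small_study_config(seed)
    corp <- gen_corpus(cfg$synth)
    data <- corpus_dataset(corp, vis_k = cfg$vis_k, n_slots = cfg$n_slots)
    model <- train_gru(data, cfg$train)
    targets <- dataset_targets(data)
    seg <- data$segments
    trials <- suppressWarnings(select_trials(
      data$vocab,
      pairwise_jaccard_table(targets[, seg$semantic, drop = FALSE]),
      pairwise_jaccard_table(targets[, seg$visual, drop = FALSE]),
      data$inv))
    .study_cache[[key]] <- list(model = model, data = data, trials = trials)
  }
  .study_cache[[key]]
}

small_study_seeds <- 1:5

# Visual-world study: the engineered fixture vocabulary (guaranteed to
# contain a valid target-absent tuple) trained under several model seeds,
# mirroring the one-vocabulary / many-models design of the full-scale
# study. 4 slots suffice for the 3-phone fixture labels.
fixture_study_run <- function(seed) {
  key <- sprintf("fix%d", seed)
  if (is.null(.study_cache[[key]])) {
    fx <- gen_vwp_fixture(seed = 1)
    data <- corpus_dataset(list(vocab = fx$vocab, inv = fx$inv,
                                semantic = fx$semantic, visual = fx$visual),
                           n_slots = 4L)
    model <- train_gru(data, train_config(epochs = 6000L, eval_every = 200L,
                                          seed = seed, loss_kind = "bce",
                                          converge_k = 1L))
    targets <- dataset_targets(data)
    seg <- data$segments
    trials <- suppressWarnings(select_trials(
      data$vocab,
      pairwise_jaccard_table(targets[, seg$semantic, drop = FALSE]),
      pairwise_jaccard_table(targets[, seg$visual, drop = FALSE]),
      data$inv))
    .study_cache[[key]] <- list(model = model, data = data, trials = trials)
  }
  .study_cache[[key]]
}

# the scaled 50-item study (shared between the learning-criterion test and
# anything else that needs a converged mid-size model)
scaled_study_cached <- function(seed = 11L) {
  key <- sprintf("scaled%d", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- run_scaled_study(seed = seed)
  .study_cache[[key]]
}
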