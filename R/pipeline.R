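# Dataset assembly, text checkpoints, run configuration, and end-to-end
# orchestration.

#' Assemble a training dataset
#'
#' Builds, for every vocabulary item, the padded dynamic unfolding input
#' and the aggregated static target (semantic, then visual, then lexical
#' segment), plus bookkeeping used by evaluation.
#'
#' @param vocab vocabulary data frame (`item_id`, `label`, `category`).
#' @param inv a [phone_inventory()].
#' @param semantic items-by-dims binary semantic matrix (rows matched to
#'   `vocab$item_id` by row name when present, by position otherwise).
#' @param visual items-by-dims binary visual matrix (already reduced and
#'   binarized; see [preprocess_visual()]).
#' @param n_slots slot capacity (default 10).
#' @return A `lexnet_dataset`: `X` (timesteps x `n_features` x items
#'   array), `Y` (`hidden_dim` x items target matrix), `segments`,
#'   `vocab` (augmented with `n_phones` and `offset_row`), `inv`, `dims`.
#' @export
prepare_dataset <- function(vocab, inv, semantic, visual, n_slots = 10L) {
  semantic <- align_rows(semantic, vocab$item_id)
  visual <- align_rows(visual, vocab$item_id)
  if (!all(semantic %in% c(0, 1)) || !all(visual %in% c(0, 1)))
    stop("semantic and visual matrices must be binary; preprocess first")
  n <- nrow(vocab)
  Tn <- 3L * n_slots + 2L
  X <- array(0, c(Tn, inv$n_features, n))
  lex <- matrix(0, n, n_slots * inv$n_features)
  n_ph <- integer(n)
  for (i in seq_len(n)) {
    lab <- parse_label(vocab$label[i])
    n_ph[i] <- length(lab)
    X[, , i] <- build_unfolding_matrix(lab, inv, n_slots, pad = TRUE)
    lex[i, ] <- build_lexical_vector(lab, inv, n_slots)
  }
  segments <- target_segments(ncol(semantic), ncol(visual), ncol(lex))
  Y <- t(cbind(semantic, visual, lex))
  colnames(Y) <- vocab$item_id
  vocab$n_phones <- n_ph
  vocab$offset_row <- 3L * (n_ph + 1L) + 2L
  structure(list(X = X, Y = Y, segments = segments, vocab = vocab,
                 inv = inv,
                 dims = c(semantic = ncol(semantic), visual = ncol(visual),
                          lexical = ncol(lex), n_slots = n_slots,
                          n_features = inv$n_features)),
            class = "lexnet_dataset")
}

align_rows <- function(m, ids) {
  m <- as.matrix(m)
  if (!is.null(rownames(m))) {
    if (!all(ids %in% rownames(m)))
      stop("representation matrix is missing rows for some vocabulary items")
    m <- m[ids, , drop = FALSE]
  } else if (nrow(m) != length(ids)) {
    stop("representation matrix row count does not match the vocabulary")
  }
  m
}

#' Targets of a dataset as an items-by-dims matrix
#'
#' @param data a `lexnet_dataset`.
#' @return Binary matrix with item ids as row names.
#' @export
dataset_targets <- function(data) {
  t(data$Y)
}

# full-precision text encoding of numeric data ("%.17g" round-trips
# doubles exactly)
num_to_chr <- function(x) sprintf("%.17g", x)

#' Save a trained model as a text checkpoint
#'
#' JSON container holding the six weight matrices (at full double
#' precision), dimensions, segment boundaries, training configuration, and
#' epoch counter. Reloading reproduces the forward pass bit-exactly.
#'
#' @param model a `gru_model`.
#' @param path output file path.
#' @export
save_checkpoint <- function(model, path) {
  p <- model$params
  enc <- lapply(p[weight_names], function(w)
    list(dim = dim(w), data = num_to_chr(as.vector(w))))
  obj <- list(format = "lexcompnet-checkpoint-1",
              input_dim = p$input_dim, hidden_dim = p$hidden_dim,
              weights = enc,
              segments = lapply(model$segments, range),
              config = unclass(model$config),
              epochs_trained = model$epochs_trained)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a text checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @return A `gru_model` (without training history).
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lexcompnet-checkpoint-1"))
    stop("not a lexcompnet checkpoint")
  params <- lapply(obj$weights, function(w)
    matrix(as.numeric(w$data), w$dim[1L], w$dim[2L]))
  params$input_dim <- as.integer(obj$input_dim)
  params$hidden_dim <- as.integer(obj$hidden_dim)
  class(params) <- "gru_params"
  segments <- lapply(obj$segments, function(r) seq(r[1L], r[2L]))
  cfg <- obj$config
  structure(list(params = params, segments = segments,
                 config = cfg,
                 epochs_trained = as.integer(obj$epochs_trained),
                 log = NULL, lex_correct = NULL, semvis_correct = NULL),
            class = "gru_model")
}

#' Load a run configuration from YAML or JSON
#'
#' Missing fields are filled with defaults mirroring the model's stated
#' hyperparameters (learning rate 0.4, momentum 0.4, Nesterov enabled, 10
#' slots, 20 features); unknown keys are rejected.
#'
#' @param path YAML or JSON file; `NULL` returns all defaults.
#' @return A validated `run_config` list with components `train` (a
#'   [train_config()]), `synth` (a [synth_config()]), `n_slots`, `vis_k`,
#'   `n_seeds`, `pct_hi`, `pct_lo`, `rhyme_method`.
#' @export
load_run_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  known <- c("train", "synth", "n_slots", "vis_k", "n_seeds",
             "pct_hi", "pct_lo", "rhyme_method")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")))
  tr <- do.call(train_config, as.list(raw$train %||% list()))
  sy <- do.call(synth_config, as.list(raw$synth %||% list()))
  cfg <- list(train = tr, synth = sy,
              n_slots = raw$n_slots %||% 10L,
              vis_k = raw$vis_k %||% 150L,
              n_seeds = raw$n_seeds %||% 1L,
              pct_hi = raw$pct_hi %||% 85,
              pct_lo = raw$pct_lo %||% 15,
              rhyme_method = raw$rhyme_method %||% "last_vowel")
  stopifnot(cfg$n_slots >= 2L, cfg$n_seeds >= 1L,
            cfg$pct_lo < cfg$pct_hi)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of the package's scaled-down learning study
#'
#' The reference desk-scale condition used by the bundled tests and the
#' acceptance script: a 50-item synthetic vocabulary with the generator
#' defaults, semantic dimension 24 and visual dimension 12 after reduction
#' (lexical stays 200 under 10 slots of 20 features, so the hidden/output
#' dimension is 236), trained full-batch at learning rate 0.4 / momentum
#' 0.4 with Nesterov momentum under the cross-entropy objective, evaluated
#' every 250 epochs, stopping at sustained 100% both-constituent
#' recognition or after `max_epochs`.
#'
#' @param seed base seed; the corpus and the weight initialization derive
#'   from it.
#' @param n_items vocabulary size (default 50).
#' @param max_epochs epoch cap (default 8000).
#' @return List with components `synth` (a [synth_config()]), `train` (a
#'   [train_config()]), and `vis_k`.
#' @export
scaled_study_config <- function(seed = 1L, n_items = 50L,
                                max_epochs = 8000L) {
  list(synth = synth_config(n_items = n_items, sem_dim = 24L, seed = seed),
       train = train_config(epochs = max_epochs, eval_every = 250L,
                            seed = seed + 1L, loss_kind = "bce",
                            converge_k = 1L),
       vis_k = 12L)
}

#' Run the scaled-down learning study
#'
#' Generates the corpus, trains one model, and returns the model, the
#' dataset, and the final recognition snapshot.
#'
#' @param seed base seed.
#' @param ... passed to [scaled_study_config()].
#' @return List `model`, `data`, `snapshot`, `pct_both`.
#' @export
run_scaled_study <- function(seed = 1L, ...) {
  cfg <- scaled_study_config(seed = seed, ...)
  corp <- gen_corpus(cfg$synth)
  data <- corpus_dataset(corp, vis_k = cfg$vis_k)
  model <- train_gru(data, cfg$train)
  snap <- learning_snapshot(model, data)
  list(model = model, data = data, snapshot = snap,
       pct_both = 100 * snap$fractions[["both"]])
}

#' Save a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
save_run_config <- function(cfg, path) {
  plain <- list(train = unclass(cfg$train),
                synth = unclass(cfg$synth)[!vapply(unclass(cfg$synth), is.null, TRUE)],
                n_slots = cfg$n_slots, vis_k = cfg$vis_k,
                n_seeds = cfg$n_seeds, pct_hi = cfg$pct_hi,
                pct_lo = cfg$pct_lo, rhyme_method = cfg$rhyme_method)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Build a dataset from a synthetic corpus
#'
#' Preprocesses the corpus's visual matrix (outliers, reduction to
#' `vis_k`, binarization) and assembles the training dataset. `vis_k` is
#' clamped to `items - 1`, the rank limit of the principal component
#' step.
#'
#' @param corpus output of [gen_corpus()] (or a list with `vocab`, `inv`,
#'   `semantic`, `visual_raw` or binary `visual`).
#' @param vis_k target visual dimensionality.
#' @param n_slots slot capacity.
#' @return A `lexnet_dataset`.
#' @export
corpus_dataset <- function(corpus, vis_k = 150L, n_slots = 10L) {
  vis <- if (!is.null(corpus[["visual"]])) corpus[["visual"]]
         else preprocess_visual(corpus$visual_raw,
                                k = min(vis_k, nrow(corpus$vocab) - 1L))$matrix
  sem <- preprocess_semantic(corpus$semantic)
  prepare_dataset(corpus$vocab, corpus$inv, sem, vis, n_slots = n_slots)
}

#' Run a multi-seed experiment end to end
#'
#' Generates (or accepts) a corpus, trains `n_seeds` models differing only
#' in their weight-initialization seed, writes per-seed checkpoints,
#' training logs and evaluation reports, simulates the visual-world trials
#' with the final models, and writes a grand-average table plus a JSON
#' summary. Re-running with the same configuration resumes from existing
#' checkpoints.
#'
#' @param cfg a [load_run_config()] object.
#' @param out_dir output directory.
#' @param corpus optional pre-built corpus (otherwise generated from
#'   `cfg$synth`).
#' @return Invisibly, a list with the trained models, the trial specs, and
#'   the grand average.
#' @export
run_experiment <- function(cfg = load_run_config(), out_dir, corpus = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_run_config(cfg, file.path(out_dir, "config.yaml"))
  if (is.null(corpus)) corpus <- gen_corpus(cfg$synth)
  write_corpus(corpus, file.path(out_dir, "corpus"))
  data <- corpus_dataset(corpus, vis_k = cfg$vis_k, n_slots = cfg$n_slots)
  models <- vector("list", cfg$n_seeds)
  for (s in seq_len(cfg$n_seeds)) {
    ck <- file.path(out_dir, sprintf("model_seed%02d.json", s))
    if (file.exists(ck)) {
      models[[s]] <- load_checkpoint(ck)
    } else {
      tcfg <- cfg$train
      tcfg$seed <- cfg$train$seed + s - 1L
      models[[s]] <- train_gru(data, tcfg)
      save_checkpoint(models[[s]], ck)
      write_training_log(models[[s]],
                         file.path(out_dir, sprintf("train_seed%02d.tsv", s)))
    }
    evaluation_report(models[[s]], data,
                      file.path(out_dir, sprintf("eval_seed%02d.tsv", s)))
  }
  targets <- dataset_targets(data)
  seg <- data$segments
  sem_tab <- pairwise_jaccard_table(targets[, seg$semantic, drop = FALSE],
                                    "semantic")
  vis_tab <- pairwise_jaccard_table(targets[, seg$visual, drop = FALSE],
                                    "visual")
  specs <- select_trials(data$vocab, sem_tab, vis_tab, data$inv,
                         pct_hi = cfg$pct_hi, pct_lo = cfg$pct_lo,
                         rhyme_method = cfg$rhyme_method)
  ga <- NULL
  if (nrow(specs)) {
    utils::write.table(specs, file.path(out_dir, "trial_specs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results <- unlist(lapply(models, run_trials, specs = specs, data = data),
                      recursive = FALSE)
    write_trial_results(results, file.path(out_dir, "trial_results.tsv"))
    ga <- grand_average(results)
    utils::write.table(ga$table, file.path(out_dir, "vwp_grand_average.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary <- list(
    n_items = nrow(data$vocab), n_seeds = cfg$n_seeds,
    hidden_dim = nrow(data$Y), n_trials = nrow(specs),
    epochs_trained = vapply(models, `[[`, integer(1L), "epochs_trained"),
    final_pct_both = vapply(models, function(m)
      100 * learning_snapshot(m, data)$fractions[["both"]], numeric(1L)),
    crossover_timestep = if (is.null(ga)) NA else ga$crossover_timestep)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(models = models, data = data, specs = specs,
                 grand_average = ga, summary = summary))
}
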