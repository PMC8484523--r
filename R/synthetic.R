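# Synthetic vocabularies, phone inventories, and semantic/visual matrices
# with the statistical structure the model assumes: onset-concentrated
# cohorts, category-prototype semantic vectors, and visual vectors coupled
# to the semantic categories.

consonant_pool <- c("b", "k", "p", "s", "t", "d", "g", "m", "n", "l", "r",
                    "f", "v", "z", "w", "j", "h", "ch", "sh", "th", "dh",
                    "ng", "zh", "y", "x", "q")
vowel_pool <- c("a", "e", "i", "o", "u", "aa", "ee", "ii", "oo", "uu",
                "ai", "au", "oi")

#' Synthetic-data configuration
#'
#' Defaults emulate the descriptive structure of a toddler-vocabulary
#' study scaled to a desk-size corpus: 50 imageable nouns over 6 semantic
#' categories, labels of 2 to 9 phones drawn from an inventory of 26
#' consonants and 13 vowels, 60% of the onset mass concentrated on the
#' five cohort-forming onsets b, k, p, s, t, a 5.5% vowel-onset fraction,
#' 100-dimensional semantic vectors, and 512-dimensional raw visual
#' vectors.
#'
#' @param n_items vocabulary size.
#' @param n_categories number of semantic categories.
#' @param length_range label length range in phones (within slot capacity).
#' @param n_consonants,n_vowels inventory composition.
#' @param n_features binary features per phone code.
#' @param cohort_onsets onset phones carrying concentrated cohort mass.
#' @param cohort_mass fraction of consonant-onset items starting with one
#'   of `cohort_onsets`.
#' @param vowel_onset_frac fraction of items with a vowel onset.
#' @param sem_dim semantic vector dimensionality.
#' @param vis_raw_dim raw visual vector dimensionality (before reduction).
#' @param sem_flip_prob per-dimension flip probability away from the
#'   semantic category prototype.
#' @param vis_flip_prob per-dimension flip probability for visual vectors.
#' @param sem_vis_coupling probability that a visual dimension follows the
#'   semantic category's visual prototype rather than the item's
#'   independent visual cluster.
#' @param vis_noise_sd additive Gaussian noise on continuousized visual
#'   vectors.
#' @param outlier_rate,outlier_mag rate and magnitude of injected visual
#'   outliers (exercises the outlier-replacement step).
#' @param seed base RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_items = 50L, n_categories = 6L,
                         length_range = c(2L, 9L),
                         n_consonants = 26L, n_vowels = 13L,
                         n_features = 20L,
                         cohort_onsets = c("b", "k", "p", "s", "t"),
                         cohort_mass = 0.6, vowel_onset_frac = 0.055,
                         sem_dim = 100L, vis_raw_dim = 512L,
                         sem_flip_prob = 0.1, vis_flip_prob = 0.1,
                         sem_vis_coupling = 0.3, vis_noise_sd = 0.5,
                         outlier_rate = 0.005, outlier_mag = 8,
                         seed = 1L) {
  stopifnot(length_range[1L] >= 1L, length_range[2L] <= 9L,
            cohort_mass >= 0, cohort_mass <= 1,
            sem_flip_prob >= 0, sem_flip_prob <= 1,
            vis_flip_prob >= 0, vis_flip_prob <= 1,
            sem_vis_coupling >= 0, sem_vis_coupling <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a random phone inventory
#'
#' Distinct random binary feature codes (never all-ones, which is reserved
#' for the segmentation character, and never all-zeros, which would be
#' indistinguishable from silence), tagged consonant or vowel.
#'
#' @param cfg a [synth_config()].
#' @return A [phone_inventory()].
#' @export
gen_phone_inventory <- function(cfg = synth_config()) {
  n <- cfg$n_consonants + cfg$n_vowels
  stopifnot(n >= 4L, 2^cfg$n_features > n)
  set.seed(cfg$seed + 101L)
  codes <- character(0)
  feats <- matrix(0, 0L, cfg$n_features)
  tries <- 0L
  while (nrow(feats) < n) {
    if ((tries <- tries + 1L) > 200L * n)
      stop("could not generate distinct phone codes; increase n_features")
    f <- stats::rbinom(cfg$n_features, 1L, 0.5)
    key <- paste(f, collapse = "")
    if (key %in% codes || all(f == 1) || all(f == 0)) next
    codes <- c(codes, key)
    feats <- rbind(feats, f)
  }
  symbols <- c(extend_pool(consonant_pool, cfg$n_consonants, "c"),
               extend_pool(vowel_pool, cfg$n_vowels, "v"))
  phone_inventory(symbols, feats,
                  rep(c("consonant", "vowel"),
                      c(cfg$n_consonants, cfg$n_vowels)))
}

extend_pool <- function(pool, n, prefix) {
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, paste0(prefix, seq_len(n - length(pool))))
}

#' Generate distinct word labels with cohort structure
#'
#' Label lengths are sampled uniformly from `length_range`. Onsets are
#' vowels with probability `vowel_onset_frac`; consonant onsets fall on
#' one of `cohort_onsets` with probability `cohort_mass` (forming large
#' cohorts) and are otherwise uniform over the remaining consonants.
#' Post-onset phones roughly alternate consonant/vowel, so every label
#' contains at least one vowel.
#'
#' @param cfg a [synth_config()].
#' @param inv a [phone_inventory()].
#' @return Character vector of `n_items` distinct space-separated labels.
#' @export
gen_labels <- function(cfg, inv) {
  set.seed(cfg$seed + 202L)
  cons <- inv$phones[inv$phone_class == "consonant"]
  vows <- inv$phones[inv$phone_class == "vowel"]
  big <- intersect(cfg$cohort_onsets, cons)
  other_cons <- setdiff(cons, big)
  labels <- character(0)
  tries <- 0L
  while (length(labels) < cfg$n_items) {
    if ((tries <- tries + 1L) > 500L * cfg$n_items)
      stop("could not generate distinct labels; enlarge the inventory or length range")
    len <- sample(seq(cfg$length_range[1L], cfg$length_range[2L]), 1L)
    if (stats::runif(1) < cfg$vowel_onset_frac || !length(cons)) {
      onset <- sample(vows, 1L)
      cls <- "vowel"
    } else if (stats::runif(1) < cfg$cohort_mass && length(big)) {
      onset <- sample(big, 1L)
      cls <- "consonant"
    } else {
      onset <- sample(other_cons, 1L)
      cls <- "consonant"
    }
    ph <- onset
    for (k in seq_len(len - 1L)) {
      cls <- if (stats::runif(1) < 0.75)
        setdiff(c("consonant", "vowel"), cls) else cls
      pool <- if (cls == "consonant") cons else vows
      ph <- c(ph, sample(pool, 1L))
    }
    if (!any(inv$phone_class[ph] == "vowel")) {
      i <- if (length(ph) > 1L) sample(2:length(ph), 1L) else 1L
      ph[i] <- sample(vows, 1L)
    }
    lab <- paste(ph, collapse = " ")
    if (!lab %in% labels) labels <- c(labels, lab)
  }
  labels
}

#' Generate semantic and visual representation matrices
#'
#' Semantic vectors are binary category prototypes (Bernoulli 0.5 per
#' dimension) with per-dimension flip noise, returned already binarized.
#' Visual vectors start from a per-dimension mixture of the semantic
#' category's visual prototype (with probability `sem_vis_coupling`) and
#' an independent visual cluster's prototype, receive flip noise, and are
#' then continuousized (`2 b - 1` plus Gaussian noise) with occasional
#' injected outliers so that the full preprocessing pipeline (outlier
#' replacement, principal component reduction, median binarization) is
#' exercised end-to-end.
#'
#' @param cfg a [synth_config()].
#' @param categories character/integer vector assigning each item to a
#'   semantic category.
#' @param item_ids row names for the returned matrices.
#' @return List: `semantic` (items by `sem_dim`, binary), `visual_raw`
#'   (items by `vis_raw_dim`, continuous), `vis_cluster` (per-item
#'   independent visual cluster assignment).
#' @export
gen_semvis <- function(cfg, categories, item_ids = NULL) {
  n <- length(categories)
  cats <- as.integer(factor(categories))
  n_cat <- max(cats)
  set.seed(cfg$seed + 303L)
  proto_sem <- matrix(stats::rbinom(n_cat * cfg$sem_dim, 1L, 0.5),
                      n_cat, cfg$sem_dim)
  sem <- proto_sem[cats, , drop = FALSE]
  flips <- matrix(stats::rbinom(n * cfg$sem_dim, 1L, cfg$sem_flip_prob),
                  n, cfg$sem_dim)
  sem <- abs(sem - flips)
  proto_vis_cat <- matrix(stats::rbinom(n_cat * cfg$vis_raw_dim, 1L, 0.5),
                          n_cat, cfg$vis_raw_dim)
  clust <- sample.int(n_cat, n, replace = TRUE)
  proto_vis_clust <- matrix(stats::rbinom(n_cat * cfg$vis_raw_dim, 1L, 0.5),
                            n_cat, cfg$vis_raw_dim)
  take_cat <- matrix(stats::rbinom(n * cfg$vis_raw_dim, 1L,
                                   cfg$sem_vis_coupling), n, cfg$vis_raw_dim)
  vis_bin <- take_cat * proto_vis_cat[cats, , drop = FALSE] +
    (1 - take_cat) * proto_vis_clust[clust, , drop = FALSE]
  vflips <- matrix(stats::rbinom(n * cfg$vis_raw_dim, 1L, cfg$vis_flip_prob),
                   n, cfg$vis_raw_dim)
  vis_bin <- abs(vis_bin - vflips)
  vis <- (2 * vis_bin - 1) +
    matrix(stats::rnorm(n * cfg$vis_raw_dim, sd = cfg$vis_noise_sd),
           n, cfg$vis_raw_dim)
  out_mask <- matrix(stats::runif(n * cfg$vis_raw_dim) < cfg$outlier_rate,
                     n, cfg$vis_raw_dim)
  vis[out_mask] <- vis[out_mask] +
    sample(c(-1, 1), sum(out_mask), replace = TRUE) * cfg$outlier_mag
  if (!is.null(item_ids)) {
    rownames(sem) <- item_ids
    rownames(vis) <- item_ids
  }
  storage.mode(sem) <- "double"
  list(semantic = sem, visual_raw = vis, vis_cluster = clust)
}

#' Generate a complete synthetic corpus
#'
#' Inventory, vocabulary (with balanced random category assignment), and
#' semantic/visual matrices, all deterministic in `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return List: `inv`, `vocab` (data frame `item_id`, `label`,
#'   `category`), `semantic`, `visual_raw`.
#' @export
gen_corpus <- function(cfg = synth_config()) {
  inv <- gen_phone_inventory(cfg)
  labels <- gen_labels(cfg, inv)
  set.seed(cfg$seed + 404L)
  categories <- sample(rep_len(paste0("cat", seq_len(cfg$n_categories)),
                               cfg$n_items))
  ids <- sprintf("w%03d", seq_len(cfg$n_items))
  sv <- gen_semvis(cfg, categories, item_ids = ids)
  list(inv = inv,
       vocab = data.frame(item_id = ids, label = labels,
                          category = categories, stringsAsFactors = FALSE),
       semantic = sv$semantic, visual_raw = sv$visual_raw)
}

#' Write a synthetic corpus to CSV files
#'
#' Emits `vocabulary.csv`, `phone_features.csv`, `semantic.csv`, and
#' `visual.csv` in the formats the loaders consume.
#'
#' @param corpus output of [gen_corpus()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vocabulary(corpus$vocab, file.path(dir, "vocabulary.csv"))
  write_phone_inventory(corpus$inv, file.path(dir, "phone_features.csv"))
  write_representation(corpus$semantic, file.path(dir, "semantic.csv"))
  write_representation(corpus$visual_raw, file.path(dir, "visual.csv"))
  invisible(dir)
}

#' Engineered fixture vocabulary containing a valid trial tuple
#'
#' Builds a 10-item vocabulary with binary semantic and visual matrices
#' placed so that the tuple (target `w01`, PREL `w02`, SREL `w03`, VREL
#' `w04`, UREL `w05`) satisfies the trial-selection criteria: `w02` shares
#' the target's onset `b` but not its rhyme and sits at the bottom of both
#' similarity distributions; `w03`/`w04` sit at the top of the semantic /
#' visual distribution respectively and at the bottom of the other; `w05`
#' is unrelated throughout. Five filler items hold the percentile
#' structure in place.
#'
#' All vectors carry 25 active bits out of 50 per modality — the 50%
#' density that per-dimension median binarization produces on real
#' embeddings — and the target and PREL share a small active block, so
#' that the cohort-ambiguous output early in a word remains representable
#' (fully disjoint competitors would binarize the ambiguous state to
#' all-zeros, which median-split representations never exhibit).
#'
#' The construction is re-verified by running [select_trials()] (filler
#' draws are retried under fresh sub-seeds if the percentile structure
#' fails); persistent failure is an error, never a silent return.
#'
#' @param seed seed for the filler items' random structure.
#' @param inv_seed seed for the phone inventory codes.
#' @return List: `inv`, `vocab`, `semantic`, `visual` (both binary),
#'   `expected` (the engineered tuple as a one-row data frame).
#' @export
gen_vwp_fixture <- function(seed = 1L, inv_seed = 1L) {
  cfg <- synth_config(n_consonants = 15L, n_vowels = 5L, seed = inv_seed)
  inv <- gen_phone_inventory(cfg)
  labels <- c("b a s", "b i k", "m o d", "n u g", "f e p",
              "d a m", "g o t", "l e n", "r i t", "w u f")
  ids <- sprintf("w%02d", 1:10)
  d <- 50L
  block <- function(ix) { v <- numeric(d); v[ix] <- 1; v }
  core_sem <- rbind(block(1:25),               # target
                    block(21:45),              # PREL: small shared block
                    block(c(1:22, 26:28)),     # SREL: near-identical
                    block(26:50),              # VREL: semantically distant
                    block(24:48))              # UREL
  core_vis <- rbind(block(1:25),
                    block(21:45),              # PREL visually distant too
                    block(26:50),              # SREL visually distant
                    block(c(1:22, 26:28)),     # VREL: near-identical
                    block(24:48))
  vocab <- data.frame(item_id = ids, label = labels,
                      category = rep(c("catA", "catB"), 5L),
                      stringsAsFactors = FALSE)
  for (attempt in 0:24) {
    set.seed(seed + 707L + attempt)
    filler_sem <- t(vapply(1:5, function(i)
      block(sample.int(d, 25L)), numeric(d)))
    filler_vis <- t(vapply(1:5, function(i)
      block(sample.int(d, 25L)), numeric(d)))
    sem <- rbind(core_sem, filler_sem)
    vis <- rbind(core_vis, filler_vis)
    rownames(sem) <- ids; rownames(vis) <- ids
    trials <- suppressWarnings(
      select_trials(vocab, pairwise_jaccard_table(sem, "semantic"),
                    pairwise_jaccard_table(vis, "visual"), inv))
    hit <- nrow(trials) > 0 &&
      any(trials$target == "w01" & trials$prel == "w02" &
            trials$srel == "w03" & trials$vrel == "w04" &
            trials$urel == "w05")
    if (hit)
      return(list(inv = inv, vocab = vocab, semantic = sem, visual = vis,
                  expected = data.frame(target = "w01", prel = "w02",
                                        srel = "w03", vrel = "w04",
                                        urel = "w05",
                                        stringsAsFactors = FALSE)))
  }
  stop("fixture construction failed verification: engineered tuple not selected")
}
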