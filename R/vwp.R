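# Target-absent visual-world trials: candidate selection by percentile
# criteria on pairwise Jaccard tables, trial simulation, and grand-average
# time courses.

#' Rhyme of a phone label
#'
#' By default the rhyme is the phone sequence from the label's last vowel
#' to its end; labels without a vowel rhyme as their full sequence.
#' `method = "final_n"` uses the final `n` phones instead.
#'
#' @param label phone label (vector or space-separated string).
#' @param inv a [phone_inventory()] (supplies vowel classes).
#' @param method `"last_vowel"` (default) or `"final_n"`.
#' @param n overlap length for `method = "final_n"`.
#' @return Character scalar, space-separated rhyme phones.
#' @export
rhyme_of <- function(label, inv, method = c("last_vowel", "final_n"), n = 2L) {
  method <- match.arg(method)
  ph <- parse_label(label)
  if (method == "final_n") {
    return(paste(utils::tail(ph, n), collapse = " "))
  }
  vcl <- inv$phone_class[ph]
  vpos <- which(vcl == "vowel")
  from <- if (length(vpos)) max(vpos) else 1L
  paste(ph[from:length(ph)], collapse = " ")
}

# percentile thresholds of a pairwise Jaccard table
jaccard_cutoffs <- function(tab, pct_hi = 85, pct_lo = 15) {
  c(hi = unname(stats::quantile(tab$jaccard, pct_hi / 100)),
    lo = unname(stats::quantile(tab$jaccard, pct_lo / 100)))
}

#' Relatedness flags for a pair of vocabulary items
#'
#' An item is semantically/visually related (unrelated) to another when the
#' Jaccard index of their representation vectors lies in the top (bottom)
#' 15th percentile of all pairwise comparisons across the vocabulary
#' (self-pairs excluded; ties at the threshold satisfy the criterion).
#' Phonological flags record shared onset phone and shared rhyme.
#'
#' @param a,b distinct item ids.
#' @param vocab vocabulary data frame.
#' @param sem_tab,vis_tab pairwise tables from [pairwise_jaccard_table()].
#' @param inv a [phone_inventory()].
#' @param pct_hi,pct_lo percentile thresholds (defaults 85 and 15).
#' @param rhyme_method,rhyme_n see [rhyme_of()].
#' @return Named logical vector: `onset_share`, `rhyme_share`,
#'   `sem_related`, `sem_unrelated`, `vis_related`, `vis_unrelated`.
#' @export
relatedness_flags <- function(a, b, vocab, sem_tab, vis_tab, inv,
                              pct_hi = 85, pct_lo = 15,
                              rhyme_method = "last_vowel", rhyme_n = 2L) {
  if (identical(a, b)) stop("relatedness is undefined for self-comparison")
  for (id in c(a, b))
    if (!id %in% vocab$item_id) stop(sprintf("unknown item '%s'", id))
  la <- parse_label(vocab$label[vocab$item_id == a])
  lb <- parse_label(vocab$label[vocab$item_id == b])
  sem_cut <- jaccard_cutoffs(sem_tab, pct_hi, pct_lo)
  vis_cut <- jaccard_cutoffs(vis_tab, pct_hi, pct_lo)
  js <- pair_jaccard(sem_tab, a, b)
  jv <- pair_jaccard(vis_tab, a, b)
  c(onset_share = la[1L] == lb[1L],
    rhyme_share = rhyme_of(la, inv, rhyme_method, rhyme_n) ==
                  rhyme_of(lb, inv, rhyme_method, rhyme_n),
    sem_related = js >= sem_cut[["hi"]],
    sem_unrelated = js <= sem_cut[["lo"]],
    vis_related = jv >= vis_cut[["hi"]],
    vis_unrelated = jv <= vis_cut[["lo"]])
}

#' Enumerate target-absent trial specifications
#'
#' For every consonant-onset target, exhaustively enumerates candidate
#' tuples satisfying the selection criteria:
#' * PREL shares the target's onset phone, does not share its rhyme, and is
#'   semantically and visually unrelated to it;
#' * SREL is semantically related but visually and phonologically (onset
#'   and rhyme) unrelated;
#' * VREL is visually related but semantically and phonologically
#'   unrelated;
#' * UREL is phonologically, semantically, and visually unrelated.
#'
#' @param vocab vocabulary data frame.
#' @param sem_tab,vis_tab pairwise Jaccard tables over the full vocabulary.
#' @param inv a [phone_inventory()].
#' @inheritParams relatedness_flags
#' @return Data frame `target`, `prel`, `srel`, `vrel`, `urel`, one row per
#'   trial; zero rows (with a warning) when no tuple satisfies the
#'   criteria.
#' @export
select_trials <- function(vocab, sem_tab, vis_tab, inv,
                          pct_hi = 85, pct_lo = 15,
                          rhyme_method = "last_vowel", rhyme_n = 2L) {
  ids <- vocab$item_id
  labels <- lapply(vocab$label, parse_label)
  onsets <- vapply(labels, `[`, character(1L), 1L)
  rhymes <- vapply(labels, rhyme_of, character(1L), inv = inv,
                   method = rhyme_method, n = rhyme_n)
  onset_cons <- inv$phone_class[onsets] == "consonant"
  sem_cut <- jaccard_cutoffs(sem_tab, pct_hi, pct_lo)
  vis_cut <- jaccard_cutoffs(vis_tab, pct_hi, pct_lo)
  jmat <- function(tab) {
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(tab$item_a, tab$item_b)] <- tab$jaccard
    m[cbind(tab$item_b, tab$item_a)] <- tab$jaccard
    m
  }
  JS <- jmat(sem_tab); JV <- jmat(vis_tab)
  out <- list()
  for (t in seq_along(ids)) {
    if (!onset_cons[t]) next
    others <- setdiff(seq_along(ids), t)
    shares_on <- onsets[others] == onsets[t]
    shares_rh <- rhymes[others] == rhymes[t]
    s_rel <- JS[ids[t], ids[others]] >= sem_cut[["hi"]]
    s_unr <- JS[ids[t], ids[others]] <= sem_cut[["lo"]]
    v_rel <- JV[ids[t], ids[others]] >= vis_cut[["hi"]]
    v_unr <- JV[ids[t], ids[others]] <= vis_cut[["lo"]]
    prel <- others[shares_on & !shares_rh & s_unr & v_unr]
    srel <- others[s_rel & v_unr & !shares_on & !shares_rh]
    vrel <- others[v_rel & s_unr & !shares_on & !shares_rh]
    urel <- others[!shares_on & !shares_rh & s_unr & v_unr]
    if (!length(prel) || !length(srel) || !length(vrel) || !length(urel))
      next
    g <- expand.grid(prel = prel, srel = srel, vrel = vrel, urel = urel,
                     KEEP.OUT.ATTRS = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      target = ids[t], prel = ids[g$prel], srel = ids[g$srel],
      vrel = ids[g$vrel], urel = ids[g$urel], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    warning("no candidate tuple satisfies the trial criteria")
    return(data.frame(target = character(0), prel = character(0),
                      srel = character(0), vrel = character(0),
                      urel = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

vwp_classes <- c("PREL", "SREL", "VREL", "UREL")

#' Simulate one target-absent trial
#'
#' Feeds the target's unfolding input through the model; at each timestep
#' the binarized semantic-visual segment of the output is scored by
#' Jaccard index against each candidate's semantic-visual representation.
#' The candidate with the highest activation is the attended one (argmax,
#' ties to the earlier class in PREL, SREL, VREL, UREL order); relative
#' activations subtract the unrelated candidate's activation, so UREL's
#' relative activation is identically zero.
#'
#' @param model a trained `gru_model`.
#' @param spec one row of [select_trials()] output (or a list with fields
#'   `target`, `prel`, `srel`, `vrel`, `urel`).
#' @param data the dataset (supplies inputs and semantic-visual targets).
#' @param threshold binarization threshold.
#' @param H optional precomputed hidden-state matrix for the target
#'   (timesteps by hidden), to reuse across trials sharing a target.
#' @return Data frame `timestep`, `class`, `activation`,
#'   `relative_activation`, `attended`.
#' @export
run_trial <- function(model, spec, data, threshold = 0.5, H = NULL) {
  ids <- c(spec$prel, spec$srel, spec$vrel, spec$urel)
  idx <- match(c(spec$target, ids), data$vocab$item_id)
  if (anyNA(idx)) stop("trial spec refers to unknown items")
  if (is.null(H)) {
    m <- matrix(data$X[, , idx[1L]], dim(data$X)[1L], dim(data$X)[2L])
    H <- gru_forward(model$params, m)
  }
  seg <- data$segments$semvis
  cand <- t(data$Y[seg, idx[-1L], drop = FALSE])  # 4 x |semvis|
  B <- (H[, seg, drop = FALSE] > threshold) * 1
  inter <- tcrossprod(B, cand)
  uni <- outer(rowSums(B), rowSums(cand), "+") - inter
  act <- ifelse(uni == 0, 1, inter / uni)          # timesteps x 4
  attended <- vwp_classes[apply(act, 1L, which.max)]
  Tn <- nrow(act)
  data.frame(
    timestep = rep(seq_len(Tn), times = 4L),
    class = rep(vwp_classes, each = Tn),
    candidate = rep(ids, each = Tn),
    activation = as.vector(act),
    relative_activation = as.vector(act - act[, 4L]),
    attended = rep(attended, times = 4L) == rep(vwp_classes, each = Tn),
    stringsAsFactors = FALSE)
}

#' Simulate a set of trials for one model
#'
#' Runs [run_trial()] for every row of a trial-spec table, caching the
#' forward pass per target.
#'
#' @param model a trained `gru_model`.
#' @param specs data frame from [select_trials()].
#' @param data the dataset.
#' @param threshold binarization threshold.
#' @return List of trial result data frames.
#' @export
run_trials <- function(model, specs, data, threshold = 0.5) {
  Hcache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    if (is.null(Hcache[[sp$target]])) {
      j <- match(sp$target, data$vocab$item_id)
      m <- matrix(data$X[, , j], dim(data$X)[1L], dim(data$X)[2L])
      Hcache[[sp$target]] <- gru_forward(model$params, m)
    }
    run_trial(model, sp, data, threshold, H = Hcache[[sp$target]])
  })
}

#' Grand-average relative activation time courses
#'
#' Averages relative activations per timestep and candidate class across
#' trials (and models, when results from several models are pooled), with
#' bootstrap 95% percentile confidence intervals over trials. Also reports
#' the crossover timestep: the first timestep at which the mean SREL
#' relative activation exceeds the mean PREL relative activation after
#' PREL has led.
#'
#' @param results list of trial result data frames from [run_trial()] /
#'   [run_trials()] (pool results from several models by concatenating the
#'   lists).
#' @param n_boot bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return List: `table` (data frame `timestep`, `class`, `mean`,
#'   `ci_lo`, `ci_hi`, `n_trials`) and `crossover_timestep` (NA when the
#'   pattern never crosses).
#' @export
grand_average <- function(results, n_boot = 200L, seed = 1L) {
  if (!length(results)) stop("no trial results supplied")
  n_tr <- length(results)
  Tn <- max(results[[1L]]$timestep)
  # trials x timesteps matrix per class
  per_class <- lapply(vwp_classes, function(cl) {
    do.call(rbind, lapply(results, function(r)
      r$relative_activation[r$class == cl][seq_len(Tn)]))
  })
  names(per_class) <- vwp_classes
  set.seed(seed)
  boot_idx <- replicate(n_boot, sample.int(n_tr, n_tr, replace = TRUE),
                        simplify = FALSE)
  tab <- do.call(rbind, lapply(vwp_classes, function(cl) {
    m <- per_class[[cl]]
    mu <- colMeans(m)
    if (n_tr > 1L) {
      bm <- vapply(boot_idx, function(ix) colMeans(m[ix, , drop = FALSE]),
                   numeric(Tn))
      ci <- apply(bm, 1L, stats::quantile, probs = c(0.025, 0.975))
    } else {
      ci <- rbind(mu, mu)
    }
    data.frame(timestep = seq_len(Tn), class = cl, mean = mu,
               ci_lo = ci[1L, ], ci_hi = ci[2L, ], n_trials = n_tr,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  mp <- colMeans(per_class$PREL); ms <- colMeans(per_class$SREL)
  led <- which(mp > ms)
  cross <- NA_integer_
  if (length(led)) {
    after <- which(ms > mp & seq_len(Tn) > led[1L])
    if (length(after)) cross <- after[1L]
  }
  list(table = tab, crossover_timestep = cross)
}

#' Write trial results in long TSV format
#'
#' @param results list of trial result data frames.
#' @param path output TSV path.
#' @export
write_trial_results <- function(results, path) {
  long <- do.call(rbind, lapply(seq_along(results), function(i)
    cbind(trial = i, results[[i]])))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
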