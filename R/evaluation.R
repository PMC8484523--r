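# Recognition scoring: Jaccard activation of vocabulary items against the
# model output, learning-progress snapshots, and activation time courses.

#' Activation of a candidate representation given a model output
#'
#' Slices the hidden state to the requested segment, binarizes it at
#' `threshold`, and returns the Jaccard index against the candidate's
#' binary representation for that segment. With
#' `method = "fuzzy"` the continuous state is compared directly via the
#' min/max (Ruzicka) generalization of the Jaccard index.
#'
#' @param h hidden-state vector (full model output).
#' @param target_part candidate binary vector for the segment.
#' @param segment index vector into `h` (see [target_segments()]).
#' @param threshold binarization threshold (default 0.5).
#' @param method `"binary"` (default) or `"fuzzy"`.
#' @return Activation in `[0, 1]`.
#' @export
model_output_activation <- function(h, target_part, segment,
                                    threshold = 0.5,
                                    method = c("binary", "fuzzy")) {
  method <- match.arg(method)
  if (length(segment) != length(target_part))
    stop("segment and target_part lengths differ")
  hs <- h[segment]
  if (method == "binary") {
    jaccard(as.numeric(hs > threshold), target_part)
  } else {
    hc <- pmin(pmax(hs, 0), 1)
    den <- sum(pmax(hc, target_part))
    if (den == 0) 1 else sum(pmin(hc, target_part)) / den
  }
}

#' Recognize the model output against a vocabulary of targets
#'
#' Computes the semantic-visual and lexical activations of every
#' vocabulary item and identifies the argmax per segment; the model is
#' correct on a constituent when the argmax is the item itself. Ties are
#' broken by lowest item index and flagged.
#'
#' @param h hidden-state vector (model output).
#' @param targets items-by-`hidden_dim` binary matrix of aggregated
#'   targets, item ids as row names.
#' @param segments segment list from [target_segments()].
#' @param item_id id of the presented item (for correctness flags);
#'   optional.
#' @param threshold binarization threshold.
#' @return List: `best_semvis_item`, `best_lexical_item`,
#'   `semvis_correct`, `lexical_correct`, `tie_semvis`, `tie_lexical`, and
#'   the `activations` data frame (one row per item).
#' @export
recognize <- function(h, targets, segments, item_id = NULL, threshold = 0.5) {
  if (nrow(targets) == 0L) stop("recognize: empty vocabulary")
  ids <- rownames(targets)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(targets)))
  hb <- as.numeric(h > threshold)
  act_sv <- jaccard_rows(hb[segments$semvis],
                         targets[, segments$semvis, drop = FALSE])
  act_lx <- jaccard_rows(hb[segments$lexical],
                         targets[, segments$lexical, drop = FALSE])
  best_sv <- which.max(act_sv)
  best_lx <- which.max(act_lx)
  list(best_semvis_item = ids[best_sv],
       best_lexical_item = ids[best_lx],
       semvis_correct = if (is.null(item_id)) NA else ids[best_sv] == item_id,
       lexical_correct = if (is.null(item_id)) NA else ids[best_lx] == item_id,
       tie_semvis = sum(act_sv == act_sv[best_sv]) > 1L,
       tie_lexical = sum(act_lx == act_lx[best_lx]) > 1L,
       activations = data.frame(item_id = ids, semvis = act_sv,
                                lexical = act_lx, stringsAsFactors = FALSE))
}

# vectorized recognition over a matrix of offset states (hidden x N);
# items are scored against their own vocabulary. Returns per-item
# correctness and the four-way recognition fractions.
learning_snapshot_states <- function(H_off, Y, segments, threshold = 0.5) {
  B <- t(H_off > threshold) * 1          # N x hidden, binarized outputs
  Tg <- t(Y)                             # N x hidden, binary targets
  sv_best <- argmax_jaccard(B[, segments$semvis, drop = FALSE],
                            Tg[, segments$semvis, drop = FALSE])
  lx_best <- argmax_jaccard(B[, segments$lexical, drop = FALSE],
                            Tg[, segments$lexical, drop = FALSE])
  n <- nrow(B)
  sv_ok <- sv_best == seq_len(n)
  lx_ok <- lx_best == seq_len(n)
  fractions <- c(both = mean(sv_ok & lx_ok),
                 semvis_only = mean(sv_ok & !lx_ok),
                 lexical_only = mean(!sv_ok & lx_ok),
                 neither = mean(!sv_ok & !lx_ok))
  list(fractions = fractions, semvis_correct = sv_ok, lexical_correct = lx_ok)
}

# row-wise argmax of Jaccard similarity between rows of A (queries) and
# rows of B (references); ties resolve to the lowest index (which.max)
argmax_jaccard <- function(A, B) {
  inter <- tcrossprod(A, B)
  uni <- outer(rowSums(A), rowSums(B), "+") - inter
  J <- ifelse(uni == 0, 1, inter / uni)
  apply(J, 1L, which.max)
}

#' Recognition snapshot of a (partially) trained model
#'
#' Runs [recognize()] at each item's word offset (the last non-padded
#' timestep) and reports the fractions of items for which both, only the
#' semantic-visual, only the lexical, or neither constituent is correctly
#' mapped. The four fractions partition the vocabulary.
#'
#' @param model a trained `gru_model` (or a `gru_params` via `params`).
#' @param data the [prepare_dataset()] object the model was trained on.
#' @param threshold binarization threshold.
#' @return List with `fractions` (named, summing to 1) and logical
#'   per-item vectors `semvis_correct`, `lexical_correct`.
#' @export
learning_snapshot <- function(model, data, threshold = 0.5) {
  p <- if (inherits(model, "gru_model")) model$params else model
  fw <- gru_forward_batch(p, data$X, keep_cache = FALSE)
  H_off <- offset_states(fw$H, data$vocab$offset_row)
  learning_snapshot_states(H_off, data$Y, data$segments, threshold)
}

#' Learning curves split by label length and cohort size
#'
#' From the per-item lexical correctness history recorded during training,
#' computes the percentage of items recognized per evaluation epoch within
#' the groups short/long label (split at `length_cut` phones) and
#' small/large cohort (split at `cohort_cut` items), and each item's first
#' evaluation epoch at criterion.
#'
#' @param model a trained `gru_model` (its `lex_correct` matrix has one
#'   row per evaluation and one column per item).
#' @param data the dataset used for training (supplies labels and
#'   cohorts).
#' @param length_cut labels with at least this many phones count as long
#'   (default 5).
#' @param cohort_cut cohorts with at least this many items count as large
#'   (default 15).
#' @return List: `curves` (long data frame `epoch`, `group`, `pct_correct`,
#'   `n_items`), `first_epoch` (per-item first epoch at criterion, NA if
#'   never), `groups` (per-item length/cohort group labels), and flags for
#'   empty groups.
#' @export
split_learning_curves <- function(model, data, length_cut = 5L,
                                  cohort_cut = 15L) {
  if (is.null(model$lex_correct) || nrow(model$lex_correct) == 0L)
    stop("model carries no per-item correctness history")
  vocab <- data$vocab
  n_ph <- vapply(vocab$label, function(l) length(parse_label(l)), integer(1L),
                 USE.NAMES = FALSE)
  coh <- unname(cohort_sizes(vocab))
  len_grp <- ifelse(n_ph >= length_cut, "long", "short")
  coh_grp <- ifelse(coh >= cohort_cut, "large", "small")
  epochs <- model$log$epoch
  hist <- model$lex_correct
  mk <- function(mask, group) {
    if (!any(mask))
      return(data.frame(epoch = integer(0), group = character(0),
                        pct_correct = numeric(0), n_items = integer(0)))
    data.frame(epoch = epochs, group = group,
               pct_correct = 100 * rowMeans(hist[, mask, drop = FALSE]),
               n_items = sum(mask))
  }
  curves <- rbind(mk(len_grp == "short", "short_label"),
                  mk(len_grp == "long", "long_label"),
                  mk(coh_grp == "small", "small_cohort"),
                  mk(coh_grp == "large", "large_cohort"))
  first_epoch <- apply(hist, 2L, function(col) {
    i <- which(col)[1L]
    if (is.na(i)) NA_real_ else epochs[i]
  })
  list(curves = curves,
       first_epoch = stats::setNames(first_epoch, vocab$item_id),
       groups = data.frame(item_id = vocab$item_id, n_phones = n_ph,
                           cohort_size = coh, length_group = len_grp,
                           cohort_group = coh_grp, stringsAsFactors = FALSE),
       empty_groups = setdiff(c("short_label", "long_label", "small_cohort",
                                "large_cohort"), unique(curves$group)))
}

#' Activation time course of an item's own representations
#'
#' Feeds the item's padded unfolding input through the model and, at each
#' timestep, scores the semantic-visual and lexical segments of the output
#' against the item's own targets.
#'
#' @param model a trained `gru_model`.
#' @param data the dataset (supplies inputs and targets).
#' @param item_id vocabulary item id.
#' @param threshold binarization threshold.
#' @return Data frame `timestep`, `semvis`, `lexical` with one row per
#'   padded timestep.
#' @export
activation_timecourse <- function(model, data, item_id, threshold = 0.5) {
  i <- match(item_id, data$vocab$item_id)
  if (is.na(i)) stop(sprintf("unknown item '%s'", item_id))
  m <- matrix(data$X[, , i], dim(data$X)[1L], dim(data$X)[2L])
  H <- gru_forward(model$params, m)
  y <- data$Y[, i]
  seg <- data$segments
  sv <- apply(H, 1L, model_output_activation, target_part = y[seg$semvis],
              segment = seg$semvis, threshold = threshold)
  lx <- apply(H, 1L, model_output_activation, target_part = y[seg$lexical],
              segment = seg$lexical, threshold = threshold)
  data.frame(timestep = seq_len(nrow(H)), semvis = sv, lexical = lx)
}

#' Per-item evaluation report
#'
#' One row per vocabulary item with offset activations of its own targets
#' and correctness flags; written as TSV if `path` is given.
#'
#' @param model a trained `gru_model`.
#' @param data the dataset.
#' @param path optional TSV output path.
#' @return The report data frame (invisibly if written to `path`).
#' @export
evaluation_report <- function(model, data, path = NULL) {
  snap <- learning_snapshot(model, data)
  fw <- gru_forward_batch(model$params, data$X, keep_cache = FALSE)
  H_off <- offset_states(fw$H, data$vocab$offset_row)
  seg <- data$segments
  own_sv <- vapply(seq_len(ncol(H_off)), function(i)
    model_output_activation(H_off[, i], data$Y[seg$semvis, i], seg$semvis),
    numeric(1L))
  own_lx <- vapply(seq_len(ncol(H_off)), function(i)
    model_output_activation(H_off[, i], data$Y[seg$lexical, i], seg$lexical),
    numeric(1L))
  rep <- data.frame(item_id = data$vocab$item_id,
                    semvis_activation = own_sv, lexical_activation = own_lx,
                    semvis_correct = snap$semvis_correct,
                    lexical_correct = snap$lexical_correct,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(rep))
  }
  rep
}
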