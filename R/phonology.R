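# Phonological encodings: phone inventories, dynamic unfolding input matrices
# with co-articulation interpolation, and static slotted lexical vectors.

#' Construct a phone inventory
#'
#' A phone inventory maps each phone symbol to a binary feature code of
#' `n_features` articulatory/phonological features and records whether the
#' phone is a consonant or a vowel. A reserved segmentation character, whose
#' code is all ones, marks the offset of every word; no ordinary phone may
#' carry the all-ones code.
#'
#' @param phones character vector of phone symbols.
#' @param features numeric matrix with one row per phone and `n_features`
#'   columns, entries in `{0, 1}`.
#' @param phone_class character vector, one of `"consonant"` or `"vowel"`
#'   per phone.
#' @param seg_symbol the segmentation character (default `"#"`); must not
#'   collide with a phone symbol.
#' @return An object of class `phone_inventory`.
#' @export
phone_inventory <- function(phones, features, phone_class, seg_symbol = "#") {
  phones <- as.character(phones)
  features <- as.matrix(features)
  if (anyDuplicated(phones)) stop("phone symbols must be distinct")
  if (nrow(features) != length(phones))
    stop("'features' needs one row per phone")
  if (!all(features %in% c(0, 1)))
    stop("feature codes must be binary")
  if (length(phone_class) != length(phones) ||
      !all(phone_class %in% c("consonant", "vowel")))
    stop("'phone_class' must label every phone as consonant or vowel")
  if (seg_symbol %in% phones)
    stop("segmentation character collides with a phone symbol")
  n_features <- ncol(features)
  codes <- apply(features, 1L, paste, collapse = "")
  if (anyDuplicated(codes)) stop("phone feature codes must be pairwise distinct")
  if (any(codes == strrep("1", n_features)))
    stop("the all-ones code is reserved for the segmentation character")
  rownames(features) <- phones
  structure(
    list(phones = phones, features = features,
         phone_class = stats::setNames(phone_class, phones),
         seg_symbol = seg_symbol, n_features = n_features),
    class = "phone_inventory")
}

#' @export
print.phone_inventory <- function(x, ...) {
  cat(sprintf("Phone inventory: %d phones (%d consonants, %d vowels), %d features, seg = '%s'\n",
              length(x$phones), sum(x$phone_class == "consonant"),
              sum(x$phone_class == "vowel"), x$n_features, x$seg_symbol))
  invisible(x)
}

#' Read a phone feature table from CSV
#'
#' Expected header: `phone,class,f1..f<n>` with binary feature values. A row
#' for the segmentation character is optional; when absent the reserved
#' all-ones character is generated.
#'
#' @param path CSV file path.
#' @param seg_symbol segmentation character to use when the table has no
#'   `class == "seg"` row.
#' @return A [phone_inventory()].
#' @export
read_phone_inventory <- function(path, seg_symbol = "#") {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("phone", "class") %in% names(tab)))
    stop("feature table needs 'phone' and 'class' columns")
  seg_row <- tab$class == "seg"
  if (any(seg_row)) {
    seg_symbol <- tab$phone[seg_row][1L]
    tab <- tab[!seg_row, , drop = FALSE]
  }
  feat_cols <- setdiff(names(tab), c("phone", "class"))
  phone_inventory(tab$phone,
                  as.matrix(tab[, feat_cols, drop = FALSE]),
                  tab$class, seg_symbol = seg_symbol)
}

#' Write a phone inventory to CSV
#'
#' @param inv a [phone_inventory()].
#' @param path output CSV path.
#' @export
write_phone_inventory <- function(inv, path) {
  feats <- inv$features
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  tab <- data.frame(phone = inv$phones,
                    class = unname(inv$phone_class[inv$phones]),
                    feats, check.names = FALSE)
  seg <- data.frame(phone = inv$seg_symbol, class = "seg",
                    matrix(1, 1L, inv$n_features,
                           dimnames = list(NULL, colnames(feats))),
                    check.names = FALSE)
  utils::write.csv(rbind(tab, seg), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode one phone as its binary feature vector
#'
#' The segmentation character returns the reserved all-ones code.
#'
#' @param phone a phone symbol present in the inventory, or the inventory's
#'   segmentation character.
#' @param inv a [phone_inventory()].
#' @return Numeric binary vector of length `inv$n_features`.
#' @export
encode_phone <- function(phone, inv) {
  stopifnot(inherits(inv, "phone_inventory"))
  if (identical(phone, inv$seg_symbol)) return(rep(1, inv$n_features))
  if (!phone %in% inv$phones)
    stop(sprintf("unknown phone symbol '%s'", phone))
  as.numeric(inv$features[phone, ])
}

# rows interpolating between feature vectors a and b at fractions 0.05 and
# 0.95; each row is anchored at its nearer endpoint so that binary features
# produce the values 0.05 and 0.95 exactly
coart_rows <- function(a, b) {
  rbind(a + 0.05 * (b - a), b + 0.05 * (a - b))
}

#' Build the dynamic unfolding input matrix for a word
#'
#' The spoken word unfolds one row per timestep: two ramp-up rows from
#' silence (all zeros) into the first phone, each phone held for one row,
#' two co-articulation rows interpolating between consecutive phone codes at
#' fractions 0.05 and 0.95 (so a feature transitioning from 1 to 0 passes
#' through 0.95 then 0.05), the all-ones segmentation character marking the
#' offset, and two ramp-down rows back to silence. A label of `p` phones
#' therefore yields `3 * (p + 1) + 2` rows; with padding, `3 * n_slots + 2`
#' rows (32 at the default 10 slots).
#'
#' @param label character vector of phone symbols (the word), or a single
#'   space-separated string.
#' @param inv a [phone_inventory()].
#' @param n_slots slot capacity including the segmentation character
#'   (default 10).
#' @param pad append all-zero rows up to `3 * n_slots + 2` rows?
#' @return An `unfolding_matrix`: a rows-by-`n_features` matrix with
#'   attributes `n_label_phones` and `n_slots`.
#' @export
build_unfolding_matrix <- function(label, inv, n_slots = 10L, pad = TRUE) {
  label <- parse_label(label)
  p <- length(label)
  if (p < 1L) stop("label must contain at least one phone")
  if (p > n_slots - 1L)
    stop(sprintf("label of %d phones exceeds capacity of %d slots (one slot is reserved for the segmentation character)",
                 p, n_slots))
  codes <- lapply(label, encode_phone, inv = inv)
  seg <- rep(1, inv$n_features)
  zero <- rep(0, inv$n_features)
  states <- c(list(zero), codes, list(seg), list(zero))
  rows <- vector("list", 0L)
  for (i in seq_len(length(states) - 1L)) {
    rows[[length(rows) + 1L]] <- coart_rows(states[[i]], states[[i + 1L]])
    if (i < length(states) - 1L)
      rows[[length(rows) + 1L]] <- matrix(states[[i + 1L]], nrow = 1L)
  }
  m <- do.call(rbind, rows)
  if (pad) {
    total <- 3L * n_slots + 2L
    m <- rbind(m, matrix(0, total - nrow(m), inv$n_features))
  }
  structure(m, n_label_phones = p, n_slots = as.integer(n_slots),
            class = c("unfolding_matrix", class(m)))
}

# accept "b a s" or c("b","a","s")
parse_label <- function(label) {
  if (length(label) == 1L && grepl(" ", label))
    label <- strsplit(trimws(label), "\\s+")[[1]]
  as.character(label)
}

#' Row indices of the phone (non-transition) rows of an unfolding matrix
#'
#' Phone `i` of the label is held at row `3 * i`; the segmentation character
#' sits at row `3 * (p + 1)`.
#'
#' @param n_label_phones number of phones in the label.
#' @param include_seg also return the segmentation-character row?
#' @return Integer row indices.
#' @export
phone_row_indices <- function(n_label_phones, include_seg = FALSE) {
  upto <- if (include_seg) n_label_phones + 1L else n_label_phones
  3L * seq_len(upto)
}

#' Last non-padded timestep (word offset) of an unfolding matrix
#'
#' @param label phone label (vector or space-separated string).
#' @return The row index of the final ramp-down row, `3 * (p + 1) + 2`.
#' @export
word_offset_row <- function(label) {
  3L * (length(parse_label(label)) + 1L) + 2L
}

#' Build the static slotted lexical vector for a word
#'
#' Concatenates each phone's feature code in order, then the segmentation
#' character's all-ones code, then zero-pads to `n_slots * n_features`
#' entries (200 at the defaults).
#'
#' @inheritParams build_unfolding_matrix
#' @param include_seg append the segmentation character before padding?
#'   Default `TRUE` (the slot capacity accommodates the longest word plus
#'   the segmentation character).
#' @return Numeric binary vector of length `n_slots * inv$n_features`.
#' @export
build_lexical_vector <- function(label, inv, n_slots = 10L, include_seg = TRUE) {
  label <- parse_label(label)
  p <- length(label)
  if (p < 1L) stop("label must contain at least one phone")
  if (p > n_slots - 1L)
    stop(sprintf("label of %d phones exceeds capacity of %d slots", p, n_slots))
  parts <- unlist(lapply(label, encode_phone, inv = inv))
  if (include_seg) parts <- c(parts, rep(1, inv$n_features))
  c(parts, rep(0, n_slots * inv$n_features - length(parts)))
}

#' Cohort of a vocabulary item
#'
#' The cohort of a word is the set of vocabulary items sharing its initial
#' phonological material; by default membership is shared first phone,
#' optionally shared first two phones.
#'
#' @param item_id id of the item whose cohort is wanted.
#' @param vocab vocabulary data frame with columns `item_id` and `label`
#'   (space-separated phone symbols).
#' @param depth number of initial phones that must match (1 or 2).
#' @return Character vector of item ids (including `item_id` itself).
#' @export
cohort_of <- function(item_id, vocab, depth = 1L) {
  if (!item_id %in% vocab$item_id) stop(sprintf("unknown item '%s'", item_id))
  onsets <- vapply(vocab$label, function(l) {
    ph <- parse_label(l)
    paste(ph[seq_len(min(depth, length(ph)))], collapse = " ")
  }, character(1L), USE.NAMES = FALSE)
  key <- onsets[match(item_id, vocab$item_id)]
  vocab$item_id[onsets == key]
}

#' Cohort sizes for every vocabulary item
#'
#' @inheritParams cohort_of
#' @return Named integer vector of cohort sizes, one per item.
#' @export
cohort_sizes <- function(vocab, depth = 1L) {
  sizes <- vapply(vocab$item_id, function(id)
    length(cohort_of(id, vocab, depth)), integer(1L))
  stats::setNames(sizes, vocab$item_id)
}

#' Read a vocabulary CSV
#'
#' Expected header: `item_id,label,category`; labels are space-separated
#' phone symbols.
#'
#' @param path CSV file path.
#' @return Data frame with character columns `item_id`, `label`, `category`.
#' @export
read_vocabulary <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "label", "category")
  if (!all(need %in% names(v)))
    stop("vocabulary needs columns item_id, label, category")
  v$item_id <- as.character(v$item_id)
  if (anyDuplicated(v$item_id)) stop("item ids must be unique")
  v[, need]
}

#' Write a vocabulary CSV
#'
#' @param vocab vocabulary data frame.
#' @param path output CSV path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.csv(vocab[, c("item_id", "label", "category")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
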