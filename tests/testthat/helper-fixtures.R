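# Deterministic hand-built fixtures shared across test files.

# Four-phone toy inventory with hand-picked 20-feature codes.
toy_inventory <- function() {
  feats <- rbind(
    b = c(1, 0, 1, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 1),
    s = c(1, 1, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0),
    a = c(0, 0, 0, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 0),
    i = c(0, 0, 1, 1, 0, 0, 0, 1, 1, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0))
  phone_inventory(rownames(feats), feats,
                  c("consonant", "consonant", "vowel", "vowel"))
}

# Two-feature inventory where phones p1/p2 differ in exactly one feature:
# isolates the co-articulation interpolation rule.
two_feature_inventory <- function() {
  feats <- rbind(p1 = c(1, 0, 1, 1), p2 = c(0, 0, 1, 1),
                 v1 = c(0, 1, 0, 1))
  phone_inventory(rownames(feats), feats,
                  c("consonant", "consonant", "vowel"))
}

# Tiny three-item vocabulary over the toy inventory.
toy_vocab <- function() {
  data.frame(item_id = c("it1", "it2", "it3"),
             label = c("b a", "b i", "s a"),
             category = c("catA", "catA", "catB"),
             stringsAsFactors = FALSE)
}

# A small prepared dataset with hand-made binary representations.
toy_dataset <- function(n_slots = 4L) {
  vocab <- toy_vocab()
  set.seed(42)
  sem <- matrix(rbinom(3 * 8, 1, 0.5), 3, 8,
                dimnames = list(vocab$item_id, NULL))
  vis <- matrix(rbinom(3 * 6, 1, 0.5), 3, 6,
                dimnames = list(vocab$item_id, NULL))
  prepare_dataset(vocab, toy_inventory(), sem, vis, n_slots = n_slots)
}

# Independent reconstruction of the unfolding matrix by a different route:
# lay out the full state sequence (silence, phones, segmentation, silence)
# and linearly interpolate each feature at fractions 0.05 / 0.95 between
# consecutive states.
oracle_unfolding <- function(label, inv) {
  ph <- strsplit(label, " ")[[1]]
  states <- rbind(0,
                  t(vapply(ph, function(s) encode_phone(s, inv),
                           numeric(inv$n_features))),
                  1, 0)
  rows <- NULL
  for (i in seq_len(nrow(states) - 1L)) {
    a <- states[i, ]; b <- states[i + 1L, ]
    rows <- rbind(rows, (1 - 0.05) * a + 0.05 * b, (1 - 0.95) * a + 0.95 * b)
    if (i + 1L < nrow(states)) rows <- rbind(rows, b)
  }
  unname(rows)
}
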