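# shared fixture: engineered vocabulary with a known valid trial tuple
fx <- gen_vwp_fixture(seed = 1)
fx_sem_tab <- pairwise_jaccard_table(fx$semantic, "semantic")
fx_vis_tab <- pairwise_jaccard_table(fx$visual, "visual")

test_that("rhyme extraction runs from the last vowel to the label end", {
  inv <- fx$inv
  expect_equal(rhyme_of("b a s", inv), "a s")
  expect_equal(rhyme_of("m o d", inv), "o d")
  expect_equal(rhyme_of("b a", inv), "a")
  expect_equal(rhyme_of("b a s t a", inv), "a")
  expect_equal(rhyme_of("b a s", inv, method = "final_n", n = 2), "a s")
})

test_that("relatedness flags match hand-computed percentiles on the fixture", {
  flags <- relatedness_flags("w01", "w02", fx$vocab, fx_sem_tab, fx_vis_tab,
                             fx$inv)
  expect_true(flags[["onset_share"]])       # b a s / b i k
  expect_false(flags[["rhyme_share"]])
  expect_true(flags[["sem_unrelated"]])
  expect_true(flags[["vis_unrelated"]])
  flags_s <- relatedness_flags("w01", "w03", fx$vocab, fx_sem_tab, fx_vis_tab,
                               fx$inv)
  expect_true(flags_s[["sem_related"]])
  expect_true(flags_s[["vis_unrelated"]])
  flags_v <- relatedness_flags("w01", "w04", fx$vocab, fx_sem_tab, fx_vis_tab,
                               fx$inv)
  expect_true(flags_v[["vis_related"]])
  expect_true(flags_v[["sem_unrelated"]])
  # brute-force percentile check with raw quantiles
  q85 <- quantile(fx_sem_tab$jaccard, 0.85)
  j13 <- pair_jaccard(fx_sem_tab, "w01", "w03")
  expect_identical(unname(flags_s[["sem_related"]]), unname(j13 >= q85))
  expect_error(relatedness_flags("w01", "w01", fx$vocab, fx_sem_tab,
                                 fx_vis_tab, fx$inv), "self-comparison")
  expect_error(relatedness_flags("w01", "zz", fx$vocab, fx_sem_tab,
                                 fx_vis_tab, fx$inv), "unknown item")
})

test_that("the vocabulary-maximum semantic pair is semantically related", {
  top <- fx_sem_tab[which.max(fx_sem_tab$jaccard), ]
  flags <- relatedness_flags(top$item_a, top$item_b, fx$vocab, fx_sem_tab,
                             fx_vis_tab, fx$inv)
  expect_true(flags[["sem_related"]])
})

test_that("trial selection finds exactly the engineered tuple and re-verifies", {
  trials <- select_trials(fx$vocab, fx_sem_tab, fx_vis_tab, fx$inv)
  expect_gte(nrow(trials), 1L)
  hit <- merge(trials, fx$expected)
  expect_equal(nrow(hit), 1L)
  # every returned tuple passes re-verification through relatedness_flags
  for (r in seq_len(nrow(trials))) {
    tr <- trials[r, ]
    fp <- relatedness_flags(tr$target, tr$prel, fx$vocab, fx_sem_tab,
                            fx_vis_tab, fx$inv)
    expect_true(fp[["onset_share"]] && !fp[["rhyme_share"]] &&
                  fp[["sem_unrelated"]] && fp[["vis_unrelated"]])
    fs <- relatedness_flags(tr$target, tr$srel, fx$vocab, fx_sem_tab,
                            fx_vis_tab, fx$inv)
    expect_true(fs[["sem_related"]] && fs[["vis_unrelated"]] &&
                  !fs[["onset_share"]] && !fs[["rhyme_share"]])
    fv <- relatedness_flags(tr$target, tr$vrel, fx$vocab, fx_sem_tab,
                            fx_vis_tab, fx$inv)
    expect_true(fv[["vis_related"]] && fv[["sem_unrelated"]] &&
                  !fv[["onset_share"]] && !fv[["rhyme_share"]])
    fu <- relatedness_flags(tr$target, tr$urel, fx$vocab, fx_sem_tab,
                            fx_vis_tab, fx$inv)
    expect_true(fu[["sem_unrelated"]] && fu[["vis_unrelated"]] &&
                  !fu[["onset_share"]] && !fu[["rhyme_share"]])
  }
})

test_that("removing the engineered onset competitor leaves zero trials", {
  keep <- fx$vocab$item_id != "w02"
  vocab2 <- fx$vocab[keep, ]
  sem2 <- pairwise_jaccard_table(fx$semantic[keep, ], "semantic")
  vis2 <- pairwise_jaccard_table(fx$visual[keep, ], "visual")
  expect_warning(trials <- select_trials(vocab2, sem2, vis2, fx$inv),
                 "no candidate tuple")
  expect_equal(nrow(trials), 0L)
})

test_that("trial selection is invariant to vocabulary row order", {
  set.seed(12)
  perm <- sample(nrow(fx$vocab))
  trials_a <- select_trials(fx$vocab, fx_sem_tab, fx_vis_tab, fx$inv)
  trials_b <- select_trials(fx$vocab[perm, ], fx_sem_tab, fx_vis_tab, fx$inv)
  key <- function(d) sort(do.call(paste, d))
  expect_equal(key(trials_a), key(trials_b))
})

test_that("trial activations match an independent slice-binarize-Jaccard oracle", {
  d <- prepare_dataset(fx$vocab, fx$inv, fx$semantic, fx$visual)
  p <- init_params(20, nrow(d$Y), seed = 13)
  for (nm in c("W_u", "H_u", "W_r", "H_r", "W", "U"))
    p[[nm]] <- p[[nm]] * 20          # spread activations away from zero
  model <- structure(list(params = p, segments = d$segments),
                     class = "gru_model")
  spec <- fx$expected
  res <- run_trial(model, spec, d)
  Tn <- dim(d$X)[1]
  expect_equal(nrow(res), 4L * Tn)
  # oracle: plain loops over timesteps and candidates
  H <- gru_forward(p, d$X[, , match("w01", d$vocab$item_id)])
  seg <- d$segments$semvis
  for (tt in c(1L, 5L, 14L, Tn)) {
    hb <- as.numeric(H[tt, seg] > 0.5)
    for (cl in c("PREL", "SREL", "VREL", "UREL")) {
      cand_id <- spec[[tolower(substr(cl, 1, 4))]]
      cand <- d$Y[seg, match(cand_id, d$vocab$item_id)]
      expect_equal(res$activation[res$class == cl & res$timestep == tt],
                   jaccard(hb, cand))
    }
  }
  # UREL relative activation is identically zero
  expect_true(all(res$relative_activation[res$class == "UREL"] == 0))
  # attended candidate is the argmax of raw activations
  att <- res[res$attended & res$timestep == 5L, ]
  acts5 <- res$activation[res$timestep == 5L]
  expect_equal(att$activation[1], max(acts5))
})

test_that("a candidate matching the model output at offset activates fully", {
  d <- prepare_dataset(fx$vocab, fx$inv, fx$semantic, fx$visual)
  seg <- d$segments$semvis
  y <- d$Y[, match("w02", d$vocab$item_id)]
  act <- model_output_activation(y - 0.001 + 0.002 * y, y[seg], seg)
  expect_equal(act, 1)
})

test_that("grand averages reduce correctly for single and duplicated trials", {
  d <- prepare_dataset(fx$vocab, fx$inv, fx$semantic, fx$visual)
  p <- init_params(20, nrow(d$Y), seed = 14)
  model <- structure(list(params = p, segments = d$segments),
                     class = "gru_model")
  r1 <- run_trial(model, fx$expected, d)
  ga1 <- grand_average(list(r1))
  expect_equal(ga1$table$mean[ga1$table$class == "PREL"],
               r1$relative_activation[r1$class == "PREL"])
  ga2 <- grand_average(list(r1, r1))
  expect_equal(ga2$table$ci_hi - ga2$table$ci_lo, rep(0, nrow(ga2$table)))
  expect_equal(ga2$table$mean, ga1$table$mean)
})
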