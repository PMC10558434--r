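# Small synthetic corpora and trained models, built once per test run and
# memoized so several test files can share them.

.fixtures <- new.env(parent = emptyenv())

tiny_corpus <- function() {
  if (is.null(.fixtures$corpus)) {
    cfg <- corpus_config(days = 6, split_days = 4)
    .fixtures$corpus <- make_training_corpus(cfg, seed = 402L)
  }
  .fixtures$corpus
}

# lightly trained predictor on the tiny corpus (enough epochs to be
# non-degenerate, few enough to stay fast)
tiny_model <- function(variant = "p", ph_min = 30, epochs = 3) {
  key <- sprintf("m_%s_%d_%d", variant, ph_min, epochs)
  if (is.null(.fixtures[[key]])) {
    cfg <- model_config(variant, ph_min = ph_min, epochs = epochs,
                       seed = 77L)
    .fixtures[[key]] <- train_predictor(tiny_corpus()$train, cfg)
  }
  .fixtures[[key]]
}
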