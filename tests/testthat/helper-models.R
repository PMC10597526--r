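# Trained toy models shared across acceptance tests.  Training is
# memoized per session so several criteria can reuse one set of models.
# Problem sizes (250/150 transcripts per class, per-task epoch budgets,
# ~26k-parameter models) are the desk-scale configuration documented in
# the methods vignette.

.model_cache <- new.env(parent = emptyenv())

accept_corpus <- function(mode = c("hard", "default")) {
  mode <- match.arg(mode)
  key <- paste0("corpus_", mode)
  if (is.null(.model_cache[[key]])) {
    p <- generatorParams(nPerClass = if (mode == "hard") 250L else 150L,
                         seed = if (mode == "hard") 1301L else 2302L,
                         hard = mode == "hard")
    .model_cache[[key]] <- generateDataset(p)
  }
  .model_cache[[key]]
}

accept_model <- function(mode, task, seed) {
  key <- paste(mode, task, seed, sep = "_")
  if (is.null(.model_cache[[key]])) {
    dd <- accept_corpus(mode)
    epochs <- if (task == "seq_wt") { if (mode == "hard") 16L else 14L }
              else if (mode == "hard") 10L else 8L
    cfg <- modelConfig("lfnet", nEncoderLayers = 2L, hiddenDim = 32L,
                       task = task)
    ck <- trainModel(buildModel(cfg, seed = seed), dd$transcripts,
                     dd$split@train, utils::head(dd$split@validation, 32L),
                     objectiveConfig(task, lambda = 0.1), batchPlan(4000L),
                     epochs = epochs, lr = 3e-3, weightDecay = 1e-4,
                     seed = seed)
    .model_cache[[key]] <- ck$model
  }
  .model_cache[[key]]
}

accept_test_f1 <- function(model, dd) {
  ids <- dd$split@test
  preds <- vapply(ids, function(id)
    classify(model, transcriptSeqs(dd$transcripts)[[id]])$label, "")
  confusionMetrics(preds, transcriptLabels(dd$transcripts)[ids])$F1
}
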