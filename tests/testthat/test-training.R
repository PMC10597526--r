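test_that("position weights match closed forms and limits", {
  expect_equal(positionWeights(1L, 5), 1)
  expect_equal(positionWeights(3L, 1e-12), rep(1 / 3, 3L), tolerance = 1e-9)
  expect_equal(positionWeights(3L, 0), rep(1 / 3, 3L))
  expect_equal(positionWeights(2L, log(2)), c(2 / 3, 1 / 3))
  w <- positionWeights(40L, 0.1)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  expect_equal(positionWeights(5L, 1e6), c(1, 0, 0, 0, 0))
  expect_error(positionWeights(3L, -1), "nonnegative")
})

test_that("sequenceLoss combines per-position losses per objective", {
  expect_equal(sequenceLoss(rep(3, 7), objectiveConfig("seq_wt", lambda = 2)), 3)
  expect_equal(sequenceLoss(c(1, 0), objectiveConfig("seq_wt", lambda = log(2))),
               2 / 3)
  expect_equal(sequenceLoss(c(1, 0, 2), objectiveConfig("seq")), 1)
  expect_equal(sequenceLoss(c(5, 9, 9), objectiveConfig("class")), 5)
  # very large lambda approaches the first-position loss
  expect_equal(sequenceLoss(c(4, 1, 1), objectiveConfig("seq_wt", lambda = 50)),
               4, tolerance = 1e-9)
})

test_that("lambda interpolates between translation and classification losses", {
  # computed on a fixed batch of model losses, not synthetic numbers
  m <- tiny_model("lfnet", task = "seq_wt")
  dd <- tiny_corpus(n = 3L, seed = 77L)
  ts <- dd$transcripts
  id <- transcriptIds(ts)[transcriptLabels(ts) == "PC"][1L]
  X <- seqToOneHot(transcriptSeqs(ts)[[id]])
  tg <- lfnetr:::.TOK[lfnetr:::.targetTokens("PC", transcriptProteins(ts)[[id]], "seq")]
  N <- length(tg)
  lossAt <- function(w) lfnetr:::.exampleGrad(m@params, m@config, X, tg, w)$loss
  l_seq <- lossAt(rep(1 / N, N))
  l_class <- lossAt(c(1, rep(0, N - 1L)))
  expect_equal(lossAt(positionWeights(N, 1e-9)), l_seq, tolerance = 1e-6)
  expect_equal(lossAt(positionWeights(N, 1e4)), l_class, tolerance = 1e-6)
})

test_that("startLoss closed forms", {
  expect_equal(startLoss(c(0, 1, 0), 2L), 0)
  L <- 17L
  expect_equal(startLoss(rep(1 / L, L), 5L), log(L))
  expect_equal(startLoss(c(1, 0), 2L), -log(1e-12))
})

test_that("length-binned batches respect the token budget", {
  lens <- c(5L, 50L, 51L, 100L, 110L, 200L)
  plan <- batchPlan(maxTokensPerBatch = 220L)
  batches <- lfnetr:::.makeBatches(lens, plan)
  expect_setequal(unlist(batches), seq_along(lens))
  for (b in batches)
    expect_lte(length(b) * max(lens[b]), 220L)
})

test_that("training reduces loss and fits separable data", {
  dd <- tiny_corpus(n = 16L, seed = 55L)
  ts <- dd$transcripts; sp <- dd$split
  m <- buildModel(modelConfig("lfnet", nEncoderLayers = 1L, hiddenDim = 16L,
                              task = "class"), seed = 2L)
  ck <- trainModel(m, ts, sp@train, character(0), objectiveConfig("class"),
                   batchPlan(1500L), epochs = 30L, lr = 5e-3, seed = 4L)
  expect_lt(utils::tail(ck$log$loss, 1L), ck$log$loss[1L])
  preds <- vapply(sp@train, function(id)
    classify(ck$model, transcriptSeqs(ts)[[id]])$label, "")
  expect_gt(mean(preds == transcriptLabels(ts)[sp@train]), 0.95)
})

test_that("start-pointer training reduces loss and drives pointer mass", {
  dd <- suppressWarnings(tiny_corpus(n = 10L, seed = 58L))
  ts <- dd$transcripts; sp <- dd$split
  m <- buildModel(modelConfig("lfnet", nEncoderLayers = 1L, hiddenDim = 16L,
                              task = "start"), seed = 3L)
  ck <- trainModel(m, ts, sp@train, character(0), objectiveConfig("start"),
                   batchPlan(2000L), epochs = 8L, lr = 3e-3, seed = 5L)
  expect_lt(utils::tail(ck$log$loss, 1L), ck$log$loss[1L])
  # pointer classification stays on its own contract after training
  id <- sp@train[1L]
  cl <- classify(ck$model, transcriptSeqs(ts)[[id]], mode = "pointer")
  expect_true(cl$label %in% c("PC", "NC"))
  expect_gte(cl$p_pc, 0); expect_lte(cl$p_pc, 1)
})

test_that("training is deterministic under a seed and resumes exactly", {
  dd <- tiny_corpus(n = 6L, seed = 60L)
  ts <- dd$transcripts; sp <- dd$split
  mk <- function() buildModel(modelConfig("lfnet", nEncoderLayers = 1L,
                                          hiddenDim = 8L, nHeads = 2L,
                                          task = "class"), seed = 1L)
  ck1 <- trainModel(mk(), ts, sp@train, character(0), objectiveConfig("class"),
                    batchPlan(2000L), epochs = 2L, seed = 9L)
  ck2 <- trainModel(mk(), ts, sp@train, character(0), objectiveConfig("class"),
                    batchPlan(2000L), epochs = 2L, seed = 9L)
  expect_equal(ck1$log$loss, ck2$log$loss)

  # resume from a saved checkpoint: the next epoch's loss must reproduce
  ck3 <- trainModel(mk(), ts, sp@train, character(0), objectiveConfig("class"),
                    batchPlan(2000L), epochs = 3L, seed = 9L,
                    lrSchedule = "constant")
  ck2b <- trainModel(mk(), ts, sp@train, character(0), objectiveConfig("class"),
                     batchPlan(2000L), epochs = 2L, seed = 9L,
                     lrSchedule = "constant")
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(ck2b, f)
  ck4 <- trainModel(loadCheckpoint(f), ts, sp@train, character(0),
                    objectiveConfig("class"), batchPlan(2000L), epochs = 1L,
                    lrSchedule = "constant")
  expect_equal(utils::tail(ck4$log$loss, 1L), utils::tail(ck3$log$loss, 1L),
               tolerance = 1e-10)
})

test_that("training aborts on divergence with a diagnostic", {
  dd <- tiny_corpus(n = 4L, seed = 61L)
  ts <- dd$transcripts; sp <- dd$split
  m <- tiny_model("lfnet")
  m@params$Wout <- m@params$Wout * 1e308    # force overflow
  expect_error(
    trainModel(m, ts, sp@train, character(0), objectiveConfig("class"),
               batchPlan(2000L), epochs = 1L),
    "non-finite")
})
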