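mem_from <- function(vals, s, method = "ism")
  new("MutationEffectMatrix", values = vals, refSequence = s,
      method = method, beta = NA_real_, steps = NA_real_, modelId = "t")

test_that("importance tracks apply the counterfactual-class definition", {
  s <- "ACG"
  vals <- rbind(c(-2, -1, 3), c(0, 0, 0), c(1, 2, -5))
  mem <- mem_from(vals, s)
  up_pc <- importanceTrack(mem, "up_PC")
  up_nc <- importanceTrack(mem, "up_NC")
  expect_equal(up_pc@values, c(2, 0, 5))
  expect_equal(up_nc@values, c(3, 0, 2))
  # negating the matrix swaps the directions
  memn <- mem_from(-vals, s)
  expect_equal(importanceTrack(memn, "up_PC")@values, up_nc@values)
  expect_equal(importanceTrack(memn, "up_NC")@values, up_pc@values)
  # all-zero matrix gives an all-zero track
  expect_true(all(importanceTrack(mem_from(matrix(0, 3, 3), s))@values == 0))
})

test_that("canonical masking covers ORF boundaries and nonsense argmaxes", {
  # 12-nt construct: AUG AAA GGG UAA, CDS [0,12)
  s <- "AUGAAAGGGUAA"
  L <- 12L
  vals <- matrix(0, L, 3L)
  # position 4 (0-based 3): codon AAA; alternatives at its first base are
  # C, G, U (ref A) -> U gives UAA, an in-frame premature stop
  # make U the up_PC argmax at that position (column 3, most negative)
  vals[4L, ] <- c(-0.1, -0.2, -5)
  # position 5 (codon AAA, second base): make C the argmax: ACA is not a stop
  vals[5L, ] <- c(-4, -0.1, -0.2)
  mem <- mem_from(vals, s)
  tr <- importanceTrack(mem, "up_PC")
  masked <- maskCanonical(tr, s, mem, cds = c(0L, 12L))
  expect_true(all(masked@mask[1:3]))        # start codon
  expect_true(all(masked@mask[10:12]))      # stop codon
  expect_true(masked@mask[4L])              # nonsense-creating argmax
  expect_false(masked@mask[5L])             # missense argmax stays unmasked
  # a track whose maximum sits on the start codon moves elsewhere after masking
  vals2 <- matrix(0, L, 3L); vals2[2L, 1L] <- -9; vals2[6L, 1L] <- -1
  mem2 <- mem_from(vals2, s)
  tr2 <- maskCanonical(importanceTrack(mem2, "up_PC"), s, mem2, cds = c(0L, 12L))
  vv <- tr2@values; vv[tr2@mask] <- -Inf
  expect_equal(which.max(vv), 6L)
  # transcript with no ORF: empty mask
  s3 <- strrep("C", 12L)
  mem3 <- mem_from(matrix(1, 12L, 3L), s3)
  expect_false(any(maskCanonical(importanceTrack(mem3, "up_PC"), s3, mem3)@mask))
})

test_that("region partitions are disjoint, ordered and covering", {
  part <- regionPartition("CCAUGAAAUAACC", cds = c(2L, 11L))
  expect_equal(part$region, c("utr5", "cds", "utr3"))
  expect_equal(part$start, c(0L, 2L, 11L))
  expect_equal(part$end, c(2L, 11L, 13L))
  # noncoding: longest ORF demarcates
  part2 <- regionPartition("CCAUGAAAUAACC")
  expect_equal(part2$region, c("upstream", "orf", "downstream"))
  part3 <- regionPartition(strrep("C", 9L))
  expect_equal(part3$region, "upstream")
  expect_equal(part3$end, 9L)
})

test_that("metagene aligns, averages, and enforces the coverage threshold", {
  # single input: profile equals the series
  p1 <- metagene(list(c(1, 2, 3)), 0L, 0.5)
  expect_equal(p1@mean, c(1, 2, 3))
  expect_equal(p1@position, 0:2)
  # two fully overlapping series: elementwise mean
  p2 <- metagene(list(c(1, 2), c(3, 4)), c(0L, 0L), 0.5)
  expect_equal(p2@mean, c(2, 3))
  # coverage counting: rel position in 6/10 dropped, 7/10 kept at 0.7
  mk <- function(n, len) replicate(n, rep(1, len), simplify = FALSE)
  series <- c(mk(7, 5), mk(3, 4))
  prof <- metagene(series, rep(0L, 10L), 0.70)
  expect_true(4L %in% prof@position)         # covered by 7 of 10
  series2 <- c(mk(6, 5), mk(4, 4))
  prof2 <- metagene(series2, rep(0L, 10L), 0.70)
  expect_false(4L %in% prof2@position)       # covered by 6 of 10
})

test_that("binned metagene uses equal-width index arithmetic", {
  s <- strrep("A", 50L)
  mem <- mem_from(matrix(2, 50L, 3L), s)
  prof <- binnedMetagene(list(mem), nBins = 25L)
  expect_equal(prof@mean, rep(2, 25L))
  # positions 0-1 in bin 0, 2-3 in bin 1, ...
  vals <- matrix(0, 50L, 3L); vals[3L, ] <- 30  # 0-based position 2
  memb <- mem_from(vals, s)
  prof2 <- binnedMetagene(list(memb), nBins = 25L)
  expect_equal(prof2@mean[2L], 15)              # bin 1 mean over 2 positions
  expect_equal(sum(prof2@mean > 0), 1L)
  # nBins equal to region length: width-1 bins
  s9 <- strrep("A", 9L)
  mem9 <- mem_from(matrix(seq_len(27), 9L, 3L), s9)
  prof3 <- binnedMetagene(list(mem9), nBins = 9L)
  expect_equal(prof3@mean, rowMeans(matrix(seq_len(27), 9L, 3L)))
})

test_that("motif windows are 21 nt, tie-break 5'-most, controls never overlap", {
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "U"), 80L, TRUE), collapse = "")
  part <- data.frame(region = "all", start = 0L, end = 80L)
  v <- rep(0.1, 80L); v[c(30L, 45L)] <- 7    # tied maxima -> 5'-most wins
  tr <- new("ImportanceTrack", values = v, direction = "up_PC",
            mask = rep(FALSE, 80L))
  win <- extractMotifWindows(list(t1 = tr), c(t1 = s), list(t1 = part))
  expect_equal(nrow(win), 1L)
  expect_equal(win$center, 29L)              # 0-based
  expect_equal(nchar(win$seq), 21L)
  expect_equal(win$end - win$start, 21L)
  expect_identical(win$seq, substr(s, win$start + 1L, win$end))

  # region shorter than the window is skipped with a log entry
  short <- data.frame(region = "all", start = 0L, end = 15L)
  tr2 <- new("ImportanceTrack", values = v[1:15], direction = "up_PC",
             mask = rep(FALSE, 15L))
  win2 <- extractMotifWindows(list(t1 = tr2), c(t1 = s), list(t1 = short))
  expect_equal(nrow(win2), 0L)
  expect_match(attr(win2, "skipped"), "shorter")

  # masked argmax never falls on a masked position
  vm <- rep(0.1, 80L); vm[40L] <- 9; vm[20L] <- 5
  trm <- new("ImportanceTrack", values = vm, direction = "up_PC",
             mask = seq_len(80L) == 40L)
  winm <- extractMotifWindows(list(t1 = trm), c(t1 = s), list(t1 = part))
  expect_equal(winm$center, 19L)

  # strategy-1 controls never overlap their primaries (interval oracle)
  for (k in 1:20) {
    ctl <- buildControlSet(win, c(t1 = s), list(t1 = part), strategy = 1L)
    expect_equal(nrow(ctl), 1L)
    expect_true(ctl$end <= win$start || ctl$start >= win$end)
    expect_equal(nchar(ctl$seq), 21L)
  }
  # strategy 2 returns the opposite-class windows unchanged
  expect_identical(buildControlSet(win, c(t1 = s), list(t1 = part),
                                   strategy = 2L, oppositeWindows = win2),
                   win2)
})

test_that("dinucleotide shuffle preserves the dinucleotide count vector", {
  dinuc_counts <- function(s) {
    ch <- strsplit(s, "")[[1L]]
    table(paste0(ch[-length(ch)], ch[-1L]))
  }
  set.seed(80)
  for (k in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 60L, TRUE), collapse = "")
    sh <- dinucleotideShuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
  }
  # shuffles differ from the original at least sometimes
  s <- strrep("AUGGCCAAAGGGUUUCCCAAA", 3L)
  expect_true(any(replicate(5, dinucleotideShuffle(s)) != s))
})

test_that("codon shuffle fixes start/stop and degenerates to identity", {
  s <- paste0("CC", "AUG", "AAA", "UAA", "GG")     # one internal codon
  expect_identical(codonShuffle(s, c(2L, 11L)), s)
  set.seed(81)
  s2 <- paste0("AUG", "AAACCCGGGUUU", "UAA")
  sh <- codonShuffle(s2, c(0L, 18L))
  expect_equal(nchar(sh), nchar(s2))
  expect_identical(substr(sh, 1L, 3L), "AUG")
  expect_identical(substr(sh, 16L, 18L), "UAA")
  split_codons <- function(x) sort(substring(x, seq(4, 13, 3), seq(6, 15, 3)))
  expect_equal(split_codons(sh), split_codons(s2))
})

test_that("nonsense scan matches a brute-force translation oracle", {
  s <- "AUGAAAAAAUAA"
  cds <- c(0L, 12L)
  vars <- lfnetr:::.nonsenseVariants(s, cds)
  # brute force: all 3L variants, check premature in-frame stop
  brute <- list()
  for (i in seq_len(nchar(s))) {
    ref <- substr(s, i, i)
    for (b in setdiff(c("A", "C", "G", "U"), ref)) {
      s2 <- s; substr(s2, i, i) <- b
      # premature stop: translation of the CDS (minus stop) truncates
      inner <- substr(s2, 1L, 9L)
      aa <- translateRNA(inner)
      if (nchar(aa) < 3L && i <= 9L)
        brute[[length(brute) + 1L]] <- c(i - 1L, b)
    }
  }
  bdf <- do.call(rbind, brute)
  got <- vars[order(vars$position, vars$alt), ]
  expect_equal(nrow(got), nrow(bdf))
  expect_equal(got$position, as.integer(bdf[, 1L]))
  expect_equal(got$alt, bdf[, 2L])
})

test_that("perturbation scoring handles applicability and seeds", {
  sc <- linear_scorer(40L)
  s <- paste0(strrep("GC", 14L), "AUGAAAUAA", "CCC")  # 5'UTR 28 nt
  cds <- c(28L, 37L)
  r1 <- perturbAndScore(sc, s, cds, "utr5_dinuc_shuffle", seed = 5L)
  r2 <- perturbAndScore(sc, s, cds, "utr5_dinuc_shuffle", seed = 5L)
  expect_equal(r1$deltaS, r2$deltaS)
  # 3'UTR of 3 nt is not shuffleable
  r3 <- perturbAndScore(sc, s, cds, "utr3_dinuc_shuffle")
  expect_equal(nrow(r3), 0L)
  expect_match(attr(r3, "reason"), "25 nt")
  r4 <- perturbAndScore(sc, s, NULL, "codon_shuffle")
  expect_match(attr(r4, "reason"), "no CDS")
  r5 <- perturbAndScore(sc, s, cds, "start_knockout")
  expect_equal(nrow(r5), 9L)
  expect_true(all(r5$position %in% 28:30))
})

test_that("attention summaries average normalized first-step attention", {
  m <- tiny_model("lfnet")
  dd <- tiny_corpus(n = 3L, seed = 90L)
  ts <- dd$transcripts
  pc <- ts[transcriptLabels(ts) == "PC"]
  prof <- attentionSummary(m, pc[1L], head = 1L, layer = 1L,
                           coverageThreshold = 0)
  # single transcript: the profile is its own attention row
  H <- encode(m, transcriptSeqs(pc)[[1L]])
  st <- decodeStep(m, "<s>", H)
  expect_equal(sort(prof@mean), sort(st$attention[[1L]][1L, , 1L]))
  expect_equal(sum(prof@mean), 1, tolerance = 1e-6)
  # averaging preserves total mass when nothing is coverage-dropped
  prof2 <- attentionSummary(m, pc, head = 2L, layer = 1L,
                            coverageThreshold = 0)
  expect_lte(sum(prof2@mean * prof2@coverage) /
               mean(prof2@coverage > 0), length(pc) + 1e-6)
})
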