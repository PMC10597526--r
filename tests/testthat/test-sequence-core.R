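test_that("standard-code translation terminates at stops and rejects bad input", {
  expect_identical(translateRNA("AUGAAAUAA"), "MK")
  expect_identical(translateRNA("AUG"), "M")
  expect_identical(translateRNA("CAUGAAA", offset = 1L), "MK")
  expect_error(translateRNA("AUGNNN"), "non-ACGU")
  expect_error(translateRNA("AU"), "too short")
})

test_that("ORF enumeration covers all frames and reports nested ORFs", {
  o <- findOrfs("AUGAAAUAA")
  expect_equal(nrow(o), 1L)
  expect_equal(c(o$start, o$end, o$frame), c(0L, 9L, 0L))
  expect_identical(o$protein, "MK")

  expect_equal(nrow(findOrfs("CCCCCC")), 0L)
  expect_null(longestOrf("CCCCCC"))

  # two nested ORFs sharing a stop on a 30-nt construct (enumerated by hand)
  s <- paste0("CCC", "AUG", "AUG", "AAA", "GGG", "UAA", "CCCCCCCCCCCC")
  o <- findOrfs(s)
  expect_equal(nrow(o), 2L)
  expect_true(all(o$end == 18L))
  expect_setequal(o$start, c(3L, 6L))
  lo <- longestOrf(s)                     # tie-break: longest wins outright here
  expect_equal(c(lo$start, lo$end), c(3L, 18L))
  expect_identical(lo$protein, "MMKG")

  # every reported ORF's protein equals translation of its span minus stop
  set.seed(5)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "U"), 120, replace = TRUE), collapse = "")
    o <- findOrfs(s)
    for (r in seq_len(nrow(o)))
      expect_identical(o$protein[r],
                       translateRNA(substr(s, o$start[r] + 1L, o$end[r] - 3L)))
  }
})

test_that("longest-ORF ties break to the 5'-most start", {
  # two ORFs of equal length in different frames; hand-constructed
  s <- paste0("AUG", "AAA", "UAA",            # frame 0: [0,9)
              "C",
              "AUG", "CCC", "UGA")            # frame 1: [10,19)
  o <- findOrfs(s)
  expect_equal(nrow(o), 2L)
  lo <- longestOrf(s)
  expect_equal(lo$start, 0L)
})

test_that("TranscriptSet validity enforces CDS/protein consistency", {
  ts <- transcriptSet("t1", "AUGAAAUAA", "PC", 0L, 9L, "MK")
  expect_s4_class(ts, "TranscriptSet")
  expect_error(transcriptSet("t1", "AUGAAAUAA", "PC", 0L, 9L, "MQ"),
               "does not match protein")
  expect_error(transcriptSet("t1", "CUGAAAUAA", "PC", 0L, 9L, "MK"),
               "AUG")
  expect_error(transcriptSet("t1", "AUGAAAUAAC", "PC", 0L, 10L, "MK"),
               "multiple of 3")
  # non-AUG flag relaxes the start invariant
  ts2 <- transcriptSet("t1", "CUGAAAUAA", "PC", 0L, 9L, "LK", nonAUG = TRUE)
  expect_s4_class(ts2, "TranscriptSet")
})

test_that("FASTA/TSV round trip is identity and normalizes DNA to RNA", {
  fa <- tempfile(fileext = ".fa"); an <- tempfile(fileext = ".tsv")
  writeLines(c(">t1", "ATGAAATAA", ">t2", "CCCGGGCCC"), fa)
  write.table(data.frame(id = c("t1", "t2"), label = c("PC", "NC"),
                         cds_start = c(0L, NA), cds_end = c(9L, NA),
                         protein = c("MK", NA)),
              an, sep = "\t", row.names = FALSE, quote = FALSE)
  ts <- readTranscripts(fa, an)
  expect_identical(unname(transcriptSeqs(ts)[1]), "AUGAAAUAA")
  fa2 <- tempfile(fileext = ".fa"); an2 <- tempfile(fileext = ".tsv")
  writeTranscripts(ts, fa2, an2)
  ts2 <- readTranscripts(fa2, an2)
  expect_identical(transcriptSeqs(ts), transcriptSeqs(ts2))
  expect_identical(transcriptLabels(ts), transcriptLabels(ts2))
  expect_identical(cdsRanges(ts), cdsRanges(ts2))
})

test_that("reader errors on missing or incomplete annotations; empty FASTA ok", {
  fa <- tempfile(fileext = ".fa"); an <- tempfile(fileext = ".tsv")
  writeLines(c(">t1", "ATGAAATAA"), fa)
  write.table(data.frame(id = "t2", label = "NC", cds_start = NA,
                         cds_end = NA, protein = NA),
              an, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readTranscripts(fa, an), "missing annotation.*t1")
  write.table(data.frame(id = "t1", label = "PC", cds_start = NA,
                         cds_end = NA, protein = NA),
              an, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readTranscripts(fa, an), "coding record")

  fa0 <- tempfile(fileext = ".fa")
  file.create(fa0)
  expect_length(readTranscripts(fa0, an), 0L)
})

test_that("length filter drops only records above the cutoff", {
  ts <- transcriptSet(c("a", "b"),
                      c(strrep("C", 50), strrep("C", 70)), c("NC", "NC"))
  expect_identical(transcriptIds(filterByLength(ts, 60L)), "a")
  expect_length(filterByLength(ts, 1200L), 2L)
})

test_that("splits are deterministic, class-balanced and length-matched", {
  dd <- tiny_corpus(n = 30L, seed = 42L)
  ts <- dd$transcripts
  sp1 <- makeSplits(ts, c(0.8, 0.1, 0.1), seed = 9L)
  sp2 <- makeSplits(ts, c(0.8, 0.1, 0.1), seed = 9L)
  expect_identical(sp1@train, sp2@train)
  expect_identical(sp1@test, sp2@test)
  all_ids <- sort(c(sp1@train, sp1@validation, sp1@test))
  expect_identical(all_ids, sort(transcriptIds(ts)))
  labs <- transcriptLabels(ts)[sp1@train]
  expect_equal(sum(labs == "PC"), sum(labs == "NC"))

  # length-skewed classes: matched split beats a random one on bin discrepancy
  set.seed(1)
  long_pc <- transcriptSet(sprintf("P%02d", 1:40),
    vapply(1:40, function(i) {
      n <- 60 + 3 * i
      paste0("AUG", paste(rep("GCC", n), collapse = ""), "UAA")
    }, ""), "PC",
    cdsStart = 0L,
    cdsEnd = vapply(1:40, function(i) 6L + 3L * (60L + 3L * i), 1L),
    protein = vapply(1:40, function(i) paste0("M", strrep("A", 60 + 3 * i)), ""))
  short_nc <- transcriptSet(sprintf("N%02d", 1:40),
    vapply(1:40, function(i)
      paste(sample(c("C", "G"), 150 + 4 * i, replace = TRUE), collapse = ""), ""),
    "NC")
  ts2 <- lfnetr:::.bindTranscriptSets(long_pc, short_nc)
  sp <- suppressWarnings(makeSplits(ts2, c(0.6, 0.2, 0.2), seed = 3L))
  set.seed(3)
  rnd <- sample(transcriptIds(ts2), length(sp@train))
  expect_lte(binDiscrepancy(ts2, sp@train), binDiscrepancy(ts2, rnd))
})
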