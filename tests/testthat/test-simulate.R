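test_that("motif planting places consensus sequences at their TSS-relative windows", {
  cfg <- SimConfig(mutationProb = 0, seed = 71)
  p <- as.character(generatePromoters(cfg, 1, seed = 71)[[1]])
  # TATA-box at -30..-25 -> 0-based indices 219..224
  expect_equal(substr(p, 220, 225), "TATAAA")
  # CAAT-box left-anchored at -80 -> indices 169..177
  expect_equal(substr(p, 170, 178), "GGCCAATCT")
  # GC-box left-anchored at -110 -> indices 139..144
  expect_equal(substr(p, 140, 145), "GGGCGG")
  expect_equal(nchar(p), 300L)
  # nonTATA promoters carry no planted TATA-box
  ntCfg <- SimConfig(promoterClass = "nonTATA", mutationProb = 0, seed = 72)
  q <- as.character(generatePromoters(ntCfg, 1, seed = 72)[[1]])
  expect_equal(substr(q, 170, 178), "GGCCAATCT")
  expect_false(substr(q, 220, 225) == "TATAAA" &&
                 substr(p, 220, 225) != substr(q, 220, 225))
})

test_that("per-position consensus match rate follows its closed form", {
  # with mutation prob p and uniform background, match rate = (1-p) + p/4
  cfg <- SimConfig(mutationProb = 0.2, seed = 73)
  n <- 4000
  seqs <- as.character(generatePromoters(cfg, n, seed = 73))
  tata <- substr(seqs, 220, 225)
  matches <- vapply(1:6, function(j)
    mean(substr(tata, j, j) == substr("TATAAA", j, j)), numeric(1))
  expected <- 0.8 + 0.2 * 0.25
  # binomial sd at n=4000 is ~0.006; allow 4 sd
  expect_true(all(abs(matches - expected) < 0.025))
})

test_that("background sequences follow the composition with no motif enrichment", {
  cfg <- SimConfig(seed = 74)
  seqs <- generateBackground(cfg, 500, seed = 74)
  expect_true(all(Biostrings::width(seqs) == 300))
  freq <- colSums(Biostrings::oligonucleotideFrequency(seqs, 1))
  expect_true(all(abs(freq / sum(freq) - 0.25) < 0.01))
  # TATAAA occurrence rate matches the composition-based expectation:
  # 295 windows x (1/4)^6 per sequence ~ 0.072 expected hits/sequence
  hits <- sum(Biostrings::vcountPattern("TATAAA", seqs))
  expected <- 500 * 295 * 0.25^6
  expect_lt(abs(hits - expected) / expected, 0.5)
  # skewed composition is honoured
  skew <- SimConfig(backgroundComposition = c(A = 1, C = 0, G = 0, T = 0),
                    promoterClass = "nonTATA", motifs = list(), seed = 75)
  expect_equal(as.character(generateBackground(skew, 1, seed = 75)[[1]]),
               strrep("A", 300))
})

test_that("a frequency scan over simulated promoters recovers the TATA window", {
  cfg <- testSimConfig(seed = 76)
  seqs <- as.character(generatePromoters(cfg, 1000, seed = 76))
  # per-position information: deviation of max base frequency from 0.25
  m <- do.call(rbind, strsplit(seqs, ""))
  maxFreq <- vapply(seq_len(ncol(m)), function(j)
    max(table(m[, j])) / nrow(m), numeric(1))
  motifCols <- c(220:225, 170:178, 140:145)
  # every planted column is far above background; the best non-motif
  # column stays near 0.25
  expect_gt(min(maxFreq[motifCols]), 0.7)
  expect_lt(max(maxFreq[-motifCols]), 0.4)
  # the TATA window is among the maximal-information columns
  expect_true(all(order(maxFreq, decreasing = TRUE)[1:21] %in% motifCols))
})

test_that("simulation is reproducible and validated", {
  cfg <- testSimConfig(seed = 77)
  a <- generatePromoters(cfg, 5, seed = 123)
  b <- generatePromoters(cfg, 5, seed = 123)
  expect_identical(as.character(a), as.character(b))
  expect_error(SimConfig(backgroundComposition = c(A = 0.5, C = 0.5,
                                                   G = 0.2, T = -0.2)),
               "sum to 1")
  expect_error(SimConfig(tssIndex = 400), "inside the sequence")
  bad <- MotifSpec("TATA-box", "TATAAA", -290, -285)
  expect_error(new("SimConfig", seqLength = 300L, tssIndex = 249L,
                   backgroundComposition = c(A = 0.25, C = 0.25, G = 0.25,
                                             T = 0.25),
                   motifs = list(bad), promoterClass = "TATA", seed = 1L),
               "outside the sequence")
})

test_that("generateBenchmark assembles balanced splits with constructed training negatives", {
  cfg <- testSimConfig(seed = 78)
  bench <- generateBenchmark(cfg, 100, seed = 78)
  expect_equal(vapply(bench, length, integer(1)),
               c(train = 160L, validation = 20L, test = 20L))
  for (tag in names(bench)) {
    expect_equal(sum(labels(bench[[tag]]) == 1),
                 sum(labels(bench[[tag]]) == 0))
  }
  # training negatives are block recombinations of the training positives
  tr <- bench$train
  pos <- sequences(tr)[labels(tr) == 1]
  neg <- sequences(tr)[labels(tr) == 0]
  expect_equal(names(neg), paste0(names(pos), "_fake"))
  for (i in c(1, 40, 80)) {
    expect_equal(sort(splitBlocks(as.character(pos[[i]]), 15)),
                 sort(splitBlocks(as.character(neg[[i]]), 15)))
  }
  # validation/test negatives are background, not recombinations
  expect_true(all(grepl("^background", names(sequences(bench$test))
                        [labels(bench$test) == 0])))
  # determinism
  bench2 <- generateBenchmark(cfg, 100, seed = 78)
  expect_identical(as.character(sequences(bench2$train)),
                   as.character(sequences(bench$train)))
})
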