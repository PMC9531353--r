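test_that("splitBlocks partitions a sequence into ordered blocks", {
  expect_equal(splitBlocks("ACGTAC", 3), c("ACG", "TAC"))
  s <- randomDna(300)
  blocks <- splitBlocks(s, 15)
  expect_length(blocks, 20)
  expect_true(all(nchar(blocks) == 15))
  expect_equal(paste(blocks, collapse = ""), s)
  expect_error(splitBlocks(randomDna(300), 7), "remainder 6")
})

test_that("constructed negatives preserve conservative blocks and the block multiset", {
  set.seed(31)
  cfg <- NegativeConfig()
  for (i in 1:20) {
    s <- randomDna(300)
    neg <- constructNegative(s, cfg, seed = 1000 + i, id = "p")
    srcBlocks <- splitBlocks(s, 15)
    negBlocks <- splitBlocks(neg@residues, 15)
    sel <- neg@selectedBlocks + 1L
    expect_length(sel, 8)
    # 12 unselected blocks are bitwise identical
    expect_equal(negBlocks[-sel], srcBlocks[-sel])
    # selected positions hold a permutation of the selected source blocks
    expect_setequal(neg@permutation + 1L, sel)
    expect_equal(negBlocks[sel], srcBlocks[neg@permutation + 1L])
    # block multiset conservation
    expect_equal(sort(negBlocks), sort(srcBlocks))
    # identity forbidden by default
    expect_false(neg@residues == s)
  }
})

test_that("construction is deterministic given (seq, config, seed)", {
  s <- randomDna(300)
  a <- constructNegative(s, seed = 99, id = "x")
  b <- constructNegative(s, seed = 99, id = "x")
  expect_identical(a@residues, b@residues)
  expect_identical(a@selectedBlocks, b@selectedBlocks)
  expect_identical(a@permutation, b@permutation)
})

test_that("degenerate configurations behave as contracted", {
  s <- randomDna(300)
  # zero substitutional blocks, identity allowed -> identity output
  idcfg <- NegativeConfig(nSubstitutional = 0, forbidIdentity = FALSE)
  expect_equal(constructNegative(s, idcfg, seed = 1, id = "x")@residues, s)
  # all-identical blocks make a non-identical recombination impossible
  mono <- strrep("ACGTAACGTAACGTA", 20)
  expect_error(constructNegative(mono, seed = 1, id = "mono"),
               "could not construct")
  # wrong length
  expect_error(constructNegative(randomDna(299), seed = 1, id = "y"),
               "expected blockSize")
  # nSubstitutional = 1 is rejected at config level
  expect_error(NegativeConfig(nSubstitutional = 1), "nSubstitutional")
})

test_that("buildTrainingNegatives yields one negative per promoter, reproducibly", {
  set.seed(32)
  proms <- Biostrings::DNAStringSet(vapply(1:100, function(i) randomDna(300),
                                           character(1)))
  names(proms) <- sprintf("p%03d", 1:100)
  negs <- buildTrainingNegatives(proms, seed = 77)
  expect_equal(length(negs), 100L)
  expect_equal(negativeTrace(negs)$source_id, names(proms))
  expect_equal(names(sequences(negs)), paste0(names(proms), "_fake"))
  # same master seed reproduces byte-identical output
  negs2 <- buildTrainingNegatives(proms, seed = 77)
  expect_identical(as.character(sequences(negs)),
                   as.character(sequences(negs2)))
  expect_identical(negativeTrace(negs), negativeTrace(negs2))
  # a subset reproduces independently (per-sequence seed derivation)
  sub <- buildTrainingNegatives(proms[1:10], seed = 77)
  expect_identical(as.character(sequences(sub)),
                   as.character(sequences(negs)[1:10]))
  # empty input
  expect_equal(length(buildTrainingNegatives(Biostrings::DNAStringSet(),
                                             seed = 1)), 0L)
})

test_that("composition report shows exact mononucleotide conservation", {
  set.seed(33)
  s <- randomDna(300)
  names(s) <- "p1"
  neg <- constructNegative(s, seed = 5, id = "p1")
  rep <- compositionReport(s, neg, id = "p1")
  mono <- rep[rep$k == 1, ]
  expect_equal(mono$source_count, mono$negative_count)
  # trinucleotide differences are confined to junction-spanning windows:
  # at most 2*(nBlocks - 1) triplets can differ in total count
  tri <- rep[rep$k == 3, ]
  expect_lte(sum(abs(tri$source_count - tri$negative_count)) / 2,
             2 * (20 - 1))
  # identity pair has identical trinucleotide counts too
  idneg <- constructNegative(s, NegativeConfig(nSubstitutional = 0,
                                               forbidIdentity = FALSE),
                             seed = 5, id = "p1")
  repId <- compositionReport(s, idneg, id = "p1")
  expect_equal(repId$source_count, repId$negative_count)
  # pairing is validated
  expect_error(compositionReport(s, neg, id = "other"), "pairing error")
})
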