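test_that("region classification matches a linear-scan oracle over the whole isoform", {
  m <- titinIsoformModel()
  r <- regionTable(m)
  # brute-force oracle: expand every region interval residue by residue
  oracle <- rep(r$label, r$last - r$first + 1L)
  expect_length(oracle, totalResidues(m))
  got <- classifyVariantRegion(m, seq_len(totalResidues(m)))
  expect_identical(got, oracle)
})

test_that("worked region calls and boundary ownership", {
  m <- titinIsoformModel()
  expect_identical(classifyVariantRegion(m, 33600), "A-band")
  expect_identical(classifyVariantRegion(m, 35800), "M-band")
  expect_identical(classifyVariantRegion(m, 1), "Z-disk")
  r <- regionTable(m)
  # every boundary residue belongs to the region whose interval holds it
  for (i in seq_len(nrow(r))) {
    expect_identical(classifyVariantRegion(m, r$first[i]), r$label[i])
    expect_identical(classifyVariantRegion(m, r$last[i]), r$label[i])
  }
  expect_error(classifyVariantRegion(m, 0), "\\[1, 35991\\]")
  expect_error(classifyVariantRegion(m, 35992), "\\[1, 35991\\]")
})

test_that("every antibody epitope maps into its expected band region", {
  m <- titinIsoformModel()
  er <- epitopeRegions(m)
  expect_identical(er[["T12"]], "I-band")
  expect_identical(er[["MIR"]], "I/A junction")
  expect_identical(er[["A170"]], "A-band")
  expect_identical(er[["M8M10"]], "M-band")
})

test_that("model validity rejects malformed region and epitope tables", {
  regions <- data.frame(label = c("a", "b"), first = c(1, 90),
                        last = c(100, 200))  # overlap
  expect_error(titinIsoformModel(totalResidues = 200, regions = regions,
                                 epitopes = data.frame(name = character(),
                                                       first = integer(),
                                                       last = integer())),
               "contiguous")
  regions2 <- data.frame(label = c("a", "b"), first = c(1, 101),
                         last = c(100, 200))
  expect_error(titinIsoformModel(totalResidues = 200, regions = regions2,
                                 epitopes = data.frame(name = "e", first = 95,
                                                       last = 110)),
               "exactly one region")
  expect_error(titinIsoformModel(totalResidues = 200, regions = regions2,
                                 epitopes = data.frame(name = character(),
                                                       first = integer(),
                                                       last = integer()),
                                 sequence = "ACD"),
               "sequence length")
})

test_that("approximate truncated-mass prediction follows the arithmetic oracle", {
  m <- titinIsoformModel()
  expect_equal(predictTruncatedMass(m, 10000), (10000 * 111.1 + 18.02) / 1000,
               tolerance = 1e-12)
  expect_equal(predictTruncatedMass(m, 10000), 1111.018, tolerance = 1e-6)
  # strictly increasing in the truncation position
  pos <- sort(sample.int(35991, 200))
  masses <- predictTruncatedMass(m, pos)
  expect_true(all(diff(masses) > 0))
  expect_error(predictTruncatedMass(m, 0), "positive integer")
})

test_that("sequence-based mass prediction agrees with per-residue oracles", {
  seq <- randomProteinSequence(2000, seed = 11)
  regions <- data.frame(label = "all", first = 1, last = 2000)
  m <- titinIsoformModel(totalResidues = 2000, regions = regions,
                         epitopes = data.frame(name = character(),
                                               first = integer(),
                                               last = integer()),
                         sequence = seq)
  # full-length mass equals the mass-table sum over the whole sequence
  expect_equal(predictTruncatedMass(m, 2000),
               (sum(residueMasses(seq)) + 18.02) / 1000, tolerance = 1e-12)
  # mass difference between r and r+100 equals the inserted residues' sum
  r <- 700
  ins <- substr(seq, r + 1, r + 100)
  expect_equal(predictTruncatedMass(m, r + 100) - predictTruncatedMass(m, r),
               sum(residueMasses(ins)) / 1000, tolerance = 1e-12)
  # sequence mode and approximate mode agree within 2% on natural-composition
  # subsequences (sizes where composition sampling noise is < ~1%)
  for (r in c(1000, 2000)) {
    approx <- predictTruncatedMass(titinIsoformModel(2000, regions,
      data.frame(name = character(), first = integer(), last = integer())), r)
    expect_lt(abs(predictTruncatedMass(m, r) - approx) / approx, 0.02)
  }
})

test_that("sequence masses cross-check against an independent implementation", {
  skip_if_not_installed("seqinr")
  seq <- randomProteinSequence(500, seed = 5)
  ours <- sum(residueMasses(seq)) + 18.02
  ref <- seqinr::pmw(strsplit(seq, "")[[1]])
  expect_lt(abs(ours - ref) / ref, 0.005)
})

test_that("consequence classification follows the pattern rules", {
  expect_identical(as.character(classifyConsequence("p.Arg17000Ter")),
                   "nonsense")
  expect_identical(as.character(classifyConsequence("p.Gly20000ValfsTer12")),
                   "frameshift")
  expect_identical(as.character(classifyConsequence("p.Trp123*")), "nonsense")
  expect_identical(as.character(classifyConsequence("c.1903+1G>A splice donor")),
                   "splice")
  expect_identical(as.character(classifyConsequence("p.Ala100Val")), "other")
  expect_error(classifyConsequence(""), "empty")
})

test_that("FASTA sequences round into the model", {
  seq <- randomProteinSequence(120, seed = 3)
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">titin_test", substring(seq, c(1, 61), c(60, 120))), path)
  expect_identical(readFastaSequence(path), seq)
})
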