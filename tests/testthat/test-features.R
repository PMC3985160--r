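asSorted <- function(x) x[order(names(x))]

test_that("2-gram counting reproduces the worked residue example", {
  got <- countNgrams("VAAGTVAGT", 2)
  expect_identical(got$seqLength, 9L)
  expect_identical(asSorted(got$counts),
                   asSorted(c(VA = 2L, AA = 1L, AG = 2L, GT = 2L, TV = 1L)))
})

test_that("exchange translation and its 2-grams match the worked example", {
  ex <- toExchangeString("VAAGTVAGT")
  expect_identical(ex, "EDDDDEDDD")
  expect_identical(asSorted(countNgrams(ex, 2)$counts),
                   asSorted(c(DE = 1L, ED = 2L, DD = 5L)))
})

test_that("exchange groups partition the 20-letter alphabet", {
  members <- unlist(EXCHANGE_GROUPS, use.names = FALSE)
  expect_setequal(members, AMINO_ACIDS)
  expect_identical(anyDuplicated(members), 0L)
  # every residue maps to exactly one group label
  expect_identical(sort(names(EXCHANGE_MAP)), sort(AMINO_ACIDS))
  expect_true(all(EXCHANGE_MAP %in% names(EXCHANGE_GROUPS)))
  expect_identical(toExchangeString("HRK"), "AAA")
  expect_identical(toExchangeString("C"), "C")
})

test_that("n-gram counts sum to l - n + 1 and keys have length n", {
  set.seed(5)
  for (i in 1:20) {
    l <- sample(2:60, 1)
    n <- sample(1:3, 1)
    s <- paste(sample(AMINO_ACIDS, l, replace = TRUE), collapse = "")
    got <- countNgrams(s, n)
    if (l >= n) {
      expect_identical(sum(got$counts), l - n + 1L)
      expect_true(all(nchar(names(got$counts)) == n))
      expect_true(all(got$counts > 0L))
    } else {
      expect_length(got$counts, 0L)
    }
  }
  expect_length(countNgrams("A", 2)$counts, 0L)
})

test_that("normalisation divides by l - n + 1 and sums to one", {
  norm <- normalizeCounts(countNgrams("VAAGTVAGT", 2))
  expect_equal(norm[["GT"]], 0.25)
  norm2 <- normalizeCounts(countNgrams("EDDDDEDDD", 2))
  expect_equal(norm2[["DD"]], 0.625)
  expect_equal(sum(norm), 1, tolerance = 1e-12)
  expect_equal(sum(norm2), 1, tolerance = 1e-12)
  # l = n: the single gram maps to 1
  expect_equal(unname(normalizeCounts(countNgrams("VA", 2))), 1)
  expect_error(normalizeCounts(countNgrams("A", 2)), "shorter")
})

test_that("the 56-dimensional feature vector matches the worked example", {
  v <- buildFeatureVector("VAAGTVAGT")
  expect_identical(dim(v), c(1L, 56L))
  expect_identical(colnames(v), featureNames())
  expect_equal(unname(v[1, "e2_DD"]), 0.625)
  expect_equal(unname(v[1, "e2_ED"]), 0.25)
  expect_equal(unname(v[1, "e2_DE"]), 0.125)
  othersE2 <- setdiff(grep("^e2_", colnames(v), value = TRUE),
                      c("e2_DD", "e2_ED", "e2_DE"))
  expect_true(all(v[1, othersE2] == 0))
  expect_equal(unname(v[1, "a1_A"]), 3 / 9)
  expect_equal(unname(v[1, "a1_G"]), 2 / 9)
  expect_equal(unname(v[1, "a1_T"]), 2 / 9)
  expect_equal(unname(v[1, "a1_V"]), 2 / 9)
  expect_equal(sum(v[1, grep("^e2_", colnames(v))]), 1, tolerance = 1e-12)
  expect_equal(sum(v[1, grep("^a1_", colnames(v))]), 1, tolerance = 1e-12)
})

test_that("feature layout is stable and block sums hold on random input", {
  set.seed(9)
  seqs <- vapply(1:10, function(i)
    paste(sample(AMINO_ACIDS, sample(5:50, 1), replace = TRUE),
          collapse = ""), character(1))
  m <- buildFeatureVector(seqs)
  expect_identical(dim(m), c(10L, 56L))
  expect_identical(colnames(m), featureNames())
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(rowSums(m[, 1:36])), rep(1, 10), tolerance = 1e-12)
  expect_equal(unname(rowSums(m[, 37:56])), rep(1, 10), tolerance = 1e-12)
  # same gram occupies the same slot across calls
  expect_identical(buildFeatureVector(seqs[3]), m[3, , drop = FALSE],
                   ignore_attr = FALSE)
  expect_error(buildFeatureVector("V"), "length")
})

test_that("FASTA round trip keeps ids and uppercases residues", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "VAAGTVAGT",
               ">s2", "vaagt", "vagt"), tf)
  recs <- readProteinFasta(tf)
  expect_identical(names(recs), c("s1", "s2"))
  expect_identical(as.character(recs[["s1"]]), "VAAGTVAGT")
  expect_identical(as.character(recs[["s2"]]), "VAAGTVAGT")
  expect_error(readProteinFasta(tempfile()), "not found")
})

test_that("sequence validation enforces the alphabet policy", {
  x <- Biostrings::AAStringSet(c(ok = "VAAGTVAGT", bad = "VAXGT"))
  expect_error(validateSequences(x, "strict"), "position 3")
  expect_warning(out <- validateSequences(x, "drop"), "dropped")
  expect_identical(as.character(out[["bad"]]), "VAGT")
  expect_identical(as.character(out[["ok"]]), "VAAGTVAGT")
  expect_silent(validateSequences(Biostrings::AAStringSet("VAAGTVAGT")))
})

test_that("the [-1,1] scaler uses training statistics only", {
  x <- cbind(c(0, 0.25, 0.5), c(1, 1, 1), c(-2, 0, 2))
  sc <- fitScaler(x)
  z <- applyScaler(sc, x)
  expect_equal(z[2, 1], 0)          # midpoint of [0, 0.5]
  expect_true(all(z[, 2] == 0))     # constant dimension
  expect_true(all(z >= -1 & z <= 1))
  # test data outside the training range may exceed [-1, 1]
  z2 <- applyScaler(sc, cbind(1, 1, 4))
  expect_gt(z2[1, 1], 1)
  expect_error(applyScaler(sc, matrix(0, 1, 2)), "columns")
})
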