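eng <- archiphonemeTable("English")
ger <- archiphonemeTable("German")
fre <- archiphonemeTable("French")

test_that("raw codes parse into the CVC/CVV frame with the special symbols", {
  expect_identical(parseCoding("#", "t1", eng)@kind, "silent")
  expect_identical(parseCoding("xxx", "t2", eng)@kind, "untranscribable")

  r <- parseCoding("b,A", "t3", eng)
  expect_identical(r@kind, "coded")
  expect_identical(r@c1, "b")
  expect_identical(r@v1, "A")
  expect_identical(r@v2, "")

  # CVV and CVC frames
  cvv <- parseCoding("d,a,u:", "t4", ger)
  expect_identical(c(cvv@c1, cvv@v1, cvv@v2), c("d", "a", "u:"))
  cvc <- parseCoding("h,@,l", "t5", eng)
  expect_identical(c(cvc@c1, cvc@v1, cvc@c2), c("h", "@", "l"))

  # a 4-element idiom keeps only its first three elements
  idiom <- parseCoding("h,@,l,@U", "t6", eng)
  expect_identical(c(idiom@c1, idiom@v1, idiom@c2), c("h", "@", "l"))
  expect_identical(idiom@v2, "")

  expect_error(parseCoding("b,qq", "t7", eng), "position 2")
  expect_error(parseCoding(",,,", "t8", eng), "position 1")
})

test_that("consolidation reproduces the published table rows", {
  expect_identical(consolidatePhoneme("p", eng), "|pb|")
  expect_identical(consolidatePhoneme("b", eng), "|pb|")
  expect_identical(consolidatePhoneme("C", ger), "|kg|")
  expect_identical(consolidatePhoneme("x", ger), "|kg|")
  expect_identical(consolidatePhoneme("J", fre), "|J|")
  expect_identical(consolidatePhoneme("pf", ger), "|fv|")
  expect_identical(consolidatePhoneme("w", eng), "|w|")
  expect_identical(consolidatePhoneme("{", eng), "|A|")
  expect_identical(consolidatePhoneme("ja", ger), "|A|")
  expect_error(consolidatePhoneme("zz", eng), "zz.*English")

  rec <- parseCoding("b,A", "t1", eng)
  lab <- consolidate(rec, eng)
  expect_identical(unname(lab), c("|pb|", "|A|", "#", "#"))
})

test_that("every phoneme in the shipped tables maps to exactly one archiphoneme", {
  for (tab in list(eng, ger, fre)) {
    expect_false(anyDuplicated(names(tab@mapping)) > 0)
    for (ph in names(tab@mapping)) {
      expect_silent(consolidatePhoneme(ph, tab))
    }
    # the five vowel categories are present in every language
    expect_true(all(vowelArchiphonemes() %in% tab@mapping))
  }
})

test_that("pairwise comparison counts same and different labels correctly", {
  a <- data.frame(tokenId = c("t1", "t2", "t3"),
                  V1 = c("|A|", "|ie|", "|O|"))
  b <- data.frame(tokenId = c("t1", "t2", "t3"),
                  V1 = c("|A|", "|ie|", "|&|"))
  cmp <- compareDatasets(a, b, "V1")
  expect_equal(cmp@totalSame, 2)
  expect_equal(cmp@totalDifferent, 1)
  expect_equal(unname(cmp@sameCounts[c("|A|", "|ie|")]), c(1, 1))
  expect_equal(unname(cmp@diffCounts[["|&|||O|"]] %||%
                        cmp@diffCounts[[grep("O", names(cmp@diffCounts))]]), 1)

  # self-comparison
  self <- compareDatasets(a, a, "V1")
  expect_equal(self@totalDifferent, 0)
  expect_equal(self@totalSame, 3)

  # unordered pair symmetry
  x <- data.frame(tokenId = c("t1", "t2"), V1 = c("|A|", "|&|"))
  y <- data.frame(tokenId = c("t1", "t2"), V1 = c("|&|", "|A|"))
  sym <- compareDatasets(x, y, "V1")
  expect_length(sym@diffCounts, 1)
  expect_equal(unname(sym@diffCounts[1]), 2)

  # missing labels are skipped, disjoint ids error
  a2 <- a; a2$V1[2] <- NA
  expect_equal(compareDatasets(a2, b, "V1")@skipped, 1)
  z <- data.frame(tokenId = c("x1"), V1 = "|A|")
  expect_error(compareDatasets(a, z, "V1"), "no token ids")
})

test_that("group summation is linear in its inputs", {
  a <- data.frame(tokenId = paste0("t", 1:4),
                  V1 = c("|A|", "|ie|", "|O|", "|A|"))
  b <- data.frame(tokenId = paste0("t", 1:4),
                  V1 = c("|A|", "|&|", "|O|", "|ie|"))
  one <- compareDatasets(a, b, "V1")
  expect_equal(sumGroupComparisons(list(one))@sameCounts, one@sameCounts)
  two <- sumGroupComparisons(list(one, one))
  expect_equal(two@totalSame, 2 * one@totalSame)
  expect_equal(two@totalDifferent, 2 * one@totalDifferent)
  expect_equal(two@sameCounts, one@sameCounts * 2)

  c2 <- compareDatasets(a, a, "V1")
  three <- sumGroupComparisons(list(one, one, c2))
  expect_equal(three@totalSame, 2 * one@totalSame + 4)
})

test_that("the two-proportion z-test matches its worked example", {
  eq <- twoProportionZTest(30, 100, 30, 100)
  expect_equal(zStatistic(eq), 0)
  expect_length(significantAt(eq), 0)

  tt <- twoProportionZTest(40, 100, 60, 100)
  expect_equal(zStatistic(tt), -2.82843, tolerance = 1e-5)
  expect_setequal(significantAt(tt), c(0.05, 0.01))

  swapped <- twoProportionZTest(60, 100, 40, 100)
  expect_equal(zStatistic(swapped), -zStatistic(tt))
  expect_identical(significantAt(swapped), significantAt(tt))

  expect_error(twoProportionZTest(5, 0, 1, 10), "positive")
  expect_warning(twoProportionZTest(1, 20, 0, 20), "large-sample")
})

test_that("the z statistic agrees with the chi-square route", {
  set.seed(14)
  for (i in 1:25) {
    n1 <- sample(30:200, 1); n2 <- sample(30:200, 1)
    x1 <- rbinom(1, n1, 0.5); x2 <- rbinom(1, n2, 0.5)
    if (min(x1, n1 - x1, x2, n2 - x2) < 6) next
    z <- zStatistic(twoProportionZTest(x1, n1, x2, n2))
    pt <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                            correct = FALSE))
    expect_equal(z^2, unname(pt$statistic), tolerance = 1e-10)
  }
})

test_that("proportion confidence intervals follow the normal approximation", {
  ci <- proportionCI(50, 100)
  expect_equal(unname(ci["lower"]), 0.40200, tolerance = 1e-4)
  expect_equal(unname(ci["upper"]), 0.59800, tolerance = 1e-4)
  expect_equal(unname(proportionCI(0, 50)["lower"]), 0)
  wide <- proportionCI(10, 25); narrow <- proportionCI(40, 100)
  expect_gt(wide["upper"] - wide["lower"], narrow["upper"] - narrow["lower"])
  expect_error(proportionCI(1, 0), "positive")
})

test_that("comparison conservation holds on random synthetic datasets", {
  set.seed(17)
  for (i in 1:10) {
    pair <- generateTranscriptionDataset(60, runif(1), eng, seed = i)
    cmp <- compareDatasets(pair$a, pair$b, "V1")
    expect_equal(cmp@totalSame, sum(cmp@sameCounts))
    expect_equal(cmp@totalSame + cmp@totalDifferent + cmp@skipped, 60)
  }
})
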