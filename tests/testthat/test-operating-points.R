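# Brute-force operating-point oracle over every threshold of the curve.
brute_points <- function(scores, y) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  data.frame(
    sens = vapply(cuts, function(ct) mean(scores[y] >= ct), 0),
    spec = vapply(cuts, function(ct) mean(scores[!y] < ct), 0)
  )
}

test_that("achieved sensitivity is the smallest attainable count fraction
           at or above the floor", {
  # with 54 positives a 0.90 floor is achievable only at m/54; smallest is 49
  set.seed(15)
  scores <- rnorm(200)
  y <- rep(c(TRUE, FALSE), c(54, 146))
  pt <- point_at_sensitivity(roc_curve(scores, y), 0.90)
  expect_equal(pt$sensitivity, 49 / 54)
  expect_equal(round(100 * pt$sensitivity, 1), 90.7)
  # and with 48 positives the smallest is 44
  y2 <- rep(c(TRUE, FALSE), c(48, 152))
  pt2 <- point_at_sensitivity(roc_curve(scores, y2), 0.90)
  expect_equal(pt2$sensitivity, 44 / 48)
  expect_equal(round(100 * pt2$sensitivity, 1), 91.7)
})

test_that("operating points match brute-force enumeration on small instances", {
  set.seed(16)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    s <- round(runif(n, 0, 4), 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    roc <- roc_curve(s, y)
    bp <- brute_points(s, y)
    for (target in c(0.5, 0.8, 1)) {
      pt <- point_at_sensitivity(roc, target)
      ok <- bp$sens >= target
      expect_equal(pt$sensitivity, min(bp$sens[ok]))
      expect_gte(pt$sensitivity, target)
      expect_equal(pt$specificity,
                   max(bp$spec[ok & bp$sens == min(bp$sens[ok])]))
    }
    yj <- youden_point(roc)
    expect_equal(yj$sensitivity + yj$specificity - 1,
                 max(bp$sens + bp$spec - 1))
  }
})

test_that("specificity floors mirror sensitivity floors", {
  set.seed(17)
  s <- rnorm(300); y <- rep(c(TRUE, FALSE), c(60, 240))
  roc <- roc_curve(s, y)
  pt <- point_at_specificity(roc, 0.9)
  # smallest k/240 >= 0.9 is 216/240 = 0.9 exactly
  expect_equal(pt$specificity, 216 / 240)
  full <- point_at_specificity(roc, 1)
  expect_equal(full$specificity, 1)
  expect_equal(full$sensitivity, mean(s[y] >= max(s[!y]) |
                                        s[y] > max(s[!y])))
  perfect <- roc_curve(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(point_at_specificity(perfect, 0.9)$sensitivity, 1)
  expect_error(point_at_sensitivity(roc, 1.2), "target")
})

test_that("sensitivity floor of 1 includes every case", {
  s <- c(3, 5, 1, 4); y <- c(TRUE, TRUE, FALSE, FALSE)
  pt <- point_at_sensitivity(roc_curve(s, y), 1)
  expect_equal(pt$sensitivity, 1)
  # threshold sits below the minimum case score (between 1 and 3)
  expect_lt(pt$threshold, 3)
  expect_equal(pt$specificity, 0.5)   # one control (score 1) below it
})

test_that("Youden point maximizes J with ties toward sensitivity", {
  perfect <- roc_curve(c(9, 8, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(youden_point(perfect)$sensitivity +
                 youden_point(perfect)$specificity - 1, 1)
  set.seed(18)
  noise <- roc_curve(rnorm(2000), rbinom(2000, 1, 0.5) == 1)
  jn <- youden_point(noise)
  expect_lt(jn$sensitivity + jn$specificity - 1, 0.12)
  # cases {3, 5}, controls {1, 4}: J = 0.5 twice, tie resolved to sens 1
  tie <- youden_point(roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(tie$sensitivity, 1)
  expect_equal(tie$specificity, 0.5)
})

test_that("specificity at the high-sensitivity point decreases with the floor", {
  set.seed(19)
  s <- rnorm(400, ifelse(rep(c(TRUE, FALSE), each = 200), 0.8, 0))
  y <- rep(c(TRUE, FALSE), each = 200)
  roc <- roc_curve(s, y)
  specs <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95, 1),
                  function(t) point_at_sensitivity(roc, t)$specificity, 0)
  expect_true(all(diff(specs) <= 0))
})

test_that("three-level table covers marker x level with per-marker orientation", {
  coh <- generate_cohort(generator_config(seed = 606))
  s1 <- stratify(coh, c(2, 10))
  tab <- three_level_table(marker_scores(s1), s1$diagnosis)
  expect_equal(nrow(tab), 15)
  expect_setequal(unique(tab$level),
                  c("high_sensitivity", "balanced", "high_specificity"))
  hs <- tab[tab$level == "high_sensitivity", ]
  expect_true(all(hs$sensitivity == 49 / 54))
  # the combined score buys specificity over tPSA at matched sensitivity
  expect_gt(hs$specificity[hs$marker == "pcp"],
            hs$specificity[hs$marker == "tpsa"])

  perfect <- data.frame(m = c(9, 8, 1, 2))
  ptab <- three_level_table(perfect, c("PCa", "PCa", "BPH", "BPH"))
  expect_true(all(ptab$sensitivity == 1 & ptab$specificity == 1))
  empty <- three_level_table(data.frame(), c("PCa", "BPH"))
  expect_equal(nrow(empty), 0)
})

test_that("lower-is-positive markers are thresholded downward", {
  # %fPSA-like: cases low, controls high
  s <- c(0.10, 0.12, 0.25, 0.30); y <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- roc_curve(s, y, orientation = "lower")
  pt <- point_at_sensitivity(roc, 0.9)
  expect_equal(pt$sensitivity, 1)
  expect_equal(pt$specificity, 1)
  # reported threshold is on the original scale: calls are s <= threshold
  expect_true(pt$threshold > 0.12 && pt$threshold < 0.25)
})
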