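test_that("size factors follow the median-of-ratios rule", {
  # symmetric case: identical columns
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1, 1))
  # hand-computed worked example
  m <- matrix(c(100, 50, 10, 200, 100, 20), ncol = 2)
  expect_equal(unname(size_factors(m)), c(0.7071, 1.4142), tolerance = 1e-4)
  # scale equivariance: doubling one column doubles its factor relative to
  # the others (size factors are defined up to a common scale because the
  # geometric-mean reference absorbs 2^(1/m))
  sf1 <- size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  sf2 <- size_factors(m2)
  expect_equal(sf2[2] / sf2[1], 2 * sf1[2] / sf1[1])
  # no strain positive everywhere -> advisory error
  expect_error(size_factors(matrix(c(0, 5, 5, 0), 2)),
               class = "barfit_validation_error")
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(10)
  # odd strain count: the median is an order statistic, so the arithmetic
  # median of ratios and DESeq2's exp(median(log ratio)) coincide exactly
  m <- matrix(rnbinom(201 * 6, mu = 300, size = 5), ncol = 6) + 1L
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("dispersion estimates are near zero for Poisson counts", {
  set.seed(20)
  m <- matrix(rpois(1000 * 4, lambda = 500), ncol = 4,
              dimnames = list(sprintf("g%04d", 1:1000), letters[1:4]))
  sf <- size_factors(m)
  d <- estimate_dispersion(m, sf, groups = list(1:2, 3:4))
  expect_lte(mean(d$alpha), 0.05)
  expect_true(all(d$alpha >= 0))
  expect_true(all(d$alpha >= d$alpha_raw - 1e-12))  # final = max(raw, trend)
})

test_that("zero within-group variance falls back to the trend value", {
  m <- matrix(rep(c(100, 200, 400), each = 4), ncol = 4, byrow = TRUE)
  rownames(m) <- c("a", "b", "c")
  d <- estimate_dispersion(m, rep(1, 4), groups = list(1:2, 3:4))
  expect_true(all(d$alpha_raw == 0))
  trend_at <- pmax(0, d$trend["a0"] + d$trend["a1"] / d$mu)
  expect_equal(unname(d$alpha), unname(trend_at))
})

test_that("dispersion recovery from negative-binomial counts", {
  set.seed(21)
  m <- matrix(rnbinom(1000 * 4, mu = 500, size = 10), ncol = 4,
              dimnames = list(sprintf("g%04d", 1:1000), letters[1:4]))
  sf <- size_factors(m)
  d <- estimate_dispersion(m, sf, groups = list(1:2, 3:4))
  expect_gt(median(d$alpha), 0.05)
  expect_lt(median(d$alpha), 0.2)
})

test_that("single-replicate groups are rejected", {
  m <- matrix(rpois(30, 100), ncol = 3)
  expect_error(estimate_dispersion(m, rep(1, 3), groups = list(1, 2:3)),
               class = "barfit_validation_error")
})

test_that("identical groups test to zero fold change and p near 1", {
  m <- matrix(rep(c(100, 250, 700), 4), ncol = 4,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  sf <- size_factors(m)
  d <- estimate_dispersion(m, sf, groups = list(1:2, 3:4))
  res <- test_contrast(m, sf, d, paste0("s", 1:2), paste0("s", 3:4))
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$p >= 0.99))
  expect_true(all(classify_calls(res)$call == "NS"))
})

test_that("swapping groups negates log2fc and preserves p", {
  set.seed(30)
  m <- matrix(rnbinom(200 * 4, mu = 400, size = 20), ncol = 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  sf <- size_factors(m)
  d <- estimate_dispersion(m, sf, groups = list(1:2, 3:4))
  ab <- test_contrast(m, sf, d, paste0("s", 1:2), paste0("s", 3:4))
  ba <- test_contrast(m, sf, d, paste0("s", 3:4), paste0("s", 1:2))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
})

test_that("scaling one sample's counts is absorbed by the size factor", {
  set.seed(31)
  m <- matrix(rnbinom(200 * 4, mu = 400, size = 20), ncol = 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  run <- function(mm) {
    sf <- size_factors(mm)
    d <- estimate_dispersion(mm, sf, groups = list(1:2, 3:4))
    test_contrast(mm, sf, d, paste0("s", 1:2), paste0("s", 3:4))
  }
  r1 <- run(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 5L
  r2 <- run(m2)
  # absorption is exact up to the fold-change pseudocount and the moment
  # re-estimation of dispersion on the rescaled normalised counts
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 2e-3)
  expect_equal(r1$p, r2$p, tolerance = 2e-2)
  expect_equal(cor(r1$p, r2$p) > 0.999, TRUE)
})

test_that("all-zero strains are reported NS with p = 1", {
  m <- rbind(a = c(100, 110, 300, 290), b = c(0, 0, 0, 0),
             c = c(50, 60, 55, 52))
  colnames(m) <- paste0("s", 1:4)
  sf <- size_factors(m + 1L)  # sf computed on a shifted copy: b is all-zero
  d <- list(alpha = setNames(rep(0.01, 3), rownames(m)))
  res <- test_contrast(m, setNames(rep(1, 4), colnames(m)),
                       d$alpha, paste0("s", 1:2), paste0("s", 3:4))
  expect_equal(res$p[res$strain_id == "b"], 1)
  expect_equal(res$log2fc[res$strain_id == "b"], 0)
  expect_equal(classify_calls(res)$call[res$strain_id == "b"], "NS")
})

test_that("HP/HI calls apply the p and fold thresholds jointly", {
  res <- data.frame(
    strain_id = c("a", "b", "c", "d"),
    baseMean = 100, log2fc = c(1.0, 0.5, -2.0, -0.7),
    se = 0.1, p = c(0.001, 0.001, 0.20, 0.01),
    padj = NA_real_, call = "NS", stringsAsFactors = FALSE)
  got <- classify_calls(res)
  expect_equal(got$call, c("HP", "NS", "NS", "HI"))
  # the strict log2 threshold variant used for intersection counts
  got2 <- classify_calls(res, theta = 1.5)
  expect_equal(got2$call, c("NS", "NS", "NS", "NS"))
  expect_error(classify_calls(res, fold = 0.9),
               class = "barfit_parameter_error")
})

test_that("padj is BH-adjusted and bounds p from above", {
  set.seed(33)
  m <- matrix(rnbinom(100 * 4, mu = 200, size = 5), ncol = 4,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  sf <- size_factors(m)
  d <- estimate_dispersion(m, sf, groups = list(1:2, 3:4))
  res <- test_contrast(m, sf, d, paste0("s", 1:2), paste0("s", 3:4))
  expect_true(all(res$padj >= res$p - 1e-12))
  expect_true(all(res$padj <= 1))
  expect_equal(res$padj, stats::p.adjust(res$p, "BH"))
})

test_that("call-set intersections match brute-force subset enumeration", {
  # disjoint sets
  got <- intersect_calls(list(A = c("s1", "s2", "s3"),
                              B = c("s4", "s5", "s6", "s7")))
  expect_equal(got$count[got$conditions == "A"], 3L)
  expect_equal(got$count[got$conditions == "B"], 4L)
  expect_equal(got$count[got$conditions == "A+B"], 0L)
  # identical sets
  got <- intersect_calls(list(A = paste0("s", 1:5), B = paste0("s", 1:5)))
  expect_equal(got$count[got$conditions == "A+B"], 5L)
  expect_equal(got$count[got$conditions == "A"], 0L)
  # random sets vs power-set oracle
  set.seed(40)
  conds <- LETTERS[1:4]
  sets <- lapply(conds, function(x) sample(paste0("s", 1:30), sample(5:20, 1)))
  names(sets) <- conds
  got <- intersect_calls(sets)
  strains <- unique(unlist(sets))
  for (i in seq_len(nrow(got))) {
    sub <- strsplit(got$conditions[i], "+", fixed = TRUE)[[1]]
    want <- sum(vapply(strains, function(s) {
      inset <- vapply(sets, function(ss) s %in% ss, TRUE)
      setequal(conds[inset], sub)
    }, TRUE))
    expect_equal(got$count[i], want)
  }
  expect_error(intersect_calls(list(A = "s1")),
               class = "barfit_parameter_error")
})
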