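# Histogram machinery, extraction models, CVOH, and the 121-feature MP
# vector.

test_that("ROI pixel pooling is additive across sides", {
  sp <- fixture_specimen(t = 10, seed = 41)
  masks <- sp$roi_truth
  n_a <- sum(masks$A); n_b <- sum(masks$B)
  pooled <- pool_roi_pixels(sp, masks)
  expect_equal(nrow(pooled), n_a + n_b)
  # one side empty: pooled equals the other side
  only_a <- pool_roi_pixels(sp, list(A = masks$A, B = masks$B & FALSE))
  expect_equal(nrow(only_a), n_a)
  # identical sides: pooled mean equals single-side mean
  same <- list(images = list(A = sp$images$A, B = sp$images$A),
               roi_truth = masks)
  both <- pool_roi_pixels(same, list(A = masks$A, B = masks$A))
  expect_equal(colMeans(both), colMeans(both[seq_len(n_a), ]))
  expect_error(pool_roi_pixels(sp, list(A = masks$A & FALSE, B = masks$B & FALSE)),
               class = "gummix_error_feature")
})

test_that("histograms cover the fixed channel range with exact counts", {
  h <- channel_histogram(0:255, "R")
  expect_equal(h$counts, rep(1L, 256))
  expect_equal(sum(h$p), 1, tolerance = 1e-9)
  hc <- channel_histogram(rep(42, 1000), "R")
  expect_equal(max(hc$counts), 1000)
  expect_equal(sum(hc$counts > 0), 1)
  # seeded uniform sample: bins fluctuate within the binomial bound
  set.seed(2)
  n <- 1e5
  hu <- channel_histogram(runif(n), "S")
  expect_lt(max(abs(hu$counts - n / 256)), 5 * sqrt(n / 256))
  expect_error(channel_histogram(numeric(), "R"), class = "gummix_error_feature")
})

test_that("entropy, energy and peak counts match closed forms", {
  uniform <- channel_histogram(rep(0:255, 10), "R")
  expect_equal(extract_feature("Eh", hist = uniform), 8, tolerance = 1e-9)
  expect_equal(extract_feature("Gh", hist = uniform), 1 / 256, tolerance = 1e-12)
  single <- channel_histogram(rep(100, 500), "R")
  expect_equal(extract_feature("Eh", hist = single), 0)
  expect_equal(extract_feature("Gh", hist = single), 1)
  expect_equal(extract_feature("Nh", hist = single), 1)
  expect_equal(extract_feature("V1", hist = single), 500)
  # sentinels with fewer than two peaks
  expect_equal(extract_feature("V2", hist = single), 0)
  expect_equal(extract_feature("P2", hist = single), -1)
  expect_error(extract_feature("Xx", hist = single), class = "gummix_error_registry")
})

test_that("a seeded bimodal histogram yields two comparable peaks", {
  set.seed(7)
  vals <- c(rnorm(5000, 64, 6), rnorm(5000, 192, 6))
  h <- channel_histogram(pmin(pmax(vals, 0), 255), "R")
  expect_equal(extract_feature("Nh", hist = h), 2)
  v1 <- extract_feature("V1", hist = h)
  v2 <- extract_feature("V2", hist = h)
  expect_lt((v1 - v2) / v1, 0.15)
  p2 <- extract_feature("P2", hist = h)
  expect_true(abs(p2 - 64) < 5 || abs(p2 - 192) < 5)
})

test_that("pixel mean/variance models use population statistics", {
  x <- c(1, 2, 3, 4)
  expect_equal(extract_feature("Mp", values = x), 2.5)
  expect_equal(extract_feature("Vp", values = x), mean((x - 2.5)^2))
  h <- channel_histogram(rep(c(0, 255), c(10, 30)), "R")
  expect_equal(extract_feature("Vh", hist = h),
               mean((h$counts - mean(h$counts))^2))
})

test_that("histogram skewness is the count-weighted bin-index skewness", {
  # mass at bins 0 and 255 with unequal weights: sign follows the tail
  h_right <- channel_histogram(rep(c(0, 255), c(90, 10)), "R")
  h_left <- channel_histogram(rep(c(0, 255), c(10, 90)), "R")
  expect_gt(extract_feature("Sh", hist = h_right), 0)
  expect_lt(extract_feature("Sh", hist = h_left), 0)
  # brute-force oracle on a small case
  h <- channel_histogram(c(rep(0:9, each = 5), rep(200, 7)), "R")
  p <- h$counts / sum(h$counts)
  i <- 0:255
  mu <- sum(p * i); m2 <- sum(p * (i - mu)^2); m3 <- sum(p * (i - mu)^3)
  expect_equal(extract_feature("Sh", hist = h), m3 / m2^1.5, tolerance = 1e-12)
})

test_that("CVOH matches circular-statistics closed forms", {
  expect_equal(cvoh(rep(1.3, 100)), 0, tolerance = 1e-12)
  expect_equal(cvoh(rep(c(0, pi), 50)), 1, tolerance = 1e-12)
  # von Mises kappa = 2: circular variance = 1 - I1(2)/I0(2)
  set.seed(11)
  n <- 1e4
  # sample von Mises by rejection (independent of the implementation)
  vm <- c()
  while (length(vm) < n) {
    x <- runif(n, 0, 2 * pi)
    u <- runif(n)
    keep <- u < exp(2 * (cos(x) - 1))
    vm <- c(vm, x[keep])
  }
  vm <- vm[seq_len(n)]
  expected <- 1 - besselI(2, 1) / besselI(2, 0)
  expect_lt(abs(cvoh(vm) - expected), 0.02)
  expect_error(cvoh(rep(NA_real_, 5)), class = "gummix_error_feature")
})

test_that("the default registry yields a 121-element deterministic vector", {
  reg <- mfc_registry()
  expect_equal(nrow(reg), 121L)
  expect_equal(sum(duplicated(reg$code)), 0L)
  sp <- fixture_specimen(t = 10, seed = 44)
  mp1 <- extract_mp(sp, sp$roi_truth)
  mp2 <- extract_mp(sp, sp$roi_truth)
  expect_length(mp1, 121L)
  expect_identical(mp1, mp2)
  expect_false(anyNA(mp1))
  # bounded invariants
  eh <- mp1[grep("^Eh", names(mp1))]
  expect_true(all(eh >= 0 & eh <= 8))
  gh <- mp1[grep("^Gh", names(mp1))]
  expect_true(all(gh >= 1 / 256 & gh <= 1))
  expect_true(mp1["CVOH"] >= 0 && mp1["CVOH"] <= 1)
  expect_true(all(mp1[grep("^V[ph]", names(mp1))] >= 0))
})

test_that("hue histogram variance separates unmixed from mixed specimens", {
  sp0 <- fixture_specimen(t = 0, seed = 45)
  sp20 <- fixture_specimen(t = 20, seed = 45)
  mp0 <- extract_mp(sp0, sp0$roi_truth)
  mp20 <- extract_mp(sp20, sp20$roi_truth)
  expect_false(isTRUE(all.equal(mp0[["VhH"]], mp20[["VhH"]])))
  expect_gt(mp0[["CVOH"]], mp20[["CVOH"]])
})

test_that("per-cycle means of VhH and CVOH are strictly monotone", {
  cfg <- small_config()
  reg <- mfc_registry()
  reg <- reg[reg$code %in% c("VhH", "CVOH"), ]
  cycles <- c(0, 5, 10, 15, 20)
  acc <- sapply(cycles, function(t) {
    rowMeans(sapply(1:20, function(s) {
      sp <- generate_specimen(t, 0.08, cfg, seed = 1300 + 31 * s + t)
      extract_mp(sp, sp$roi_truth, registry = reg)
    }))
  })
  expect_equal(abs(cor(cycles, acc["VhH", ], method = "spearman")), 1)
  expect_equal(abs(cor(cycles, acc["CVOH", ], method = "spearman")), 1)
})
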