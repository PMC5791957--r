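# Dataset splitting, MCC, stage training, cascade assembly and
# classification.

test_that("stratified split respects the 40/30/30 fractions per class", {
  labs <- rep(c(0, 5, 10, 15, 20), each = 80)
  s <- split_dataset(labs, seed = 3)
  expect_equal(as.vector(table(s)), c(160, 120, 120))
  tab <- table(labs, s)
  expect_true(all(tab[, "TG"] == 32 & tab[, "VG"] == 24 & tab[, "SG"] == 24))
  expect_identical(s, split_dataset(labs, seed = 3))
  expect_false(identical(s, split_dataset(labs, seed = 4)))
  expect_error(split_dataset(rep(c(0, 5), c(50, 5))), class = "gummix_error_input")
})

test_that("MCC matches its closed-form anchor cases", {
  expect_equal(mcc(50, 50, 0, 0), 1)
  expect_equal(mcc(0, 0, 50, 50), -1)
  expect_equal(mcc(25, 25, 25, 25), 0)
  # zero denominator factor -> 0 by convention
  expect_equal(mcc(10, 0, 0, 5), 0)
  expect_error(mcc(0, 0, 0, 0), class = "gummix_error_input")
  expect_error(mcc(-1, 2, 3, 4), class = "gummix_error_input")
  # symmetry under class swap
  expect_equal(mcc(13, 29, 7, 3), mcc(29, 13, 3, 7))
})

test_that("MCC equals the phi correlation of prediction/label vectors", {
  withr::with_seed(21, {
    for (i in 1:1000) {
      cc <- as.list(sample(0:20, 4, replace = TRUE))
      names(cc) <- c("tp", "tn", "fp", "fn")
      total <- sum(unlist(cc))
      if (total == 0) next
      pred <- rep(c(1, 0, 1, 0), unlist(cc))
      truth <- rep(c(1, 0, 0, 1), unlist(cc))
      oracle <- suppressWarnings(cor(pred, truth))
      got <- mcc(cc)
      if (is.na(oracle)) {
        expect_equal(got, 0)
      } else {
        expect_equal(got, oracle, tolerance = 1e-12)
      }
    }
  })
})

test_that("the h sweep covers ceiling(k/3)..k", {
  expect_equal(h_sweep_values <- gummix:::h_sweep_values(35, 100), 12:35)
  reduced <- gummix:::h_sweep_values(35, 10)
  expect_length(reduced, 10)
  expect_equal(min(reduced), 12)
  expect_equal(max(reduced), 35)
})

test_that("the serialized forward pass reproduces nnet predictions", {
  withr::with_seed(31, {
    X <- matrix(rnorm(200), ncol = 4)
    y <- as.integer(X[, 1] + X[, 2] > 0)
    fit <- nnet::nnet(X, y, size = 3, decay = 1e-3, maxit = 100, trace = FALSE)
    w <- gummix:::nnet_to_weights(fit, 4, 3)
    expect_equal(gummix:::mlp_forward(w, X), as.numeric(predict(fit, X)),
                 tolerance = 1e-6)
  })
})

test_that("a separable planted problem trains a suitable perfect stage", {
  dat <- planted_mp_table(n_per_class = 16, m_signal = 4, m_noise = 0,
                          sep = 6, seed = 5)
  split <- split_dataset(dat$t, seed = 5)
  Xs <- scale(dat$mp)
  st <- train_stage(Xs, dat$t, split, target_t = 10,
                    params = cascade_params(sweep_points = 2, restarts = 1),
                    seed = 5)
  expect_s3_class(st, "gum_cascade_stage")
  expect_equal(st$mcc_sg, 1)
  expect_true(st$suitable)
  k <- ncol(Xs)
  expect_gte(st$h, ceiling(k / 3))
  expect_lte(st$h, k)
})

test_that("randomly permuted labels produce an unsuitable stage", {
  dat <- planted_mp_table(n_per_class = 16, m_signal = 4, m_noise = 0,
                          sep = 6, seed = 6)
  t_perm <- withr::with_seed(99, sample(dat$t))
  split <- split_dataset(t_perm, seed = 6)
  st <- train_stage(scale(dat$mp), t_perm, split, target_t = 10,
                    params = cascade_params(sweep_points = 2, restarts = 1),
                    seed = 6)
  expect_lt(st$mcc_sg, 0.5)
  expect_false(st$suitable)
})

test_that("cascade assembly enforces suitability and ascending order", {
  pc <- planted_cascade(seed = 7)
  casc <- pc$fit$cascade
  tt <- vapply(casc$stages, function(s) s$target_t, integer(1))
  expect_equal(tt, sort(tt))
  expect_length(casc$stages, 5L)
  # a sub-threshold stage blocks assembly, naming the class
  bad <- pc$fit$stages
  bad[[2]]$suitable <- FALSE
  bad[[2]]$mcc_sg <- 0.90
  expect_error(assemble_cascade(bad, casc$kept_codes, casc$center, casc$scale),
               regexp = "5", class = "gummix_error_calibration")
  expect_error(assemble_cascade(list(), casc$kept_codes, casc$center, casc$scale),
               class = "gummix_error_calibration")
})

test_that("cascade classification is first-fire, deterministic, typed", {
  pc <- planted_cascade(seed = 7)
  casc <- pc$fit$cascade
  sg <- pc$fit$split == "SG"
  P1 <- classify_mp(pc$dat$mp[sg, ], casc)
  P2 <- classify_mp(pc$dat$mp[sg, ], casc)
  expect_identical(P1, P2)
  expect_gt(mean(P1 == pc$dat$t[sg], na.rm = TRUE), 0.9)
  # missing feature -> typed error
  broken <- pc$dat$mp[sg, setdiff(colnames(pc$dat$mp), "MpR")]
  expect_error(classify_mp(broken, casc), class = "gummix_error_feature_mismatch")
  # all-false stages -> UNCLASSIFIED
  casc0 <- casc
  for (i in seq_along(casc0$stages)) {
    casc0$stages[[i]]$weights$W2 <- c(-50, rep(0, casc0$stages[[i]]$h))
  }
  expect_true(all(is.na(classify_mp(pc$dat$mp[sg, ], casc0))))
  ev0 <- evaluate_cascade(casc0, pc$dat$mp[sg, ], pc$dat$t[sg])
  expect_equal(ev0$n_unclassified, sum(sg))
  expect_null(ev0$pooled)
})

test_that("a perfect cascade scores 1 on every pooled metric", {
  pc <- planted_cascade(seed = 8)
  ev <- pc$fit$evaluation
  # planted classes are widely separated: expect (near-)perfect SG scores
  expect_gte(ev$pooled$mcc, 0.95)
  if (ev$pooled$mcc == 1) {
    expect_equal(ev$pooled$sensitivity, 1)
    expect_equal(ev$pooled$specificity, 1)
    expect_equal(ev$pooled$accuracy, 1)
  }
  expect_error(evaluate_cascade(pc$fit$cascade, pc$dat$mp, numeric()),
               class = "gummix_error_input")
})
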