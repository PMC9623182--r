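test_that("pearson screening flags significance at the alpha = 0.01 line", {
  # identity and antisymmetry
  pnc <- seq(2, 4.5, length.out = 48)
  tab <- pearson_screen(data.frame(same = pnc, neg = -pnc), pnc)
  expect_equal(tab$r, c(1, -1))
  expect_true(all(tab$significant))
  # critical |r| for n = 48 sits near 0.368: r = 0.40 crosses it, 0.35 not
  p40 <- pair_with_cor(48, 0.40, seed = 2)
  p35 <- pair_with_cor(48, 0.35, seed = 3)
  tab2 <- pearson_screen(data.frame(a = p40$x), p40$y)
  tab3 <- pearson_screen(data.frame(a = p35$x), p35$y)
  expect_equal(tab2$r, 0.40, tolerance = 1e-12)
  expect_true(tab2$significant)
  expect_equal(tab3$r, 0.35, tolerance = 1e-12)
  expect_false(tab3$significant)
  # p-value equals the closed-form t transform with df = n - 2
  tstat <- 0.40 * sqrt(46) / sqrt(1 - 0.40^2)
  expect_equal(tab2$p_value, 2 * pt(tstat, df = 46, lower.tail = FALSE),
               tolerance = 1e-12)
  # zero-variance feature flagged, not errored
  tab4 <- pearson_screen(data.frame(flat = rep(1, 48)), p40$y)
  expect_true(is.na(tab4$r)); expect_false(tab4$significant)
})

test_that("top-k index selection orders by |r| with registry tie-breaking", {
  tab <- data.frame(
    feature = c("R", "G", "B", "GRRI", "GLA", "GLI", "GRVI", "VARI", "EXG", "NDI", "H", "CV"),
    r = c(-0.9, 0.2, 0.3, 0.8, 0.7, -0.7, 0.6, 0.5, 0.4, 0.35, 0.99, 0.95))
  # H and CV are never selected despite the largest |r|
  top <- select_top_vis(tab, 5)
  expect_identical(top, c("R", "GRRI", "GLA", "GLI", "GRVI"))
  # tie at |r| = 0.7 for 5th place resolved by registry order (GLA first)
  tab2 <- tab; tab2$r[tab2$feature == "GRVI"] <- 0.1
  expect_identical(select_top_vis(tab2, 5),
                   c("R", "GRRI", "GLA", "GLI", "VARI"))
  expect_identical(length(select_top_vis(tab, 10)), 10L)
  expect_error(select_top_vis(tab[1:3, ], 5), "fewer than")
})

test_that("replication split is the fixed 32/16 partition", {
  design <- generate_design()
  sp <- split_by_replication(design)
  expect_identical(sum(sp$train), 32L)
  expect_identical(sum(sp$validation), 16L)
  expect_true(all(xor(sp$train, sp$validation)))
  only2 <- data.frame(replication = rep(2L, 8))
  expect_error(split_by_replication(only2), "training")
  expect_error(split_by_replication(data.frame(x = 1)), "replication")
})

test_that("MLR reproduces an exact linear law and the normal equations", {
  set.seed(4)
  X <- data.frame(x1 = rnorm(32), x2 = rnorm(32))
  y <- 1.5 + 2 * X$x1 - 3 * X$x2
  m <- fit_model("MLR", X, y)
  expect_lt(max(abs(predict(m, X) - y)), 1e-9)
  expect_equal(unname(coef(m$fit)), c(1.5, 2, -3), tolerance = 1e-9)
  # noisy case against the closed-form normal-equations oracle
  yn <- 2 * X$x1 - X$x2 + rnorm(32, 0, 0.1)
  mn <- fit_model("MLR", X, yn)
  A <- cbind(1, as.matrix(X))
  beta <- solve(t(A) %*% A, t(A) %*% yn)
  expect_equal(unname(coef(mn$fit)), as.numeric(beta), tolerance = 1e-9)
  se <- sqrt(diag(solve(t(A) %*% A)) * sum(residuals(mn$fit)^2) / (32 - 3))
  expect_lt(abs(coef(mn$fit)[["x1"]] - 2), 3 * se[2])
  expect_lt(abs(coef(mn$fit)[["x2"]] + 1), 3 * se[3])
  # degenerate designs error
  expect_error(fit_model("MLR", data.frame(a = X$x1, b = X$x1), y), "singular")
  expect_error(fit_model("MLR", X[1:2, ], y[1:2]), "more training rows")
})

test_that("KNN with k = 1 memorises the training set", {
  set.seed(5)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  y <- rnorm(20)
  m <- fit_model("KNN", X, y, hyper = list(k = 1))
  expect_equal(predict(m, X), y, tolerance = 1e-9)
  expect_error(fit_model("KNN", X, y, hyper = list(k = 21)), "exceeds")
})

test_that("KNN and seeded RF are invariant to training-row order", {
  set.seed(6)
  X <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  y <- X$a - X$b + rnorm(30, 0, 0.2)
  Xnew <- data.frame(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  perm <- sample(30)
  for (me in c("KNN", "RF")) {
    m1 <- fit_model(me, X, y, seed = 77)
    m2 <- fit_model(me, X[perm, ], y[perm], seed = 77)
    expect_equal(predict(m1, Xnew), predict(m2, Xnew), tolerance = 1e-12)
  }
})

test_that("regression metrics reproduce hand arithmetic", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$R2, 0.5)
  expect_equal(m$RMSE, sqrt(1 / 3))
  expect_equal(m$NRMSE, sqrt(1 / 3) / 2 * 100)
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect), c(R2 = 1, RMSE = 0, NRMSE = 0))
  null_model <- regression_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(null_model$R2, 0)
  expect_warning(regression_metrics(c(2, 2), c(1, 2)), "zero variance")
})

test_that("ground-truth summaries use the sample SD and CV%", {
  s <- summarize_ground_truth(c(1, 2, 3))
  expect_equal(unname(s), c(3, 1, 2, 1, 50))
  expect_equal(unname(summarize_ground_truth(rep(5, 4))[c("sd", "cv_pct")]),
               c(0, 0))
})

test_that("the model suite emits both partitions for every cell", {
  set.seed(8)
  n <- 48
  design <- generate_design()
  feats <- data.frame(plot_id = design$records$plot_id,
                      replication = design$records$replication)
  pnc <- rnorm(n, 3, 0.5)
  for (nm in vi_registry()) feats[[nm]] <- pnc * runif(1, 0.5, 2) + rnorm(n, 0, 0.3)
  feats$H <- 10 * pnc + rnorm(n); feats$CC <- pmin(1, pmax(0, 0.2 * pnc))
  feats$CV <- feats$H * feats$CC
  feats$PNC <- pnc
  feats <- do.call(rbind, lapply(c("S1", "S2", "S3"), function(st)
    transform(feats, stage = st)))
  rep_ <- run_model_suite(feats, feature_sets = c("VIs+MPs"))
  expect_identical(nrow(rep_), 3L * 3L * 1L * 2L)
  expect_true(all(rep_$RMSE >= 0) && all(rep_$NRMSE >= 0) && all(rep_$R2 <= 1))
  expect_identical(unique(rep_$n[rep_$partition == "calibration"]), 32L)
  expect_identical(unique(rep_$n[rep_$partition == "validation"]), 16L)
})

test_that("permuting the response destroys validation skill", {
  design <- generate_design()
  r2s <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 48
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- X$a + 0.5 * X$b + rnorm(n, 0, 0.4)
    yperm <- sample(y)
    sp <- split_by_replication(design)
    m <- fit_model("MLR", X[sp$train, ], yperm[sp$train])
    evaluate(m, X[sp$validation, ], yperm[sp$validation])$R2
  }, numeric(1))
  expect_lte(median(r2s), 0.1)
})
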