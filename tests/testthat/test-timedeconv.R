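test_that("an exactly determined one-condition system is solved exactly", {
  vals <- matrix(c(3, 1), 1, 2, dimnames = list("g1", NULL))
  st <- make_study(vals, class = c("defeat", "control"),
                   timepoint = c(1, 1))
  fit <- fit_time_model(st)
  expect_equal(unname(fit$alpha), 2)
  expect_equal(unname(fit$beta[1, 1]), 1)
  expect_equal(unname(fit$residual_ss), 0)
})

test_that("zero-noise generative parameters are recovered exactly", {
  alpha <- rep(1.5, 10)
  beta <- matrix(rep(c(0.2, 0.4, -0.1, 0.3), each = 10), 10, 4)
  tc <- make_timecourse(10, 3, alpha = alpha, beta = beta, sigma = 0)
  fit <- fit_time_model(tc$study)
  expect_equal(unname(fit$alpha), alpha, tolerance = 1e-10)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("unbalanced noisy fits match the normal-equations oracle", {
  set.seed(21)
  n_genes <- 30
  tp <- c(rep(1, 5), rep(2, 7), rep(3, 4), rep(4, 6))
  cls <- c(rep(c("defeat", "control"), c(2, 3)),
           rep(c("defeat", "control"), c(4, 3)),
           rep(c("defeat", "control"), c(2, 2)),
           rep(c("defeat", "control"), c(3, 3)))
  vals <- matrix(rnorm(n_genes * length(tp), 5, 1), n_genes)
  rownames(vals) <- sprintf("g%03d", 1:n_genes)
  st <- make_study(vals, class = cls, timepoint = tp,
                   timepoint_labels = coremod::DEFAULT_TIMEPOINTS)
  fit <- fit_time_model(st)
  # explicit (X'X)^-1 X'y oracle, gene by gene
  X <- cbind(as.numeric(cls == "defeat"),
             sapply(1:4, function(j) as.numeric(tp == j)))
  XtXi <- solve(t(X) %*% X)
  for (i in c(1, 13, 30)) {
    coef <- XtXi %*% t(X) %*% vals[i, ]
    expect_equal(unname(fit$alpha[i]), coef[1, 1], tolerance = 1e-8)
    expect_equal(unname(fit$beta[i, ]), coef[-1, 1], tolerance = 1e-8)
  }
  # residuals orthogonal to every design column
  resid <- st$values - cbind(fit$alpha, fit$beta) %*% t(X)
  expect_lt(max(abs(resid %*% X)), 1e-8)
})

test_that("a condition lacking one class triggers minimum-norm fallback", {
  tc <- make_timecourse(5, 2, sigma = 0.1, seed = 8)
  st <- tc$study
  keep <- !(st$samples$timepoint == 2 & st$samples$class == "defeat")
  st2 <- expression_study(st$values[, keep], st$samples[keep, ],
                          st$timepoint_labels)
  expect_warning(fit <- fit_time_model(st2), "rank-deficient")
  expect_true(all(is.finite(fit$alpha)))
})

test_that("time adjustment zeroes controls and preserves variance", {
  alpha <- seq(-1, 1, length.out = 8)
  beta <- matrix(rnorm(32), 8, 4)
  tc <- make_timecourse(8, 3, alpha = alpha, beta = beta, sigma = 0)
  fit <- fit_time_model(tc$study)
  adj <- adjust_expression(tc$study, fit)
  ctl <- adj$samples$class == "control"
  expect_equal(max(abs(adj$values[, ctl])), 0, tolerance = 1e-10)
  expect_equal(unname(adj$values[, !ctl]),
               matrix(alpha, 8, sum(!ctl)), tolerance = 1e-10)

  # noisy case: per-condition mean of adjusted controls ~ 0 within 3 SE,
  # and refitting on the adjusted matrix gives beta ~ 0
  tcn <- make_timecourse(50, 10, sigma = 0.5, seed = 22)
  fitn <- fit_time_model(tcn$study)
  adjn <- adjust_expression(tcn$study, fitn)
  for (j in 1:4) {
    sel <- adjn$samples$timepoint == j & adjn$samples$class == "control"
    se <- 0.5 / sqrt(sum(sel) * 50)
    expect_lt(abs(mean(adjn$values[, sel])), 3 * se + 1e-12)
  }
  refit <- fit_time_model(adjn)
  expect_lt(max(abs(refit$beta)), 1e-8)

  # within-(class, condition) variance untouched
  sel <- tcn$study$samples$timepoint == 2 &
    tcn$study$samples$class == "defeat"
  expect_equal(apply(adjn$values[, sel], 1, var),
               apply(tcn$study$values[, sel], 1, var), tolerance = 1e-12)

  expect_error(adjust_expression(tc$study, fitn), "do not match")
})

test_that("average time curves are class mean differences per timepoint", {
  # equal class means -> identically zero
  vals <- matrix(rep(c(2, 2, 5, 5), each = 2), 2, 4, byrow = TRUE)
  rownames(vals) <- c("g1", "g2")
  st <- make_study(vals, class = c("defeat", "control", "defeat",
                                   "control"),
                   timepoint = c(1, 1, 2, 2),
                   timepoint_labels = c("T1", "T2"))
  expect_equal(unname(average_time_curve(st)),
               matrix(0, 2, 2))

  # hand computation under the log-difference convention
  vals2 <- matrix(c(5, 5, 3, 3), 1, 4, dimnames = list("g1", NULL))
  st2 <- make_study(vals2, class = c("defeat", "defeat", "control",
                                     "control"),
                    timepoint = rep(1, 4), timepoint_labels = "T1")
  expect_equal(unname(average_time_curve(st2)[1, 1]), 2)

  # doubling linear-scale defeated intensities raises the curve by 1
  st3 <- st2
  st3$values[, 1:2] <- st3$values[, 1:2] + 1  # +1 in log2 = x2 linear
  expect_equal(unname(average_time_curve(st3)[1, 1]), 3)

  # a timepoint missing one class is NA
  st4 <- make_study(matrix(1:4, 1, 4, dimnames = list("g1", NULL)),
                    class = c("defeat", "control", "control", "control"),
                    timepoint = c(1, 1, 2, 2),
                    timepoint_labels = c("T1", "T2"))
  expect_true(is.na(average_time_curve(st4)[1, 2]))
  expect_false(is.na(average_time_curve(st4)[1, 1]))
})

test_that("alpha error shrinks as replication doubles", {
  err <- sapply(c(5, 10, 20), function(n) {
    tc <- make_timecourse(200, n, sigma = 0.5, seed = 23)
    fit <- fit_time_model(tc$study)
    mean(abs(fit$alpha - tc$alpha))
  })
  expect_true(all(diff(err) < 0))
})
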