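test_that("standardize gives unit-variance genes and is idempotent", {
  st <- make_study(matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", NULL)),
                   class = c("defeat", "control", "defeat"))
  z <- standardize(st)
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$values), 1, tolerance = 1e-12)

  set.seed(51)
  st2 <- make_study(c(10, 8))
  z1 <- standardize(st2)
  expect_equal(standardize(z1)$values, z1$values, tolerance = 1e-12)

  cst <- make_study(matrix(4, 2, 5, dimnames = list(c("g1", "g2"), NULL)))
  expect_warning(zc <- standardize(cst), "constant")
  expect_true(all(zc$values == 0))
})

# a fixture with concordant signal so that greedy growth is non-trivial
make_corg_fixture <- function(seed = 52, n_genes = 120, n = 20,
                              n_signal = 30) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
  cls <- rep(c("defeat", "control"), each = n / 2)
  x[1:n_signal, cls == "defeat"] <-
    x[1:n_signal, cls == "defeat"] +
    rep(stats::runif(n_signal, 0.3, 1.5), n / 2)
  st <- make_study(x, class = cls)
  de <- moderated_t_test(st)
  list(st = st, std = standardize(st), de = de)
}

test_that("single-gene pathways return that gene's standardized profile", {
  fx <- make_corg_fixture()
  m <- infer_corg_module(fx$std, fx$de, "g001")
  expect_equal(m$member_genes, "g001")
  expect_equal(unname(m$activity), unname(fx$std$values["g001", ]))
  expect_error(infer_corg_module(fx$std, fx$de, "absent"), "no pathway")
})

test_that("greedy growth matches the brute-force prefix-scan oracle", {
  fx <- make_corg_fixture()
  set.seed(53)
  for (i in 1:25) {
    genes <- sample(rownames(fx$st$values), sample(3:12, 1))
    m <- infer_corg_module(fx$std, fx$de, genes)
    o <- corg_oracle(fx$std, fx$de, genes)
    expect_equal(m$member_genes, o$genes)
    expect_equal(abs(m$activity_t), o$t, tolerance = 1e-9)
    # the final module never scores below its best single ordered gene
    first <- infer_corg_module(fx$std, fx$de, m$member_genes[1])
    expect_gte(abs(m$activity_t) + 1e-12, abs(first$activity_t))
  }
})

test_that("the arithmetic-mean aggregation is used, not sqrt-k scaling", {
  fx <- make_corg_fixture()
  m <- infer_corg_module(fx$std, fx$de, c("g001", "g002", "g003"))
  k <- length(m$member_genes)
  expect_gt(k, 1)  # fixture signal makes growth happen
  expect_equal(unname(m$activity),
               unname(colMeans(fx$std$values[m$member_genes, ,
                                             drop = FALSE])),
               tolerance = 1e-12)
})

test_that("strongly concordant pathways hit the 25-gene module cap", {
  # growth needs every step to strictly improve |t|; with few samples the
  # selection-inflated gap of early genes makes late additions dilutive,
  # so reaching the cap requires a large sample to stabilize the ordering
  set.seed(54)
  n <- 200
  x <- matrix(stats::rnorm(40 * n, 0, 0.25), 40, n,
              dimnames = list(sprintf("g%03d", 1:40), NULL))
  cls <- rep(c("defeat", "control"), each = n / 2)
  x[, cls == "defeat"] <- x[, cls == "defeat"] + 1
  st <- make_study(x, class = cls)
  m <- infer_corg_module(standardize(st), moderated_t_test(st),
                         rownames(x))
  expect_equal(length(m$member_genes), 25L)
})

test_that("candidate ranking returns top_k deduplicated modules in order", {
  fx <- make_corg_fixture()
  paths <- lapply(1:30, function(i) {
    set.seed(100 + i)
    sample(rownames(fx$st$values), 8)
  })
  names(paths) <- sprintf("P%02d", 1:30)
  paths$DUP <- paths$P01  # identical pathway -> identical module
  cands <- infer_candidates(fx$st, paths, top_k = 10, min_size = 3,
                            de = fx$de)
  expect_length(cands, 10)
  tt <- abs(vapply(cands, `[[`, numeric(1), "activity_t"))
  expect_true(all(diff(tt) <= 1e-12))  # sorted non-increasing
  keys <- vapply(cands, function(m)
    paste(sort(m$member_genes), collapse = ","), character(1))
  expect_false(any(duplicated(keys)))

  expect_warning(
    few <- infer_candidates(fx$st, paths[1:3], top_k = 10, min_size = 3,
                            de = fx$de),
    "only")
  expect_lte(length(few), 3)
})

test_that("activities regenerate exactly on the inference tissue", {
  fx <- make_corg_fixture()
  m <- infer_corg_module(fx$std, fx$de,
                         rownames(fx$st$values)[1:6])
  pa <- compute_activity(fx$std, m)
  expect_equal(unname(pa), unname(m$activity), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(pa, "direction"), m$direction)
})

test_that("validation activities degrade gracefully with absent genes", {
  fx <- make_corg_fixture()
  m <- make_module("P", c("g001", "zz_absent"))
  sub <- fx$std
  expect_warning(pa <- compute_activity(sub, m), "absent")
  expect_equal(unname(pa), unname(sub$values["g001", ]),
               ignore_attr = TRUE)
  m2 <- make_module("P", c("zz1", "zz2"))
  expect_warning(expect_null(compute_activity(sub, m2)), "unvalidatable")
})

test_that("pathway activity is invariant to per-gene affine rescaling", {
  fx <- make_corg_fixture()
  genes <- rownames(fx$st$values)[1:5]
  m1 <- infer_corg_module(fx$std, fx$de, genes)
  resc <- fx$st
  scale <- stats::runif(nrow(resc$values), 0.5, 3)
  resc$values <- resc$values * scale + seq_len(nrow(resc$values))
  m2 <- infer_corg_module(standardize(resc), fx$de, genes)
  expect_equal(m2$activity, m1$activity, tolerance = 1e-9)
  expect_equal(m2$member_genes, m1$member_genes)
})
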