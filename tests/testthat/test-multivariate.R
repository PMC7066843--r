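test_that("PLS-DA separates an informative feature and is orthogonal", {
  d <- sep_data(n = 10, p = 8, n_sig = 1, gap = 5, sd = 0.1, seed = 2)
  fit <- plsda_fit(d$X, d$y, 1)
  expect_equal(which.max(abs(fit$W[, 1])), 1L, ignore_attr = TRUE)
  expect_true(all((fit$fitted > 0.5) == (d$y == 1)))

  for (s in 1:5) {
    dd <- sep_data(seed = 10 + s)
    f3 <- plsda_fit(dd$X, dd$y, 3)
    g <- crossprod(f3$scores)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
    expect_equal(colSums(f3$W^2), rep(1, 3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_error(plsda_fit(d$X, rep(1, 10), 1), "two classes")
  expect_error(plsda_fit(d$X, d$y, 50), "rank bound")
})

test_that("VIP scores satisfy their sum identity and symmetry", {
  # two features contributing equally -> VIP = {1, 1}
  X <- cbind(c(-1, -1, 1, 1), c(-1, -1, 1, 1) + c(1, -1, 1, -1) * 1e-8)
  colnames(X) <- c("a", "b")
  fit <- plsda_fit(X, c(0, 0, 1, 1), 1)
  v <- vip_scores(fit)
  expect_equal(unname(v), c(1, 1), tolerance = 1e-6)

  for (s in 1:5) {
    d <- sep_data(seed = 20 + s)
    f <- plsda_fit(d$X, d$y, 2)
    vv <- vip_scores(f)
    expect_equal(sum(vv^2), ncol(d$X), tolerance = 1e-9)
  }

  # informative features carry higher VIP than nulls
  d <- sep_data(n = 20, p = 40, n_sig = 10, gap = 2, seed = 30)
  f <- plsda_fit(d$X, d$y, 2)
  vv <- vip_scores(f)
  expect_gt(mean(vv[1:10]), mean(vv[11:40]))
})

test_that("training R2 is non-decreasing in component count", {
  d <- sep_data(n = 14, p = 20, seed = 40)
  r2 <- vapply(1:4, function(a) plsda_fit(d$X, d$y, a)$r_squared,
               numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("cross-validation separates signal from noise", {
  d <- sep_data(n = 12, p = 30, n_sig = 5, gap = 3, sd = 0.3, seed = 50)
  cv <- cross_validate_plsda(d$X, d$y, 2)
  expect_gt(cv$q_squared, 0.5)
  expect_lte(cv$q_squared, cv$r_squared)

  noise <- withr::with_seed(51, {
    list(X = matrix(stats::rnorm(12 * 30), 12, 30),
         y = rep(c(0, 1), each = 6))
  })
  cvn <- cross_validate_plsda(noise$X, noise$y, 2)
  expect_lt(cvn$q_squared, cv$q_squared)

  unbalanced_y <- c(0, rep(1, 11))
  expect_error(cross_validate_plsda(d$X, unbalanced_y, 1), "lost one class")
})

test_that("PerMANOVA matches the trace-form oracle and vegan", {
  skip_if_not_installed("vegan")
  withr::with_seed(60, {
    X <- rbind(matrix(stats::rnorm(15, 0), 3), matrix(stats::rnorm(15, 2), 3))
    D <- as.matrix(stats::dist(X))
    g <- rep(c("a", "b"), each = 3)
    got <- permanova(D, g, n_perm = 99, seed = 7)
    expect_equal(got$f_statistic, oracle_permanova_f(D, g), tolerance = 1e-9)
    expect_equal(got$ss_between + got$ss_within, got$ss_total,
                 tolerance = 1e-9)
    va <- vegan::adonis2(stats::as.dist(D) ~ g, permutations = 19)
    expect_equal(got$f_statistic, va$F[1], tolerance = 1e-8)
  })
})

test_that("PerMANOVA permutation p-values are seeded and label-invariant", {
  withr::with_seed(61, {
    X <- matrix(stats::rnorm(8 * 4), 8)
    D <- as.matrix(stats::dist(X))
    g <- rep(c("u", "v"), each = 4)
    p1 <- permanova(D, g, n_perm = 199, seed = 5)$p_value
    p2 <- permanova(D, g, n_perm = 199, seed = 5)$p_value
    expect_identical(p1, p2)
    relabel <- c(u = "grp1", v = "grp2")[g]
    expect_identical(permanova(D, relabel, n_perm = 199, seed = 5)$p_value,
                     p1)
    expect_gte(p1, 1 / 200)
  })
})

test_that("PerMANOVA is calibrated under the null", {
  withr::with_seed(62, {
    rej <- vapply(1:200, function(i) {
      X <- matrix(stats::rnorm(10 * 3), 10)
      D <- as.matrix(stats::dist(X))
      g <- sample(rep(c("a", "b"), each = 5))
      permanova(D, g, n_perm = 199, seed = i)$p_value <= 0.05
    }, logical(1))
    expect_gte(mean(rej), 0.02)
    expect_lte(mean(rej), 0.08)
  })
})

test_that("compound classification applies thresholds with OR logic", {
  expect_equal(classify_compound(0.9, 0.5)$class, "I")   # by Q2
  expect_equal(classify_compound(-0.2, 0.01)$class, "I") # by shift
  expect_equal(classify_compound(0.1, 0.5)$class, "II")
  expect_equal(classify_compound(0.4, 0.5)$class, "I")   # boundary >= rule
  expect_error(classify_compound(NA, 0.5), "missing")
})

test_that("a synthetic panel recovers effect and null compounds", {
  com <- generate_community(20, 15, 0.2, seed = 301)
  g <- unique(com$taxa$genus)[1]
  ids <- com$taxa$taxon_id[com$taxa$genus == g]
  effs <- list(
    kill = drug_effect("kill", global_scale = 0.3),
    select = drug_effect("select",
                         survival = stats::setNames(rep(0.1, length(ids)),
                                                    ids)))
  des <- make_design(5, c("kill", "select", "n1", "n2", "n3", "n4"))
  q <- simulate_quant_tables(com, des, effs, noise_model(), seed = 401)
  filt <- filter_protein_groups(q$proteins, des)
  pm <- quant_matrix(filt, samples = des$sample_id, fill = NA)
  norm <- normalize_log_quotient(ifelse(is.na(pm), 0, pm))
  norm[is.na(pm)] <- NA
  adj <- combat_adjust(impute_by_batch(norm, des$batch)$mat, des$batch)
  shift <- drug_shift_test(quant_matrix(filt, samples = des$sample_id,
                                        fill = 0), des)
  calls <- vapply(c("kill", "select", "n1", "n2", "n3", "n4"), function(cmp) {
    cols <- des$sample_id[des$compound %in% c(cmp, "DMSO")]
    y <- des$compound[match(cols, des$sample_id)] == cmp
    cv <- cross_validate_plsda(t(adj[, cols]), y, 2)
    sq <- shift$test$q_value[shift$test$compound == cmp]
    classify_compound(cv$q_squared, sq)$class
  }, character(1))
  expect_equal(unname(calls[c("kill", "select")]), c("I", "I"))
  expect_gte(sum(calls[c("n1", "n2", "n3", "n4")] == "II"), 3L)
})
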