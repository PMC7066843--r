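make_long <- function(groups, samples, values) {
  df <- expand.grid(group_id = groups, sample_id = samples,
                    stringsAsFactors = FALSE)
  df$intensity <- values
  df
}

test_that("presence filter reads '> 80% of individuals' strictly", {
  des <- make_design(5, "d")
  # p_all quantified in all 5 individuals; p_four in 4 (exactly 80%); p_none
  ctrl <- des$sample_id[des$is_control]
  long <- rbind(
    data.frame(group_id = "p_all", sample_id = ctrl, intensity = 1),
    data.frame(group_id = "p_four", sample_id = ctrl[1:4], intensity = 1),
    data.frame(group_id = "p_none", sample_id = ctrl, intensity = 0))
  filt <- filter_protein_groups(long, des)
  expect_identical(attr(filt, "retained"), "p_all")
})

test_that("log2/quotient normalization fixes per-sample means at one", {
  m <- matrix(2^c(2, 4, 6), ncol = 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.numeric(normalize_log_quotient(m, pseudocount = 0)),
               c(0.5, 1.0, 1.5))
  const <- matrix(8, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_true(all(normalize_log_quotient(const, 0) == 1))
  set.seed(63)
  r <- matrix(stats::rgamma(60, 2) * 100, 10,
              dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:6)))
  expect_equal(colMeans(normalize_log_quotient(r)), rep(1, 6),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(normalize_log_quotient(-r), "non-negative")
})

test_that("batch correction removes location shifts and is near-idempotent", {
  # single batch: identity
  m <- matrix(stats::rnorm(40), 8, 5,
              dimnames = list(sprintf("f%d", 1:8), sprintf("s%d", 1:5)))
  expect_identical(combat_adjust(m, rep("b1", 5)), m)
  expect_error(combat_adjust(m, c("a", "a", "a", "a", "b")), "singleton")

  # pure constant offset, zero residual noise: exact equalization
  base <- matrix(rep(stats::rnorm(6), 6), 6, 6)
  dimnames(base) <- list(sprintf("f%d", 1:6), sprintf("s%d", 1:6))
  batch <- rep(c("b1", "b2"), each = 3)
  shifted <- base + outer(stats::rnorm(6), as.numeric(batch == "b2") * 2)
  adj <- combat_adjust(shifted, batch)
  gap <- rowMeans(adj[, 1:3]) - rowMeans(adj[, 4:6])
  expect_lt(max(abs(gap)), 1e-6)
  # grand means preserved
  expect_equal(rowMeans(adj), rowMeans(shifted), tolerance = 1e-8)

  # EB route: simulated offsets shrink; re-running does not reintroduce
  # batch structure (the exact-location path above is exactly idempotent)
  set.seed(64)
  nf <- 100
  dat <- matrix(stats::rnorm(nf * 10, sd = 0.3), nf, 10)
  off <- stats::rnorm(nf)
  dat[, 6:10] <- dat[, 6:10] + off
  dimnames(dat) <- list(sprintf("f%d", 1:nf), sprintf("s%d", 1:10))
  b2 <- rep(c("x", "y"), each = 5)
  a1 <- combat_adjust(dat, b2)
  gap0 <- mean(abs(rowMeans(dat[, 1:5]) - rowMeans(dat[, 6:10])))
  gap1 <- mean(abs(rowMeans(a1[, 1:5]) - rowMeans(a1[, 6:10])))
  expect_lt(gap1, 0.15 * gap0)
  a2 <- combat_adjust(a1, b2)
  gap2 <- mean(abs(rowMeans(a2[, 1:5]) - rowMeans(a2[, 6:10])))
  expect_lte(gap2, gap1 + 1e-6)
  expect_identical(combat_adjust(adj, batch), adj)  # exact-location case
})

test_that("imputation fills by individual and flags cells", {
  m <- matrix(c(1, 2, NA, 4, 5, 6), 2, 3,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  got <- impute_by_batch(m, c("a", "a", "b"))
  # f1 is missing in s2 (batch a): filled with batch a's observed mean
  expect_equal(got$mat["f1", "s2"], 1)
  expect_true(got$imputed["f1", "s2"])
  expect_equal(sum(got$imputed), 1L)
})

test_that("annotation aggregation conserves totals and pools unannotated", {
  ann <- data.frame(group_id = c("g1", "g2", "g3"),
                    cog_category = c("E", "E", NA),
                    stringsAsFactors = FALSE)
  m <- matrix(c(3, 5, 2), 3, 1, dimnames = list(c("g1", "g2", "g3"), "s1"))
  agg <- aggregate_by_annotation(m, ann, "cog_category")
  expect_equal(agg["E", "s1"], 8)
  expect_equal(agg["unannotated", "s1"], 2)
  expect_equal(colSums(agg), colSums(m))

  # zero-noise function-only regulation: category ratio equals the factor
  com <- generate_community(6, 8, 0, seed = 65)
  tid <- com$taxa$taxon_id[1]
  cc <- com$proteins$cog_category[com$proteins$taxon_id == tid][1]
  reg <- data.frame(taxon_id = tid, cog_category = cc, factor = 2)
  des <- make_design(1, "d")
  q <- simulate_quant_tables(
    com, des, list(d = drug_effect("d", regulation = reg)),
    zero_noise(), seed = 66)
  pm <- quant_matrix(q$proteins, samples = des$sample_id, fill = 0)
  taxon_groups <- q$annotations$group_id[q$annotations$taxon_id == tid &
                                           q$annotations$cog_category == cc]
  in_t <- intersect(taxon_groups, rownames(pm))
  ratio <- sum(pm[in_t, "V1_d_r1"]) / sum(pm[in_t, "V1_DMSO_r1"])
  expect_equal(ratio, 2, tolerance = 1e-9)
})

test_that("differential features cover both designs and degenerate input", {
  des <- make_design(3, "d", n_replicates = 3)
  n <- nrow(des)
  mat <- matrix(1, 3, n, dimnames = list(c("flat", "sig", "const"),
                                         des$sample_id))
  set.seed(67)
  mat["sig", ] <- stats::rnorm(n, 5, 0.1) +
    2 * (des$compound == "d")
  mat["flat", ] <- stats::rnorm(n, 5, 0.1)
  mat["const", des$compound == "d"] <- 2  # zero variance in both arms

  rep_mode <- differential_features(mat, des, "d",
                                    mode = "within_replicates",
                                    individual = "V1")
  expect_equal(rep_mode$statistic[rep_mode$feature == "const"], Inf)
  expect_equal(rep_mode$p_value[rep_mode$feature == "const"],
               .Machine$double.xmin)
  expect_true(rep_mode$degenerate[rep_mode$feature == "const"])
  expect_lt(rep_mode$p_value[rep_mode$feature == "sig"], 0.05)

  across <- differential_features(mat, des, "d", mode = "across_individuals")
  expect_false(any(across$degenerate))
  expect_lt(across$p_value[across$feature == "sig"],
            across$p_value[across$feature == "flat"])

  # identical arms: t = 0, p = 1
  same <- matrix(rep(c(1, 2, 5, 1, 2, 5), each = 1), 1,
                 dimnames = list("f", NULL))
  des1 <- make_design(1, "d", n_replicates = 3)
  m1 <- matrix(c(1, 2, 5, 1, 2, 5), 1, 6,
               dimnames = list("f", des1$sample_id))
  r1 <- differential_features(m1, des1, "d", mode = "within_replicates",
                              individual = "V1")
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)
})

test_that("replicate-mode t-test recovers regulated features with FDR control", {
  set.seed(68)
  nf <- 400; n_reg <- 20
  des <- make_design(1, "d", n_replicates = 3)
  mat <- matrix(stats::rnorm(nf * 6, mean = 10, sd = 0.2), nf, 6,
                dimnames = list(sprintf("f%03d", 1:nf), des$sample_id))
  reg_ids <- sprintf("f%03d", 1:n_reg)
  mat[reg_ids, !des$is_control] <- mat[reg_ids, !des$is_control] + 2
  got <- differential_features(mat, des, "d", mode = "within_replicates",
                               individual = "V1")
  hits <- got$feature[got$q_value < 0.05]
  expect_gte(mean(reg_ids %in% hits), 0.8)
  expect_lte(mean(!(hits %in% reg_ids)), 0.1)
})

test_that("enrichment matches the exact hypergeometric tail", {
  cats <- data.frame(id = sprintf("i%03d", 1:100),
                     category = rep(c("T", "other"), c(20, 80)),
                     stringsAsFactors = FALSE)
  bg <- cats$id
  fg <- c(cats$id[1:8], cats$id[21:22])  # 8 of 10 in T
  got <- enrichment_test(fg, bg, cats)
  expect_equal(got$p_value[got$category == "T"],
               oracle_hyper(8, 20, 100, 10), tolerance = 1e-12)

  all_fg <- enrichment_test(bg, bg, cats)
  expect_true(all(all_fg$p_value == 1))

  # category with no background members is not tested
  cats2 <- rbind(cats, data.frame(id = "zzz", category = "ghost"))
  got2 <- enrichment_test(fg, bg, cats2)
  expect_false("ghost" %in% got2$category)

  expect_error(enrichment_test(c("nope"), bg, cats), "subset")
})

test_that("taxon-function distribution counts conserve and localize", {
  ann <- data.frame(group_id = c("g1", "g2", "g3", "g4"),
                    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes",
                               "Firmicutes"),
                    cog_category = c("E", "E", "G", "J"),
                    stringsAsFactors = FALSE)
  empty <- taxon_function_distribution(
    data.frame(feature = character(0), direction = character(0)), ann)
  expect_equal(nrow(empty), 0L)

  diff <- data.frame(feature = c("g1", "g2", "g3", "g4"),
                     direction = c("down", "down", "up", "down"),
                     stringsAsFactors = FALSE)
  got <- taxon_function_distribution(diff, ann)
  expect_equal(sum(got$count), 4L)
  down <- got[got$direction == "down", ]
  expect_equal(sum(down$count[down$phylum == "Firmicutes"]), 3L)
})
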