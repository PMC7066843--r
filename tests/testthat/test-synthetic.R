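test_that("communities are deterministic and honour the sharing fraction", {
  a <- generate_community(5, 4, 0.2, seed = 3)
  b <- generate_community(5, 4, 0.2, seed = 3)
  expect_identical(a, b)
  d <- generate_community(5, 4, 0.2, seed = 4)
  expect_false(identical(a$taxa$abundance, d$taxa$abundance))

  # no sharing: every peptide names exactly one candidate taxon
  solo <- generate_community(2, 5, 0, seed = 1)
  expect_false(any(grepl(";", solo$peptides$taxa, fixed = TRUE)))
  expect_true(all(table(solo$peptide_map$peptide_id) == 1L))

  big <- generate_community(20, 10, 0.3, seed = 7)
  frac <- mean(grepl(";", big$peptides$taxa, fixed = TRUE))
  expect_lt(abs(frac - 0.3), 0.05)
  # shared candidates span taxa with a genus or phylum in common
  shared <- big$peptides[big$peptides$shared, ]
  ids <- strsplit(shared$taxa, ";", fixed = TRUE)
  lin <- big$taxa
  ok <- vapply(ids, function(pr) {
    i <- match(pr, lin$taxon_id)
    lin$genus[i[1]] == lin$genus[i[2]] || lin$phylum[i[1]] == lin$phylum[i[2]]
  }, logical(1))
  expect_true(all(ok))
})

test_that("community invariants hold", {
  com <- generate_community(12, 8, 0.25, seed = 42)
  expect_true(all(com$taxa$abundance > 0))
  fr <- tapply(com$proteins$expression_fraction, com$proteins$taxon_id, sum)
  expect_equal(as.numeric(fr), rep(1, nrow(com$taxa)), tolerance = 1e-12)
  # every peptide's candidate set contains the owners of its parent proteins
  owners <- com$proteins$taxon_id[match(com$peptide_map$protein_id,
                                        com$proteins$protein_id)]
  cand <- com$peptides$taxa[match(com$peptide_map$peptide_id,
                                  com$peptides$peptide_id)]
  expect_true(all(mapply(function(o, cc)
    o %in% strsplit(cc, ";", fixed = TRUE)[[1]], owners, cand)))
})

test_that("drug effects scale abundances and expression exactly", {
  com <- generate_community(6, 5, 0, seed = 2)
  base <- apply_drug_effect(com, NULL)
  expect_equal(unname(base$taxon_abundance), com$taxa$abundance)

  half <- apply_drug_effect(com, drug_effect("x", global_scale = 0.5))
  expect_equal(half$taxon_abundance, base$taxon_abundance / 2)

  tid <- com$taxa$taxon_id[1]
  kill <- apply_drug_effect(
    com, drug_effect("x", survival = stats::setNames(0, tid)))
  killed <- com$proteins$protein_id[com$proteins$taxon_id == tid]
  expect_true(all(kill$protein_amount[killed] == 0))
  others <- setdiff(names(kill$protein_amount), killed)
  expect_equal(kill$protein_amount[others], base$protein_amount[others])

  # function-only regulation without renormalization: targeted category
  # doubles, everything else is untouched, biomass shifts by the regulated
  # expression share
  cc <- com$proteins$cog_category[com$proteins$taxon_id == tid][1]
  reg <- data.frame(taxon_id = tid, cog_category = cc, factor = 2)
  up <- apply_drug_effect(com, drug_effect("x", regulation = reg))
  hit <- com$proteins$protein_id[com$proteins$taxon_id == tid &
                                   com$proteins$cog_category == cc]
  expect_equal(up$protein_amount[hit], 2 * base$protein_amount[hit])
  rest <- setdiff(names(base$protein_amount), hit)
  expect_equal(up$protein_amount[rest], base$protein_amount[rest])
  share <- sum(com$proteins$expression_fraction[
    com$proteins$taxon_id == tid & com$proteins$cog_category == cc])
  expect_equal(sum(up$protein_amount[com$proteins$taxon_id == tid]),
               com$taxa$abundance[1] * (1 + share), tolerance = 1e-12)

  expect_error(apply_drug_effect(
    com, drug_effect("x", survival = c(nope = 0.5))), "unknown taxon")
})

test_that("simulation respects the equal-volume observation contract", {
  com <- generate_community(8, 6, 0.2, seed = 5)
  des <- make_design(2, c("drugA"), n_replicates = 2)

  # zero peptide noise: replicate controls of one individual are identical
  # even with batch and individual structure present
  q <- simulate_quant_tables(
    com, des, list(drugA = drug_effect("drugA")),
    noise_model(sigma = 0, batch_sigma = 0.5, indiv_sigma = 1,
                miss_slope = 0), seed = 9)
  b <- total_biomass(q$peptides, samples = des$sample_id)
  expect_equal(b[["V1_DMSO_r1"]], b[["V1_DMSO_r2"]])

  # global kill with zero noise: exact proportionality of totals
  q2 <- simulate_quant_tables(
    com, des, list(drugA = drug_effect("drugA", global_scale = 0.25)),
    zero_noise(), seed = 9)
  b2 <- total_biomass(q2$peptides, samples = des$sample_id)
  expect_equal(b2[["V1_drugA_r1"]] / b2[["V1_DMSO_r1"]], 0.25,
               tolerance = 1e-12)

  expect_identical(
    simulate_quant_tables(com, des, noise = noise_model(), seed = 11),
    simulate_quant_tables(com, des, noise = noise_model(), seed = 11))
})

test_that("noisy simulations recover a global kill on average", {
  ratios <- vapply(1:20, function(i) {
    com <- generate_community(6, 5, 0.2, seed = i)
    des <- make_design(1, "d")
    q <- simulate_quant_tables(
      com, des, list(d = drug_effect("d", global_scale = 0.5)),
      noise_model(sigma = 0.3, batch_sigma = 0, indiv_sigma = 0,
                  miss_slope = 0), seed = 100 + i)
    b <- total_biomass(q$peptides, samples = des$sample_id)
    b[["V1_d_r1"]] / b[["V1_DMSO_r1"]]
  }, numeric(1))
  expect_gt(mean(ratios), 0.45)
  expect_lt(mean(ratios), 0.55)
})

test_that("dilution series emit the requested ladder", {
  com <- generate_community(6, 5, 0, seed = 8)
  one <- make_dilution_series(com, 1, 3, zero_noise(), seed = 2)
  b <- total_biomass(one$peptides)
  expect_equal(length(b), 3L)
  expect_equal(max(b) - min(b), 0)

  two <- make_dilution_series(com, c(0.5, 1), 1, zero_noise(), seed = 2)
  b2 <- total_biomass(two$peptides)
  expect_equal(unname(b2["GRD2_r1"] / b2["GRD1_r1"]), 2, tolerance = 1e-12)

  full <- make_dilution_series(com, c(0.1, 0.2, 0.4, 0.6, 0.8, 1), 3,
                               noise_model(), seed = 3)
  expect_equal(nrow(full$concentrations), 18L)

  expect_error(make_dilution_series(com, numeric(0)), "non-empty")
  expect_error(make_dilution_series(com, c(1, 0.5, 0.7)), "monotone")
})

test_that("missingness is empirically non-increasing in intensity", {
  com <- generate_community(20, 15, 0.2, seed = 13)
  des <- make_design(2, "d")
  truth <- simulate_quant_tables(com, des, noise = zero_noise(), seed = 21)
  observed <- simulate_quant_tables(
    com, des,
    noise = noise_model(sigma = 0, batch_sigma = 0, indiv_sigma = 0,
                        miss_mid = 16, miss_slope = -1), seed = 21)
  key_t <- paste(truth$peptides$peptide_id, truth$peptides$sample_id)
  key_o <- paste(observed$peptides$peptide_id, observed$peptides$sample_id)
  missing <- !(key_t %in% key_o)
  dec <- cut(rank(truth$peptides$intensity, ties.method = "first"),
             breaks = 10, labels = FALSE)
  rate <- tapply(missing, dec, mean)
  expect_true(all(diff(rate) <= 0.03))
  expect_gt(rate[1], rate[10])
})
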