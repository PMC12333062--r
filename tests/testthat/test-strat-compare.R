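ref <- jader_ir_reference()
fix <- jader_ir_counts()
amap <- jader_attribute_map()

test_that("pooling drug-level counts reproduces the published group tables", {
  pos <- fix$drug_name[fix$adcc_status == "positive"]
  neg <- fix$drug_name[fix$adcc_status == "negative"]
  expect_length(pos, 14); expect_length(neg, 11)
  tb_pos <- pooled_contingency(fix, pos, n_total = ref$n_total,
                               n_event = ref$n_event)
  expect_equal(unlist(tb_pos[c("a", "b", "c", "d")], use.names = FALSE),
               c(1142L, 28317L, 620L, 67488L))
  est <- ror_with_ci(tb_pos)
  expect_equal(round(c(est$ror, est$ci_low, est$ci_high), 2),
               c(4.39, 3.98, 4.85))
  est_neg <- ror_with_ci(pooled_contingency(fix, neg, n_total = ref$n_total,
                                            n_event = ref$n_event))
  expect_equal(round(c(est_neg$ror, est_neg$ci_low, est_neg$ci_high), 2),
               c(0.16, 0.14, 0.18))
  expect_error(pooled_contingency(fix, "ghost", n_total = ref$n_total,
                                  n_event = ref$n_event), "ghost")
})

test_that("pooling a singleton reduces to the per-drug table and is additive", {
  solo <- pooled_contingency(fix, "avelumab", n_total = ref$n_total,
                             n_event = ref$n_event)
  expect_equal(solo, contingency_from_counts(25, 278, ref$n_total, ref$n_event))
  # additivity of a-values over an arbitrary partition
  set.seed(5150)
  grp <- sample(1:3, nrow(fix), replace = TRUE)
  a_sum <- sum(vapply(1:3, function(g) {
    pooled_contingency(fix, fix$drug_name[grp == g],
                       n_total = ref$n_total, n_event = ref$n_event)$a
  }, integer(1)))
  expect_equal(a_sum, sum(fix$ir_cases))
  # and the universe method agrees with per-drug construction on synthetic data
  cfg <- small_config(n_cases = 3000, seed = 77, profiles = rbind(
    small_profile(drug_name = "drugA", share = 0.2, planted_ror = 3),
    small_profile(drug_name = "drugB", share = 0.2, planted_ror = 1)))
  u <- build_universe(generate_reports(cfg), cfg$event_pt_codes)
  pooled <- pooled_contingency(u, c("druga", "drugb"))
  ta <- build_contingency(u, "druga"); tb <- build_contingency(u, "drugb")
  expect_equal(pooled$a, ta$a + tb$a)
  expect_equal(pooled$a + pooled$b, ta$a + ta$b + tb$a + tb$b)
  expect_equal(pooled_contingency(u, "druga"), ta)
})

test_that("detection tables cross-tabulate signal flags by attribute", {
  res <- analyze_counts(fix, ref$n_total, ref$n_event)
  adcc <- detection_table(res, amap, "adcc_status")
  expect_equal(adcc, matrix(c(9L, 1L, 5L, 10L), nrow = 2, byrow = TRUE,
                            dimnames = list(c("detected", "not_detected"),
                                            c("positive", "negative"))))
  type <- detection_table(res, amap, "antibody_type")
  expect_equal(unname(type),
               matrix(c(1L, 2L, 5L, 2L, 0L, 2L, 8L, 5L), nrow = 2, byrow = TRUE))
  expect_equal(colnames(type),
               c("mouse", "chimeric", "humanized", "fully_human"))
  expect_error(detection_table(res, amap[-1, ], "adcc_status"),
               fix$drug_name[1])
  empty <- detection_table(res[0, ], amap, "adcc_status")
  expect_equal(dim(empty), c(2L, 0L))
})

test_that("the 2xK exact test matches the 2x2 test, the oracle, and the published values", {
  t4 <- matrix(c(9, 5, 1, 10), nrow = 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2xk(t4), 4), 0.0119)
  expect_equal(fisher_exact_2xk(t4), fisher_exact_2x2(t(t4)),
               tolerance = 1e-12)
  t5 <- matrix(c(1, 2, 5, 2, 0, 2, 8, 5), nrow = 2, byrow = TRUE)
  # the enumeration oracle adjudicates the published value
  expect_equal(fisher_exact_2xk(t5), oracle_fisher_2xk(t5), tolerance = 1e-12)
  expect_equal(round(fisher_exact_2xk(t5), 3), 0.667)
})

test_that("the 2xK exact test equals complete margin-preserving enumeration", {
  set.seed(60606)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    m <- matrix(sample(0:6, 2 * k, replace = TRUE), nrow = 2)
    if (any(rowSums(m) == 0) || sum(m) == 0) next
    expect_equal(fisher_exact_2xk(m), oracle_fisher_2xk(m), tolerance = 1e-12,
                 info = paste(m, collapse = ","))
    # invariant under column permutation and row swap
    perm <- sample(ncol(m))
    expect_equal(fisher_exact_2xk(m[, perm, drop = FALSE]),
                 fisher_exact_2xk(m), tolerance = 1e-12)
    expect_equal(fisher_exact_2xk(m[2:1, , drop = FALSE]),
                 fisher_exact_2xk(m), tolerance = 1e-12)
  }
})

test_that("degenerate and oversized detection tables are handled explicitly", {
  zero_row <- matrix(c(0, 0, 0, 3, 4, 5), nrow = 2, byrow = TRUE)
  expect_equal(fisher_exact_2xk(zero_row), 1)
  big <- matrix(c(1000, 2000, 1500, 800), nrow = 2)
  expect_error(fisher_exact_2xk(big, max_total = 2000), "not computed")
})

test_that("attribute maps are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(amap, path)
  rt <- read_attribute_map(path)
  expect_equal(rt$drug_name, amap$drug_name)
  bad <- amap; bad$adcc_status[1] <- "maybe"
  readr::write_csv(bad, path)
  expect_error(read_attribute_map(path), "adcc_status")
  readr::write_csv(amap[, c("drug_name", "adcc_status")], path)
  expect_error(read_attribute_map(path), "antibody_type")
})

test_that("pooled_by_attribute summarises both ADCC groups with signal flags", {
  pooled <- pooled_by_attribute(fix, amap, "adcc_status",
                                n_total = ref$n_total, n_event = ref$n_event)
  expect_equal(pooled$level, c("positive", "negative"))
  expect_equal(pooled$n_drugs, c(14L, 11L))
  expect_equal(round(pooled$ror, 2), c(4.39, 0.16))
  expect_equal(pooled$signal, c(TRUE, FALSE))
})
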