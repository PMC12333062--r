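ref <- jader_ir_reference()

test_that("contingency construction reproduces the published margins", {
  tb <- contingency_from_counts(25, 278, ref$n_total, ref$n_event)
  expect_equal(unlist(tb[c("a", "b", "c", "d")], use.names = FALSE),
               c(25L, 253L, 1737L, 95552L))
  # margin identities on every fixture row
  fix <- jader_ir_counts()
  for (i in seq_len(nrow(fix))) {
    t_i <- contingency_from_counts(fix$ir_cases[i], fix$reports[i],
                                   ref$n_total, ref$n_event)
    expect_equal(t_i$a + t_i$b, fix$reports[i])
    expect_equal(t_i$a + t_i$c, ref$n_event)
    expect_equal(t_i$a + t_i$b + t_i$c + t_i$d, ref$n_total)
  }
  expect_error(contingency_2x2(1, -1, 2, 3), "nonnegative")
})

test_that("degenerate universes yield the documented degenerate tables", {
  tabs <- toy_tables(drug_row("c1", "x"), reac_row("c1", ir_pts[1]))
  u <- build_universe(tabs, ir_pts)
  one <- build_contingency(u, "x")
  expect_equal(unlist(one[c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 0L, 0L, 0L))
  expect_warning(absent <- build_contingency(u, "ghost"), "ghost")
  expect_equal(unlist(absent[c("a", "b", "c", "d")], use.names = FALSE),
               c(0L, 0L, u$n_event, u$n_total - u$n_event))
})

test_that("ROR with Woolf CI reproduces the published per-drug values at 2 dp", {
  spot <- list(avelumab     = list(c(25, 278),    c(5.44, 3.59, 8.22)),
               cetuximab    = list(c(591, 4799),  c(10.99, 9.90, 12.19)),
               blinatumomab = list(c(59, 244),    c(17.91, 13.31, 24.10)),
               trastuzumab  = list(c(155, 3568),  c(2.61, 2.21, 3.09)),
               nivolumab    = list(c(142, 18246), c(0.38, 0.32, 0.45)),
               durvalumab   = list(c(9, 2851),    c(0.17, 0.09, 0.32)))
  for (nm in names(spot)) {
    cnt <- spot[[nm]][[1]]
    est <- ror_with_ci(contingency_from_counts(cnt[1], cnt[2],
                                               ref$n_total, ref$n_event))
    expect_equal(round(c(est$ror, est$ci_low, est$ci_high), 2),
                 spot[[nm]][[2]], info = nm)
  }
})

test_that("a balanced table gives ROR exactly 1", {
  est <- ror_with_ci(contingency_2x2(10, 90, 100, 900))
  expect_equal(est$ror, 1)
  expect_lt(est$ci_low, 1); expect_gt(est$ci_high, 1)
})

test_that("ROR obeys the table symmetries", {
  set.seed(424242)
  for (i in 1:25) {
    m <- random_2x2(200) + 1   # keep cells positive so the ROR is defined
    tb <- contingency_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    est <- ror_with_ci(tb)
    # transposing the table (swap rows and columns together) leaves it fixed
    t_tb <- contingency_2x2(m[1, 1], m[2, 1], m[1, 2], m[2, 2])
    expect_equal(ror_with_ci(t_tb)$ror, est$ror)
    # swapping rows only inverts the estimate and swaps/inverts the bounds
    s_tb <- contingency_2x2(m[2, 1], m[2, 2], m[1, 1], m[1, 2])
    s_est <- ror_with_ci(s_tb)
    expect_equal(s_est$ror, 1 / est$ror)
    expect_equal(s_est$ci_low, 1 / est$ci_high)
    expect_equal(s_est$ci_high, 1 / est$ci_low)
  }
})

test_that("zero cells flag the estimate undefined unless continuity is requested", {
  tb <- contingency_2x2(0, 10, 5, 100)
  est <- ror_with_ci(tb)
  expect_true(est$undefined)
  expect_true(is.na(est$ror))
  cc <- ror_with_ci(tb, continuity = TRUE)
  expect_false(cc$undefined)
  expect_equal(cc$ror, (0.5 * 100.5) / (10.5 * 5.5))
  expect_false(signal_flag(tb, est$ci_low))
})

test_that("the signal rule requires ci_low > 1 strictly and at least two cases", {
  tb25 <- contingency_from_counts(25, 278, ref$n_total, ref$n_event)
  expect_true(signal_flag(tb25, ror_with_ci(tb25)$ci_low))
  tb1 <- contingency_from_counts(1, 5, ref$n_total, ref$n_event)
  expect_false(signal_flag(tb1, 3.5))          # one case never signals
  expect_false(signal_flag(tb25, 1.0))         # boundary is excluded
  expect_true(signal_flag(tb25, 1.0000001))
})

test_that("the exact 2x2 test matches its published value and handles zero margins", {
  p <- fisher_exact_2x2(matrix(c(9, 1, 5, 10), nrow = 2))
  expect_equal(round(p, 4), 0.0119)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), nrow = 2)), 1)
  expect_equal(fisher_exact_2x2(contingency_2x2(0, 5, 0, 7)), 1)
})

test_that("the exact 2x2 test equals hypergeometric enumeration", {
  m <- matrix(c(2, 4, 3, 1), nrow = 2)
  expect_equal(fisher_exact_2x2(m), oracle_fisher_2x2(m), tolerance = 1e-12)
  set.seed(909090)
  for (i in 1:200) {
    m <- random_2x2(30)
    expect_equal(fisher_exact_2x2(m), oracle_fisher_2x2(m),
                 tolerance = 1e-12,
                 info = paste(m, collapse = ","))
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.02, 6)), rep(0.02, 6))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(31337)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                       # never decreases
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in rank
    expect_true(all(adj <= 1))
  }
})
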