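test_that("conversion probability matches the closed form", {
  m <- error_model(rho = 0.0066, l = 26, f_max = 1000)
  # frozen 50-digit reference values
  expect_equal(p_conversion(1, m), 0.0018643462447640215, tolerance = 1e-14)
  expect_equal(p_conversion(0, m), 0.84183707252208135, tolerance = 1e-14)
  expect_equal(p_conversion(0, m), (1 - 0.0066)^26, tolerance = 1e-14)
  expect_error(p_conversion(27, m), "\\[0, l\\]")

  # vanishing error rate: converting to a different sequence is impossible
  tiny <- error_model(rho = 1e-12, l = 26, f_max = 10)
  expect_lt(p_conversion(1, tiny), 1e-11)
})

test_that("conversion probabilities sum to one over sequence space", {
  # enumeration over all sequences at l = 6: grouping by distance d there
  # are choose(l, d) * 3^d sequences at distance d from a fixed source
  m <- error_model(rho = 0.0123, l = 6, f_max = 10)
  total <- sum(choose(6, 0:6) * 3^(0:6) * p_conversion(0:6, m))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("log-Bayes factor matches arbitrary-precision references", {
  frozen <- list(
    list(d = 1, f_c = 3, n_hat = 1090, rho = 0.005, f_max = 1000,
         lnK = 34.450255725557816),
    list(d = 2, f_c = 7, n_hat = 850, rho = 0.0033, f_max = 2000,
         lnK = -27.323431734196396),
    list(d = 1, f_c = 90000, n_hat = 109000, rho = 0.0033, f_max = 100000,
         lnK = -570111.96882451678),
    list(d = 3, f_c = 1, n_hat = 500, rho = 0.02, f_max = 1500,
         lnK = 18.5782526711283),
    list(d = 1, f_c = 12, n_hat = 200000, rho = 0.0066, f_max = 500000,
         lnK = -279.24650595039286))
  for (cs in frozen) {
    m <- error_model(cs$rho, 26, cs$f_max)
    got <- log_bayes_factor(test_case(cs$d, cs$f_c, cs$n_hat), m)
    expect_equal(got, cs$lnK, tolerance = 1e-10)
  }
})

test_that("log-Bayes factor honours the degenerate conventions", {
  # f_c > n_hat: the binomial mass is zero, the candidate must be real
  m <- error_model(0.0033, 26, f_max = 1e5)
  expect_identical(log_bayes_factor(test_case(1, 101, 100), m), -Inf)
  # vanishing rho with d >= 1: errors (essentially) impossible
  tiny <- error_model(1e-300, 26, f_max = 1e5)
  expect_lt(log_bayes_factor(test_case(1, 5, 1000), tiny), -1000)
  expect_identical(classify_sequence(test_case(1, 5, 1000), tiny),
                   "TRUE_BARCODE")
})

test_that("log-Bayes factor decreases with distance above the error mode", {
  # for candidates at least as frequent as the expected distance-1 error
  # child (the regime where promotions are actually decided), every extra
  # mismatch makes the error-child explanation strictly less likely; far
  # below that expectation the comparison is two-sided and no monotonicity
  # is claimed
  set.seed(91)
  for (i in 1:200) {
    rho <- runif(1, 1e-4, 0.05)
    n_hat <- sample(100:1e6, 1)
    m <- error_model(rho, 26, f_max = n_hat)
    f_lo <- max(1, ceiling(n_hat * p_conversion(1, m)))
    if (f_lo >= n_hat) next
    f_c <- min(n_hat, f_lo * sample(1:50, 1))
    lnK <- vapply(1:3, function(d)
      log_bayes_factor(test_case(d, f_c, n_hat), m), numeric(1))
    expect_true(all(diff(lnK) < 0))
  }
})

test_that("classification threshold favors the error-sequence model", {
  # a case engineered to sit exactly at lnK = threshold stays ERROR_SEQUENCE
  m <- error_model(0.0033, 26, f_max = 1000)
  lnK <- log_bayes_factor(test_case(1, 5, 2000), m)
  m_at <- error_model(0.0033, 26, f_max = 1000, log_bf_threshold = lnK)
  expect_identical(classify_sequence(test_case(1, 5, 2000), m_at),
                   "ERROR_SEQUENCE")
  m_above <- error_model(0.0033, 26, f_max = 1000,
                         log_bf_threshold = lnK + 1e-9)
  expect_identical(classify_sequence(test_case(1, 5, 2000), m_above),
                   "TRUE_BARCODE")
})

test_that("a TRUE_BARCODE verdict survives further count growth", {
  # above the binomial mode n_hat * p_hat, lnK decreases in f_c, so once a
  # candidate's count is implausibly large for an error child, growing it
  # further never flips the verdict back
  set.seed(92)
  for (i in 1:100) {
    rho <- runif(1, 1e-3, 0.03)
    n_hat <- sample(1000:1e5, 1)
    d <- sample(1:3, 1)
    m <- error_model(rho, 26, f_max = n_hat)
    mode <- n_hat * p_conversion(d, m)
    f_c <- max(ceiling(mode), 1)
    verdicts <- vapply(unique(pmin(round(f_c * c(1, 2, 5, 20)), n_hat)),
                       function(fc)
                         classify_sequence(test_case(d, fc, n_hat), m),
                       character(1))
    first_true <- match("TRUE_BARCODE", verdicts)
    if (!is.na(first_true))
      expect_true(all(verdicts[first_true:length(verdicts)] == "TRUE_BARCODE"))
  }
})

test_that("n_hat de-biases the accumulated cluster count", {
  m <- error_model(0.01, 26, f_max = 100)
  expect_equal(n_hat_estimate(1000, m), round(1000 / 0.99^26))
  expect_gte(n_hat_estimate(1000, m), 1000)
})

test_that("the substitution rate is recovered from simulated reads", {
  sim <- simulate_reads(5000, rho = 0.0066, seed = 131)
  idx <- build_kmer_index(sim$reads,
                          kmer_scheme(26, 1, n = length(sim$reads$sequences)))
  rho_hat <- estimate_rho(sim$reads, idx)
  expect_lt(abs(rho_hat - 0.0066) / 0.0066, 0.05)
})

test_that("error-free data floors the rate estimate with a warning", {
  set.seed(141)
  bc <- generate_barcodes(500)
  rs <- read_set(bc, assign_counts(500))
  idx <- build_kmer_index(rs, kmer_scheme(26, 1, n = 500))
  expect_warning(rho_hat <- estimate_rho(rs, idx), "error free")
  expect_lte(rho_hat, 1e-6)
})

test_that("epsilon selection follows the expected-escape rule", {
  set.seed(151)
  bc <- generate_barcodes(2)
  mk <- function(total) read_set(bc, c(total - 10, 10))
  # independent recomputation of the rule with pbinom
  rule <- function(total, rho, cap = 26) {
    eps <- 1
    while (eps < 26 && total * pbinom(eps, 26, rho, lower.tail = FALSE) >= 1)
      eps <- eps + 1
    min(eps, cap)
  }
  for (cfg in list(list(t = 5e7, rho = 0.0033), list(t = 1e8, rho = 0.02),
                   list(t = 1e6, rho = 0.0033))) {
    expect_identical(choose_epsilon(mk(cfg$t), cfg$rho),
                     as.integer(rule(cfg$t, cfg$rho, cap = 3)))
    expect_identical(choose_epsilon(mk(cfg$t), cfg$rho, max_epsilon = 26),
                     as.integer(rule(cfg$t, cfg$rho)))
  }
  # default clamp engages for the high-rate, deep-sequencing settings
  expect_identical(choose_epsilon(mk(5e7), 0.0033), 3L)
  expect_identical(choose_epsilon(mk(1e8), 0.02), 3L)
  # vanishing error rate: clamp floor
  expect_identical(choose_epsilon(mk(1e6), 1e-9), 1L)
})
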