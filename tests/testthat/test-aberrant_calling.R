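test_that("the one-sample t test matches its closed form and handles ties", {
  r <- one_sample_t(c(1, 2, 3), 2)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_false(r$degenerate)
  # event absent from every control, present in the patient
  r0 <- one_sample_t(rep(0, 345), 30)
  expect_true(r0$degenerate)
  expect_equal(r0$p, 0)
  expect_equal(r0$t, -Inf)
  # zero variance with equality
  expect_equal(one_sample_t(rep(5, 10), 5)$p, 1)
  expect_error(one_sample_t(3, 1), "at least 2")
})

test_that("t and p agree with stats::t.test as an independent reference", {
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    x <- rnorm(n, mean = runif(1, 0, 40), sd = runif(1, 0.5, 15))
    mu <- mean(x) + runif(1, -4, 4) * sd(x) / sqrt(n)
    r <- one_sample_t(x, mu)
    ref <- t.test(x, mu = mu)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
    expect_equal(r$df, unname(ref$parameter))
  }
  # the spec'd magnitude: patient 5 SEM above the control mean
  set.seed(77)
  x <- rnorm(100, 10, 2)
  patient <- mean(x) + 5 * sd(x) / sqrt(100)
  r <- one_sample_t(x, patient)
  expect_equal(abs(r$t), 5)
  expect_equal(r$p, 2 * pt(-5, 99), tolerance = 1e-12)
})

test_that("Holm-Sidak follows the step-down formula", {
  expect_equal(holm_sidak(0.05), 0.05)  # m = 1: no correction
  adj <- holm_sidak(c(0.01, 0.02, 0.04))
  expect_equal(adj, c(1 - 0.99^3, 1 - 0.98^2, 0.04), tolerance = 1e-12)
  # ties collapse to the single-step value
  expect_equal(holm_sidak(rep(0.03, 5)), rep(1 - 0.97^5, 5), tolerance = 1e-12)
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(holm_sidak(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("Holm-Sidak is bounded by raw p and the single-step adjustment", {
  brute <- function(p) {
    m <- length(p); o <- order(p)
    adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
    for (i in seq_len(m)[-1]) adj[i] <- max(adj[i], adj[i - 1])
    out <- numeric(m); out[o] <- pmin(adj, 1); out
  }
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    a <- holm_sidak(p)
    expect_equal(a, brute(p), tolerance = 1e-12)
    expect_true(all(a >= p - 1e-15))
    expect_true(all(a <= 1 - (1 - p)^length(p) + 1e-12))
    expect_equal(order(a[order(p)]), seq_along(p))  # monotone in rank
  }
})

# minimal profile: one common event with controls below 29, plus one rare event
fake_profile <- function(n = 60) {
  set.seed(4)
  common <- pmin(28.9, pmax(0.5, rnorm(n, 15, 6)))
  rare <- c(rep(0, n - 3), 6, 8, 7)
  mat <- rbind("G:common" = common, "G:rare" = rare)
  colnames(mat) <- paste0("C", seq_len(n))
  q <- do.call(rbind, lapply(colnames(mat), function(s) {
    data.frame(sample_id = s, gene = "G", event = c("common", "rare"),
               alt_reads = 0L, region_reads = 200L, psi = mat[, s])
  }))
  build_profile(q)
}

patient_q <- function(events, psis, regions = 200L) {
  data.frame(sample_id = "P", gene = "G", event = events, alt_reads = 0L,
             region_reads = regions, psi = psis)
}

test_that("aberrant calls enforce all four significance criteria", {
  prof <- fake_profile()
  # clear outlier on the common event (twice the highest control PSI)
  calls <- call_aberrant(patient_q("common", 57.7), prof)
  expect_true(calls$significant)
  expect_gt(calls$patient_psi, calls$control_mean_psi)
  # PSI below 5 never significant, however small the p value
  c2 <- call_aberrant(patient_q("common", 4.9), prof)
  expect_false(c2$significant)
  expect_false(c2$tested)
  # coverage below 50 reads never significant
  c3 <- call_aberrant(patient_q("common", 90, regions = 49L), prof)
  expect_false(c3$significant)
  # patient PSI below the control mean: excluded from the tested family
  c4 <- call_aberrant(patient_q("common", 1e-6), prof)
  expect_false(c4$tested)
  expect_true(is.na(c4$p_adjusted))
})

test_that("novel events use the degenerate all-zero control branch", {
  prof <- fake_profile()
  calls <- call_aberrant(patient_q(c("common", "novelEv"), c(57.7, 30)), prof)
  nov <- calls[calls$event == "novelEv", ]
  expect_true(nov$novel_in_patient)
  expect_true(nov$degenerate)
  expect_equal(nov$control_mean_psi, 0)
  expect_equal(nov$p_raw, 0)
  expect_true(nov$significant)
  expect_equal(nov$n_controls, prof$n_controls)
  # adjusted p never below raw p
  expect_true(all(calls$p_adjusted[calls$tested] >=
                    calls$p_raw[calls$tested] - 1e-15))
})

test_that("detected-only control summaries ride along on calls", {
  prof <- fake_profile()
  calls <- call_aberrant(patient_q("rare", 40), prof)
  expect_equal(calls$n_controls_detected, 3L)
  expect_equal(calls$control_median_psi, 7)
  # control mean uses the zero-assigned vector
  expect_equal(calls$control_mean_psi, mean(c(rep(0, 57), 6, 8, 7)))
  expect_error(call_aberrant(patient_q("x", 10),
                             structure(list(stats = data.frame(),
                                            psi = matrix(0, 0, 0),
                                            n_controls = 10),
                                       class = "control_profile")),
               "empty")
})
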