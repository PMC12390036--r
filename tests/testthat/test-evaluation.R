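test_that("error metrics match hand-computed examples", {
  expect_equal(rr_mae(rr_pair(c(20, 20), c(20, 20))), 0)
  expect_equal(rr_mae(rr_pair(c(10, 20), c(12, 18))), 2)
  expect_equal(rr_mae(rr_pair(15, 18)), 3)
  expect_equal(rr_mape(rr_pair(c(10, 20), c(12, 18))), 15)
  expect_equal(rr_mape(rr_pair(c(10, 20), c(10, 20))), 0)
  expect_warning(m <- rr_mape(rr_pair(c(0, 10), c(1, 11))), "excluded")
  expect_equal(m, 10)
  expect_error(rr_mape(rr_pair(c(0, 0), c(1, 1))), "undefined")
  expect_equal(rr_rmse(rr_pair(c(10, 20), c(12, 18))), 2)
  expect_equal(rr_rmse(rr_pair(15, 18)), 3)
  expect_equal(rr_rmse(rr_pair(c(0, 0), c(3, 4))), sqrt(12.5))
  expect_error(rr_pair(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("metrics equal brute-force formulas and obey mae <= rmse", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    ref <- stats::runif(n, 5, 35)
    der <- ref + stats::rnorm(n, sd = 3)
    der[der < 0] <- 0
    pr <- rr_pair(ref, der)
    d <- ref - der
    expect_equal(rr_mae(pr), sum(abs(d)) / n, tolerance = 1e-12)
    expect_equal(rr_rmse(pr), sqrt(sum(d^2) / n), tolerance = 1e-12)
    expect_equal(rr_mape(pr), 100 / n * sum(abs(d) / ref), tolerance = 1e-12)
    expect_gte(rr_rmse(pr) + 1e-12, rr_mae(pr))
    # brute-force Pearson via the covariance formula
    rho_bf <- (mean(der * ref) - mean(der) * mean(ref)) /
      sqrt((mean(der^2) - mean(der)^2) * (mean(ref^2) - mean(ref)^2))
    expect_equal(rr_pearson(pr)$rho, rho_bf, tolerance = 1e-9)
    # permutation invariance
    p <- sample(n)
    expect_equal(rr_mae(rr_pair(ref[p], der[p])), rr_mae(pr))
  }
})

test_that("Pearson interpretation bands and degenerate cases", {
  x <- c(10, 12, 15, 18)
  p1 <- rr_pearson(rr_pair(x, x))
  expect_equal(p1$rho, 1)
  expect_equal(p1$class, "strong")
  p2 <- rr_pearson(rr_pair(x, 40 - x))
  expect_equal(p2$rho, -1)
  expect_error(rr_pearson(rr_pair(x, rep(2, 4))), "constant")
  expect_error(rr_pearson(rr_pair(x[1:2], x[1:2])), "at least 3")
})

test_that("Wilcoxon signed-rank exact path matches full enumeration", {
  expect_equal(wilcoxon_signed_rank(rr_pair(c(5, 7), c(6, 6)))$p, 1.0)
  r3 <- wilcoxon_signed_rank(rr_pair(c(10, 10, 10), c(11, 12, 13)))
  expect_equal(r3$p, 0.25)
  expect_warning(rz <- wilcoxon_signed_rank(rr_pair(c(4, 5), c(4, 5))),
                 "zero")
  expect_equal(rz$p, 1.0)
  set.seed(19)
  for (i in 1:30) {
    m <- sample(2:10, 1)
    d <- round(stats::rnorm(m, sd = 2), sample(0:1, 1))  # ties likely
    ref <- stats::runif(m, 10, 20)
    pr <- rr_pair(ref, pmax(ref + d, 0))
    d_eff <- pmax(ref + d, 0) - ref
    if (all(d_eff == 0)) next
    got <- suppressWarnings(wilcoxon_signed_rank(pr))
    expect_equal(got$p, wilcoxon_enum(d_eff), tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with the reference implementation where comparable", {
  # tie-free, zero-free differences: exact p must match wilcox.test
  set.seed(29)
  for (i in 1:20) {
    m <- sample(5:12, 1)
    ref <- stats::runif(m, 10, 30)
    der <- ref + stats::rnorm(m)
    pr <- rr_pair(ref, der)
    got <- wilcoxon_signed_rank(pr)
    want <- stats::wilcox.test(der, ref, paired = TRUE, exact = TRUE)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
  }
  # large-m path: normal approximation with tie correction
  set.seed(37)
  ref <- stats::runif(40, 10, 30)
  der <- ref + round(stats::rnorm(40), 1)
  keep <- der != ref
  pr <- rr_pair(ref[keep], der[keep])
  got <- wilcoxon_signed_rank(pr)
  want <- stats::wilcox.test(der[keep], ref[keep], paired = TRUE,
                             exact = FALSE, correct = FALSE)
  expect_equal(got$method, "normal approximation")
  expect_equal(got$p, want$p.value, tolerance = 1e-9)
})

test_that("Bland-Altman bias, limits, and coverage", {
  ba1 <- bland_altman(rr_pair(c(10, 11, 12), c(9, 10, 11)))
  expect_equal(ba1$bias, -1)
  expect_equal(ba1$sd, 0)
  expect_equal(c(ba1$loa_lower, ba1$loa_upper), c(-1, -1))
  ba2 <- bland_altman(rr_pair(c(10, 10), c(10, 12)))
  expect_equal(ba2$bias, 1)
  expect_equal(ba2$sd, sqrt(2))
  expect_equal(ba2$loa_lower, 1 - 1.96 * sqrt(2))
  expect_equal(ba2$loa_upper, 1 + 1.96 * sqrt(2))
  # bias identity
  set.seed(41)
  ref <- stats::runif(50, 10, 30)
  der <- pmax(ref + stats::rnorm(50), 0)
  ba3 <- bland_altman(rr_pair(ref, der))
  expect_equal(ba3$bias, mean(der) - mean(ref), tolerance = 1e-12)
  expect_error(bland_altman(rr_pair(10, 12)), "at least 2")
})

test_that("intra- and inter-subject aggregation have the expected shape", {
  tab <- expand.grid(subject = paste0("s", 1:3), window = 1:15,
                     method = c("r_amp", "ppg_am"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(43)
  tab$rr_ref <- stats::runif(nrow(tab), 14, 22)
  tab$rr_est <- pmax(tab$rr_ref + stats::rnorm(nrow(tab)), 0)
  intra <- aggregate_intra(tab)
  expect_equal(nrow(intra), 3 * 2)
  expect_true(all(c("mean_ref", "sd_ref", "mean_est", "sd_est",
                    "p_wilcoxon") %in% names(intra)))
  expect_false(anyNA(intra$p_wilcoxon))
  inter <- aggregate_inter(tab)
  expect_equal(nrow(inter), 15 * 2)
  # hand-checked one-subject example
  small <- data.frame(subject = "s1", window = 1:2, method = "r_amp",
                      rr_ref = c(20, 22), rr_est = c(19, 23))
  ai <- aggregate_intra(small)
  expect_equal(ai$mean_ref, 21)
  expect_equal(ai$sd_ref, sqrt(2), tolerance = 1e-12)
  expect_equal(ai$mean_est, 21)
  expect_equal(ai$sd_est, sqrt(8), tolerance = 1e-12)
  # identical ref/der: Wilcoxon degenerates to p = 1
  same <- data.frame(subject = "s1", window = 1:4, method = "r_amp",
                     rr_ref = c(18, 20, 22, 24), rr_est = c(18, 20, 22, 24))
  expect_equal(suppressWarnings(aggregate_intra(same))$p_wilcoxon, 1)
  expect_error(aggregate_intra(tab[, -4]), "missing column")
})

test_that("overall metrics implement the two-stage average", {
  tab <- expand.grid(subject = paste0("s", 1:4), window = 1:10,
                     method = "r_amp",
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(47)
  tab$rr_ref <- stats::runif(nrow(tab), 12, 25)
  tab$rr_est <- pmax(tab$rr_ref + stats::rnorm(nrow(tab), sd = 2), 0)
  got <- overall_metrics(tab)
  # brute-force re-implementation of "average of intra-subject means then
  # average of inter-subject means"
  two_stage <- function(metric) {
    per <- function(unit) {
      refs <- tapply(tab$rr_ref, tab[[unit]], mean)
      ests <- tapply(tab$rr_est, tab[[unit]], mean)
      metric(as.numeric(refs), as.numeric(ests))
    }
    (per("subject") + per("window")) / 2
  }
  expect_equal(got$mae, two_stage(function(r, e) mean(abs(r - e))),
               tolerance = 1e-12)
  expect_equal(got$rmse, two_stage(function(r, e) sqrt(mean((r - e)^2))),
               tolerance = 1e-12)
  expect_equal(got$mape_pct,
               two_stage(function(r, e) 100 * mean(abs(r - e) / r)),
               tolerance = 1e-12)
  expect_equal(got$rho, two_stage(function(r, e) stats::cor(r, e)),
               tolerance = 1e-12)
  # constant offset: MAE 1 and BA bias +1
  tab$rr_est <- tab$rr_ref + 1
  got1 <- overall_metrics(tab)
  expect_equal(got1$mae, 1, tolerance = 1e-12)
  expect_equal(bland_altman(rr_pair(tab$rr_ref, tab$rr_est))$bias, 1,
               tolerance = 1e-12)
})

test_that("EDR beats PDR in accuracy at matched modulation depths", {
  # trend over seeded ramp records, not per record
  n_rec <- 8
  wins_e <- numeric(0); wins_p <- numeric(0)
  for (s in seq_len(n_rec)) {
    spec <- modulation_spec(120, 300, hr_bpm = 70, rr_bpm = 19,
                            rr_end_bpm = 22, am_depth = 0.15,
                            fm_depth = 0, noise_sd = 0.02, seed = 500 + s)
    rec <- suppressMessages(generate_record(spec))
    truth <- true_rr_windows(spec, segment_windows(120, 30))
    e <- estimate_rr(rec$ecg, "r_amp")$rr_bpm
    p <- estimate_rr(rec$ppg, "am")$rr_bpm
    wins_e <- c(wins_e, mean(abs(e - truth)))
    wins_p <- c(wins_p, mean(abs(p - truth)))
  }
  expect_lte(mean(wins_e), mean(wins_p))
})
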