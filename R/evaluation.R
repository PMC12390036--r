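#' Paired reference/derived respiratory-rate series
#'
#' @param reference Reference RR values (breaths/min, >= 0).
#' @param derived Derived (estimated) RR values, same length.
#' @param label Optional context label (subject or window id).
#' @return An object of class `rr_pair`.
#' @export
rr_pair <- function(reference, derived, label = NULL) {
  if (length(reference) != length(derived)) {
    stop("reference and derived series must have equal length", call. = FALSE)
  }
  if (length(reference) < 1L) stop("empty series", call. = FALSE)
  if (any(reference < 0) || any(derived < 0)) {
    stop("respiratory rates must be non-negative", call. = FALSE)
  }
  structure(list(reference = as.numeric(reference),
                 derived = as.numeric(derived),
                 n = length(reference), label = label),
            class = "rr_pair")
}

#' Mean absolute error
#'
#' `MAE = mean(|f_i - fhat_i|)` in breaths/min, with `f` the reference and
#' `fhat` the derived rate.
#'
#' @param pair An [rr_pair].
#' @return MAE in breaths/min.
#' @export
rr_mae <- function(pair) {
  stopifnot(inherits(pair, "rr_pair"))
  mean(abs(pair$reference - pair$derived))
}

#' Mean absolute percentage error
#'
#' `MAPE = 100 * mean(|f_i - fhat_i| / f_i)` percent. Pairs whose reference
#' rate is zero have no defined percentage error; they are excluded with a
#' warning reporting the count.
#'
#' @param pair An [rr_pair].
#' @return MAPE in percent.
#' @export
rr_mape <- function(pair) {
  stopifnot(inherits(pair, "rr_pair"))
  ok <- pair$reference > 0
  if (!any(ok)) stop("all reference rates are zero; MAPE undefined",
                     call. = FALSE)
  if (any(!ok)) {
    warning(sum(!ok), " zero-reference pair(s) excluded from MAPE",
            call. = FALSE)
  }
  100 * mean(abs(pair$reference[ok] - pair$derived[ok]) / pair$reference[ok])
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((f_i - fhat_i)^2))` in breaths/min. Always >= MAE.
#'
#' @param pair An [rr_pair].
#' @return RMSE in breaths/min.
#' @export
rr_rmse <- function(pair) {
  stopifnot(inherits(pair, "rr_pair"))
  sqrt(mean((pair$reference - pair$derived)^2))
}

#' Pearson correlation with interpretation band
#'
#' Sample Pearson coefficient between derived and reference rates with a
#' two-sided p-value (t-transform on n - 2 degrees of freedom) and the
#' conventional interpretation band: below 0.3 weak, 0.3-0.7 moderate, above
#' 0.7 strong (band boundaries count as moderate).
#'
#' @param pair An [rr_pair] with `n >= 3` and both series non-constant.
#' @return List with `rho`, `p`, and `class` (`"weak"`, `"moderate"`,
#'   `"strong"`).
#' @export
rr_pearson <- function(pair) {
  stopifnot(inherits(pair, "rr_pair"))
  if (pair$n < 3L) stop("need at least 3 pairs for a correlation",
                        call. = FALSE)
  if (stats::sd(pair$reference) == 0 || stats::sd(pair$derived) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  ct <- stats::cor.test(pair$derived, pair$reference, method = "pearson")
  rho <- unname(ct$estimate)
  cls <- if (abs(rho) < 0.3) "weak"
         else if (abs(rho) <= 0.7) "moderate"
         else "strong"
  list(rho = rho, p = ct$p.value, class = cls)
}

#' Wilcoxon signed-rank test for paired rates
#'
#' Two-sided test on the paired differences. Zero differences are dropped;
#' ties among the absolute differences are mid-ranked. For up to
#' `exact_max` remaining differences the null distribution is computed
#' exactly by enumerating all `2^m` sign assignments (valid under ties);
#' beyond that the normal approximation with tie correction is used.
#'
#' @param pair An [rr_pair].
#' @param exact_max Enumeration cut-over (default 15).
#' @return List with statistic `W` (sum of ranks of positive differences),
#'   `p`, `m` (differences used), and `method`.
#' @export
wilcoxon_signed_rank <- function(pair, exact_max = 15) {
  stopifnot(inherits(pair, "rr_pair"))
  d <- pair$derived - pair$reference
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all paired differences are zero", call. = FALSE)
    return(list(W = 0, p = 1.0, m = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))  # midranks for ties
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (m <= exact_max) {
    # enumerate all sign assignments; null is symmetric about mu even
    # under midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    Wall <- as.numeric(signs %*% r)
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(W = W, p = min(p, 1), m = m, method = method)
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented derived minus reference, so a negative bias means
#' the derived method underestimates. Limits of agreement are
#' `bias +/- 1.96 * sd` with the sample (n - 1) standard deviation.
#'
#' @param pair An [rr_pair] with `n >= 2`.
#' @return An object of class `ba_result`: list with `bias`, `sd`,
#'   `loa_lower`, `loa_upper`, and a data frame `points` of (mean,
#'   difference) scatter pairs for plotting.
#' @export
bland_altman <- function(pair) {
  stopifnot(inherits(pair, "rr_pair"))
  if (pair$n < 2L) stop("need at least 2 pairs for Bland-Altman",
                        call. = FALSE)
  d <- pair$derived - pair$reference
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         points = data.frame(mean = (pair$derived + pair$reference) / 2,
                             difference = d)),
    class = "ba_result"
  )
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("<ba_result> bias %.3f, LoA [%.3f, %.3f] breaths/min (n = %d)\n",
              x$bias, x$loa_lower, x$loa_upper, nrow(x$points)))
  invisible(x)
}

check_rr_table <- function(tab) {
  need <- c("subject", "window", "method", "rr_ref", "rr_est")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("rr table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(tab[need])) stop("rr table contains missing cells", call. = FALSE)
  tab
}

#' Intra-subject aggregation
#'
#' For each subject and method: mean and standard deviation across windows of
#' the reference and derived rates, plus the Wilcoxon signed-rank p-value on
#' the window-paired values (skipped with `NA` and a note for subjects with
#' fewer than 2 windows).
#'
#' @param tab Long-format data frame with columns `subject`, `window`,
#'   `method`, `rr_ref`, `rr_est`.
#' @return Data frame with one row per subject x method.
#' @export
aggregate_intra <- function(tab) {
  tab <- check_rr_table(tab)
  agg_by(tab, "subject")
}

#' Inter-subject aggregation
#'
#' The transpose of [aggregate_intra()]: for each window and method, mean and
#' standard deviation across subjects plus the paired Wilcoxon p-value.
#'
#' @inheritParams aggregate_intra
#' @return Data frame with one row per window x method.
#' @export
aggregate_inter <- function(tab) {
  tab <- check_rr_table(tab)
  agg_by(tab, "window")
}

agg_by <- function(tab, unit) {
  parts <- split(tab, list(tab[[unit]], tab$method), drop = TRUE)
  rows <- lapply(parts, function(g) {
    p <- if (nrow(g) >= 2L) {
      wilcoxon_signed_rank(rr_pair(g$rr_ref, g$rr_est))$p
    } else {
      message("fewer than 2 observations for ", unit, " ", g[[unit]][1],
              " / ", g$method[1], ": Wilcoxon skipped")
      NA_real_
    }
    out <- data.frame(unit = g[[unit]][1], method = g$method[1],
                      mean_ref = mean(g$rr_ref), sd_ref = stats::sd(g$rr_ref),
                      mean_est = mean(g$rr_est), sd_est = stats::sd(g$rr_est),
                      p_wilcoxon = p, n = nrow(g))
    names(out)[1] <- unit
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$method, res[[unit]]), , drop = FALSE]
}

#' Overall performance metrics per method
#'
#' Two-stage summary: metrics (MAE, MAPE, RMSE, Pearson) are computed on the
#' per-subject mean pairs (intra-subject means) and on the per-window mean
#' pairs (inter-subject means), then the two values are averaged.
#'
#' @inheritParams aggregate_intra
#' @return Data frame with one row per method and columns `mae`, `mape_pct`,
#'   `rmse`, `rho`, `rho_p`, `rho_class` (correlation on the pooled
#'   per-subject and per-window mean pairs is reported per stage and
#'   averaged like the error metrics; the class comes from the averaged
#'   `rho`).
#' @export
overall_metrics <- function(tab) {
  tab <- check_rr_table(tab)
  rows <- lapply(split(tab, tab$method), function(g) {
    stage <- function(unit) {
      parts <- split(g, g[[unit]])
      ref <- vapply(parts, function(s) mean(s$rr_ref), numeric(1))
      est <- vapply(parts, function(s) mean(s$rr_est), numeric(1))
      pr <- rr_pair(ref, est)
      pe <- rr_pearson(pr)
      c(mae = rr_mae(pr), mape = rr_mape(pr), rmse = rr_rmse(pr),
        rho = pe$rho, rho_p = pe$p)
    }
    s1 <- stage("subject")
    s2 <- stage("window")
    avg <- (s1 + s2) / 2
    cls <- if (abs(avg["rho"]) < 0.3) "weak"
           else if (abs(avg["rho"]) <= 0.7) "moderate"
           else "strong"
    data.frame(method = g$method[1],
               mae = unname(avg["mae"]), mape_pct = unname(avg["mape"]),
               rmse = unname(avg["rmse"]), rho = unname(avg["rho"]),
               rho_p = unname(avg["rho_p"]), rho_class = cls)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
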