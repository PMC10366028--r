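# Psychometric evaluation: internal consistency, outlier screening,
# correlation tables with FDR control.

#' Cronbach's alpha
#'
#' Internal consistency of an item matrix (participants x items):
#' `alpha = k/(k-1) * (1 - sum(var(item_i)) / var(rowsum))`, with sample
#' (n-1) variances. For the assessment this is computed on the participant x
#' scenario matrix of one measure (13 items for the full task), and values
#' of at least 0.70 are conventionally treated as acceptable.
#'
#' @param M Numeric matrix or data frame, participants in rows, items in
#'   columns; no missing cells.
#' @return Alpha (unitless, at most 1).
#' @export
#' @examples
#' M <- cbind(a = c(2, 4, 1, 5), b = c(1, 3, 2, 4), c = c(3, 5, 2, 4))
#' cronbach_alpha(M) # 0.9
cronbach_alpha <- function(M) {
  M <- as.matrix(M)
  k <- ncol(M)
  n <- nrow(M)
  if (k < 2L) stop_epelir("alpha needs at least 2 items", "epelir_structure_error")
  if (n < 3L) stop_epelir("alpha needs at least 3 participants", "epelir_structure_error")
  if (anyNA(M)) stop_epelir("item matrix contains missing cells", "epelir_structure_error")
  rs <- rowSums(M)
  v_tot <- stats::var(rs)
  if (v_tot <= 0) stop_epelir("zero total-score variance", "epelir_structure_error")
  cm <- colMeans(M)
  v_items <- (colSums(M^2) - n * cm^2) / (n - 1)
  k / (k - 1) * (1 - sum(v_items) / v_tot)
}

#' Bootstrap percentile confidence interval for Cronbach's alpha
#'
#' Participants (rows) are resampled with replacement; the percentile
#' interval of the resampled alphas is reported. A degenerate resample (zero
#' total variance) is redrawn and counted.
#'
#' @param M Item matrix (participants x items).
#' @param n_boot Number of bootstrap resamples (at least 100; default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return An `epeli_reliability`: list with `alpha`, `ci_low`, `ci_high`,
#'   `n_boot`, `conf`, `acceptable` (alpha >= 0.70) and `n_redrawn`.
#' @export
bootstrap_alpha_ci <- function(M, n_boot = 1000L, conf = 0.95, seed = 1L) {
  M <- as.matrix(M)
  if (n_boot < 100L) stop_epelir("n_boot must be >= 100", "epelir_structure_error")
  a <- cronbach_alpha(M)
  n <- nrow(M)
  k <- ncol(M)
  redrawn <- 0L
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Mb <- M[idx, , drop = FALSE]
        rs <- rowSums(Mb)
        v_tot <- stats::var(rs)
        if (v_tot > 0) {
          cm <- colMeans(Mb)
          v_items <- (colSums(Mb^2) - n * cm^2) / (n - 1)
          return(k / (k - 1) * (1 - sum(v_items) / v_tot))
        }
        redrawn <<- redrawn + 1L
      }
    }, 0)
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(alpha = a, ci_low = qs[1L], ci_high = qs[2L],
                 n_boot = as.integer(n_boot), conf = conf,
                 acceptable = a >= 0.70, n_redrawn = redrawn),
            class = "epeli_reliability")
}

#' @export
print.epeli_reliability <- function(x, ...) {
  cat(sprintf("Cronbach's alpha %.3f [%.3f, %.3f] (%d%% bootstrap CI, %d resamples)%s\n",
              x$alpha, x$ci_low, x$ci_high, round(100 * x$conf), x$n_boot,
              if (x$acceptable) " - acceptable (>= 0.70)" else " - below 0.70"))
  invisible(x)
}

#' Alpha-if-item-dropped scan
#'
#' @param M Item matrix with at least 3 items.
#' @return Named numeric vector: alpha recomputed with each single item
#'   removed.
#' @export
alpha_drop_scan <- function(M) {
  M <- as.matrix(M)
  if (ncol(M) < 3L) stop_epelir("drop scan needs at least 3 items", "epelir_structure_error")
  out <- vapply(seq_len(ncol(M)), function(j) cronbach_alpha(M[, -j, drop = FALSE]), 0)
  names(out) <- colnames(M) %||% as.character(seq_len(ncol(M)))
  out
}

#' Greedy reduced-item reliability curve
#'
#' Starting from the full item set, repeatedly removes the item whose removal
#' maximizes alpha, recording alpha at each set size down to `k_min`. Used to
#' ask how short the task could be made while keeping consistency acceptable.
#'
#' @param M Item matrix.
#' @param k_min Smallest item count to retain (>= 2).
#' @return Data frame with columns `k` (items remaining), `dropped` (item
#'   removed at this step, NA for the full set) and `alpha`.
#' @export
alpha_reduced_sets <- function(M, k_min = 2L) {
  M <- as.matrix(M)
  if (k_min < 2L) stop_epelir("k_min must be >= 2", "epelir_structure_error")
  if (is.null(colnames(M))) colnames(M) <- as.character(seq_len(ncol(M)))
  ks <- integer(); dropped <- character(); alphas <- numeric()
  cur <- M
  ks <- ncol(cur); dropped <- NA_character_; alphas <- cronbach_alpha(cur)
  while (ncol(cur) > k_min) {
    scan <- vapply(seq_len(ncol(cur)),
                   function(j) cronbach_alpha(cur[, -j, drop = FALSE]), 0)
    j <- which.max(scan)
    dropped <- c(dropped, colnames(cur)[j])
    cur <- cur[, -j, drop = FALSE]
    ks <- c(ks, ncol(cur))
    alphas <- c(alphas, scan[j])
  }
  fast_df(list(k = ks, dropped = dropped, alpha = alphas))
}

# ---------------------------------------------------------------------------
# Outlier screening

#' Flag univariate outliers beyond k standard deviations
#'
#' Values farther than `k_sd` sample standard deviations from the group mean
#' are flagged. A constant vector flags nothing.
#'
#' @param x Numeric vector (length >= 3).
#' @param k_sd Flagging threshold in SD units (default 3).
#' @return Data frame with columns `index`, `value`, `z` for flagged entries.
#' @export
flag_univariate_outliers <- function(x, k_sd = 3) {
  if (length(x) < 3L) stop_epelir("need at least 3 values", "epelir_structure_error")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(fast_df(list(index = integer(), value = numeric(), z = numeric())))
  }
  z <- (x - mean(x)) / s
  i <- which(abs(z) > k_sd)
  fast_df(list(index = i, value = x[i], z = z[i]))
}

#' Flag multivariate outliers by Mahalanobis distance
#'
#' Squared Mahalanobis distances against the sample mean and covariance are
#' referred to a chi-squared distribution with `ncol(X)` degrees of freedom;
#' participants whose upper-tail probability falls below `p_threshold`
#' (default 0.001) are flagged.
#'
#' @param X Numeric matrix or data frame, participants x measures.
#' @param p_threshold Chi-squared upper-tail cutoff.
#' @return Data frame with columns `index`, `d2`, `p` for flagged rows.
#' @export
flag_multivariate_outliers <- function(X, p_threshold = 0.001) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) {
    stop_epelir("need more participants than measures", "epelir_structure_error")
  }
  S <- stats::cov(X)
  d2 <- tryCatch(stats::mahalanobis(X, colMeans(X), S), error = function(e) {
    stop_epelir("singular covariance matrix", "epelir_structure_error")
  })
  p <- stats::pchisq(d2, df = ncol(X), lower.tail = FALSE)
  i <- which(p < p_threshold)
  fast_df(list(index = i, d2 = d2[i], p = p[i]))
}

#' Full outlier screen over the session-level measures
#'
#' Mirrors the two-stage screen used for the assessment: univariate flags
#' (beyond `k_sd` SDs on any measure) first determine the exclusion list;
#' Mahalanobis screening (chi-squared p below `p_threshold`) is then run on
#' the remaining participants and can add further exclusions.
#'
#' @param scores Data frame of session-level scores with `participant_id`.
#' @param measures Character vector of measure columns to screen.
#' @param k_sd,p_threshold Thresholds for the two stages.
#' @return An `epeli_outlier_report`: list with `univariate` (measure,
#'   participant_id, value, z), `multivariate` (participant_id, d2, p) and
#'   `excluded` (participant ids).
#' @export
screen_outliers <- function(scores, measures = MEASURES, k_sd = 3,
                            p_threshold = 0.001) {
  uni <- do.call(rbind, lapply(measures, function(m) {
    fl <- flag_univariate_outliers(scores[[m]], k_sd)
    if (nrow(fl) == 0L) return(NULL)
    fast_df(list(measure = rep(m, nrow(fl)),
                 participant_id = scores$participant_id[fl$index],
                 value = fl$value, z = fl$z))
  }))
  if (is.null(uni)) {
    uni <- fast_df(list(measure = character(), participant_id = character(),
                        value = numeric(), z = numeric()))
  }
  excluded <- unique(uni$participant_id)
  keep <- !(scores$participant_id %in% excluded)
  multi <- fast_df(list(participant_id = character(), d2 = numeric(),
                        p = numeric()))
  if (sum(keep) > length(measures) + 1L) {
    X <- as.matrix(scores[keep, measures])
    if (!anyNA(X) && all(apply(X, 2L, stats::sd) > 0)) {
      fl <- flag_multivariate_outliers(X, p_threshold)
      if (nrow(fl)) {
        multi <- fast_df(list(
          participant_id = scores$participant_id[keep][fl$index],
          d2 = fl$d2, p = fl$p))
        excluded <- union(excluded, multi$participant_id)
      }
    }
  }
  structure(list(univariate = uni, multivariate = multi, excluded = excluded),
            class = "epeli_outlier_report")
}

#' @export
print.epeli_outlier_report <- function(x, ...) {
  cat(sprintf("Outlier screen: %d univariate flag(s), %d multivariate flag(s), %d participant(s) excluded\n",
              nrow(x$univariate), nrow(x$multivariate), length(x$excluded)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Item matrices and correlation tables

#' Build a participant x scenario item matrix for one measure
#'
#' @param scenario_scores Long data frame of per-scenario scores (as produced
#'   by [simulate_and_score_cohort()] or [write_scores_csv()]), with columns
#'   `participant_id`, `scenario_id` and the measure.
#' @param measure Measure column name.
#' @param drop_incomplete Drop participants with any undefined cell (the
#'   per-scenario efficacies can be undefined when a scenario saw no action
#'   or no movement); the number dropped is recorded in attribute
#'   `n_dropped`.
#' @return Numeric matrix, participants in rows (named), scenarios in
#'   columns.
#' @export
item_matrix <- function(scenario_scores, measure, drop_incomplete = TRUE) {
  pid <- unique(scenario_scores$participant_id)
  sid <- unique(scenario_scores$scenario_id)
  M <- matrix(NA_real_, length(pid), length(sid),
              dimnames = list(pid, sid))
  M[cbind(match(scenario_scores$participant_id, pid),
          match(scenario_scores$scenario_id, sid))] <- scenario_scores[[measure]]
  n_dropped <- 0L
  if (drop_incomplete) {
    ok <- stats::complete.cases(M)
    n_dropped <- sum(!ok)
    M <- M[ok, , drop = FALSE]
  }
  attr(M, "n_dropped") <- n_dropped
  M
}

#' Pearson correlations with Benjamini-Hochberg FDR correction
#'
#' Every x-y pair forms one family; two-sided p values are adjusted over the
#' whole family (step-up false-discovery-rate control) and significance
#' stars are assigned from the adjusted values (`**` p < 0.01, `*` p < 0.05).
#'
#' @param data Data frame holding all variables.
#' @param x_vars,y_vars Character vectors of column names.
#' @return An `epeli_corr_table` data frame: `x`, `y`, `n`, `r`, `p_raw`,
#'   `p_fdr`, `sig`.
#' @export
corr_fdr <- function(data, x_vars, y_vars) {
  pairs <- expand.grid(x = x_vars, y = y_vars, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- data[[pairs$x[i]]]
    y <- data[[pairs$y[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4L) stop_epelir("need n >= 4 per pair", "epelir_structure_error")
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      stop_epelir(sprintf("zero variance in pair (%s, %s)",
                          pairs$x[i], pairs$y[i]), "epelir_structure_error")
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    c(n = sum(ok), r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  p_fdr <- stats::p.adjust(res[, "p"], method = "BH")
  out <- fast_df(list(x = pairs$x, y = pairs$y, n = as.integer(res[, "n"]),
                      r = res[, "r"], p_raw = res[, "p"], p_fdr = p_fdr,
                      sig = ifelse(p_fdr < 0.01, "**",
                                   ifelse(p_fdr < 0.05, "*", ""))))
  class(out) <- c("epeli_corr_table", class(out))
  out
}

#' @export
print.epeli_corr_table <- function(x, ...) {
  cat("Correlation table (Pearson r, BH-FDR adjusted p; ** p<0.01, * p<0.05)\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
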