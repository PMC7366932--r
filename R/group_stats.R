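# Group-level inference: one-way repeated-measures ANOVA with
# Greenhouse-Geisser correction as the omnibus gate, followed by paired
# t-tests of each drug against the first saline session with
# Benjamini-Hochberg FDR correction across drugs.

# Paired t robust to degenerate differences: identical pairs carry no
# evidence (t = 0, p = 1); a constant non-zero shift is unbounded evidence.
safe_paired_t <- function(x, y) {
  d <- x - y
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1e-300)) {
    if (abs(mean(d)) < 1e-12 * (stats::sd(x) + 1)) {
      return(list(t = 0, p = 1))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Rows are subjects (mice), columns are within-subject conditions
#' (treatments). Rows with any missing cell are dropped (listwise deletion)
#' before computing the within-subjects F. The sphericity estimate epsilon
#' is computed from the double-centered sample covariance of the conditions,
#' and both degrees of freedom are multiplied by it; the p-value comes from
#' the F distribution at the fractional df.
#'
#' @param m Numeric matrix, subjects x conditions; NAs allowed (listwise
#'   deletion).
#' @return List of class \code{"rm_anova_gg"}: \code{F}, \code{df1},
#'   \code{df2}, \code{epsilon}, \code{p}, \code{n}, \code{k}.
#' @export
rm_anova_gg <- function(m) {
  m <- as.matrix(m)
  cc <- stats::complete.cases(m)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")

  grand <- mean(m)
  subj_means <- rowMeans(m)
  cond_means <- colMeans(m)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- m - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- if (ss_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else {
    (ss_cond / df1) / (ss_err / df2)
  }

  # Greenhouse-Geisser epsilon from the double-centered covariance
  s <- stats::cov(m)
  cmat <- diag(k) - matrix(1 / k, k, k)
  sc <- cmat %*% s %*% cmat
  tr <- sum(diag(sc))
  eps <- if (tr == 0) 1 else tr^2 / ((k - 1) * sum(sc^2))
  eps <- min(1, max(1 / (k - 1), eps))

  p <- if (is.infinite(f)) 0 else
    stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(list(F = f, df1 = df1 * eps, df2 = df2 * eps, epsilon = eps,
                 p = p, n = n, k = k),
            class = "rm_anova_gg")
}

#' @export
print.rm_anova_gg <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA (Greenhouse-Geisser): F(%.1f, %.1f) = %.2f, eps = %.2f, p = %.4g (n = %d, k = %d)\n",
    x$df1, x$df2, x$F, x$epsilon, x$p, x$n, x$k))
  invisible(x)
}

#' Paired t-tests versus a control condition with FDR correction
#'
#' Each non-control column is compared with the control column by a paired,
#' two-sided t-test on the subjects present in both (overlapping animals
#' only); p-values are Benjamini-Hochberg adjusted across the tested
#' columns. By convention the control is the first saline session.
#'
#' @param m Numeric matrix, subjects x conditions, with column names.
#' @param control Name (or index) of the control column.
#' @param alpha Significance level on adjusted p-values, default 0.05.
#' @return Data frame \code{condition}, \code{n_pairs}, \code{t}, \code{p},
#'   \code{q}, \code{sig}; comparisons with fewer than 2 overlapping
#'   subjects are reported with NA statistics and excluded from the FDR
#'   family.
#' @export
paired_t_fdr <- function(m, control = 1L, alpha = 0.05) {
  m <- as.matrix(m)
  if (is.character(control)) control <- match(control, colnames(m))
  if (is.na(control)) stop("control column not found")
  others <- setdiff(seq_len(ncol(m)), control)
  res <- lapply(others, function(j) {
    ok <- stats::complete.cases(m[, c(control, j)])
    n_pairs <- sum(ok)
    if (n_pairs < 2L) {
      return(data.frame(condition = colnames(m)[j] %||% as.character(j),
                        n_pairs = n_pairs, t = NA_real_, p = NA_real_))
    }
    tt <- safe_paired_t(m[ok, j], m[ok, control])
    data.frame(condition = colnames(m)[j] %||% as.character(j),
               n_pairs = n_pairs, t = tt$t, p = tt$p)
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  tested <- !is.na(res$p)
  res$q[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$sig <- !is.na(res$q) & res$q < alpha
  res
}

#' Stability check between two control (saline) sessions
#'
#' Paired t-test per measure between the two saline sessions, used as a
#' gatekeeping report that repeated vehicle injections do not change any
#' measured parameter.
#'
#' @param saline1,saline2 Numeric vectors (one value per mouse) or matrices
#'   (mice x measures) of the two saline sessions.
#' @return Data frame \code{measure}, \code{n_pairs}, \code{t}, \code{p}.
#' @export
saline_stability_check <- function(saline1, saline2) {
  if (is.vector(saline1)) saline1 <- matrix(saline1, ncol = 1L)
  if (is.vector(saline2)) saline2 <- matrix(saline2, ncol = 1L)
  stopifnot(ncol(saline1) == ncol(saline2))
  nm <- colnames(saline1) %||% paste0("measure", seq_len(ncol(saline1)))
  res <- lapply(seq_len(ncol(saline1)), function(j) {
    ok <- stats::complete.cases(saline1[, j], saline2[, j])
    if (sum(ok) < 2L) {
      return(data.frame(measure = nm[j], n_pairs = sum(ok), t = NA_real_,
                        p = NA_real_))
    }
    tt <- safe_paired_t(saline2[ok, j], saline1[ok, j])
    data.frame(measure = nm[j], n_pairs = sum(ok), t = tt$t, p = tt$p)
  })
  do.call(rbind, res)
}
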