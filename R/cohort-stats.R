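#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their mean
#' rank). Incomplete pairs are dropped (pairwise-complete deletion).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("usage error: vectors differ in length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("usage error: need at least 3 complete pairs", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined metric: zero variance in ranks", call. = FALSE)
  }
  stats::cor(rx, ry)
}

#' Shapiro-Wilk normality test p-value
#'
#' Used as the gate that records why nonparametric (Spearman) correlation is
#' used for the cohort analysis.
#'
#' @param x Numeric vector with 3 to 5000 finite values.
#' @return The p-value of the Shapiro-Wilk test.
#' @export
shapiro_wilk_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("usage error: Shapiro-Wilk needs 3 <= n <= 5000", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("undefined metric: all values identical", call. = FALSE)
  }
  stats::shapiro.test(x)$p.value
}

#' Spearman correlation matrix of cohort measures
#'
#' Computes [spearman_rho()] for every pair of the requested columns.
#' Pairs whose correlation is undefined (too few complete pairs, zero rank
#' variance) become `NA` cells; the diagonal is exactly 1.
#'
#' @param tab Data frame (e.g. a cohort table).
#' @param columns Character vector of column names; defaults to all numeric
#'   columns.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(tab, columns = NULL) {
  tab <- as.data.frame(tab)
  if (is.null(columns)) {
    columns <- names(tab)[vapply(tab, is.numeric, logical(1))]
  }
  stopifnot(length(columns) >= 1L, all(columns %in% names(tab)))
  k <- length(columns)
  m <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  diag(m) <- 1
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        rho <- tryCatch(spearman_rho(tab[[columns[i]]], tab[[columns[j]]]),
                        error = function(e) NA_real_)
        m[i, j] <- rho
        m[j, i] <- rho
      }
    }
  }
  m
}

#' Normality report for cohort columns
#'
#' @param tab Data frame.
#' @param columns Columns to test; defaults to all numeric columns.
#' @return Data frame with `column`, `n`, `shapiro_p`.
#' @export
normality_report <- function(tab, columns = NULL) {
  tab <- as.data.frame(tab)
  if (is.null(columns)) {
    columns <- names(tab)[vapply(tab, is.numeric, logical(1))]
  }
  rows <- lapply(columns, function(cl) {
    x <- tab[[cl]][is.finite(tab[[cl]])]
    p <- tryCatch(shapiro_wilk_p(x), error = function(e) NA_real_)
    data.frame(column = cl, n = length(x), shapiro_p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
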