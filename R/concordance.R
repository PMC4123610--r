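# Method-agreement statistics across density pathways: Pearson correlation
# matrices and paired mean differences with Benjamini-Hochberg FDR control.
# The measure table is long format: subject_id, method, pct_g, gv_ml, fv_ml,
# tv_ml; missingness is handled pairwise-complete, never imputed.

.BD_OUTCOMES <- c("pct_g", "gv_ml", "fv_ml", "tv_ml")

#' Read a long-format measure table
#'
#' @param path CSV with columns `subject_id, method, pct_g, gv_ml, fv_ml,
#'   tv_ml` (one row per subject x method; missing values allowed).
#' @return A validated data.frame.
#' @export
read_measures <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measures(tab)
}

validate_measures <- function(tab) {
  need <- c("subject_id", "method", .BD_OUTCOMES)
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stopf("measure table lacks column(s): %s", paste(miss, collapse = ", "))
  tab
}

# subjects x methods matrix for one outcome
measures_wide <- function(tab, outcome) {
  outcome <- match.arg(outcome, .BD_OUTCOMES)
  tab <- validate_measures(tab)
  subjects <- unique(tab$subject_id)
  methods <- unique(tab$method)
  wide <- matrix(NA_real_, length(subjects), length(methods),
                 dimnames = list(as.character(subjects), methods))
  idx <- cbind(match(tab$subject_id, subjects), match(tab$method, methods))
  wide[idx] <- tab[[outcome]]
  wide
}

#' Pearson correlation matrix between measurement methods
#'
#' One outcome at a time, pairwise-complete over subjects. Cells with fewer
#' than `min_pairs` complete subject pairs are left `NA` (flagged, not
#' fabricated).
#'
#' @param table long-format measure table (see [read_measures()]).
#' @param outcome one of `"pct_g"`, `"gv_ml"`, `"fv_ml"`, `"tv_ml"`.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return Symmetric method x method matrix of Pearson r with unit diagonal.
#' @export
correlation_matrix <- function(table, outcome, min_pairs = 3L) {
  wide <- measures_wide(table, outcome)
  k <- ncol(wide)
  r <- diag(1, k)
  dimnames(r) <- list(colnames(wide), colnames(wide))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- stats::complete.cases(wide[, c(i, j)])
    if (sum(ok) < min_pairs) {
      warnf("fewer than %d complete pairs for %s vs %s; correlation left NA",
            min_pairs, colnames(wide)[i], colnames(wide)[j])
      r[i, j] <- r[j, i] <- NA_real_
    } else {
      r[i, j] <- r[j, i] <- stats::cor(wide[ok, i], wide[ok, j])
    }
  }
  r
}

#' Pairwise mean differences between methods with FDR control
#'
#' Every unordered method pair is compared on the paired per-subject
#' differences (same subjects measured by each method): mean difference, a
#' paired-t 95% confidence interval and p-value, with Benjamini-Hochberg
#' adjustment across the family of pairs. A degenerate pair with zero
#' difference variance gets a point interval at the observed difference. A
#' method with no data is skipped with a warning.
#'
#' @param table long-format measure table.
#' @param outcome one of `"pct_g"`, `"gv_ml"`, `"fv_ml"`, `"tv_ml"`.
#' @param alpha significance level applied to the adjusted p-values.
#' @param conf_level confidence level of the intervals (default 0.95).
#' @return Data.frame of class `pairwise_comparisons`: columns `method_a`,
#'   `method_b`, `n`, `mean_diff`, `ci_low`, `ci_high`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
pairwise_mean_differences <- function(table, outcome, alpha = 0.05,
                                      conf_level = 0.95) {
  wide <- measures_wide(table, outcome)
  methods <- colnames(wide)
  if (length(methods) < 2L) stopf("at least two methods required")
  empty <- colSums(!is.na(wide)) == 0L
  if (any(empty)) {
    warnf("method(s) with no data skipped: %s",
          paste(methods[empty], collapse = ", "))
    wide <- wide[, !empty, drop = FALSE]
    methods <- colnames(wide)
    if (length(methods) < 2L) stopf("fewer than two methods carry data")
  }
  pairs <- utils::combn(methods, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    d <- wide[, a] - wide[, b]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2L) {
      warnf("fewer than 2 complete pairs for %s vs %s; pair skipped", a, b)
      return(NULL)
    }
    m <- mean(d)
    if (stats::sd(d) == 0) {
      ci <- c(m, m)
      p_val <- if (m == 0) 1 else 0
    } else {
      tt <- stats::t.test(d, conf.level = conf_level)
      ci <- as.numeric(tt$conf.int)
      p_val <- tt$p.value
    }
    data.frame(method_a = a, method_b = b, n = n, mean_diff = m,
               ci_low = ci[1L], ci_high = ci[2L], p_value = p_val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no method pair has enough complete data")
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted <= alpha
  attr(out, "outcome") <- outcome
  attr(out, "alpha") <- alpha
  class(out) <- c("pairwise_comparisons", "data.frame")
  out
}

#' @export
print.pairwise_comparisons <- function(x, digits = 4L, ...) {
  cat(sprintf("Pairwise mean differences (%s), BH-FDR at alpha = %g\n",
              attr(x, "outcome"), attr(x, "alpha")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
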