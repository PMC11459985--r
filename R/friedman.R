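# Friedman rank test for paired insert configurations across
# reconstruction settings, and the all-pairs distinguishability rule.

#' Friedman rank sums and Q statistic
#'
#' Rows (reconstruction settings) are ranked ascending with midranks for
#' ties; `R_j` are the column (region) rank sums and
#' `Q = 12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)`.
#'
#' @param x Numeric matrix, `n` settings (rows) by `k` regions (columns),
#'   no missing entries.
#' @return List with `rank_sums` and `Q`.
#' @examples
#' friedman_q(cbind(a = 2:5, b = 1:4))  # column a wins every row
#' @export
friedman_q <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2) stop("friedman requires n >= 2 rows")
  if (k < 2) stop("friedman requires k >= 2 columns")
  if (anyNA(x)) stop("missing entries in the Friedman table")
  r <- t(apply(x, 1, rank))  # midranks for ties
  rj <- colSums(r)
  q <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  list(rank_sums = rj, Q = q)
}

#' p-value for the Friedman Q statistic
#'
#' `method = "chisq"` uses the upper tail of the chi-square distribution
#' with `k - 1` degrees of freedom. `method = "exact"` (k = 2 only) uses
#' the exact permutation null: under H0 each non-tied row independently
#' favours either column, so `|R_1 - R_2|` follows a folded binomial and
#' the p-value is the two-sided sign-test tail. Tied rows contribute zero
#' to the rank-sum difference and drop out of the exact null.
#'
#' @param Q Observed statistic.
#' @param n Number of rows.
#' @param k Number of columns.
#' @param method `"chisq"` or `"exact"`.
#' @param rank_sums Column rank sums (used in exact mode; recovered from
#'   `Q` when absent).
#' @param n_untied Number of rows without a tie (exact mode; defaults to
#'   `n`, i.e. a tie-free table).
#' @return p-value in `[0, 1]`.
#' @examples
#' friedman_p(21, n = 21, k = 2)
#' @export
friedman_p <- function(Q, n, k, method = c("chisq", "exact"),
                       rank_sums = NULL, n_untied = NULL) {
  method <- match.arg(method)
  if (Q < 0) stop("parameter error: Q must be >= 0")
  if (k < 2) stop("parameter error: invalid degrees of freedom")
  if (method == "chisq")
    return(stats::pchisq(Q, df = k - 1, lower.tail = FALSE))
  if (k != 2) stop("exact p-values are implemented for k = 2 only")
  # For k = 2, Q = (R1 - R2)^2 / n. Each of the m non-tied rows favours a
  # column with probability 1/2 under H0 and contributes +/-1 to
  # d = R1 - R2; tied rows (midranks) contribute 0. So |d| = |m - 2w| with
  # w ~ Binomial(m, 1/2): the p-value is the two-sided sign-test tail,
  # enumerating all 2^m equiprobable win patterns in closed form.
  d <- if (!is.null(rank_sums)) abs(diff(rank_sums)) else sqrt(Q * n)
  m <- if (is.null(n_untied)) n else n_untied
  d <- round(d)
  if (m == 0) return(1)
  if (d > m) stop("parameter error: rank-sum difference exceeds row count")
  w_losing <- (m - d) / 2  # wins of the losing column
  min(1, 2 * stats::pbinom(w_losing, m, 0.5))
}

#' Friedman test for one feature and one pair of insert configurations
#'
#' @param x `n x 2` matrix of feature values (settings by regions).
#' @param alpha Significance level.
#' @param method p-value mode, see [friedman_p()].
#' @return List with `rank_sums`, `Q`, `p`, `significant`.
#' @export
friedman_pair_test <- function(x, alpha = 0.05,
                               method = c("chisq", "exact")) {
  method <- match.arg(method)
  fq <- friedman_q(x)
  p <- friedman_p(fq$Q, n = nrow(x), k = ncol(x), method = method,
                  rank_sums = fq$rank_sums,
                  n_untied = sum(x[, 1] != x[, 2]))
  c(fq, list(p = p, significant = p < alpha))
}

#' Select features that distinguish every pair of insert configurations
#'
#' Runs the Friedman test for each stable feature on all `C(4,2) = 6`
#' shape pairs (feature values across the same settings, two regions per
#' test). A feature is distinguishable iff `p < alpha` for every pair.
#'
#' @param stable_features Character vector of feature names to test.
#' @param features Long data.frame with columns `feature`, `shape_id`,
#'   `setting_id`, `family`, `value`.
#' @param alpha Significance level.
#' @param method p-value mode, see [friedman_p()].
#' @return List with `tests` (data.frame: feature, pair, Q, p, significant)
#'   and `distinguishable` (character vector).
#' @export
select_distinguishable <- function(stable_features, features, alpha = 0.05,
                                   method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (length(stable_features) == 0)
    return(list(tests = data.frame(feature = character(), pair = character(),
                                   Q = numeric(), p = numeric(),
                                   significant = logical()),
                distinguishable = character()))
  shapes <- sort(unique(features$shape_id))
  pairs <- utils::combn(shapes, 2)
  rows <- list()
  for (f in stable_features) {
    df <- features[features$feature == f, ]
    wide <- stats::reshape(df[, c("setting_id", "shape_id", "value")],
                           idvar = "setting_id", timevar = "shape_id",
                           direction = "wide")
    for (pc in seq_len(ncol(pairs))) {
      a <- pairs[1, pc]; b <- pairs[2, pc]
      x <- as.matrix(wide[, paste0("value.", c(a, b))])
      if (anyNA(x)) stop("incomplete table for feature ", f)
      ft <- friedman_pair_test(x, alpha = alpha, method = method)
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, pair = sprintf("%dv%d", a, b),
                   Q = ft$Q, p = ft$p, significant = ft$significant,
                   stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  sig_all <- vapply(split(tests$significant, tests$feature), all, TRUE)
  keep <- names(sig_all)[sig_all]
  list(tests = tests,
       distinguishable = stable_features[stable_features %in% keep])
}
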