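#' Tip-link percentage per hair bundle
#'
#' Percentage of intact tip links among the stereocilia pairs scored on each
#' bundle (conventionally 10 adjacent pairs per bundle in a given row pair).
#'
#' @param links_present Intact tip links counted per bundle.
#' @param pairs_scored Pairs scored per bundle (default 10); recycled.
#' @return Numeric vector of percentages (one per bundle).
#' @export
tip_link_percentage <- function(links_present, pairs_scored = 10) {
  pairs_scored <- rep_len(pairs_scored, length(links_present))
  if (any(pairs_scored < 1)) stop("pairs_scored must be >= 1")
  if (any(links_present < 0) || any(links_present > pairs_scored))
    stop("links_present must lie in [0, pairs_scored]")
  100 * links_present / pairs_scored
}

# Mann-Whitney U from midranks: U = (rank sum of x) - n1 (n1 + 1) / 2.
.mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Exact two-sided Mann-Whitney p-value by enumeration
#'
#' Enumerates every assignment of the pooled observations into the two
#' groups (ties handled through midranks, which are invariant across
#' assignments) and reports the two-sided p-value as the proportion of
#' assignments whose U statistic deviates from its null mean
#' `n1 n2 / 2` at least as much as the observed one.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (U of `x`), `p_value`, `n_arrangements`.
#' @export
mann_whitney_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  if (choose(n, n1) > 5e6)
    stop("too many arrangements for exact enumeration; ",
         "use the normal approximation")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  w <- utils::combn(n, n1, FUN = function(i) sum(r[i]))
  u_all <- w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(statistic = u_obs, p_value = p, n_arrangements = length(u_all))
}

# Normal approximation with tie correction (no continuity correction).
.mw_normal <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- .mw_u(x, y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(statistic = u, p_value = 1))
  z <- (u - mu) / sqrt(sig2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Compare two groups of measurements
#'
#' Summary statistics plus a two-group test: Welch's t test (unequal
#' variances) or the Mann-Whitney U test, two-sided. The Mann-Whitney
#' p-value is exact by full enumeration for combined n <= `exact_max`
#' (default 20, midranks for ties); larger samples use the normal
#' approximation with tie correction. Degenerate inputs (zero variance in
#' both groups for the t test) are reported with an NA p-value and a note
#' rather than an error.
#'
#' @param a,b Numeric samples.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param labels Length-2 group labels.
#' @param exact_max Combined-n limit for exact Mann-Whitney enumeration.
#' @return A `ComparisonResult`: list with `labels`, `mean`, `sd`, `n` (per
#'   group), `test`, `statistic`, `p_value`, `note`.
#' @export
compare_groups <- function(a, b, test = c("welch_t", "mann_whitney"),
                           labels = c("A", "B"), exact_max = 20) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  note <- NA_character_
  if (test == "welch_t") {
    res <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) {
      statistic <- NA_real_; p <- NA_real_
      note <- "degenerate input: zero variance in both groups"
    } else {
      statistic <- unname(res$statistic); p <- res$p.value
    }
    test_name <- "Welch t"
  } else {
    if (length(a) + length(b) <= exact_max) {
      res <- mann_whitney_exact(a, b)
      test_name <- "Mann-Whitney U (exact)"
    } else {
      res <- .mw_normal(a, b)
      test_name <- "Mann-Whitney U (normal approximation)"
    }
    statistic <- res$statistic; p <- res$p_value
  }
  structure(list(labels = labels,
                 mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
                 n = c(length(a), length(b)),
                 test = test_name, statistic = statistic, p_value = p,
                 note = note),
            class = "ComparisonResult")
}
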