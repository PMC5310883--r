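# Two-sided Grubbs outlier test.
#
# The most extreme value of a univariate sample is tested against a
# normality null via G = max|x - mean| / sd. The critical value at level
# alpha is
#   G_crit = (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
# with t the upper alpha/(2n) quantile of Student's t on n - 2 degrees of
# freedom.

#' Grubbs critical value
#'
#' @param n Number of observations (>= 3).
#' @param alpha Two-sided significance level in (0, 1).
#' @return The critical value for G = max|x - mean|/sd. Vectorized over
#'   \code{n}.
#' @examples
#' grubbsCritical(10, 0.05)
#' @export
grubbsCritical <- function(n, alpha = 0.05) {
  if (any(!is.finite(n)) || any(n < 3))
    .domainError("Grubbs undefined below 3 observations")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    .domainError("alpha must lie strictly between 0 and 1")
  n <- as.numeric(n)
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Grubbs outlier test
#'
#' Two-sided test on the most extreme value; with \code{iterative = TRUE}
#' (the default) a flagged value is removed and the test repeats on the
#' remainder until nothing is flagged or fewer than 3 observations remain,
#' so several outliers can be reported. Values tied at the maximal
#' deviation are flagged together in the same iteration. Direction is
#' \code{"up"} for values above the iteration's mean, \code{"down"} below.
#'
#' @param values Named or unnamed numeric vector (>= 3 finite values with
#'   positive standard deviation).
#' @param alpha Two-sided significance level.
#' @param iterative Repeat after removing flagged values.
#' @return data.frame with columns \code{term_id} (names of \code{values},
#'   or index as character), \code{value}, \code{G}, \code{critical},
#'   \code{direction}, \code{iteration}; zero rows when nothing is flagged.
#' @export
grubbsTest <- function(values, alpha = 0.05, iterative = TRUE) {
  x <- values
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  if (any(!is.finite(x))) .domainError("values must all be finite")
  if (length(x) < 3L) .domainError("Grubbs undefined below 3 observations")
  if (stats::sd(x) == 0)
    .degenerateError("zero standard deviation: Grubbs test undefined")

  hits <- list()
  iter <- 0L
  while (length(x) >= 3L) {
    s <- stats::sd(x)
    if (s == 0) break
    m <- mean(x)
    dev <- abs(x - m)
    G <- max(dev) / s
    if (G <= grubbsCritical(length(x), alpha)) break
    iter <- iter + 1L
    flag <- which(dev == max(dev))   # ties flagged together
    hits[[iter]] <- data.frame(
      term_id = names(x)[flag],
      value = unname(x[flag]),
      G = G,
      critical = grubbsCritical(length(x), alpha),
      direction = ifelse(x[flag] > m, "up", "down"),
      iteration = iter,
      stringsAsFactors = FALSE)
    x <- x[-flag]
    if (!iterative) break
  }
  if (length(hits) == 0L)
    return(data.frame(term_id = character(), value = numeric(),
                      G = numeric(), critical = numeric(),
                      direction = character(), iteration = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
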