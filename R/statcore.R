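#' Upper-tail binomial probability
#'
#' Computes \eqn{P(X \ge k)} for \eqn{X \sim Binomial(n, p)}, the one-sided
#' p-value of observing at least \code{k} successes in \code{n} trials. This
#' is the test used for the first-acceptor-site preference of trans-splice
#' acceptor sites and for stage-1 local motif enrichment against the
#' intergenic background.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 0).
#' @param p Success probability in [0, 1].
#' @return The upper-tail probability, a single numeric in [0, 1].
#' @examples
#' binomUpperTail(2, 3, 0.5)  # 0.5
#' binomUpperTail(0, 10, 0.3) # 1
#' @export
binomUpperTail <- function(k, n, p) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p) == 1L)
  if (is.na(k) || is.na(n) || is.na(p) || k < 0 || n < 0 || k > n ||
      p < 0 || p > 1)
    stop("binomUpperTail: need 0 <= k <= n and 0 <= p <= 1")
  if (k == 0) return(1)
  # P(X >= k) = P(X > k - 1); pbinom works in log space internally
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' One-sided Fisher's exact test (enrichment direction)
#'
#' Upper-tail hypergeometric probability for a 2x2 table given in the
#' (N, C, R, x) parameterization used for stage-2 local motif enrichment:
#' N sequences in total (target + control), C of them carrying the motif in
#' the window, R target sequences, and x target sequences carrying the motif
#' in the window. The p-value is \eqn{\sum_{j \ge x} P(j)} over the
#' hypergeometric pmf with those margins.
#'
#' @param N Total number of target + control sequences.
#' @param C Total number of sequences with the motif in the window.
#' @param R Number of target sequences.
#' @param x Number of target sequences with the motif in the window.
#' @return One-sided p-value.
#' @examples
#' fisherOneSided(4, 2, 2, 2) # 1/6
#' @export
fisherOneSided <- function(N, C, R, x) {
  stopifnot(length(N) == 1L, length(C) == 1L, length(R) == 1L,
            length(x) == 1L)
  if (C > N || R > N || x > min(C, R) || x < max(0, C + R - N))
    stop("fisherOneSided: table margins violated: need max(0, C+R-N) <= x <= min(C, R)")
  if (C == 0 || C == N) return(1)
  # X ~ Hypergeometric(white = C, black = N - C, drawn = R)
  stats::phyper(x - 1, m = C, n = N - C, k = R, lower.tail = FALSE)
}

# Midranks of the pooled sample, returned split into the two groups.
.pooledRanks <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  list(rx = r[seq_along(x)], ry = r[length(x) + seq_along(y)])
}

# U statistic of x relative to y from pooled midranks.
.uStat <- function(rx, nx, ny) {
  sum(rx) - nx * (nx + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. For small problems
#' (\code{length(x) + length(y) <= exactLimit}) the p-value is computed by
#' complete enumeration of all group assignments of the pooled midranks, so
#' it is exact even in the presence of ties. Larger problems use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' \code{alternative = "greater"} tests whether \code{x} tends to exceed
#' \code{y}.
#'
#' @param x,y Numeric sample vectors.
#' @param alternative One of \code{"two.sided"}, \code{"greater"},
#'   \code{"less"}.
#' @param exactLimit Use exact enumeration when
#'   \code{length(x) + length(y)} is at most this; default 16.
#' @return A list with elements \code{U} (the U statistic for \code{x})
#'   and \code{p.value}.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4), alternative = "less")$p.value # 1/6
#' @export
mannWhitneyU <- function(x, y,
                         alternative = c("two.sided", "greater", "less"),
                         exactLimit = 16L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("mannWhitneyU: both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  rr <- .pooledRanks(x, y)
  U <- .uStat(rr$rx, nx, ny)

  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p.value = 1))

  if (nx + ny <= exactLimit) {
    # enumerate all choose(nx+ny, nx) assignments of pooled ranks to group x
    r <- rank(pooled, ties.method = "average")
    idx <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    pGreater <- mean(us >= U)
    pLess <- mean(us <= U)
    p <- switch(alternative,
                greater = pGreater,
                less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
    return(list(U = U, p.value = p))
  }

  # normal approximation, tie-corrected variance, continuity correction
  n <- nx + ny
  r <- rank(pooled, ties.method = "average")
  ties <- table(r)
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  sigma <- sqrt(sigma2)
  z <- U - mu
  p <- switch(alternative,
              greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
              less = stats::pnorm((z + 0.5) / sigma),
              two.sided = {
                zc <- (abs(z) - 0.5) / sigma
                min(1, 2 * stats::pnorm(zc, lower.tail = FALSE))
              })
  list(U = U, p.value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment applied to one batch of tests
#' (one batch = one content spec across windows, or one motif across
#' windows, etc.).
#'
#' @param p Numeric vector of p-values in [0, 1]; NAs are passed through.
#' @return Vector of BH-adjusted values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("bhAdjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
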