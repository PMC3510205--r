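#' Spearman correlation with a Fisher-transform confidence interval
#'
#' Computes Spearman's rank correlation (average ranks for ties), a
#' confidence interval obtained by Fisher z-transformation
#' (`atanh(rho) +/- z * 1/sqrt(n - 3)`, back-transformed), and a two-sided
#' p-value from the normal approximation on the transformed scale. This is
#' the statistic used to report reproducibility of per-gene quantification
#' between replicate libraries and the log-linear association between
#' transcription frequency and maximum coverage depth.
#'
#' @param x,y Paired numeric vectors (length >= 4, finite).
#' @param level Confidence level, default 0.95.
#' @return A list with elements `rho`, `n`, `ciLow`, `ciHigh`, `p`. When one
#'   of the inputs is constant, `rho` and the interval are `NA`.
#' @examples
#' spearmanCI(1:10, (1:10)^2)  # rho = 1 under any monotone transform
#' @export
spearmanCI <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired finite values")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, n = n, ciLow = NA_real_, ciHigh = NA_real_,
                p = NA_real_))
  rho <- stats::cor(x, y, method = "spearman")
  se <- 1 / sqrt(n - 3)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  if (abs(rho) >= 1) {
    ci <- c(NA_real_, NA_real_)
    p <- 0
  } else {
    z <- atanh(rho)
    ci <- tanh(c(z - zc * se, z + zc * se))
    p <- 2 * stats::pnorm(-abs(z) / se)
  }
  list(rho = rho, n = n, ciLow = ci[1], ciHigh = ci[2], p = p)
}

#' Log odds ratio of a 2x2 contingency table
#'
#' Natural-log odds ratio `log(a*d / (b*c))` with optional Haldane
#' correction: when any cell is zero, 0.5 is added to all four cells before
#' taking the ratio. The standard error is `sqrt(sum(1/cell))` and the
#' p-value comes from the Wald z statistic.
#'
#' @param a,b,c,d Non-negative counts. `a`/`b` are the "exposed" successes
#'   and failures, `c`/`d` the reference ones, so a positive log odds means
#'   enrichment in the first row.
#' @param haldane Apply the 0.5 correction when a cell is zero (default TRUE).
#' @return A list with `logOdds`, `se`, `p` and the (possibly corrected)
#'   `table`.
#' @examples
#' logOdds(20, 5, 5, 20)$logOdds  # log(16)
#' @export
logOdds <- function(a, b, c, d, haldane = TRUE) {
  cells <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
             d = as.numeric(d))
  if (any(cells < 0)) stop("counts must be non-negative")
  if (sum(cells) == 0) stop("all-zero table")
  if (haldane && any(cells == 0)) cells <- cells + 0.5
  lor <- log(cells["a"] * cells["d"] / (cells["b"] * cells["c"]))
  se <- sqrt(sum(1 / cells))
  p <- 2 * stats::pnorm(-abs(lor / se))
  list(logOdds = unname(lor), se = unname(se), p = unname(p),
       table = unname(cells))
}

# JT statistic: concordant cross-pairs over ordered groups, ties count 1/2
.jtStatistic <- function(groups) {
  jt <- 0
  k <- length(groups)
  for (i in seq_len(k - 1L)) {
    xi <- groups[[i]]
    for (j in (i + 1L):k) {
      xj <- groups[[j]]
      for (v in xi) jt <- jt + sum(xj > v) + 0.5 * sum(xj == v)
    }
  }
  jt
}

# enumerate all distinct assignments of pooled values to the group-size
# pattern and return the exact JT distribution (small n only)
.jtExactDistribution <- function(values, sizes) {
  out <- numeric(0)
  recurse <- function(remaining, gi, acc) {
    if (gi > length(sizes)) {
      out[[length(out) + 1L]] <<- .jtStatistic(acc)
      return(invisible(NULL))
    }
    idx <- utils::combn(length(remaining), sizes[gi], simplify = FALSE)
    for (sel in idx) {
      recurse(remaining[-sel], gi + 1L, c(acc, list(remaining[sel])))
    }
    invisible(NULL)
  }
  recurse(values, 1L, list())
  unlist(out)
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' The statistic is the sum over all ordered pairs of groups of Mann-Whitney
#' counts (pairs where the later group's value exceeds the earlier group's;
#' ties count one half). Inference uses the normal approximation with the
#' tie-adjusted variance; `exact = TRUE` enumerates the permutation
#' distribution instead (only feasible for small samples, used for
#' validation).
#'
#' @param groups A list of numeric vectors in increasing hypothesised order.
#' @param alternative `"two.sided"`, `"increasing"` (later groups larger) or
#'   `"decreasing"`.
#' @param exact Use the exhaustive permutation distribution (default FALSE).
#' @return A list with `JT`, `z`, `p`, `n` and `alternative`. When every
#'   observation is tied the variance is zero; `z` is reported as 0 with a
#'   one-sided p of 0.5 (two-sided 1).
#' @examples
#' jonckheereTest(list(c(1, 2), c(3, 4)), alternative = "increasing",
#'                exact = TRUE)
#' @export
jonckheereTest <- function(groups,
                           alternative = c("two.sided", "increasing",
                                           "decreasing"),
                           exact = FALSE) {
  alternative <- match.arg(alternative)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  jt <- .jtStatistic(groups)
  ni <- lengths(groups)
  n <- sum(ni)
  pooled <- unlist(groups)

  if (exact) {
    dist <- .jtExactDistribution(pooled, ni)
    p <- switch(alternative,
      increasing = mean(dist >= jt),
      decreasing = mean(dist <= jt),
      two.sided = min(1, 2 * min(mean(dist >= jt), mean(dist <= jt))))
    return(list(JT = jt, z = NA_real_, p = p, n = n,
                alternative = alternative, exact = TRUE))
  }

  mu <- (n^2 - sum(ni^2)) / 4
  tj <- table(pooled)
  t1 <- n * (n - 1) * (2 * n + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
        sum(tj * (tj - 1) * (2 * tj + 5))
  t2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  t3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  v <- t1 / 72
  if (n > 2) v <- v + t2 / (36 * n * (n - 1) * (n - 2))
  v <- v + t3 / (8 * n * (n - 1))
  if (v <= 0) {
    z <- 0
    p <- if (alternative == "two.sided") 1 else 0.5
  } else {
    z <- (jt - mu) / sqrt(v)
    p <- switch(alternative,
      increasing = stats::pnorm(z, lower.tail = FALSE),
      decreasing = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(-abs(z)))
  }
  list(JT = jt, z = z, p = p, n = n, alternative = alternative,
       exact = FALSE)
}

# tie-corrected Kruskal-Wallis H for a list of groups
.kwStatistic <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) 0 else h / corr
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k-1 degrees
#' of freedom (delegating to [stats::kruskal.test()]); `exact = TRUE`
#' computes the permutation p-value by exhaustive enumeration of group
#' assignments (small samples only, used for validation). When every
#' observation is identical, H is 0 and p is 1.
#'
#' @param groups A list of numeric vectors (>= 2 groups).
#' @param exact Use exhaustive permutation inference (default FALSE).
#' @return A list with `H`, `df`, `p` and `n`.
#' @examples
#' kruskalWallisTest(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskalWallisTest <- function(groups, exact = FALSE) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  x <- unlist(groups)
  if (length(x) < 2L) stop("need at least 2 observations")
  df <- length(groups) - 1L
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = df, p = 1, n = length(x)))
  if (exact) {
    h <- .kwStatistic(groups)
    sizes <- lengths(groups)
    hs <- numeric(0)
    recurse <- function(remaining, gi, acc) {
      if (gi > length(sizes)) {
        hs[[length(hs) + 1L]] <<- .kwStatistic(acc)
        return(invisible(NULL))
      }
      for (sel in utils::combn(length(remaining), sizes[gi],
                               simplify = FALSE)) {
        recurse(remaining[-sel], gi + 1L, c(acc, list(remaining[sel])))
      }
      invisible(NULL)
    }
    recurse(x, 1L, list())
    hs <- unlist(hs)
    return(list(H = h, df = df, p = mean(hs >= h - 1e-12), n = length(x)))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(x))
}

#' Trimmed mean with symmetric ceiling-rule trimming
#'
#' Removes `ceiling(trim * n)` observations from each tail before averaging.
#' The ceiling rule is pinned down explicitly because a "5% trimmed mean" is
#' ambiguous for small n; with `trim = 0` this is the plain mean.
#'
#' @param x Numeric vector.
#' @param trim Fraction to remove from each tail, in [0, 0.5).
#' @return The trimmed mean, or `NA` for an empty vector.
#' @examples
#' trimmedMean(1:20, 0.05)  # drops 1 and 20 -> 10.5
#' @export
trimmedMean <- function(x, trim = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  k <- ceiling(trim * n)
  if (2 * k >= n) return(stats::median(x))
  mean(sort(x)[(k + 1L):(n - k)])
}
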