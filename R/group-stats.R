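# Two-group comparison of component scores: rank-sum tests (exact by
# enumeration for small untied samples, tie-corrected normal approximation
# otherwise), leave-one-out LDA with ROC AUC, covariate checks, and median
# expression maps.

#' Two-sided Mann-Whitney rank-sum test
#'
#' Independent two-sample rank-sum test of a location shift. For
#' \eqn{n_1 + n_2 \le 12} without ties the p-value is exact, by full
#' enumeration of the \eqn{\binom{N}{n_1}} equally likely rank
#' assignments (the null U distribution is symmetric, so the two-sided
#' p is \eqn{P(|U - n_1 n_2/2| \ge |u - n_1 n_2/2|)}). Otherwise a
#' normal approximation is used, with tie-corrected variance, continuity
#' correction, and an Edgeworth term for the (negative) excess kurtosis
#' of the null U distribution; for untied samples with at least 3 per
#' group and 9 or more in total, the two routes agree within 0.01 (the
#' exact route is authoritative below that).
#'
#' @param x,y numeric score vectors of the two groups (both non-empty,
#'   at least 2 observations in total).
#' @return list with \code{statistic} (U for the first sample),
#'   \code{p.value}, and \code{method} ("exact" or "normal").
#' @export
rankSumTest <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || length(x) + length(y) < 2L)
    stop("need non-empty samples with at least 2 observations in total")
  if (any(!is.finite(c(x, y)))) stop("non-finite observations")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  mu <- n1 * n2 / 2
  if (N <= 12L && !ties) {
    sets <- utils::combn(N, n1)
    Uall <- colSums(matrix(seq_len(N)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    tab <- table(r)
    tieTerm <- sum(tab ^ 3 - tab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = U, p.value = 1, method = "normal"))
    # null U distribution is symmetric about mu (exchangeability), so the
    # two-sided p is twice the lower-tail cdf at min(U, n1*n2 - U);
    # Edgeworth term uses the untied excess kurtosis of U
    e4 <- -(6 / 5) * (n1 ^ 2 + n2 ^ 2 + n1 * n2 + N) / (n1 * n2 * (N + 1))
    z <- (min(U, n1 * n2 - U) + 0.5 - mu) / sqrt(sigma2)
    cdf <- stats::pnorm(z) - e4 / 24 * (z ^ 3 - 3 * z) * stats::dnorm(z)
    # the expansion is invalid deep in the tail, where it can undershoot
    # zero; fall back to the plain normal cdf there
    if (cdf <= 0) cdf <- stats::pnorm(z)
    p <- min(1, 2 * cdf)
    method <- "normal"
  }
  list(statistic = U, p.value = p, method = method)
}

#' Leave-one-out linear discriminant values
#'
#' For each subject, a two-class LDA with pooled within-group covariance
#' and empirical class priors is fitted on the other n-1 subjects
#' (closed form), and the held-out subject's linear discriminant value,
#' signed toward the second group level, is returned. Feeding these
#' threshold-free values to [aucStatistic()] gives the cross-validated
#' ROC AUC.
#'
#' @param S n x K matrix of component scores (or a vector for K = 1).
#' @param labels a [GroupLabels-class] aligned with the rows of S.
#' @return length-n numeric held-out discriminant values.
#' @export
ldaLooScores <- function(S, labels) {
  stopifnot(is(labels, "GroupLabels"))
  S <- as.matrix(S)
  g <- labels@group
  n <- nrow(S); K <- ncol(S)
  if (length(g) != n) stop("labels must align with score rows")
  if (min(table(g)) < K + 2L)
    stop("need at least K + 2 subjects per group; try fewer components")
  lev <- levels(g)
  out <- numeric(n)
  for (i in seq_len(n)) {
    Str <- S[-i, , drop = FALSE]
    gtr <- g[-i]
    X1 <- Str[gtr == lev[1L], , drop = FALSE]
    X2 <- Str[gtr == lev[2L], , drop = FALSE]
    n1 <- nrow(X1); n2 <- nrow(X2)
    mu1 <- colMeans(X1); mu2 <- colMeans(X2)
    W <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
    w <- tryCatch(solve(W, mu2 - mu1),
                  error = function(e)
                    stop("singular pooled covariance; try fewer components"))
    out[i] <- sum((S[i, ] - (mu1 + mu2) / 2) * w) + log(n2 / n1)
  }
  out
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen subject of the second group level
#' (the "positive" class) outranks a randomly chosen subject of the first,
#' with ties counted one half; computed by the midrank formula, which
#' equals concordant-pair counting.
#'
#' @param values per-subject statistic (larger = more positive-like).
#' @param labels a [GroupLabels-class]; the second factor level is the
#'   positive class.
#' @return AUC in \[0, 1\].
#' @export
aucStatistic <- function(values, labels) {
  stopifnot(is(labels, "GroupLabels"))
  g <- labels@group
  if (length(values) != length(g)) stop("values must align with labels")
  pos <- g == levels(g)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both groups must be present")
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Median expression map of a component
#'
#' The group's median score times the component function: the node map a
#' "typical" member of that group adds to the mean connectivity map.
#'
#' @param pc a [SmoothPC-class].
#' @param labels a [GroupLabels-class] aligned with the component scores.
#' @param group which group level.
#' @return length-m node map \code{median(s\[group\]) * f}.
#' @export
medianExpressionMap <- function(pc, labels, group) {
  stopifnot(is(pc, "SmoothPC"), is(labels, "GroupLabels"))
  sel <- labels@group == group
  if (!any(sel)) stop(sprintf("group '%s' is empty or absent", group))
  stats::median(pc@s[sel]) * pc@f
}

#' Pearson correlation of two covariates
#'
#' Product-moment correlation with input checks (equal length >= 3, both
#' non-constant), e.g. between component scores and age.
#'
#' @param a,b numeric vectors.
#' @return correlation in \[-1, 1\].
#' @export
pearsonR <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("need equal-length vectors with at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input has no defined correlation")
  as.numeric(stats::cor(a, b))
}

#' Group-comparison report over fitted components
#'
#' Per component: group score medians, rank-sum U and p with a flag at the
#' chosen significance level; overall leave-one-out LDA AUC over all K
#' score columns; optional covariate checks (sex rank-sum p per component,
#' age Pearson correlation per component).
#'
#' @param comps list of [SmoothPC-class] from [sfpca()], or a list with a
#'   \code{scores} matrix (the multivariate baseline).
#' @param labels a [GroupLabels-class].
#' @param alpha significance threshold for the flag (default 0.01).
#' @return list with \code{perComponent} (data.frame), \code{auc},
#'   \code{loo} (discriminant values), and \code{covariates} (data.frame
#'   or NULL).
#' @export
groupComparison <- function(comps, labels, alpha = 0.01) {
  stopifnot(is(labels, "GroupLabels"))
  S <- if (!is.null(comps$scores)) as.matrix(comps$scores)
       else do.call(cbind, lapply(comps, componentScores))
  g <- labels@group
  lev <- levels(g)
  per <- do.call(rbind, lapply(seq_len(ncol(S)), function(k) {
    ts <- rankSumTest(S[g == lev[1L], k], S[g == lev[2L], k])
    data.frame(component = k,
               median1 = stats::median(S[g == lev[1L], k]),
               median2 = stats::median(S[g == lev[2L], k]),
               U = ts$statistic, p = ts$p.value,
               significant = ts$p.value < alpha)
  }))
  loo <- ldaLooScores(S, labels)
  covariates <- NULL
  if (length(labels@sex) || length(labels@age)) {
    covariates <- do.call(rbind, lapply(seq_len(ncol(S)), function(k) {
      pSex <- if (length(labels@sex) && nlevels(labels@sex) == 2L) {
        sl <- levels(labels@sex)
        rankSumTest(S[labels@sex == sl[1L], k],
                    S[labels@sex == sl[2L], k])$p.value
      } else NA_real_
      rAge <- if (length(labels@age)) pearsonR(S[, k], labels@age)
              else NA_real_
      data.frame(component = k, sexP = pSex, ageR = rAge)
    }))
  }
  list(perComponent = per, auc = aucStatistic(loo, labels),
       loo = loo, covariates = covariates)
}
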