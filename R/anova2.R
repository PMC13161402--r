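# Two-factor fixed-effects ANOVA engine shared by the selectivity scan and
# the omega-squared PEV time course.
#
# The factor labels are constant across time bins, so the model matrices
# (and their QR decompositions) are computed once and applied to the whole
# trials x bins rate matrix; residual sums of squares per bin then come from
# a handful of dense matrix products.  Sums of squares are type II
# (SS(A | B), SS(B | A), SS(AB | A + B)), appropriate for the mildly
# unbalanced cell counts that error trials induce; with balanced cells they
# coincide with the classical sequential decomposition.

#' Two-factor ANOVA decomposition for one or many response vectors
#'
#' @param y numeric vector (one response) or matrix with one column per time
#'   bin (trials in rows).
#' @param a,b factor labels (e.g. numerosity and format), length = number of
#'   trials.
#' @param type `2` (default) or `1` (sequential, a-then-b).
#' @return object of class `anova_decomposition`: list with `ss` (matrix
#'   3 x bins; rows number/format/interaction -- named for the canonical
#'   use, but valid for any two factors), `df` (named vector with
#'   `df_error`), `ss_total`, `ss_error`, `ms_error`, `F`, `p` (3 x bins),
#'   `n`.
#' @export
anova2_decomposition <- function(y, a, b, type = 2) {
  Y <- as.matrix(y)
  fa <- factor(a)
  fb <- factor(b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors need at least 2 levels")
  if (nrow(Y) != length(fa) || length(fa) != length(fb))
    stop("y, a, b must agree in length")
  cells <- table(fa, fb)
  if (any(cells == 0))
    stop("empty factor cells: two-factor ANOVA with interaction undefined")
  n <- nrow(Y)

  rss <- function(X) {
    q <- qr(X)
    r <- qr.resid(q, Y)
    colSums(r^2)
  }
  one <- matrix(1, n, 1)
  XA <- stats::model.matrix(~fa)
  XB <- stats::model.matrix(~fb)
  XAB <- stats::model.matrix(~fa + fb)
  XF <- stats::model.matrix(~fa * fb)

  rss1 <- rss(one); rssA <- rss(XA); rssB <- rss(XB)
  rssAB <- rss(XAB); rssF <- rss(XF)

  if (type == 2) {
    ssA <- pmax(0, rssB - rssAB)
    ssB <- pmax(0, rssA - rssAB)
  } else {
    ssA <- pmax(0, rss1 - rssA)
    ssB <- pmax(0, rssA - rssAB)
  }
  ssI <- pmax(0, rssAB - rssF)
  ss_err <- rssF
  ss_tot <- rss1

  dfA <- nlevels(fa) - 1
  dfB <- nlevels(fb) - 1
  dfI <- dfA * dfB
  df_err <- n - qr(XF)$rank
  if (df_err <= 0) stop("no residual degrees of freedom")
  ms_err <- ss_err / df_err

  ss <- rbind(number = ssA, format = ssB, interaction = ssI)
  dfv <- c(number = dfA, format = dfB, interaction = dfI)
  Fv <- sweep(ss / dfv, 2, ms_err, "/")
  pv <- Fv
  for (k in 1:3) pv[k, ] <- stats::pf(Fv[k, ], dfv[k], df_err,
                                      lower.tail = FALSE)
  structure(list(ss = ss, df = dfv, df_error = df_err, ss_total = ss_tot,
                 ss_error = ss_err, ms_error = ms_err, F = Fv, p = pv,
                 n = n, type = type),
            class = "anova_decomposition")
}

#' Omega-squared percent explained variance
#'
#' Effect size of one ANOVA term as the bias-corrected percentage of total
#' variance it explains:
#' `omega^2 = (SS_term - df * MS_error) / (SS_total + MS_error) * 100`.
#' Under the null the expectation is ~0 and small negative values are a
#' statistically honest outcome; they are not clipped unless requested.
#'
#' @param dec an [anova2_decomposition()] result.
#' @param factor `"number"`, `"format"` or `"interaction"` (or an index).
#' @param clip if `TRUE`, negative values are clipped to 0.
#' @return omega squared in percent (vector over bins if `dec` was computed
#'   on a matrix).
#' @export
omega_squared <- function(dec, factor = "number", clip = FALSE) {
  stopifnot(inherits(dec, "anova_decomposition"))
  if (any(dec$ms_error < 0)) stop("MS_error must be >= 0")
  denom <- dec$ss_total + dec$ms_error
  if (any(denom <= 0)) stop("zero total variance: omega^2 undefined")
  k <- if (is.character(factor)) match.arg(factor, rownames(dec$ss))
       else rownames(dec$ss)[factor]
  w <- (dec$ss[k, ] - dec$df[[k]] * dec$ms_error) / denom * 100
  if (clip) w <- pmax(0, w)
  unname(w)
}
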