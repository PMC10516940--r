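## SNP-panel mixture deconvolution. A sorted pool containing a fraction p of
## target cells has expected alternate-allele fraction
##   f_i = p * g_t,i + (1 - p) * g_b,i
## at variant i, where g_t and g_b are the known target/background dosages
## (0, 0.5, 1; equal ploidy, copy-neutral). Only informative variants
## (g_t != g_b) constrain p; p is estimated by binomial maximum likelihood
## over those variants, with a Wald interval from observed Fisher
## information.

#' Expected alternate-allele fraction of a mixture
#'
#' @param p Target-cell fraction in [0, 1].
#' @param gTarget,gBackground Dosages in {0, 0.5, 1} (vectorised).
#' @return `p * gTarget + (1 - p) * gBackground`.
#' @examples
#' expectedAlleleFraction(0.23, 1, 0)   # 0.23
#' @export
expectedAlleleFraction <- function(p, gTarget, gBackground) {
  checkFraction(p, "p")
  if (!all(gTarget %in% c(0, 0.5, 1)) || !all(gBackground %in% c(0, 0.5, 1))) {
    stop("dosages must be 0, 0.5 or 1")
  }
  p * gTarget + (1 - p) * gBackground
}

## Internal: log-likelihood, score and observed information at p.
purityLikelihood <- function(p, gT, gB, alt, ref) {
  eps <- 1e-12
  f <- pmin(pmax(p * gT + (1 - p) * gB, eps), 1 - eps)
  delta <- gT - gB
  ll <- sum(alt * log(f) + ref * log(1 - f))
  score <- sum(delta * (alt / f - ref / (1 - f)))
  info <- sum(delta^2 * (alt / f^2 + ref / (1 - f)^2))
  list(ll = ll, score = score, info = info, f = f)
}

#' Estimate sorted-pool purity from SNP allele counts
#'
#' Maximises the binomial likelihood
#' `prod_i Binom(alt_i | depth_i, p * g_t,i + (1 - p) * g_b,i)` over the
#' informative variants with positive depth. The optimum is located by
#' bounded scalar search on [0, 1] and polished by Newton steps on the score
#' function to tolerance 1e-8; the standard error comes from observed Fisher
#' information and the Wald 95% interval is truncated to [0, 1].
#'
#' @param panel A [GenotypePanel-class].
#' @param counts An [AlleleCounts-class] aligned with the panel (matched by
#'   variant id when ids are shared, by position otherwise).
#' @return A [PurityEstimate-class].
#' @examples
#' panel <- GenotypePanel(c("v1", "v2"), gTarget = c(1, 1), gBackground = c(0, 0))
#' cnt <- AlleleCounts(c("v1", "v2"), refCount = c(77, 70), altCount = c(23, 30))
#' estimatePurity(panel, cnt)
#' @export
estimatePurity <- function(panel, counts) {
  stopifnot(is(panel, "GenotypePanel"), is(counts, "AlleleCounts"))
  if (length(counts@variantId) != length(panel@variantId)) {
    stop("counts must align 1:1 with the panel")
  }
  idx <- seq_along(panel@variantId)
  if (all(counts@variantId %in% panel@variantId)) {
    idx <- match(panel@variantId, counts@variantId)
    if (anyNA(idx)) stop("counts are missing panel variants")
  }
  alt <- as.numeric(counts@altCount[idx])
  ref <- as.numeric(counts@refCount[idx])
  depth <- alt + ref
  info <- isInformative(panel) & depth > 0
  if (!any(info)) {
    stop("no informative variant with positive depth")
  }
  if (sum(depth[info]) == 0) stop("zero total depth at informative variants")
  gT <- panel@gTarget[info]
  gB <- panel@gBackground[info]
  altI <- alt[info]
  refI <- ref[info]

  negll <- function(p) -purityLikelihood(p, gT, gB, altI, refI)$ll
  opt <- optimize(negll, c(0, 1), tol = 1e-9)
  p <- opt$minimum
  ## Newton polish on the score function (guarded to stay in [0, 1])
  for (it in 1:50) {
    lk <- purityLikelihood(p, gT, gB, altI, refI)
    if (lk$info <= 0) break
    step <- lk$score / lk$info
    pNew <- min(max(p + step, 0), 1)
    if (abs(pNew - p) < 1e-12) { p <- pNew; break }
    p <- pNew
    if (abs(step) < 1e-10) break
  }
  ## snap to a boundary when the score still points outward there
  clamped <- FALSE
  for (b in c(0, 1)) {
    if (abs(p - b) < 1e-7) {
      sc <- purityLikelihood(b, gT, gB, altI, refI)$score
      if ((b == 0 && sc <= 0) || (b == 1 && sc >= 0)) {
        p <- b
        clamped <- TRUE
      }
    }
  }
  lk <- purityLikelihood(p, gT, gB, altI, refI)
  se <- if (lk$info > 0) 1 / sqrt(lk$info) else NA_real_
  ciL <- if (is.na(se)) NA_real_ else max(0, p - 1.96 * se)
  ciU <- if (is.na(se)) NA_real_ else min(1, p + 1.96 * se)
  fObs <- ifelse(depth > 0, alt / depth, NA_real_)
  fFit <- expectedAlleleFraction(p, panel@gTarget, panel@gBackground)
  resid <- data.frame(variantId = panel@variantId, informative = isInformative(panel),
                      depth = depth, observed = fObs, fitted = fFit,
                      residual = fObs - fFit, stringsAsFactors = FALSE)
  new("PurityEstimate", pHat = p, se = se, ciLower = ciL, ciUpper = ciU,
      nInformative = as.integer(sum(info)), residuals = resid,
      clamped = clamped, logLik = lk$ll)
}

#' Weighted least-squares purity from depth-free allele fractions
#'
#' Fallback estimator for inputs that carry fractions without read depths:
#' solves `f_i - g_b,i = p * (g_t,i - g_b,i)` by weighted least squares over
#' informative variants, clamped to [0, 1].
#'
#' @param panel A [GenotypePanel-class].
#' @param fractions Observed allele fractions aligned with the panel.
#' @param weights Optional non-negative weights (default equal).
#' @return The clamped point estimate of p.
#' @export
estimatePurityWLS <- function(panel, fractions,
                              weights = rep(1, length(fractions))) {
  stopifnot(is(panel, "GenotypePanel"),
            length(fractions) == length(panel@variantId),
            length(weights) == length(fractions))
  info <- isInformative(panel) & !is.na(fractions)
  if (!any(info)) stop("no informative variant with an observed fraction")
  delta <- (panel@gTarget - panel@gBackground)[info]
  y <- fractions[info] - panel@gBackground[info]
  wgt <- weights[info]
  p <- sum(wgt * delta * y) / sum(wgt * delta^2)
  min(max(p, 0), 1)
}

#' Fold-enrichment report between two purity estimates
#'
#' @param pre,post [PurityEstimate-class] objects for the pre-sort and sorted
#'   pools; `pre` must have positive purity (otherwise enrichment is
#'   undefined).
#' @return An [EnrichmentReport-class] with a delta-method 95% CI on the
#'   ratio.
#' @export
enrichmentReport <- function(pre, post) {
  stopifnot(is(pre, "PurityEstimate"), is(post, "PurityEstimate"))
  if (pre@pHat <= 0) {
    stop("enrichment undefined: pre-sort purity is zero")
  }
  fold <- post@pHat / pre@pHat
  relVar <- 0
  if (!is.na(pre@se) && pre@pHat > 0) relVar <- relVar + (pre@se / pre@pHat)^2
  if (!is.na(post@se) && post@pHat > 0) relVar <- relVar + (post@se / post@pHat)^2
  sdFold <- fold * sqrt(relVar)
  new("EnrichmentReport", foldEnrichment = fold,
      ciLower = max(0, fold - 1.96 * sdFold), ciUpper = fold + 1.96 * sdFold,
      pre = pre, post = post)
}
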