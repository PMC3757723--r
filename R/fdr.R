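#' Benjamini-Hochberg critical p-value
#'
#' Step-up rule over m valid tests: sort the p-values ascending and find
#' the largest \eqn{p_{(i)}} with \eqn{p_{(i)} \le i q / m}. That value
#' is the critical p-value — the highest p-value threshold at which the
#' expected proportion of false positives among surviving tests is q —
#' and every test with \eqn{p \le} critical p survives. Ties share the
#' rank of their last occurrence. When nothing satisfies the rule the
#' critical p-value is 0 and nothing survives.
#'
#' @param pvals numeric vector of p-values in \code{[0, 1]}.
#' @param q target FDR level in \code{(0, 1)}.
#' @return an \linkS4class{FDRResult}.
#' @examples
#' bhCriticalP(c(0.001, 0.02, 0.03, 0.04, 0.2), q = 0.05)
#' @export
bhCriticalP <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) stop("pvals must be nonempty")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(pvals)
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) * q / m)
  critical <- if (length(ok)) ps[max(ok)] else 0
  survivors <- if (critical > 0) pvals <= critical else rep(FALSE, m)
  new("FDRResult", q = q, m = as.integer(m), criticalP = critical,
      nSurviving = as.integer(sum(survivors)), survivors = survivors)
}

#' Analysis mask for voxel-wise statistics
#'
#' All cerebral tissue voxels excluding the brainstem: labels 1 and 2
#' plus a one-voxel shell adjacent to the ventricle, with label 4
#' explicitly excluded.
#'
#' @param template a \linkS4class{PhantomTemplate}.
#' @return logical 3D array.
#' @export
analysisMask <- function(template) {
  lab <- labelVolume(template)
  shell <- dilate6(lab == 3L) & lab != 3L
  (lab %in% c(1L, 2L) | shell) & lab != 4L
}

#' Threshold beta maps at the FDR critical p-value
#'
#' Retains the predictor's beta values where its p-value survives the
#' supplied FDR result; everything else is NA. The FDR result must have
#' been computed from that predictor's valid p-values on the same fit
#' (checked through the valid-test count).
#'
#' @param stats a \linkS4class{StatMapSet}.
#' @param predictor predictor name.
#' @param fdr an \linkS4class{FDRResult} computed from
#'   \code{statMap(stats, predictor, "p")[stats@valid]}.
#' @return list with \code{map} (thresholded beta
#'   \linkS4class{ChangeMap}-like 3D array), \code{survivorMask}
#'   (logical 3D), \code{criticalP}, \code{nSurviving}, \code{peakBeta}
#'   (largest absolute surviving beta, NA when none survive).
#' @export
thresholdMaps <- function(stats, predictor, fdr) {
  p <- statMap(stats, predictor, "p")
  valid <- stats@valid
  if (fdr@m != sum(valid))
    stop("stale FDR result: fdr m = ", fdr@m, " but fit has ",
         sum(valid), " valid tests")
  beta <- statMap(stats, predictor, "beta")
  survivorMask <- array(FALSE, dim = dim(valid))
  if (fdr@criticalP > 0)
    survivorMask[valid] <- p[valid] <= fdr@criticalP
  out <- array(NA_real_, dim = dim(beta))
  out[survivorMask] <- beta[survivorMask]
  list(map = out, survivorMask = survivorMask, criticalP = fdr@criticalP,
       nSurviving = sum(survivorMask),
       peakBeta = if (any(survivorMask)) max(abs(beta[survivorMask])) else NA_real_)
}
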