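#' Shifted Hill regulatory function
#'
#' Sigmoidal multiplier applied to a target's production rate by a regulator at
#' level `A`. It interpolates between 1 (no regulator) and the saturating
#' fold-change `lam`: values of `lam < 1` encode inhibition, `lam > 1`
#' activation.
#'
#' \deqn{H^S(A, A_0, n, \lambda) = \lambda + \frac{1 - \lambda}{1 + (A/A_0)^n}}
#'
#' @param A regulator level (molecules), non-negative; vectorised.
#' @param A0 half-effect threshold (molecules), strictly positive.
#' @param n Hill coefficient, >= 1.
#' @param lam saturating fold-change (dimensionless, > 0).
#' @return dimensionless multiplier bounded between `min(1, lam)` and
#'   `max(1, lam)`; equals `(1 + lam)/2` at `A = A0`.
#' @examples
#' shifted_hill(0, 100, 2, 0.1)    # 1: no regulator
#' shifted_hill(100, 100, 2, 0.1)  # 0.55: half-saturation
#' shifted_hill(1e9, 100, 2, 0.1)  # ~0.1: saturation
#' @export
shifted_hill <- function(A, A0, n, lam) {
  if (any(!is.finite(A)) || any(A < 0)) {
    stop("shifted_hill: regulator level 'A' must be finite and non-negative")
  }
  if (!is.finite(A0) || A0 <= 0) stop("shifted_hill: threshold 'A0' must be > 0")
  if (!is.finite(n) || n < 1) stop("shifted_hill: Hill coefficient 'n' must be >= 1")
  if (!is.finite(lam) || lam <= 0) stop("shifted_hill: fold-change 'lam' must be > 0")
  lam + (1 - lam) / (1 + (A / A0)^n)
}

# Combinatorial microRNA-binding weights for a transcript with `sites` binding
# sites: M_i(u) = C(s, i) (u/u0)^i / (1 + u/u0)^s. Returns the coefficient-
# weighted sum used for translation (l), mRNA degradation (gamma_m) and
# microRNA turnover (gamma_u).
mirna_weighted_sum <- function(u, u0, coef, sites = 6L) {
  stopifnot(length(coef) == sites + 1L, u0 > 0)
  m <- u / u0
  i <- 0:sites
  vapply(m, function(mm) {
    sum(coef * choose(sites, i) * mm^i) / (1 + mm)^sites
  }, numeric(1))
}
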