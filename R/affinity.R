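# Affinity unit utilities for descriptor consumers: Gibbs free energy
# from a dissociation (or, under the competitive-inhibition assumption,
# inhibition) constant, and the pK transform.

#' Gibbs free energy from a binding constant
#'
#' dG = R*T*ln(K) with R = 8.31446 J/(mol*K), reported in kJ/mol.
#' K_i values are treated like K_d (competitive-inhibition assumption).
#'
#' @param K binding constant, molar
#' @param T_kelvin temperature in Kelvin (default 298)
#' @return dG in kJ/mol (vectorized over K)
#' @export
affinityToDeltaG <- function(K, T_kelvin = 298) {
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("binding constant K must be positive and finite")
  }
  if (T_kelvin <= 0) stop("temperature must be positive")
  R <- 8.31446  # J/(mol*K)
  R * T_kelvin * log(K) / 1000
}

#' Negative decadic logarithm of a binding constant (pK)
#'
#' @param K binding constant, molar
#' @return pK = -log10(K)
#' @export
affinityToPK <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("binding constant K must be positive and finite")
  }
  -log10(K)
}
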