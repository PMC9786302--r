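#' Parameters of the empirical quadruplex melting-temperature model
#'
#' The stability of a putative three-tetrad G-quadruplex is scored by an
#' empirical estimate of its melting temperature,
#' \deqn{T_m^{est} = a - b \log_{10}(L_1 L_2 L_3) - d N_b - f (L_b - N_b),}
#' where \eqn{L_1, L_2, L_3} are the three loop lengths (nt), \eqn{N_b} the
#' number of bulges and \eqn{L_b} the total number of bulged residues. The
#' defaults come from linear fits of published melting data for loop-length
#' variants (intercept `a`, slope `b` against the log of the loop-length
#' product) and for bulged variants (`d` per bulge, `f` per bulged residue
#' beyond the first); `d` is the mean of the 12 mM and 60 mM potassium fits
#' (20.5 and 19.4), `f` is common to both. A putative structure is considered
#' stable when `tm_est()` is at or above `threshold`.
#'
#' `tm_est` is a ranking score tied to physically reasonable melting
#' temperatures, not a thermodynamic prediction: high values mean short loops
#' and small or absent bulges.
#'
#' @param a Intercept in degrees Celsius; the score of the minimal
#'   (G3T)3G3 layout with loops (1,1,1) and no bulge.
#' @param b Slope in degrees Celsius per log10 unit of the loop-length
#'   product.
#' @param d Penalty in degrees Celsius per bulge.
#' @param f Penalty in degrees Celsius per bulged residue beyond one per
#'   bulge.
#' @param threshold Stability cutoff in degrees Celsius; structures with
#'   `tm_est() >= threshold` are retained (inclusive comparison, no epsilon).
#'
#' @return A list of class `tm_params` with elements `a`, `b`, `d`, `f`,
#'   `threshold`.
#' @examples
#' tm_params()
#' tm_params(threshold = 60)
#' @export
tm_params <- function(a = 89.9, b = 19.2, d = 20, f = 8.5, threshold = 50) {
  vals <- c(a = a, b = b, d = d, f = f, threshold = threshold)
  if (!all(is.finite(vals))) {
    rlang::abort("all melting-model parameters must be finite numbers")
  }
  structure(as.list(vals), class = "tm_params")
}

#' @export
print.tm_params <- function(x, ...) {
  cat(sprintf(
    "<tm_params> Tm_est = %.1f - %.1f*log10(l1*l2*l3) - %.1f*Nb - %.1f*(Lb-Nb); threshold %.1f degC\n",
    x$a, x$b, x$d, x$f, x$threshold
  ))
  invisible(x)
}

# Salt-specific fits of the bulge penalty, kept for documentation only;
# scoring always uses the merged d and f in tm_params().
tm_bulge_fits <- list(
  k12mM = c(c = 89.9, d = 20.5, f = 8.5),
  k60mM = c(c = 97.8, d = 19.4, f = 8.5)
)

#' Estimated melting temperature of a putative G-quadruplex
#'
#' Evaluates the empirical stability score from the three loop lengths and
#' the bulge burden (see [tm_params()] for the model). Vectorised over all
#' length arguments.
#'
#' @param l1,l2,l3 Loop lengths in nucleotides; each must be at least 1
#'   (a zero-length loop is geometrically impossible in this model and the
#'   logarithm of zero is never evaluated).
#' @param n_bulges Number of bulges (`Nb`), non-negative.
#' @param total_bulged Total bulged residues (`Lb`); must be at least
#'   `n_bulges` (every bulge contains at least one residue).
#' @param params A [tm_params()] object.
#'
#' @return Numeric vector of estimated melting temperatures in degrees
#'   Celsius.
#' @examples
#' tm_est(1, 1, 1)               # 89.9, the model intercept
#' tm_est(7, 7, 7)               # long loops are strongly penalised
#' tm_est(1, 1, 1, n_bulges = 1, total_bulged = 3)
#' @export
tm_est <- function(l1, l2, l3, n_bulges = 0, total_bulged = n_bulges,
                   params = tm_params()) {
  if (any(l1 < 1) || any(l2 < 1) || any(l3 < 1)) {
    rlang::abort("loop lengths must all be >= 1")
  }
  if (any(n_bulges < 0) || any(total_bulged < n_bulges)) {
    rlang::abort("need n_bulges >= 0 and total_bulged >= n_bulges")
  }
  params$a - params$b * log10(l1 * l2 * l3) -
    params$d * n_bulges - params$f * (total_bulged - n_bulges)
}
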