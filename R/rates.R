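#' Fixed-environment rate set
#'
#' Bundles the constant (or period-averaged) parameters of the two-population
#' competition model with horizontal gene transfer: reproduction rates,
#' the 2x2 competition-rate matrix and the gene-transfer balance rate.
#'
#' @param r_A,r_B Reproduction rates of populations A and B (per unit time,
#'   both strictly positive).
#' @param a_AA,a_AB,a_BA,a_BB Within- and between-population competition rates
#'   (per individual per unit time). Strictly positive for raw rate sets; an
#'   `effective` rate set (produced by [effective_rates()]) may carry negative
#'   between-population entries, which is how oscillation-induced mutualism
#'   manifests.
#' @param gamma Gene-transfer balance rate (per individual per unit time).
#'   `gamma > 0` means net conversion of B individuals into A; `gamma = 0` is
#'   balanced transfer. Any real value is allowed.
#' @param effective Logical; marks a rate set whose between-population entries
#'   already absorb the emergent payoffs (exempt from the positivity check on
#'   `a_AB`, `a_BA`).
#'
#' @return An object of class `fixed_rates` (a named list).
#' @examples
#' fixed_rates(r_A = 1.8, r_B = 1, a_AA = 0.1, a_AB = 0.1, a_BA = 0.1, a_BB = 0.1)
#' @export
fixed_rates <- function(r_A, r_B, a_AA, a_AB, a_BA, a_BB, gamma = 0,
                        effective = FALSE) {
  vals <- c(r_A = r_A, r_B = r_B, a_AA = a_AA, a_AB = a_AB,
            a_BA = a_BA, a_BB = a_BB, gamma = gamma)
  if (!all(is.finite(vals)))
    stop("all rate parameters must be finite numbers", call. = FALSE)
  if (r_A <= 0 || r_B <= 0)
    stop("reproduction rates r_A, r_B must be strictly positive", call. = FALSE)
  if (a_AA <= 0 || a_BB <= 0)
    stop("within-population competition rates a_AA, a_BB must be strictly positive",
         call. = FALSE)
  if (!effective && (a_AB <= 0 || a_BA <= 0))
    stop("between-population competition rates a_AB, a_BA must be strictly positive ",
         "(use effective = TRUE for oscillation-adjusted rates)", call. = FALSE)
  structure(
    list(r_A = r_A, r_B = r_B, a_AA = a_AA, a_AB = a_AB, a_BA = a_BA,
         a_BB = a_BB, gamma = gamma, effective = isTRUE(effective)),
    class = "fixed_rates"
  )
}

#' @export
print.fixed_rates <- function(x, ...) {
  cat(if (x$effective) "<effective rates>" else "<fixed rates>", "\n")
  cat(sprintf("  r_A = %g, r_B = %g, gamma = %g\n", x$r_A, x$r_B, x$gamma))
  cat(sprintf("  a = [%g %g; %g %g]\n", x$a_AA, x$a_AB, x$a_BA, x$a_BB))
  invisible(x)
}

#' @export
as.list.fixed_rates <- function(x, ...) {
  x[c("r_A", "r_B", "a_AA", "a_AB", "a_BA", "a_BB", "gamma")]
}

#' Rebuild a rate set from a flat key-value list
#'
#' Inverse of `as.list()` on a `fixed_rates` object; used by the config reader.
#'
#' @param x Named list (or section of a parsed config) with keys `r_A`, `r_B`,
#'   `a_AA`, `a_AB`, `a_BA`, `a_BB` and optionally `gamma`.
#' @return A `fixed_rates` object.
#' @export
rates_from_list <- function(x) {
  allowed <- c("r_A", "r_B", "a_AA", "a_AB", "a_BA", "a_BB", "gamma")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown rate keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(setdiff(allowed, "gamma"), names(x))
  if (length(missing))
    stop("missing rate keys: ", paste(missing, collapse = ", "), call. = FALSE)
  fixed_rates(r_A = x$r_A, r_B = x$r_B, a_AA = x$a_AA, a_AB = x$a_AB,
              a_BA = x$a_BA, a_BB = x$a_BB,
              gamma = if (is.null(x$gamma)) 0 else x$gamma)
}

#' Population state in count and fraction view
#'
#' @param n_A,n_B Non-negative abundances of the two populations.
#' @return A list with `n_A`, `n_B`, total `N`, fractions `p_A`, `p_B` and an
#'   `extinct` flag. At `N = 0` the fraction view is undefined: `p_A`, `p_B`
#'   are `NA` and `extinct` is `TRUE` (the trivial rest point, always unstable
#'   for positive reproduction rates).
#' @export
population_state <- function(n_A, n_B) {
  if (!is.finite(n_A) || !is.finite(n_B) || n_A < 0 || n_B < 0)
    stop("abundances must be finite and non-negative", call. = FALSE)
  N <- n_A + n_B
  if (N == 0) {
    list(n_A = 0, n_B = 0, N = 0, p_A = NA_real_, p_B = NA_real_,
         extinct = TRUE)
  } else {
    list(n_A = n_A, n_B = n_B, N = N, p_A = n_A / N, p_B = n_B / N,
         extinct = FALSE)
  }
}
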