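#' Validate a reaction-time sampler against its analytic distribution
#'
#' Draws `n` reaction times for one reaction of a scheme at a fixed initial
#' separation, using the sampler matching the reaction type (inversion for
#' totally diffusion-controlled pairs, the two-stage scheme for partially
#' controlled pairs, with the effective-distance transform for charged
#' pairs), and compares the empirical conditional CDF of the accepted times
#' with the analytic distribution evaluated at the sampled points.
#'
#' @param table a [build_reaction_table()] result
#' @param a,b reactant species names
#' @param r0 initial separation (nm)
#' @param n number of draws
#' @return list with `ks` (Kolmogorov-Smirnov distance), `accept_frac`,
#'   `p_inf` (analytic asymptotic reaction probability) and `cdf` (tibble
#'   of sampled times with empirical and analytic conditional CDFs)
#' @export
sampler_check <- function(table, a, b, r0, n = 1e5) {
  rx <- reaction_lookup(table, a, b)
  if (is.null(rx)) stop("no reaction for pair ", a, " + ", b)
  charged <- rx$rc != 0
  if (rx$rtype == "totally") {
    r0t <- effective_distance(r0, rx$rc)
    t <- sample_time_total(r0t, rx$Reff, rx$D, n)
    p_inf <- rx$Reff / r0t
    Fcond <- function(tt) erfc((r0t - rx$Reff) / sqrt(4 * rx$D * tt))
  } else {
    t <- sample_time_partial(r0, rx$R, rx$D, rx$kdif, rx$kact, n,
                             charged = charged, rc = rx$rc)
    r0t <- effective_distance(r0, rx$rc)
    p_inf <- rx$Reff / r0t
    Fcond <- function(tt) {
      p_react_partial(r0, rx$R, rx$D, rx$kdif, rx$kact, tt,
                      charged = charged, rc = rx$rc) / p_inf
    }
  }
  acc <- sort(t[is.finite(t)])
  m <- length(acc)
  if (m == 0) stop("no accepted draws; r0 too large for this sample size")
  Fa <- Fcond(acc)
  Fe_hi <- seq_len(m) / m
  Fe_lo <- (seq_len(m) - 1) / m
  ks <- max(pmax(abs(Fe_hi - Fa), abs(Fe_lo - Fa)))
  list(
    ks = ks,
    accept_frac = m / n,
    p_inf = p_inf,
    cdf = tibble::tibble(time_ps = acc, empirical = Fe_hi, analytic = Fa)
  )
}
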