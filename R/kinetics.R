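#' Reaction probability for a totally diffusion-controlled pair
#'
#' Solution of the Smoluchowski equation with an absorbing boundary at the
#' reaction radius: the probability that a pair initially separated by `r0`
#' has reacted by time `t`,
#' \deqn{p(t | r_0) = (R/r_0)\,\mathrm{erfc}\!\left(\frac{r_0 - R}{\sqrt{4 D t}}\right).}
#' The long-time asymptote is `R/r0`.  For charged pairs, pass the
#' Debye-transformed quantities: `r0 = effective_distance(r0, rc)` and
#' `R = Reff` derived from the observed rate constant.
#'
#' @param r0 initial separation (nm); must satisfy `r0 >= R`
#' @param R reaction radius (nm)
#' @param D relative (summed) diffusion coefficient (nm^2/ps)
#' @param t time (ps)
#' @return reaction probability, vectorized over any argument
#' @export
p_react_total <- function(r0, R, D, t) {
  stopifnot(all(R > 0), all(D > 0), all(t >= 0))
  if (any(r0 < R)) {
    stop("r0 < R: pair already in contact; use contact_reaction_prob()")
  }
  out <- (R / r0) * erfc((r0 - R) / sqrt(4 * D * t))
  # t = 0 limit is 0 for r0 > R, 1 at contact
  ifelse(t == 0, as.numeric(r0 == R), out)
}

#' Debye effective distance for a charged pair
#'
#' Maps a physical separation `d` to the effective separation that makes the
#' Coulomb-biased diffusion problem look like free diffusion:
#' \deqn{d_{eff} = -r_c / (1 - e^{r_c/d}) = r_c / (e^{r_c/d} - 1).}
#' The Onsager radius `rc` carries the sign of the charge product: positive
#' for like charges (repulsive, `deff < d`), negative for unlike charges
#' (attractive, `deff > d`); `rc = 0` returns `d` unchanged.
#'
#' @param d physical separation (nm), positive
#' @param rc signed Onsager radius (nm)
#' @return effective separation (nm)
#' @export
effective_distance <- function(d, rc) {
  stopifnot(all(d > 0))
  if (length(rc) == 1 && rc == 0) return(d)
  ifelse(rc == 0, d, rc / expm1(rc / d))
}

#' Sample reaction times for a totally diffusion-controlled pair
#'
#' Inversion sampler for [p_react_total()]: draw U ~ Uniform(0,1); if
#' `U >= R/r0` the pair never reacts (time `Inf`), otherwise
#' \deqn{t = \left(\frac{r_0 - R}{2\sqrt{D}\,\mathrm{erfc}^{-1}(U r_0 / R)}\right)^2.}
#'
#' @inheritParams p_react_total
#' @param n number of independent draws
#' @return numeric vector of `n` reaction times in ps; `Inf` means the pair
#'   escapes and never reacts
#' @export
sample_time_total <- function(r0, R, D, n = 1) {
  stopifnot(r0 >= R, R > 0, D > 0)
  u <- stats::runif(n)
  t <- rep(Inf, n)
  hit <- u < R / r0
  if (r0 == R) {
    t[hit] <- 0
    return(t)
  }
  t[hit] <- ((r0 - R) / (2 * sqrt(D) * erfcinv(u[hit] * r0 / R)))^2
  t
}

#' Reaction probability for a partially diffusion-controlled pair
#'
#' Radiation-boundary-condition solution of the Smoluchowski equation:
#' \deqn{p(t|r_0) = P_0\left[\mathrm{erfc}(y) - e^{x^2+2xy}\,\mathrm{erfc}(x+y)\right]}
#' with \eqn{P_0 = R_{eff}/r_0}, \eqn{R_{eff} = R\,k_{act}/(k_{dif}+k_{act})},
#' \eqn{x = (k_{dif}+k_{act})\sqrt{D t}/(k_{dif} R)} and
#' \eqn{y = (r_0 - R)/\sqrt{4 D t}}.  The exponentially growing term is
#' evaluated through the scaled complementary error function,
#' \eqn{e^{x^2+2xy}\mathrm{erfc}(x+y) = \mathrm{erfcx}(x+y)\,e^{-y^2}},
#' so the expression never overflows.
#'
#' For a charged pair set `charged = TRUE` and supply the signed Onsager
#' radius `rc`: distances are mapped through [effective_distance()] and the
#' neutral machinery is applied to the transformed problem.  In that case
#' `R`, `r0` are the physical quantities and `kdif`, `kact` must be the
#' transformed rates stored in the reaction table
#' (`kdif = 4 pi effective_distance(R, rc) D`).
#'
#' @inheritParams p_react_total
#' @param kdif transport rate constant to encounter (nm^3/ps)
#' @param kact activation rate constant from encounter (nm^3/ps)
#' @param charged logical; apply the effective-distance transform
#' @param rc signed Onsager radius (nm), used when `charged`
#' @return reaction probability, bounded by `Reff/r0`
#' @export
p_react_partial <- function(r0, R, D, kdif, kact, t, charged = FALSE, rc = 0) {
  stopifnot(all(kdif > 0), all(kact > 0), all(t >= 0), all(D > 0))
  if (charged) {
    r0 <- effective_distance(r0, rc)
    R <- effective_distance(R, rc)
  }
  if (any(r0 < R)) stop("r0 < R: pair already in contact")
  P0 <- (R / r0) * kact / (kdif + kact)
  s <- sqrt(4 * D * t)
  x <- (kdif + kact) * sqrt(D * t) / (kdif * R)
  y <- (r0 - R) / s
  p <- P0 * (erfc(y) - erfcx(x + y) * exp(-y^2))
  ifelse(t == 0, 0, pmin(pmax(p, 0), P0))
}

#' Sample the encounter-to-reaction part of a partially controlled pair
#'
#' Starting from contact (`r0 = R`), the probability of eventual reaction is
#' \eqn{k_{act}/(k_{dif}+k_{act})} and the conditional reaction-time CDF is
#' \eqn{1 - e^{x^2}\mathrm{erfc}(x)} with
#' \eqn{x = (k_{dif}+k_{act})\sqrt{D t}/(k_{dif} R)}.  The sampler draws two
#' uniforms U1, U2: if U1 exceeds the acceptance weight the pair never
#' reacts; otherwise Y is drawn half-normal with scale sqrt(2) and
#' \deqn{t = \frac{1}{D}\left(\frac{-R\,k_{dif}\ln U_2}{(k_{dif}+k_{act})\,Y}\right)^2.}
#' The ratio \eqn{-\ln U_2 / Y} of an exponential to a half-normal(sqrt 2)
#' variate has CDF \eqn{1 - e^{z^2}\mathrm{erfc}(z)} exactly, so the sampler
#' is an exact inversion of the contact distribution.
#'
#' @inheritParams p_react_partial
#' @param n number of draws
#' @return reaction times in ps (`Inf` = never)
#' @export
sample_time_from_encounter <- function(kdif, kact, R, D, n = 1) {
  stopifnot(kdif > 0, kact >= 0, R > 0, D > 0)
  t <- rep(Inf, n)
  if (kact == 0) return(t)
  u1 <- stats::runif(n)
  acc <- u1 <= kact / (kdif + kact)
  m <- sum(acc)
  if (m == 0) return(t)
  u2 <- stats::runif(m)
  y <- abs(stats::rnorm(m, sd = sqrt(2)))
  while (any(y == 0)) {
    z <- y == 0
    y[z] <- abs(stats::rnorm(sum(z), sd = sqrt(2)))
  }
  x <- -log(u2) / y
  t[acc] <- (x * kdif * R / (kdif + kact))^2 / D
  t
}

#' Sample reaction times for a partially diffusion-controlled pair
#'
#' Two-stage scheme: stage 1 samples the first-passage time to the reaction
#' radius with [sample_time_total()]; stage 2 samples the
#' encounter-to-reaction time with [sample_time_from_encounter()].  By the
#' strong Markov property the sum is distributed per the radiation-boundary
#' solution sampled by [p_react_partial()] (verified by KS tests).  Charged
#' pairs are handled through the effective-distance transform as in
#' [p_react_partial()].
#'
#' @inheritParams p_react_partial
#' @param n number of draws
#' @return reaction times in ps (`Inf` = never)
#' @export
sample_time_partial <- function(r0, R, D, kdif, kact, n = 1,
                                charged = FALSE, rc = 0) {
  if (charged) {
    r0 <- effective_distance(r0, rc)
    R <- effective_distance(R, rc)
  }
  stopifnot(r0 >= R)
  t1 <- sample_time_total(r0, R, D, n)
  enc <- is.finite(t1)
  t <- rep(Inf, n)
  if (!any(enc)) return(t)
  if (is.infinite(kact)) {
    t[enc] <- t1[enc]
    return(t)
  }
  t2 <- sample_time_from_encounter(kdif, kact, R, D, sum(enc))
  t[enc] <- t1[enc] + t2
  t
}

#' Contact-reaction probability for an overlapping pair
#'
#' When free diffusion of all species over a global step brings a pair
#' inside its reaction radius, the pair reacts with the unsuccessful-
#' encounter probability.  Neutral pairs:
#' \deqn{\wp = \frac{R_s}{R_s + (k_{dif}/k_{act})(R + R_s)},}
#' charged pairs:
#' \deqn{\wp = \frac{e^{-r_c/R} - e^{-r_c/(R+R_s)}}
#'   {e^{-r_c/R} - e^{-r_c/(R+R_s)} - (k_{dif}/k_{act})(1 - e^{-r_c/R})},}
#' where `Rs` is the encounter separation (0.3 nm).  Totally controlled
#' reactions have `kact = Inf` and react with probability 1.
#'
#' @param R reaction radius (nm)
#' @param Rs encounter separation (nm)
#' @inheritParams p_react_partial
#' @return probability in `[0, 1]`
#' @export
contact_reaction_prob <- function(R, Rs, kdif, kact, rc = 0,
                                  charged = FALSE) {
  stopifnot(all(R > 0), all(Rs > 0), all(kdif > 0), all(kact >= 0))
  ratio <- kdif / kact          # 0 when kact = Inf
  if (!charged || all(rc == 0)) {
    p <- Rs / (Rs + ratio * (R + Rs))
  } else {
    a <- exp(-rc / R) - exp(-rc / (R + Rs))
    p <- a / (a - ratio * (1 - exp(-rc / R)))
  }
  ifelse(kact == 0, 0, pmin(pmax(p, 0), 1))
}

#' Protection-domain (dynamic) time step
#'
#' The largest time step over which a totally diffusion-controlled pair's
#' reaction probability stays below `1 - confidence`, obtained by inverting
#' the Smoluchowski probability:
#' \deqn{\Delta t = \left(\frac{r_0 - R}{2\sqrt{D}\,
#'   \mathrm{erfc}^{-1}((1-c)\,r_0/R)}\right)^2.}
#' When `R/r0 <= 1 - confidence` the asymptotic reaction probability never
#' reaches the threshold and the step is unbounded (`Inf`); callers cap it.
#'
#' @inheritParams p_react_total
#' @param confidence confidence level in (0, 1); 0.95 by default
#' @return time step in ps (possibly `Inf`)
#' @export
dynamic_time_step <- function(r0, R, D, confidence = 0.95) {
  stopifnot(all(confidence > 0), all(confidence < 1))
  if (any(r0 <= R)) stop("r0 must exceed R")
  q <- (1 - confidence) * r0 / R
  ifelse(q >= 1, Inf, ((r0 - R) / (2 * sqrt(D) * erfcinv(pmin(q, 2 - 1e-16))))^2)
}

#' Brownian-bridge encounter probability over one step
#'
#' Probability that a pair whose separation was `d0` before and `d1` after a
#' Brownian step of duration `dt` came within the reaction radius `R` at
#' some intermediate time.  The image (reflection-principle) solution for
#' the radial coordinate gives the exact form
#' \deqn{p = \frac{e^{-(d_0-R)(d_1-R)/(D\Delta t)} - e^{-d_0 d_1/(D\Delta t)}}
#'            {1 - e^{-d_0 d_1/(D\Delta t)}},}
#' which reduces to the familiar minimum-time-step expression
#' \eqn{\exp(-(d_0-R)(d_1-R)/(D\Delta t))} whenever \eqn{D\Delta t \ll d_0 d_1}
#' and stays correct over the long protection-domain steps, where the
#' radial process is transient and the plain exponential would saturate
#' to 1.  Used by the SBS stepper to compensate reactions missed between
#' discrete positions.
#'
#' @param d0,d1 separations before and after the step (nm), `>= R`
#' @param R reaction radius (nm)
#' @param D relative diffusion coefficient (nm^2/ps)
#' @param dt step duration (ps)
#' @return encounter probability in `[0, 1]`
#' @export
brownian_bridge_prob <- function(d0, d1, R, D, dt) {
  stopifnot(all(d0 >= R), all(d1 >= R), all(dt > 0))
  far <- exp(-d0 * d1 / (D * dt))
  p <- (exp(-(d0 - R) * (d1 - R) / (D * dt)) - far) / (1 - far)
  pmin(pmax(p, 0), 1)
}
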