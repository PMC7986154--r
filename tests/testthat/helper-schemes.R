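# shared fixtures: reaction tables are deterministic, build once
tab_mixed <- build_reaction_table("table1_thiswork")
tab_tdc <- build_reaction_table("table1_tdc")

# a pair snapshot replicated over n histories at separation r0 along x
pair_snapshot <- function(a, b, r0, n) {
  tibble::tibble(
    history = rep(seq_len(n), each = 2),
    species = rep(c(a, b), n),
    x_nm = rep(c(0, r0), n), y_nm = 0, z_nm = 0, t_ps = 0
  )
}

# binomial three-sigma half-width
sigma3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)

# KS distance between accepted (finite) samples and a conditional CDF
ks_distance <- function(times, Fcond) {
  acc <- sort(times[is.finite(times)])
  m <- length(acc)
  Fa <- Fcond(acc)
  max(pmax(abs(seq_len(m) / m - Fa), abs((seq_len(m) - 1) / m - Fa)))
}

# internal helpers used by oracle computations in tests
erfc_vec <- irtchem:::erfc
erfcx_vec <- irtchem:::erfcx
cpp_bridge_mc_shim <- irtchem:::cpp_bridge_mc
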