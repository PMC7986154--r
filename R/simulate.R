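#' @useDynLib irtchem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% .data
NULL

event_labels <- c("reaction", "damage", "escape")

# flatten a reaction_table to the plain-vector form the C++ core takes
scheme_cpp <- function(table) {
  sp <- species_table(table)
  constants <- attr(table, "constants")
  nR <- nrow(table)
  prod <- matrix(-1L, nrow = max(nR, 1), ncol = 3)
  contactP <- numeric(nR)
  for (r in seq_len(nR)) {
    pr <- match(table$products[[r]], sp$name) - 1L
    if (length(pr) > 3) stop("more than three products in a reaction")
    if (length(pr)) prod[r, seq_along(pr)] <- pr
    contactP[r] <- if (table$rtype[r] == "totally") 1.0 else
      contact_reaction_prob(table$R[r], constants$encounter_separation,
                            table$kdif[r], table$kact[r],
                            rc = table$rc[r], charged = table$rc[r] != 0)
  }
  if (nR == 0) prod <- matrix(-1L, 0, 3)
  list(
    D = sp$D,
    ra = match(table$a, sp$name) - 1L,
    rb = match(table$b, sp$name) - 1L,
    Rgeom = table$R, Reff = table$Reff,
    kdif = table$kdif, kact = table$kact, rc = table$rc,
    partial = as.integer(table$rtype == "partially"),
    spin = as.integer(table$spin),
    prod = prod, contactP = contactP
  )
}

sinks_cpp <- function(geometry, table, dna_table) {
  sp <- species_table(table)
  if (is.null(geometry)) {
    return(list(pos = matrix(0, 0, 3), cls = integer(0),
                R = matrix(0, 0, nrow(sp))))
  }
  classes <- c("deoxyribose", "adenine", "guanine", "thymine", "cytosine")
  Rm <- matrix(0, nrow = length(classes), ncol = nrow(sp))
  for (i in seq_len(nrow(dna_table))) {
    r <- match(dna_table$target[i], classes)
    s <- match(dna_table$species[i], sp$name)
    if (is.na(r)) stop("unknown DNA target: ", dna_table$target[i])
    if (is.na(s)) stop("DNA scheme radical absent from species table: ",
                       dna_table$species[i])
    Rm[r, s] <- dna_table$R[i]
  }
  re <- geometry$reactive
  list(pos = cbind(re$x, re$y, re$z), cls = re$cls, R = Rm)
}

empty_events <- function() {
  tibble::tibble(history = integer(0), time_ps = numeric(0),
                 type = character(0), reaction = character(0),
                 species_a = character(0), species_b = character(0),
                 sink = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0))
}

# shared driver behind run_irt / run_sbs / run_chemistry
run_core <- function(snapshots, table, method, geometry, end_time,
                     start_time, dna_table, spin_weight, cutoff_prob,
                     schedule, confidence, bridge, bridge_cut) {
  if (is.character(table)) table <- build_reaction_table(table)
  if (!is.null(geometry) && is.null(dna_table)) {
    dna_table <- dna_reaction_table(table)
  }
  if (!"history" %in% names(snapshots)) snapshots$history <- 1L
  start_time <- start_time %||%
    (if ("t_ps" %in% names(snapshots) && nrow(snapshots))
       min(snapshots$t_ps) else 0)
  n_hist <- length(unique(snapshots$history))
  if (nrow(snapshots) == 0) {
    out <- list(events = empty_events(),
                final = tibble::tibble(history = integer(0),
                                       species = character(0),
                                       x_nm = numeric(0), y_nm = numeric(0),
                                       z_nm = numeric(0)),
                initial = snapshots,
                damage = damage_records(empty_events(), geometry),
                n_histories = n_hist, method = method, table = table,
                geometry = geometry, start_time = start_time,
                end_time = end_time)
    return(structure(out, class = "chem_history"))
  }
  snapshots <- snapshots[order(snapshots$history), , drop = FALSE]
  sp <- species_table(table)
  kinds <- match(snapshots$species, sp$name)
  if (anyNA(kinds)) {
    stop("species not in the reaction scheme: ",
         paste(unique(snapshots$species[is.na(kinds)]), collapse = ", "))
  }
  res <- cpp_run_chem(
    if (method == "irt") 0L else 1L,
    cbind(snapshots$x_nm, snapshots$y_nm, snapshots$z_nm),
    kinds - 1L, as.integer(snapshots$history),
    scheme_cpp(table), sinks_cpp(geometry, table, dna_table),
    if (is.null(geometry)) -1 else geometry$voxel_half,
    start_time, end_time, spin_weight, cutoff_prob,
    schedule$bound, schedule$step, confidence, bridge, bridge_cut)
  evl <- res$events
  rxn_name <- if (nrow(table) > 0) paste(table$a, "+", table$b) else character(0)
  events <- tibble::tibble(
    history = evl$history,
    time_ps = evl$time_ps,
    type = event_labels[evl$type + 1L],
    reaction = ifelse(evl$reaction >= 0, rxn_name[evl$reaction + 1L], NA),
    species_a = ifelse(evl$kind_a >= 0, sp$name[evl$kind_a + 1L], NA),
    species_b = ifelse(evl$kind_b >= 0, sp$name[evl$kind_b + 1L], NA),
    sink = ifelse(evl$sink >= 0, evl$sink + 1L, NA_integer_),
    x = evl$x, y = evl$y, z = evl$z
  )
  final <- tibble::tibble(
    history = res$final_hist,
    species = if (length(res$final_kind)) sp$name[res$final_kind + 1L]
      else character(0),
    x_nm = res$final_x, y_nm = res$final_y, z_nm = res$final_z
  )
  structure(list(events = events, final = final, initial = snapshots,
                 damage = damage_records(events, geometry),
                 n_histories = n_hist, method = method, table = table,
                 geometry = geometry, start_time = start_time,
                 end_time = end_time),
            class = "chem_history")
}

#' Run the synchronous IRT stepper
#'
#' Independent-reaction-time variant with explicit positions: each step,
#' reaction times of all admissible reactant pairs (and radical-sink pairs
#' when a fiber geometry is attached) are sampled from their two-body
#' first-passage distributions; the global minimum fires; every surviving
#' molecule is diffused to that time by an isotropic Gaussian displacement
#' (position approach); pairs brought inside their reaction radius react in
#' a contact sweep with the unsuccessful-encounter probability; then all
#' times are resampled from the new positions.
#'
#' @param snapshot tibble with columns `species`, `x_nm`, `y_nm`, `z_nm`,
#'   optionally `t_ps` (creation time) and `history`
#' @param table a [build_reaction_table()] result (or a shipped scheme name)
#' @param geometry optional [build_fiber()] geometry; when attached,
#'   radical-DNA reactions are sampled per the DNA rate table and molecules
#'   leaving the voxel are discarded
#' @param end_time end of the simulated interval (ps)
#' @param start_time chemistry start (ps); defaults to the snapshot time
#' @param dna_table radical-DNA rates from [dna_reaction_table()] (defaults
#'   to the shipped table when a geometry is attached)
#' @param spin_weight singlet weight of the spin statistical factor
#' @param cutoff_prob candidate pairs whose reaction probability within the
#'   remaining time falls below this are skipped
#' @return a `chem_history`: `$events` (reactions, damage, escapes),
#'   `$final` (survivors), `$damage` (indirect damage records)
#' @export
run_irt <- function(snapshot, table, geometry = NULL, end_time,
                    start_time = NULL, dna_table = NULL,
                    spin_weight = 0.25, cutoff_prob = 1e-4) {
  run_core(snapshot, table, "irt", geometry, end_time, start_time,
           dna_table, spin_weight, cutoff_prob,
           schedule_fixed(0.1), 0.95, TRUE, 10)
}

#' Minimum-time-step schedules for the SBS stepper
#'
#' `schedule_kreipl()` is the variable schedule with minimum steps growing
#' with virtual time (0.1 ps below 10 ps, up to 100 ps above 10 ns);
#' `schedule_fixed()` keeps one minimum step for the whole run.
#'
#' @param step minimum time step in ps
#' @return tibble with columns `bound` (upper slice bound, ps) and `step`
#' @export
schedule_kreipl <- function() {
  tibble::tibble(bound = c(10, 100, 1e3, 1e4, Inf),
                 step = c(0.1, 1, 3, 10, 100))
}

#' @rdname schedule_kreipl
#' @export
schedule_fixed <- function(step = 0.1) {
  tibble::tibble(bound = Inf, step = step)
}

#' Run the SBS dynamic-time-step stepper
#'
#' Reference Brownian-dynamics stepper: all molecules take Gaussian steps of
#' duration max(minimum step, smallest protection-domain step); pairs whose
#' post-step separation is inside the reaction radius react, and near misses
#' react with the Brownian-bridge encounter probability.  All reactions are
#' treated as totally diffusion-controlled (use the all-TDC scheme).
#'
#' @inheritParams run_irt
#' @param schedule a [schedule_kreipl()] or [schedule_fixed()] tibble
#' @param confidence protection-domain confidence level
#' @param bridge enable Brownian-bridge compensation of missed reactions
#' @param bridge_cut apply the bridge to pairs within this multiple of the
#'   reaction radius
#' @return a `chem_history` (same contract as [run_irt()])
#' @export
run_sbs <- function(snapshot, table, geometry = NULL, end_time,
                    start_time = NULL, dna_table = NULL,
                    schedule = schedule_kreipl(), confidence = 0.95,
                    bridge = TRUE, bridge_cut = 10) {
  run_core(snapshot, table, "sbs", geometry, end_time, start_time,
           dna_table, 0.25, 1e-4, schedule, confidence, bridge, bridge_cut)
}

#' Run many independent histories through either stepper
#'
#' Histories (column `history` of the snapshot) are independent primaries:
#' each one sees an undamaged fiber, and event logs are concatenated with
#' their history ids.
#'
#' @param snapshots tibble with columns `history`, `species`, `x_nm`,
#'   `y_nm`, `z_nm`, `t_ps`
#' @param table reaction table (or shipped scheme name)
#' @param method `"irt"` or `"sbs"`
#' @inheritParams run_irt
#' @param ... passed to [run_irt()] or [run_sbs()]
#' @return a `chem_history` with per-history event logs and damage records
#' @export
run_chemistry <- function(snapshots, table, method = c("irt", "sbs"),
                          geometry = NULL, end_time, ...) {
  method <- match.arg(method)
  if (method == "irt") {
    run_irt(snapshots, table, geometry = geometry, end_time = end_time, ...)
  } else {
    run_sbs(snapshots, table, geometry = geometry, end_time = end_time, ...)
  }
}

#' Indirect damage records from an event log
#'
#' Maps damage events (radical + sink reactions) to addressed damage
#' records: nucleotide index, strand, element, damaging agent and time.
#'
#' @param events event tibble from a `chem_history`
#' @param geometry the fiber geometry the run used
#' @return tibble of indirect primary-damage records
#' @export
damage_records <- function(events, geometry) {
  if (is.null(geometry) || nrow(events) == 0) {
    return(tibble::tibble(history = integer(0), time_ps = numeric(0),
                          nucleotide_index = integer(0), strand = integer(0),
                          element = character(0), base = character(0),
                          mechanism = character(0), agent = character(0)))
  }
  dmg <- events[events$type == "damage", , drop = FALSE]
  re <- geometry$reactive
  tibble::tibble(
    history = dmg$history,
    time_ps = dmg$time_ps,
    nucleotide_index = re$nucleotide_index[dmg$sink],
    strand = re$strand[dmg$sink],
    element = re$element[dmg$sink],
    base = re$base[dmg$sink],
    mechanism = rep("indirect", nrow(dmg)),
    agent = dmg$species_a
  )
}

#' Product placement rule
#'
#' A single product is placed at the diffusion-weighted encounter point
#' `(sqrt(Db) pa + sqrt(Da) pb) / (sqrt(Da) + sqrt(Db))`; two products are
#' placed at the two parent positions; a third product (the three-product
#' bimolecular channel) at the encounter point.
#'
#' @param pos_a,pos_b parent positions (length-3 numerics, nm)
#' @param D_a,D_b parent diffusion coefficients (nm^2/ps)
#' @param n_products number of products (0-3)
#' @return matrix with one row per product
#' @export
place_products <- function(pos_a, pos_b, D_a, D_b, n_products) {
  if (n_products > 3) stop("more than three products is not in any scheme")
  wa <- sqrt(D_b) / (sqrt(D_a) + sqrt(D_b))
  enc <- wa * pos_a + (1 - wa) * pos_b
  if (n_products == 0) return(matrix(numeric(0), 0, 3))
  if (n_products == 1) return(matrix(enc, 1, 3, byrow = TRUE))
  out <- rbind(pos_a, pos_b, enc)[seq_len(n_products), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Two-particle Brownian trial kernel
#'
#' Simulates `n_trials` relative-coordinate Brownian paths of duration `dt`
#' (with `n_sub` substeps and reflection-principle bridge correction
#' between substeps) and returns the fraction in which the pair never came
#' within the reaction radius.  Used to verify the protection-domain
#' confidence contract.
#'
#' @inheritParams p_react_total
#' @param dt trial duration (ps)
#' @param n_trials number of trials
#' @param n_sub substeps per trial
#' @return non-reacting fraction
#' @export
two_particle_nonreact <- function(r0, R, D, dt, n_trials = 1e5, n_sub = 64) {
  cpp_two_particle_nonreact(r0, R, D, dt, as.integer(n_trials),
                            as.integer(n_sub))
}
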