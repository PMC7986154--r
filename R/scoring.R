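#' Logarithmic scoring grid
#'
#' @param from,to grid limits in ps (1 ps to 1 us default)
#' @param per_decade points per decade (50 default)
#' @return strictly increasing numeric grid
#' @export
log_time_grid <- function(from = 1, to = 1e6, per_decade = 50) {
  n <- ceiling(log10(to / from) * per_decade) + 1
  10^seq(log10(from), log10(to), length.out = n)
}

# per-history, per-species count deltas implied by the event log
count_deltas <- function(history) {
  ev <- history$events
  init <- history$initial
  tab <- history$table
  prods <- stats::setNames(tab$products, paste(tab$a, "+", tab$b))
  pieces <- list(
    tibble::tibble(history = init$history, time_ps = init$t_ps,
                   species = init$species, delta = 1)
  )
  if (nrow(ev)) {
    cons <- ev[ev$type %in% c("reaction", "damage", "escape"), ]
    pieces[[2]] <- tibble::tibble(history = cons$history,
                                  time_ps = cons$time_ps,
                                  species = cons$species_a, delta = -1)
    rx <- ev[ev$type == "reaction", ]
    if (nrow(rx)) {
      pieces[[3]] <- tibble::tibble(history = rx$history,
                                    time_ps = rx$time_ps,
                                    species = rx$species_b, delta = -1)
      pl <- prods[rx$reaction]
      np <- lengths(pl)
      if (sum(np)) {
        pieces[[4]] <- tibble::tibble(
          history = rep(rx$history, np), time_ps = rep(rx$time_ps, np),
          species = unlist(pl, use.names = FALSE), delta = 1)
      }
    }
  }
  dplyr::bind_rows(pieces)
}

#' G-value time series
#'
#' Radiochemical yields: for each species, the mean number of molecules
#' alive at each grid time per history, scaled to molecules per 100 eV of
#' deposited energy.  Counts are right-continuous step functions of the
#' event log (instantaneous populations, not cumulative production).
#'
#' @param history a `chem_history` from [run_chemistry()]
#' @param E_dep deposited energy per history (eV); defaults to the
#'   snapshot's `E_dep` attribute
#' @param grid scoring times in ps ([log_time_grid()] default)
#' @return a `gvalue_series` tibble: `time_ps`, `species`, `G`
#' @export
g_value_series <- function(history, E_dep = NULL,
                           grid = log_time_grid(
                             from = max(history$start_time, 1e-3),
                             to = history$end_time)) {
  E_dep <- E_dep %||% attr(history$initial, "E_dep")
  if (is.null(E_dep) || E_dep <= 0) stop("E_dep must be positive")
  stopifnot(all(diff(grid) > 0))
  n_hist <- max(history$n_histories, 1L)
  deltas <- count_deltas(history)
  species <- unique(c(species_table(history$table)$name, deltas$species))
  out <- purrr::map_dfr(species, function(s) {
    d <- deltas[deltas$species == s, , drop = FALSE]
    if (nrow(d) == 0) {
      return(tibble::tibble(time_ps = grid, species = s, G = 0))
    }
    d <- d[order(d$time_ps), , drop = FALSE]
    cum <- cumsum(d$delta)
    idx <- findInterval(grid, d$time_ps)
    count <- ifelse(idx == 0, 0, cum[pmax(idx, 1)])
    tibble::tibble(time_ps = grid, species = s,
                   G = 100 * count / (n_hist * E_dep))
  })
  structure(out, E_dep = E_dep, n_histories = n_hist,
            class = c("gvalue_series", class(out)))
}

#' Water material-balance audit
#'
#' The net water decomposition counted from the reducing side must equal
#' the oxidizing side at all times:
#' `G(eaq-) + 2 G(H2) + G(H) = G(OH) + 2 G(H2O2)`.
#' Every reaction of the water scheme changes both sides equally, so a run
#' started from a balanced initial population keeps the identity to
#' floating-point accuracy; the audit returns the worst relative deviation
#' over the grid.
#'
#' @param series a [g_value_series()] result covering the five species
#' @return maximum relative deviation (dimensionless; multiply by 100 for
#'   percent)
#' @export
material_balance <- function(series) {
  prof <- material_balance_profile(series)
  max(prof$rel_dev)
}

#' @rdname material_balance
#' @return `material_balance_profile()`: tibble with the two sides and the
#'   relative deviation at each grid time
#' @export
material_balance_profile <- function(series) {
  need <- c("eaq", "H2", "H", "OH", "H2O2")
  have <- unique(series$species)
  if (!all(need %in% have)) {
    stop("series must cover species: ", paste(setdiff(need, have), collapse = ", "))
  }
  wide <- tidyr::pivot_wider(series, id_cols = "time_ps",
                             names_from = "species", values_from = "G")
  L <- wide$eaq + 2 * wide$H2 + wide$H
  R <- wide$OH + 2 * wide$H2O2
  denom <- pmax(L, R)
  tibble::tibble(time_ps = wide$time_ps, reducing = L, oxidizing = R,
                 rel_dev = ifelse(denom == 0, 0, abs(L - R) / denom))
}

#' Compare two G-value series or two damage series
#'
#' Per-time relative differences with the second argument as the
#' reference, following the `(candidate - reference)/reference`
#' convention.
#'
#' @param a,b two [g_value_series()] results on identical grids (or two
#'   [damage_yield_series()] results)
#' @return tibble of per-time relative differences
#' @export
compare_methods <- function(a, b) {
  if (inherits(a, "damage_series")) {
    if (!isTRUE(all.equal(a$time_ps, b$time_ps))) stop("grid mismatch")
    return(tibble::tibble(
      time_ps = a$time_ps,
      candidate = a$cumulative, reference = b$cumulative,
      rel_diff = ifelse(b$cumulative == 0, NA_real_,
                        (a$cumulative - b$cumulative) / b$cumulative)))
  }
  if (!identical(unique(a$time_ps), unique(b$time_ps))) stop("grid mismatch")
  j <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(a), candidate = "G"),
    dplyr::rename(tibble::as_tibble(b), reference = "G"),
    by = c("time_ps", "species"))
  j$rel_diff <- ifelse(j$reference == 0, NA_real_,
                       (j$candidate - j$reference) / j$reference)
  j
}

#' Direct-damage scoring from energy deposits
#'
#' Sums deposited energy per incident primary within each nucleotide
#' backbone group (the phosphate and 2-deoxyribose spheres of one strand
#' plus their hydration shells) and emits a direct primary-damage record
#' when the per-primary sum strictly exceeds the threshold.  A deposit
#' belongs to the group of the nearest backbone sphere containing it.
#'
#' @param deposits tibble `history`, `x_nm`, `y_nm`, `z_nm`, `energy_eV`
#' @param geometry a [build_fiber()] object
#' @param threshold energy threshold in eV (strict `>`)
#' @return tibble of direct damage records
#' @export
score_direct <- function(deposits, geometry, threshold = 17.5) {
  empty <- tibble::tibble(history = integer(0), nucleotide_index = integer(0),
                          strand = integer(0), energy_eV = numeric(0),
                          mechanism = character(0))
  if (nrow(deposits) == 0) return(empty)
  sk <- geometry$sinks
  bb <- sk[sk$element %in% c("deoxyribose", "phosphate"), , drop = FALSE]
  bb$outer <- bb$radius + geometry$params$shell_thickness
  cs <- 2 * max(bb$outer)
  key <- function(x, y, z) paste(floor(x / cs), floor(y / cs), floor(z / cs))
  bb$.row <- seq_len(nrow(bb))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  sphere_cells <- purrr::map_dfr(seq_len(nrow(offs)), function(i) {
    tibble::tibble(
      .key = key(bb$x + offs$dx[i] * cs, bb$y + offs$dy[i] * cs,
                 bb$z + offs$dz[i] * cs),
      .row = bb$.row)
  })
  dep <- deposits
  dep$.dep <- seq_len(nrow(dep))
  dep$.key <- key(dep$x_nm, dep$y_nm, dep$z_nm)
  cand <- dplyr::inner_join(dep[, c(".dep", ".key")], sphere_cells,
                            by = ".key", relationship = "many-to-many")
  if (nrow(cand) == 0) return(empty)
  d2 <- (dep$x_nm[cand$.dep] - bb$x[cand$.row])^2 +
    (dep$y_nm[cand$.dep] - bb$y[cand$.row])^2 +
    (dep$z_nm[cand$.dep] - bb$z[cand$.row])^2
  keep <- d2 < bb$outer[cand$.row]^2
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand$d2 <- d2[keep]
  # nearest containing sphere wins
  cand <- cand[order(cand$.dep, cand$d2), , drop = FALSE]
  cand <- cand[!duplicated(cand$.dep), , drop = FALSE]
  hit <- tibble::tibble(
    history = dep$history[cand$.dep],
    energy_eV = dep$energy_eV[cand$.dep],
    nucleotide_index = bb$nucleotide_index[cand$.row],
    strand = bb$strand[cand$.row]
  )
  agg <- dplyr::summarise(
    dplyr::group_by(hit, .data$history, .data$nucleotide_index, .data$strand),
    energy_eV = sum(.data$energy_eV), .groups = "drop")
  out <- agg[agg$energy_eV > threshold, , drop = FALSE]
  out$mechanism <- rep("direct", nrow(out))
  out
}

#' Damage-yield time series
#'
#' Bins primary-damage events on a time grid, normalized per primary:
#' direct records are scored at the grid origin (they exist as soon as the
#' physical stage ends), indirect records at their reaction times.  The
#' cumulative series is the running sum of the per-bin series.
#'
#' @param indirect indirect damage records ([damage_records()] /
#'   `history$damage`)
#' @param direct direct damage records ([score_direct()])
#' @param n_primaries number of incident primaries
#' @param grid scoring time grid (ps)
#' @return a `damage_series` tibble: `time_ps`, `per_bin`, `cumulative`
#'   (damages per primary)
#' @export
damage_yield_series <- function(indirect, direct = NULL, n_primaries,
                                grid = log_time_grid(1, 1e4)) {
  stopifnot(n_primaries > 0, all(diff(grid) > 0))
  times <- c(indirect$time_ps,
             if (!is.null(direct)) rep(grid[1], nrow(direct)))
  counts <- numeric(length(grid))
  if (length(times)) {
    bin <- findInterval(times, grid, rightmost.closed = FALSE)
    bin <- pmax(bin, 1)   # events at/before the origin land in bin 1
    tb <- table(factor(bin, levels = seq_along(grid)))
    counts <- as.numeric(tb)
  }
  out <- tibble::tibble(time_ps = grid, per_bin = counts / n_primaries,
                        cumulative = cumsum(counts) / n_primaries)
  structure(out, n_primaries = n_primaries,
            class = c("damage_series", class(out)))
}
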