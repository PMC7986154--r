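#' Synthetic electron-spur source model
#'
#' Stand-in for the physical and physicochemical stages: emits the radical
#' population present at the 1 ps chemistry start for one low-LET electron
#' history depositing 1 keV.  Species are generated in three stoichiometric
#' groups, each of which is charge-neutral and balances the water
#' material-balance identity exactly:
#' \itemize{
#' \item ionization: eaq- + OH + H3O+ (water ionization followed by proton
#'   transfer and electron hydration),
#' \item excitation: OH + H (dissociative de-excitation),
#' \item molecular: H2 + 2 OH (dissociative channel).
#' }
#' Group yields per 100 eV are literature-informed 1 ps values; sites are
#' strung along a random walk so spurs are well separated at low LET.
#'
#' @param E_dep deposited energy per history (eV)
#' @param g_ionization,g_excitation,g_molecular group yields per 100 eV at
#'   1 ps
#' @param sites_mean mean number of spur sites per history
#' @param site_spacing_mean mean inter-site spacing (nm)
#' @param sigma Gaussian spur radius at 1 ps (nm)
#' @param t_ps creation time of the species (ps)
#' @return model parameter list for [gen_electron_spurs()]
#' @export
spur_model <- function(E_dep = 1000, g_ionization = 4.4, g_excitation = 0.6,
                       g_molecular = 0.15, sites_mean = 8,
                       site_spacing_mean = 100, sigma = 2.0, t_ps = 1) {
  stopifnot(E_dep > 0, sigma > 0)
  list(E_dep = E_dep, g_ionization = g_ionization,
       g_excitation = g_excitation, g_molecular = g_molecular,
       sites_mean = sites_mean, site_spacing_mean = site_spacing_mean,
       sigma = sigma, t_ps = t_ps)
}

species_groups <- list(
  ionization = c("eaq", "OH", "H3O+"),
  excitation = c("OH", "H"),
  molecular = c("H2", "OH", "OH")
)

# draw group species for one history; balance holds per group by construction
draw_groups <- function(model) {
  n <- c(
    ionization = stats::rpois(1, model$E_dep * model$g_ionization / 100),
    excitation = stats::rpois(1, model$E_dep * model$g_excitation / 100),
    molecular = stats::rpois(1, model$E_dep * model$g_molecular / 100)
  )
  rep(names(n), times = n)
}

#' Generate synthetic electron-spur histories
#'
#' @param model a [spur_model()]
#' @param n_histories number of independent primary histories
#' @return snapshot tibble (`history`, `species`, `x_nm`, `y_nm`, `z_nm`,
#'   `t_ps`) with attribute `E_dep` (eV per history)
#' @export
gen_electron_spurs <- function(model = spur_model(), n_histories = 1) {
  out <- vector("list", n_histories)
  for (h in seq_len(n_histories)) {
    groups <- draw_groups(model)
    if (length(groups) == 0) next
    n_sites <- 1 + stats::rpois(1, max(model$sites_mean - 1, 0))
    # random-walk site centres
    steps <- matrix(stats::rnorm(3 * n_sites), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) *
      stats::rexp(n_sites, 1 / model$site_spacing_mean)
    centres <- apply(steps, 2, cumsum)
    centres <- matrix(centres, ncol = 3)
    site <- sample.int(n_sites, length(groups), replace = TRUE)
    sp <- unlist(species_groups[groups], use.names = FALSE)
    gsite <- rep(site, times = lengths(species_groups[groups]))
    m <- length(sp)
    out[[h]] <- tibble::tibble(
      history = h, species = sp,
      x_nm = centres[gsite, 1] + stats::rnorm(m, sd = model$sigma),
      y_nm = centres[gsite, 2] + stats::rnorm(m, sd = model$sigma),
      z_nm = centres[gsite, 3] + stats::rnorm(m, sd = model$sigma),
      t_ps = model$t_ps
    )
  }
  snap <- dplyr::bind_rows(out)
  attr(snap, "E_dep") <- model$E_dep
  snap
}

#' Synthetic proton-track source model
#'
#' High-LET surrogate for a 500 keV proton crossing the fiber voxel at
#' normal incidence: entry points uniform on a disc of 20 nm radius, a
#' dense radical column along the axis, and energy-deposit events sharing
#' the same radial profile for direct-damage scoring.  The linear energy
#' transfer surrogate (eV/nm) controls the species density through the same
#' 1 ps group yields as the spur model.
#'
#' @param let_eV_nm energy deposited per nm of track (500 keV protons in
#'   water lose roughly 27 eV/nm)
#' @param beam_radius radius of the incidence disc (nm)
#' @param radial_scale Gaussian radial scale of the radical column at 1 ps
#'   (nm)
#' @param group_jitter spread of species around their group centre (nm)
#' @param deposits_per_nm mean energy-deposit events per nm
#' @param g_ionization,g_excitation,g_molecular 1 ps group yields per 100 eV
#' @param t_ps chemistry start time (ps)
#' @return model list for [gen_proton_track()]
#' @export
track_model <- function(let_eV_nm = 27, beam_radius = 20, radial_scale = 1.0,
                        group_jitter = 0.3, deposits_per_nm = 2.0,
                        g_ionization = 4.4, g_excitation = 0.6,
                        g_molecular = 0.15, t_ps = 1) {
  stopifnot(radial_scale > 0, beam_radius > 0, let_eV_nm > 0)
  list(let_eV_nm = let_eV_nm, beam_radius = beam_radius,
       radial_scale = radial_scale, group_jitter = group_jitter,
       deposits_per_nm = deposits_per_nm, g_ionization = g_ionization,
       g_excitation = g_excitation, g_molecular = g_molecular, t_ps = t_ps)
}

#' Generate synthetic proton-track histories with energy deposits
#'
#' @param model a [track_model()]
#' @param n_histories number of primaries
#' @param voxel_half half-side of the crossed voxel (nm)
#' @return list with `snapshot` (radical tibble as in
#'   [gen_electron_spurs()]) and `deposits` (tibble `history`, `x_nm`,
#'   `y_nm`, `z_nm`, `energy_eV`)
#' @export
gen_proton_track <- function(model = track_model(), n_histories = 1,
                             voxel_half = 20) {
  L <- 2 * voxel_half
  E_track <- model$let_eV_nm * L
  snaps <- vector("list", n_histories)
  deps <- vector("list", n_histories)
  for (h in seq_len(n_histories)) {
    # entry point uniform on the incidence disc; axis along z
    rr <- model$beam_radius * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    ax <- rr * cos(th); ay <- rr * sin(th)
    ng <- c(
      ionization = stats::rpois(1, E_track * model$g_ionization / 100),
      excitation = stats::rpois(1, E_track * model$g_excitation / 100),
      molecular = stats::rpois(1, E_track * model$g_molecular / 100)
    )
    groups <- rep(names(ng), times = ng)
    sp <- unlist(species_groups[groups], use.names = FALSE)
    gn <- length(groups)
    gz <- stats::runif(gn, -voxel_half, voxel_half)
    gx <- ax + stats::rnorm(gn, sd = model$radial_scale)
    gy <- ay + stats::rnorm(gn, sd = model$radial_scale)
    gi <- rep(seq_len(gn), times = lengths(species_groups[groups]))
    m <- length(sp)
    snaps[[h]] <- tibble::tibble(
      history = h, species = sp,
      x_nm = gx[gi] + stats::rnorm(m, sd = model$group_jitter),
      y_nm = gy[gi] + stats::rnorm(m, sd = model$group_jitter),
      z_nm = gz[gi] + stats::rnorm(m, sd = model$group_jitter),
      t_ps = model$t_ps
    )
    nd <- stats::rpois(1, model$deposits_per_nm * L)
    mean_e <- model$let_eV_nm / model$deposits_per_nm
    deps[[h]] <- tibble::tibble(
      history = h,
      x_nm = ax + stats::rnorm(nd, sd = model$radial_scale),
      y_nm = ay + stats::rnorm(nd, sd = model$radial_scale),
      z_nm = stats::runif(nd, -voxel_half, voxel_half),
      energy_eV = stats::rexp(nd, 1 / mean_e)
    )
  }
  snap <- dplyr::bind_rows(snaps)
  attr(snap, "E_dep") <- E_track
  list(snapshot = snap, deposits = dplyr::bind_rows(deps))
}

#' Read / write initial-species snapshots
#'
#' Snapshots are plain CSV with columns `history`, `species`, `x_nm`,
#' `y_nm`, `z_nm`, `t_ps`.
#'
#' @param path file path
#' @return [read_snapshot()] returns the snapshot tibble
#' @export
read_snapshot <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_snapshot
#' @param snapshot snapshot tibble
#' @export
write_snapshot <- function(snapshot, path) {
  utils::write.csv(snapshot, path, row.names = FALSE)
  invisible(path)
}
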