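#' Default chromatin-fiber construction parameters
#'
#' 18 nucleosomes of 160 bp plus 19 linkers of 40 bp give the 3640
#' nucleotide pairs of the 40 nm heterochromatin voxel (the unique
#' near-canonical integer split of 18 n + 19 l = 3640).  The fiber is a
#' continuous coiled coil: the DNA axis winds with uniform rise around a
#' solenoidal tube (radius `tube_radius`, one winding per
#' `winding_spacing` of tube length) whose centre line spirals up the
#' fiber axis (radius `fiber_radius`, pitch `fiber_pitch`), so roughly
#' 2.3 windings wrap each 160 bp nucleosome block around its histone
#' sphere and the chain has no junctions.  Element-sphere radii are
#' placeholders sized so that no two core element spheres overlap
#' anywhere in the default build (damage comparisons here are
#' method-vs-method on a fixed geometry and insensitive to the exact
#' radii).  All lengths in nm, angles in degrees.
#'
#' @return named list of parameters accepted by [build_fiber()]
#' @export
fiber_params <- function() {
  list(
    n_nucleosomes = 18L, n_linkers = 19L,
    bp_per_nucleosome = 160L, bp_per_linker = 40L,
    voxel_side = 40,
    fiber_radius = 12, fiber_pitch = 11,
    tube_radius = 3.7, winding_spacing = 3.5, rise = 0.34,
    histone_radius = 2.4,
    twist = 36, strand_phase = 140,
    phosphate_angle = 22, base_angle = 25,
    sugar_radial = 0.58, sugar_size = 0.20,
    phosphate_radial = 0.85, phosphate_size = 0.15,
    base_radial = 0.25, base_size = 0.13,
    shell_thickness = 0.16,
    spacing_bounds = c(0.30, 0.38)
  )
}

# DNA axis on the coiled coil, arclength-parameterized at constant rise.
# Returns the bp axis points and the tube centre line evaluated at the
# same tube-arclength values (for histone placement).
coil_axis <- function(p, n_bp) {
  Lpt <- sqrt((2 * pi * p$fiber_radius)^2 + p$fiber_pitch^2)
  om <- 2 * pi / Lpt          # solenoid angle per tube arclength
  sb <- p$fiber_pitch / Lpt   # climb per tube arclength
  cb <- sqrt(1 - sb^2)
  tube <- function(tau) {
    cbind(p$fiber_radius * cos(om * tau), p$fiber_radius * sin(om * tau),
          tau * sb)
  }
  dna <- function(tau) {
    th <- om * tau
    u <- cbind(cos(th), sin(th), rep(0, length(tau)))
    tg <- cbind(-sin(th) * cb, cos(th) * cb, rep(sb, length(tau)))
    n2 <- cbind(tg[, 2] * u[, 3] - tg[, 3] * u[, 2],
                tg[, 3] * u[, 1] - tg[, 1] * u[, 3],
                tg[, 1] * u[, 2] - tg[, 2] * u[, 1])
    ph <- 2 * pi * tau / p$winding_spacing
    tube(tau) + p$tube_radius * (cos(ph) * u + sin(ph) * n2)
  }
  need <- (n_bp - 1) * p$rise
  dt <- p$winding_spacing / 500
  # DNA arclength per tube arclength is at least ~2 pi a / lambda
  mult <- sqrt((2 * pi * p$tube_radius)^2 + p$winding_spacing^2) /
    p$winding_spacing
  tau <- seq(0, 1.1 * need / mult + 4 * p$winding_spacing, by = dt)
  pts <- dna(tau)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (max(s) < need) stop("internal: tube sampling too short")
  tk <- stats::approx(s, tau, xout = (seq_len(n_bp) - 1) * p$rise)$y
  ax <- dna(tk)
  zshift <- mean(range(ax[, 3]))
  ax[, 3] <- ax[, 3] - zshift
  centre <- tube(tk)
  centre[, 3] <- centre[, 3] - zshift
  list(axis = ax, centre = centre, tau = tk)
}

# parallel-transported orthonormal frames along a polyline
transport_frames <- function(ax) {
  nb <- nrow(ax)
  Tg <- rbind(ax[2, ] - ax[1, ],
              ax[3:nb, ] - ax[1:(nb - 2), ],
              ax[nb, ] - ax[nb - 1, ])
  Tg <- Tg / sqrt(rowSums(Tg^2))
  Nv <- matrix(0, nb, 3)
  n0 <- c(0, 0, 1) - sum(c(0, 0, 1) * Tg[1, ]) * Tg[1, ]
  if (sqrt(sum(n0^2)) < 1e-6) n0 <- c(1, 0, 0) - sum(c(1, 0, 0) * Tg[1, ]) * Tg[1, ]
  Nv[1, ] <- n0 / sqrt(sum(n0^2))
  for (i in 2:nb) {
    v <- Nv[i - 1, ] - sum(Nv[i - 1, ] * Tg[i, ]) * Tg[i, ]
    Nv[i, ] <- v / sqrt(sum(v^2))
  }
  Bv <- cbind(Tg[, 2] * Nv[, 3] - Tg[, 3] * Nv[, 2],
              Tg[, 3] * Nv[, 1] - Tg[, 1] * Nv[, 3],
              Tg[, 1] * Nv[, 2] - Tg[, 2] * Nv[, 1])
  list(N = Nv, B = Bv)
}

#' Build the 40 nm heterochromatin-fiber sink geometry
#'
#' Deterministic construction: identical parameters give bit-identical sink
#' lists.  Each nucleotide contributes, per strand, a 2-deoxyribose sphere,
#' a phosphate sphere, a base sphere (A/C/G/T cycling along the fiber,
#' complementary across strands) and a hydration shell wrapped
#' concentrically around the two backbone spheres.  Deoxyribose and base
#' spheres are the reactive sinks of the radical-DNA scheme; phosphates and
#' shells enter direct-damage scoring only.
#'
#' @param params parameter list from [fiber_params()] (entries can be
#'   overridden)
#' @return a `fiber_geometry` object: `$sinks` (every element sphere with
#'   nucleotide/strand addressing), `$reactive` (the chemistry subset with
#'   0-based class codes), `$histones`, `$axis` (base-pair axis points),
#'   `$voxel_half`, `$n_bp`
#' @examples
#' fib <- build_fiber()
#' fib$n_bp  # 3640
#' @export
build_fiber <- function(params = fiber_params()) {
  p <- utils::modifyList(fiber_params(), params)
  nN <- p$n_nucleosomes; nL <- p$n_linkers
  bpN <- p$bp_per_nucleosome; bpL <- p$bp_per_linker
  if (!(nL == nN + 1 || nL == 0)) {
    stop("supported linker counts: one more than nucleosomes, or zero")
  }
  with_linkers <- nL > 0
  n_bp <- nN * bpN + nL * bpL
  half <- p$voxel_side / 2

  co <- coil_axis(p, n_bp)
  axis <- co$axis
  # block labels along the chain: [linker] nucleosome [linker] ...
  if (with_linkers) {
    blocks <- c(rbind(rep(bpL, nN), rep(bpN, nN)), bpL)
    types <- c(rbind(rep("linker", nN), rep("nucleosome", nN)), "linker")
  } else {
    blocks <- rep(bpN, nN)
    types <- rep("nucleosome", nN)
  }
  seg_lab <- rep(types, times = blocks)
  # histone centres: tube centre line at the middle of each nucleosome block
  block_id <- rep(seq_along(blocks), times = blocks)
  nuc_blocks <- which(types == "nucleosome")
  hist_centres <- t(vapply(nuc_blocks, function(b) {
    colMeans(co$centre[block_id == b, , drop = FALSE])
  }, numeric(3)))

  fr <- transport_frames(axis)
  nb <- nrow(axis)
  idx <- seq_len(nb)
  chi <- (idx - 1) * p$twist * pi / 180
  bases0 <- c("A", "C", "G", "T")[(idx - 1) %% 4 + 1]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  phase <- p$strand_phase * pi / 180

  mk <- function(strand, element, radial, size, angle_off, base) {
    a <- chi + strand * phase + angle_off * pi / 180
    tibble::tibble(
      nucleotide_index = idx, strand = strand,
      element = element, base = base,
      x = axis[, 1] + radial * (cos(a) * fr$N[, 1] + sin(a) * fr$B[, 1]),
      y = axis[, 2] + radial * (cos(a) * fr$N[, 2] + sin(a) * fr$B[, 2]),
      z = axis[, 3] + radial * (cos(a) * fr$N[, 3] + sin(a) * fr$B[, 3]),
      radius = size
    )
  }
  parts <- list()
  for (s in 0:1) {
    b <- if (s == 0) bases0 else unname(comp[bases0])
    sgn <- if (s == 0) 1 else -1
    parts[[length(parts) + 1]] <-
      mk(s, "deoxyribose", p$sugar_radial, p$sugar_size, 0, NA_character_)
    parts[[length(parts) + 1]] <-
      mk(s, "phosphate", p$phosphate_radial, p$phosphate_size,
         p$phosphate_angle, NA_character_)
    parts[[length(parts) + 1]] <-
      mk(s, "base", p$base_radial, p$base_size, sgn * p$base_angle, b)
  }
  core <- dplyr::bind_rows(parts)
  shells <- core[core$element %in% c("deoxyribose", "phosphate"), ]
  shells$element <- "hydration_shell"
  shells$radius <- shells$radius + p$shell_thickness
  sinks <- dplyr::bind_rows(core, shells)

  lim <- max(abs(cbind(sinks$x, sinks$y, sinks$z))) + max(sinks$radius)
  if (lim >= half) {
    stop("fiber does not fit the voxel: extent ", round(lim, 2),
         " nm vs half-side ", half, " nm")
  }

  cls_names <- c("deoxyribose", "adenine", "guanine", "thymine", "cytosine")
  base_cls <- c(A = "adenine", G = "guanine", T = "thymine", C = "cytosine")
  reactive <- core[core$element %in% c("deoxyribose", "base"), ]
  target <- ifelse(reactive$element == "deoxyribose", "deoxyribose",
                   unname(base_cls[reactive$base]))
  reactive$cls <- match(target, cls_names) - 1L
  reactive$damaged <- FALSE

  structure(list(
    sinks = sinks, reactive = reactive,
    histones = tibble::tibble(x = hist_centres[, 1], y = hist_centres[, 2],
                              z = hist_centres[, 3],
                              radius = p$histone_radius),
    axis = axis, segment = seg_lab,
    voxel_half = half, n_bp = n_bp,
    n_nucleosomes = nN, n_linkers = nL, params = p
  ), class = "fiber_geometry")
}

#' @export
print.fiber_geometry <- function(x, ...) {
  cat("<fiber_geometry> ", x$n_bp, " nucleotide pairs (",
      x$n_nucleosomes, " nucleosomes + ", x$n_linkers, " linkers), ",
      nrow(x$sinks), " element spheres in a ", 2 * x$voxel_half,
      " nm voxel\n", sep = "")
  invisible(x)
}

#' Validate a fiber geometry
#'
#' Checks that every element sphere lies inside the voxel, that consecutive
#' base-pair spacings stay within the configured B-DNA bounds, and counts
#' overlapping core element spheres (hydration shells excluded: they are
#' accounting volumes).
#'
#' @param geometry a [build_fiber()] object
#' @param spacing_bounds rise bounds in nm
#' @return list with `inside_voxel`, `spacing_range`, `spacing_ok`,
#'   `n_overlaps`
#' @export
validate_fiber <- function(geometry,
                           spacing_bounds = geometry$params$spacing_bounds) {
  ax <- geometry$axis
  d <- sqrt(rowSums((ax[-1, ] - ax[-nrow(ax), ])^2))
  sk <- geometry$sinks
  inside <- max(abs(c(sk$x, sk$y, sk$z))) + 0 < geometry$voxel_half
  core <- sk[sk$element != "hydration_shell", ]
  # neighbour-cell candidate search for overlapping core spheres
  cs <- 1.0
  key <- function(ix, iy, iz) paste(ix, iy, iz)
  ci <- floor(cbind(core$x, core$y, core$z) / cs)
  core$.row <- seq_len(nrow(core))
  core$.key <- key(ci[, 1], ci[, 2], ci[, 3])
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  neigh <- purrr::map_dfr(seq_len(nrow(offs)), function(i) {
    tibble::tibble(.key = key(ci[, 1] + offs$dx[i], ci[, 2] + offs$dy[i],
                              ci[, 3] + offs$dz[i]),
                   .other = core$.row)
  })
  cand <- dplyr::inner_join(
    tibble::tibble(.key = core$.key, .row = core$.row),
    neigh, by = ".key", relationship = "many-to-many")
  cand <- cand[cand$.row < cand$.other, ]
  dx <- core$x[cand$.row] - core$x[cand$.other]
  dy <- core$y[cand$.row] - core$y[cand$.other]
  dz <- core$z[cand$.row] - core$z[cand$.other]
  rr <- core$radius[cand$.row] + core$radius[cand$.other]
  n_overlap <- sum(dx^2 + dy^2 + dz^2 < (rr - 1e-9)^2)
  list(
    inside_voxel = inside,
    spacing_range = range(d),
    spacing_ok = all(d >= spacing_bounds[1] & d <= spacing_bounds[2]),
    n_overlaps = n_overlap
  )
}

#' Candidate sinks for a radical near the fiber
#'
#' Returns the undamaged sinks a radical can react with (per the
#' radical-DNA rate table) within a cutoff distance, with the reaction
#' radius derived from `kobs = 4 pi R D` (D = the radical's own diffusion
#' coefficient; the sink is static).
#'
#' @param geometry a [build_fiber()] object
#' @param species radical species name
#' @param position length-3 position (nm)
#' @param dna_table a [dna_reaction_table()] result
#' @param cutoff search radius (nm)
#' @return tibble of candidate sinks with distance and reaction radius
#' @export
sink_candidates <- function(geometry, species, position, dna_table,
                            cutoff = Inf) {
  cls_names <- c("deoxyribose", "adenine", "guanine", "thymine", "cytosine")
  re <- geometry$reactive
  dt <- dna_table[dna_table$species == species, , drop = FALSE]
  if (nrow(dt) == 0) return(re[0, ])
  Rof <- stats::setNames(rep(NA_real_, length(cls_names)), cls_names)
  Rof[dt$target] <- dt$R
  R <- unname(Rof[cls_names[re$cls + 1L]])
  d <- sqrt((re$x - position[1])^2 + (re$y - position[2])^2 +
              (re$z - position[3])^2)
  out <- re[!re$damaged & !is.na(R) & d <= cutoff, , drop = FALSE]
  out$reaction_radius <- R[!re$damaged & !is.na(R) & d <= cutoff]
  out$distance <- d[!re$damaged & !is.na(R) & d <= cutoff]
  out
}

#' Register an indirect damage event
#'
#' Marks a sink damaged (monotone: a damaged sink never becomes available
#' again) and emits the primary-damage record; the radical is consumed by
#' the caller.  The steppers do this internally; this function exposes the
#' bookkeeping for single events.
#'
#' @param geometry a [build_fiber()] object
#' @param sink_row row index into `geometry$reactive`
#' @param species the attacking radical
#' @param time_ps reaction time
#' @return list with the updated `geometry` and the damage `record`
#' @export
register_indirect <- function(geometry, sink_row, species, time_ps) {
  if (geometry$reactive$damaged[sink_row]) {
    stop("sink already damaged: double-damage is not allowed")
  }
  geometry$reactive$damaged[sink_row] <- TRUE
  rec <- tibble::tibble(
    time_ps = time_ps,
    nucleotide_index = geometry$reactive$nucleotide_index[sink_row],
    strand = geometry$reactive$strand[sink_row],
    element = geometry$reactive$element[sink_row],
    base = geometry$reactive$base[sink_row],
    mechanism = "indirect", agent = species
  )
  list(geometry = geometry, record = rec)
}
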