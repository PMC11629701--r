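#' Bottle-incubation experiment specification
#'
#' Describes a simulated size-fractionation incubation: which filtration
#' treatments to run, how many replicate bottles, the sampling grid, the
#' food-web parameters driving the latent dynamics, the size of the virus
#' spike added at t = 0, and the multiplicative measurement noise on the
#' flow-cytometry counts. Defaults mirror triplicate bottles sampled at 0,
#' 0.5, 1, 2, 4 and 8 days under three filtration levels with a spike of
#' 3e7 virus ml^-1 and a 10% count CV.
#'
#' @param treatments filtration levels to simulate
#' @param n_replicates replicate bottles per treatment (>= 1)
#' @param times sampling times (days)
#' @param params `foodweb_params` for the latent dynamics
#' @param spike virus concentration (ml^-1) set at t = 0
#' @param cv coefficient of variation of the lognormal measurement noise
#' @param seed RNG seed
#' @return object of class `experiment_spec`
#' @export
experiment_spec <- function(treatments = c("lt100", "lt1p2", "lt0p1"),
                            n_replicates = 3L,
                            times = c(0, 0.5, 1, 2, 4, 8),
                            params = foodweb_params(),
                            spike = 3e7, cv = 0.1, seed = 1L) {
  treatments <- match.arg(treatments, c("lt100", "lt1p2", "lt0p1"),
                          several.ok = TRUE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (cv < 0) stop("cv must be >= 0")
  if (!inherits(params, "foodweb_params")) params <- do.call(foodweb_params, as.list(params))
  structure(list(treatments = treatments, n_replicates = as.integer(n_replicates),
                 times = times, params = params, spike = spike,
                 cv = cv, seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Generate flow-cytometry-like abundance series
#'
#' Simulates each treatment's latent virus and bacteria trajectories with
#' [simulate_treatment()] and observes them with independent multiplicative
#' lognormal noise (meanlog 0, sdlog `sqrt(log(1 + cv^2))`) per replicate,
#' time and target. Bit-reproducible for a fixed spec (seeded).
#'
#' @param spec an [experiment_spec()]
#' @return abundance table (`treatment, replicate, time_days, target,
#'   count_per_ml`) of class `abundance_series`, with attribute `latent`
#'   (list of noiseless trajectories per treatment)
#' @export
generate_abundance_series <- function(spec) {
  if (!inherits(spec, "experiment_spec")) stop("spec must be an experiment_spec")
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  latent <- list()
  rows <- list()
  for (tr in spec$treatments) {
    ts <- treatment_spec(tr, duration = max(spec$times),
                         output_times = spec$times)
    traj <- simulate_treatment(ts, spec$params, spike = spec$spike)
    latent[[tr]] <- traj
    for (rep in seq_len(spec$n_replicates)) {
      for (target in c("virus", "bacteria")) {
        lat <- traj$states[, if (target == "virus") "V" else "B"]
        noise <- if (spec$cv > 0)
          stats::rlnorm(length(lat), meanlog = 0, sdlog = sdlog)
        else rep(1, length(lat))
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr, replicate = paste0("rep", rep),
          time_days = traj$times, target = target,
          count_per_ml = lat * noise)
      }
    }
  }
  out <- as_abundance_series(do.call(rbind, rows))
  attr(out, "latent") <- latent
  out
}

#' Synthetic nanoSIMS scene specification
#'
#' Describes a planted-particle ion-imaging scene: raster geometry, particle
#' list (position, equivalent diameter, shape, relative C and N densities,
#' isotope atom fractions), a uniform background, per-mass-family ion
#' yields, cycle count and beam blur. Defaults emulate a 20 x 20 um raster
#' at 256 x 256 px, 25 cycles, and a ~150 nm FWHM beam.
#'
#' @param dim_px image size (rows, cols)
#' @param pixel_size_nm pixel edge length (nm)
#' @param particles data.frame with columns `row, col` (centre, px),
#'   `diameter_um`, `shape` ("disk" or "ellipse"), `axis_ratio` (minor/major,
#'   ellipses), `angle` (radians, ellipses), `c_density`, `n_density`
#'   (relative element densities), `f13C`, `f15N` (atom fractions)
#' @param background_c,background_n background relative densities
#' @param yield_c2,yield_cn expected counts per cycle per pixel per unit
#'   density for the C2 and CN mass families
#' @param f13C_bg,f15N_bg background atom fractions (natural abundance)
#' @param n_cycles raster cycles
#' @param beam_fwhm_nm Gaussian beam blur FWHM applied to the expected-count
#'   maps before the Poisson draw; 0 disables
#' @param dwell_ms dwell time (ms per pixel)
#' @param seed RNG seed
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(dim_px = c(256L, 256L), pixel_size_nm = 78.125,
                       particles = NULL,
                       background_c = 0.5, background_n = 0.05,
                       yield_c2 = 100, yield_cn = 200,
                       f13C_bg = 0.0111, f15N_bg = 0.003676,
                       n_cycles = 25L, beam_fwhm_nm = 150,
                       dwell_ms = 1, seed = 1L) {
  if (is.null(particles))
    particles <- data.frame(row = numeric(0), col = numeric(0),
                            diameter_um = numeric(0), shape = character(0),
                            axis_ratio = numeric(0), angle = numeric(0),
                            c_density = numeric(0), n_density = numeric(0),
                            f13C = numeric(0), f15N = numeric(0))
  if (!"shape" %in% names(particles)) particles$shape <- "disk"
  if (!"axis_ratio" %in% names(particles)) particles$axis_ratio <- 1
  if (!"angle" %in% names(particles)) particles$angle <- 0
  stopifnot(all(c("row", "col", "diameter_um", "c_density", "n_density",
                  "f13C", "f15N") %in% names(particles)))
  if (any(particles$f13C < 0 | particles$f13C > 1) ||
      any(particles$f15N < 0 | particles$f15N > 1))
    stop("particle atom fractions must lie in [0, 1]")
  if (any(particles$row < 1 | particles$row > dim_px[1L]) ||
      any(particles$col < 1 | particles$col > dim_px[2L]))
    stop("particle centres must lie within the image")
  if (yield_c2 <= 0 || yield_cn <= 0) stop("ion yields must be > 0")
  structure(list(dim_px = as.integer(dim_px), pixel_size_nm = pixel_size_nm,
                 particles = particles,
                 background_c = background_c, background_n = background_n,
                 yield_c2 = yield_c2, yield_cn = yield_cn,
                 f13C_bg = f13C_bg, f15N_bg = f15N_bg,
                 n_cycles = as.integer(n_cycles),
                 beam_fwhm_nm = beam_fwhm_nm, dwell_ms = dwell_ms,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# circular FFT Gaussian blur (sigma in pixels); adequate for smooth
# expected-count maps whose mass sits away from the frame edge
gauss_blur_fft <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  dist1 <- function(n) {
    i <- seq_len(n) - 1L
    pmin(i, n - i)
  }
  kr <- stats::dnorm(dist1(nr), sd = sigma)
  kc <- stats::dnorm(dist1(nc), sd = sigma)
  ker <- outer(kr, kc)
  ker <- ker / sum(ker)
  Re(stats::fft(stats::fft(img) * stats::fft(ker), inverse = TRUE)) / (nr * nc)
}

particle_mask <- function(p, dim_px, pixel_size_nm) {
  r_px <- (p$diameter_um * 1000 / pixel_size_nm) / 2
  rows <- matrix(seq_len(dim_px[1L]), dim_px[1L], dim_px[2L])
  cols <- matrix(seq_len(dim_px[2L]), dim_px[1L], dim_px[2L], byrow = TRUE)
  dy <- rows - p$row
  dx <- cols - p$col
  if (identical(p$shape, "ellipse")) {
    ca <- cos(p$angle); sa <- sin(p$angle)
    u <- dy * ca + dx * sa
    v <- -dy * sa + dx * ca
    # equivalent-diameter parameterisation: a*b = r_px^2
    a <- r_px / sqrt(p$axis_ratio)
    b <- r_px * sqrt(p$axis_ratio)
    (u / a)^2 + (v / b)^2 <= 1
  } else {
    dy^2 + dx^2 <= r_px^2
  }
}

#' Generate a Poisson ion-image stack with planted particles
#'
#' Builds per-pixel expected count maps for the four masses — C2 masses via
#' binomial pairing of the local 13C atom fraction
#' (P(12C2) = (1-f)^2, P(13C12C) = 2f(1-f)), CN masses split by the local
#' 15N atom fraction — optionally blurs them with the beam point-spread
#' function, and draws independent Poisson counts per pixel and cycle.
#'
#' @param scene a [scene_spec()]
#' @return list with `stack` (an [ion_image_stack()]), `masks` (integer
#'   label image of the planted particles, row i of the truth table = label
#'   i), and `truth` (the particle table with planted atom fractions and
#'   pixel areas)
#' @export
generate_ion_stack <- function(scene) {
  if (!inherits(scene, "scene_spec")) stop("scene must be a scene_spec")
  set.seed(scene$seed)
  nr <- scene$dim_px[1L]; nc <- scene$dim_px[2L]
  lam <- list(C2 = matrix(0, nr, nc), C13C12 = matrix(0, nr, nc),
              CN14 = matrix(0, nr, nc), CN15 = matrix(0, nr, nc))
  add_pool <- function(mask_or_all, dens_c, dens_n, f13, f15) {
    pc <- c2_isotopologue_probs(f13)
    lam$C2[mask_or_all] <<- lam$C2[mask_or_all] +
      dens_c * scene$yield_c2 * pc[, "P12C2"]
    lam$C13C12[mask_or_all] <<- lam$C13C12[mask_or_all] +
      dens_c * scene$yield_c2 * pc[, "P13C12C"]
    lam$CN14[mask_or_all] <<- lam$CN14[mask_or_all] +
      dens_n * scene$yield_cn * (1 - f15)
    lam$CN15[mask_or_all] <<- lam$CN15[mask_or_all] +
      dens_n * scene$yield_cn * f15
  }
  add_pool(rep(TRUE, nr * nc), scene$background_c, scene$background_n,
           scene$f13C_bg, scene$f15N_bg)
  labels <- matrix(0L, nr, nc)
  np <- nrow(scene$particles)
  areas <- integer(np)
  for (i in seq_len(np)) {
    p <- scene$particles[i, ]
    m <- particle_mask(p, scene$dim_px, scene$pixel_size_nm)
    areas[i] <- sum(m)
    labels[m] <- i
    add_pool(m, p$c_density, p$n_density, p$f13C, p$f15N)
  }
  sigma_px <- scene$beam_fwhm_nm / (2 * sqrt(2 * log(2))) / scene$pixel_size_nm
  if (scene$beam_fwhm_nm > 0)
    lam <- lapply(lam, gauss_blur_fft, sigma = sigma_px)
  if (any(vapply(lam, max, numeric(1)) > 1e6))
    stop("expected counts exceed 1e6 per pixel per cycle; lower densities or yields")
  counts <- array(0, dim = c(4L, scene$n_cycles, nr, nc))
  mass_names <- c("C2", "C13C12", "CN14", "CN15")
  for (m in 1:4) {
    lm <- pmax(lam[[mass_names[m]]], 0)
    for (j in seq_len(scene$n_cycles))
      counts[m, j, , ] <- matrix(stats::rpois(nr * nc, lm), nr, nc)
  }
  truth <- scene$particles
  truth$label <- seq_len(np)
  truth$area_px <- areas
  list(stack = ion_image_stack(counts, scene$pixel_size_nm, scene$dwell_ms),
       masks = labels, truth = truth)
}

#' Generate a synthetic single-cell protist isotope table
#'
#' Draws per-cell substrate-derived nitrogen fractions (`n_net`, %) from a
#' two-component uniform mixture (default: 80% of cells in U(0, 10)%, 20% in
#' U(10, 85)%, mimicking a minority of cells feeding intensely on labelled
#' virus particles) and couples carbon to nitrogen through
#' `c_net = slope * n_net + noise`, clipped to [0, 100), producing the
#' strong positive C-N enrichment correlation seen in virus-grazing cells.
#'
#' @param n_cells number of cells (>= 1)
#' @param weights mixture weights (must sum to 1)
#' @param ranges list of `c(lo, hi)` percent ranges, one per component
#' @param slope c_net per unit n_net
#' @param noise_sd Gaussian noise SD on c_net (%)
#' @param seed RNG seed
#' @return data.frame with columns `cell_id, c_net, n_net`
#' @export
generate_protist_table <- function(n_cells = 27L,
                                   weights = c(0.8, 0.2),
                                   ranges = list(c(0, 10), c(10, 85)),
                                   slope = 1, noise_sd = 5, seed = 1L) {
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (length(weights) != length(ranges)) stop("weights/ranges length mismatch")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("mixture weights must be non-negative and sum to 1")
  set.seed(seed)
  comp <- sample.int(length(weights), n_cells, replace = TRUE, prob = weights)
  n_net <- vapply(comp, function(k)
    stats::runif(1, ranges[[k]][1L], ranges[[k]][2L]), numeric(1))
  c_net <- slope * n_net +
    if (noise_sd > 0) stats::rnorm(n_cells, 0, noise_sd) else 0
  c_net <- pmin(pmax(c_net, 0), 100 - 1e-9)
  data.frame(cell_id = sprintf("cell_%03d", seq_len(n_cells)),
             c_net = c_net, n_net = n_net)
}
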