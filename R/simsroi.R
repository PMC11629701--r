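#' Ion-count image stack
#'
#' Container for nanoSIMS-style multi-cycle ion-count rasters. Four mass
#' channels are recorded simultaneously and share one geometry: 12C2-,
#' 13C12C-, 12C14N- and 12C15N-. Counts are stored as a 4-dimensional array
#' `[mass, cycle, row, col]`.
#'
#' @param counts numeric array `4 x n_cycles x height x width`, non-negative
#' @param pixel_size_nm pixel edge length in nm (default 78.125 = 20000/256,
#'   a 20 x 20 um raster at 256 x 256 px)
#' @param dwell_ms beam dwell time per pixel in ms
#' @param require_integer validate that counts are integer-valued (raw data);
#'   set FALSE for dead-time-corrected stacks
#' @return object of class `ion_image_stack`
#' @export
ion_image_stack <- function(counts, pixel_size_nm = 78.125, dwell_ms = 1,
                            require_integer = TRUE) {
  if (!is.array(counts) || length(dim(counts)) != 4L || dim(counts)[1L] != 4L)
    stop("counts must be a 4 x n_cycles x height x width array")
  if (any(!is.na(counts) & counts < 0)) stop("counts must be non-negative")
  if (isTRUE(require_integer) &&
      any(abs(counts - round(counts)) > 1e-9, na.rm = TRUE))
    stop("counts must be integer-valued (set require_integer = FALSE for corrected stacks)")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  if (dwell_ms <= 0) stop("dwell_ms must be > 0")
  dimnames(counts) <- list(mass = c("C2", "C13C12", "CN14", "CN15"),
                           NULL, NULL, NULL)
  structure(list(counts = counts, pixel_size_nm = pixel_size_nm,
                 dwell_ms = dwell_ms,
                 n_cycles = dim(counts)[2L],
                 dim_px = dim(counts)[3:4]),
            class = "ion_image_stack")
}

#' @export
print.ion_image_stack <- function(x, ...) {
  cat(sprintf("Ion image stack: %d x %d px (%.1f nm px), %d cycles, 4 masses (C2, 13C12C, 12C14N, 12C15N)\n",
              x$dim_px[1L], x$dim_px[2L], x$pixel_size_nm, x$n_cycles))
  invisible(x)
}

stack_mass <- function(stack, mass) {
  m <- match(mass, c("C2", "C13C12", "CN14", "CN15"))
  if (is.na(m)) stop("unknown mass channel '", mass, "'")
  m
}

#' Cycle-summed image for one channel
#'
#' @param stack an `ion_image_stack`
#' @param channel `"C2"`, `"C13C12"`, `"CN14"`, `"CN15"`, or `"CN_total"`
#'   (12C14N + 12C15N)
#' @return numeric matrix `height x width`
#' @export
channel_sum_image <- function(stack, channel = "CN14") {
  if (channel == "CN_total") {
    a <- stack$counts[stack_mass(stack, "CN14"), , , , drop = FALSE] +
      stack$counts[stack_mass(stack, "CN15"), , , , drop = FALSE]
  } else {
    a <- stack$counts[stack_mass(stack, channel), , , , drop = FALSE]
  }
  colSums(array(a, dim = dim(a)[2:4]), na.rm = TRUE)
}

# integer translation with zero fill; returns the translated matrix
translate_int <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  src_r <- max(1, 1 - dr):min(nr, nr - dr)
  src_c <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(src_r) && length(src_c))
    out[src_r + dr, src_c + dc] <- img[src_r, src_c]
  out
}

#' Align cycles by integer-pixel cross-correlation
#'
#' Each cycle's reference-mass image is cross-correlated (FFT, circular)
#' against cycle 1; the integer shift maximising the correlation within
#' `max_shift` pixels is removed from all four mass channels of that cycle.
#' Integer shifts only: sub-pixel interpolation would redistribute counts.
#' Pixels translated in from outside the frame are zero and marked invalid.
#'
#' @param stack an `ion_image_stack` with at least 2 cycles
#' @param reference_mass channel used to estimate the shifts (default CN14,
#'   the biomass channel)
#' @param max_shift maximum allowed shift magnitude in pixels
#' @return list with `stack` (aligned), `shifts` (n_cycles x 2 matrix of the
#'   detected (row, col) displacement of each cycle relative to cycle 1),
#'   `valid` (height x width logical; TRUE where every cycle has in-frame
#'   data) and `flagged` (cycles whose reference image was all zero; shift 0)
#' @export
align_cycles <- function(stack, reference_mass = "CN14", max_shift = 10L) {
  if (!inherits(stack, "ion_image_stack")) stop("stack must be an ion_image_stack")
  if (stack$n_cycles < 2L) stop("alignment needs at least 2 cycles")
  nr <- stack$dim_px[1L]; nc <- stack$dim_px[2L]
  mi <- stack_mass(stack, reference_mass)
  ref <- matrix(stack$counts[mi, 1L, , ], nr, nc)
  Fref <- stats::fft(ref)
  shifts <- matrix(0L, stack$n_cycles, 2L,
                   dimnames = list(NULL, c("row", "col")))
  flagged <- integer(0)
  # allowed circular lags
  lag_of <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  lag_r <- lag_of(seq_len(nr), nr)
  lag_c <- lag_of(seq_len(nc), nc)
  ok <- outer(abs(lag_r) <= max_shift, abs(lag_c) <= max_shift, "&")
  for (j in 2L:stack$n_cycles) {
    img <- matrix(stack$counts[mi, j, , ], nr, nc)
    if (all(img == 0)) {
      flagged <- c(flagged, j)
      next
    }
    # corr(dr, dc) = sum ref[i, k] * img[i + dr, k + dc]
    cc <- Re(stats::fft(Conj(Fref) * stats::fft(img), inverse = TRUE))
    cc[!ok] <- -Inf
    w <- arrayInd(which.max(cc), dim(cc))
    shifts[j, ] <- c(lag_r[w[1L]], lag_c[w[2L]])
  }
  out <- stack$counts
  valid <- matrix(TRUE, nr, nc)
  for (j in 2L:stack$n_cycles) {
    dr <- -shifts[j, 1L]; dc <- -shifts[j, 2L]
    if (dr == 0L && dc == 0L) next
    for (m in 1:4)
      out[m, j, , ] <- translate_int(matrix(stack$counts[m, j, , ], nr, nc), dr, dc)
    vj <- translate_int(matrix(1, nr, nc), dr, dc) > 0
    valid <- valid & vj
  }
  list(stack = ion_image_stack(out, stack$pixel_size_nm, stack$dwell_ms),
       shifts = shifts, valid = valid, flagged = flagged)
}

#' Non-paralyzable dead-time correction
#'
#' Applies `n_true = n / (1 - n * tau / dwell)` per pixel and cycle, with tau
#' the detector dead time. `tau_ns = 0` disables the correction (the default
#' for synthetic data). Saturated pixels (`n * tau / dwell >= 1`) become NA.
#'
#' @param stack an `ion_image_stack`
#' @param tau_ns detector dead time in nanoseconds (default 44)
#' @return corrected `ion_image_stack` (real-valued); attribute
#'   `n_saturated` counts the invalidated pixels
#' @export
deadtime_correct <- function(stack, tau_ns = 44) {
  if (!inherits(stack, "ion_image_stack")) stop("stack must be an ion_image_stack")
  if (tau_ns < 0) stop("tau_ns must be >= 0")
  if (tau_ns == 0) return(stack)
  frac <- stack$counts * (tau_ns * 1e-6) / stack$dwell_ms
  sat <- frac >= 1
  corrected <- stack$counts / (1 - frac)
  corrected[sat] <- NA_real_
  out <- ion_image_stack(corrected, stack$pixel_size_nm, stack$dwell_ms,
                         require_integer = FALSE)
  attr(out, "n_saturated") <- sum(sat)
  out
}

# 4-connected component labelling by iterative minimum-label propagation
label_components_4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nr, nc))
  lab[idx] <- idx
  pad_inf <- Inf
  repeat {
    up <- rbind(lab[-1L, , drop = FALSE], pad_inf)
    dn <- rbind(pad_inf, lab[-nr, , drop = FALSE])
    lf <- cbind(lab[, -1L, drop = FALSE], pad_inf)
    rt <- cbind(pad_inf, lab[, -nc, drop = FALSE])
    new <- pmin(lab, up, dn, lf, rt)
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  labs <- lab[idx]
  out[idx] <- match(labs, sort(unique(labs)))
  out
}

equiv_diameter_um <- function(area_px, pixel_size_nm) {
  2 * sqrt(area_px / pi) * pixel_size_nm / 1000
}

make_roi <- function(id, pixels, source, pixel_size_nm) {
  area_px <- nrow(pixels)
  structure(list(id = id, pixels = pixels, source = source,
                 area_um2 = area_px * (pixel_size_nm / 1000)^2,
                 equiv_diameter_um = equiv_diameter_um(area_px, pixel_size_nm)),
            class = "sims_roi")
}

#' @export
print.sims_roi <- function(x, ...) {
  cat(sprintf("ROI %s (%s): %d px, %.3f um^2, equivalent diameter %.2f um\n",
              x$id, x$source, nrow(x$pixels), x$area_um2, x$equiv_diameter_um))
  invisible(x)
}

#' Automatic particle segmentation
#'
#' Thresholds the cycle-summed biomass channel and extracts 4-connected
#' components whose equivalent diameter lies within a size band. The default
#' threshold is `median + k * MAD` of the summed image (MAD scaled to the
#' normal, `stats::mad`), a robust background-plus-k-sigma rule; a fixed
#' numeric `threshold` overrides it. Particles low in 12C14N- because they
#' are highly 15N-enriched are recovered with `channel = "CN_total"`.
#'
#' @param stack an `ion_image_stack`
#' @param channel `"CN14"` (default) or `"CN_total"`
#' @param min_diameter_um,max_diameter_um equivalent-diameter band (um);
#'   defaults 0.3 um (bacteria scale) to Inf
#' @param k threshold: k robust sigmas above the background median
#' @param threshold fixed numeric threshold on the summed image (overrides k)
#' @param source tag recorded on each ROI
#' @return list of `sims_roi`, sorted by area (desc), ties by top-left pixel
#' @export
segment_particles <- function(stack, channel = c("CN14", "CN_total"),
                              min_diameter_um = 0.3, max_diameter_um = Inf,
                              k = 5, threshold = NULL,
                              source = "auto_threshold") {
  if (!inherits(stack, "ion_image_stack")) stop("stack must be an ion_image_stack")
  channel <- match.arg(channel)
  img <- channel_sum_image(stack, channel)
  if (is.null(threshold))
    threshold <- stats::median(img) + k * stats::mad(img)
  mask <- img > threshold
  lab <- label_components_4(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  rois <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    pix <- arrayInd(which(lab == i), dim(lab))
    colnames(pix) <- c("row", "col")
    d <- equiv_diameter_um(nrow(pix), stack$pixel_size_nm)
    keep[i] <- d >= min_diameter_um && d <= max_diameter_um
    rois[[i]] <- make_roi(sprintf("roi_%03d", i), pix, source,
                          stack$pixel_size_nm)
  }
  rois <- rois[keep]
  if (!length(rois)) return(list())
  area <- vapply(rois, function(r) nrow(r$pixels), numeric(1))
  tl_r <- vapply(rois, function(r) min(r$pixels[, "row"]), numeric(1))
  tl_c <- vapply(rois, function(r) min(r$pixels[, "col"]), numeric(1))
  ord <- order(-area, tl_r, tl_c)
  rois <- rois[ord]
  for (i in seq_along(rois)) rois[[i]]$id <- sprintf("roi_%03d", i)
  rois
}

#' Find large biomass hotspots
#'
#' Shallow-analysis mode for locating protist-scale targets: same pipeline as
#' [segment_particles()] but restricted to equivalent diameters of 4-50 um
#' and a more conservative threshold (default k = 10). Intended for stitched
#' / mosaic stacks whose field of view exceeds a single 20 um raster.
#'
#' @inheritParams segment_particles
#' @export
find_hotspots <- function(stack, min_diameter_um = 4, max_diameter_um = 50,
                          k = 10, threshold = NULL, channel = "CN14") {
  segment_particles(stack, channel = channel,
                    min_diameter_um = min_diameter_um,
                    max_diameter_um = max_diameter_um,
                    k = k, threshold = threshold, source = "hotspot")
}

#' Manually specified ROI
#'
#' Wraps a pixel list (e.g. drawn from a correlated SEM image) as a ROI.
#'
#' @param pixels two-column matrix of (row, col) coordinates (1-based)
#' @param stack the `ion_image_stack` the ROI lives on (for bounds/geometry)
#' @param id ROI identifier
#' @return a `sims_roi` with source `"manual"`
#' @export
manual_roi <- function(pixels, stack, id = "manual_001") {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L || nrow(pixels) == 0L)
    stop("pixels must be a non-empty two-column (row, col) matrix")
  colnames(pixels) <- c("row", "col")
  if (any(pixels[, 1L] < 1) || any(pixels[, 1L] > stack$dim_px[1L]) ||
      any(pixels[, 2L] < 1) || any(pixels[, 2L] > stack$dim_px[2L]))
    stop("ROI pixels out of image bounds")
  make_roi(id, pixels, "manual", stack$pixel_size_nm)
}

#' Per-ROI isotope statistics from ratios by cycle
#'
#' For every cycle, ion counts are summed over the ROI pixels and the two
#' isotope ratios formed from the sums (13C12C/12C2 and 12C15N/12C14N);
#' summing counts before dividing is the standard low-count ratio estimator.
#' Cycles with a zero denominator are excluded (and counted). The ratio mean
#' and standard error of the mean across usable cycles are reported, and the
#' mean ratios are converted to atom fractions, APE and X_net.
#'
#' @param stack an `ion_image_stack`
#' @param roi a `sims_roi`
#' @param constants an [isotope_constants()] block
#' @return list of class `roi_isotope_record`: per-cycle ratio vectors,
#'   means, SEMs, cycles used/excluded per element, a `usable` flag, and the
#'   derived [isotope_measurement()]
#' @export
roi_isotope_stats <- function(stack, roi, constants = isotope_constants()) {
  if (!inherits(stack, "ion_image_stack")) stop("stack must be an ion_image_stack")
  if (!inherits(roi, "sims_roi")) stop("roi must be a sims_roi")
  nr <- stack$dim_px[1L]; nc <- stack$dim_px[2L]
  px <- roi$pixels
  if (any(px[, 1L] < 1) || any(px[, 1L] > nr) ||
      any(px[, 2L] < 1) || any(px[, 2L] > nc))
    stop("ROI pixels out of image bounds")
  flat <- (px[, 2L] - 1L) * nr + px[, 1L]
  sums <- matrix(NA_real_, stack$n_cycles, 4L,
                 dimnames = list(NULL, c("C2", "C13C12", "CN14", "CN15")))
  for (m in 1:4) for (j in seq_len(stack$n_cycles)) {
    sl <- matrix(stack$counts[m, j, , ], nr, nc)
    sums[j, m] <- sum(sl[flat], na.rm = TRUE)
  }
  ratio_c <- ifelse(sums[, "C2"] > 0, sums[, "C13C12"] / sums[, "C2"], NA_real_)
  ratio_n <- ifelse(sums[, "CN14"] > 0, sums[, "CN15"] / sums[, "CN14"], NA_real_)
  mstat <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    list(mean = if (n) mean(x) else NA_real_,
         sem = if (n > 1L) stats::sd(x) / sqrt(n) else if (n == 1L) 0 else NA_real_,
         n = n)
  }
  sc <- mstat(ratio_c); sn <- mstat(ratio_n)
  usable <- sc$n > 0L && sn$n > 0L
  meas <- if (usable)
    isotope_measurement(carbon_ion_ratio_to_atom_fraction(sc$mean),
                        nitrogen_ion_ratio_to_atom_fraction(sn$mean),
                        constants)
  else NULL
  structure(list(
    roi_id = roi$id,
    ratios_c_by_cycle = ratio_c, ratios_n_by_cycle = ratio_n,
    ratio_mean_c = sc$mean, ratio_sem_c = sc$sem,
    ratio_mean_n = sn$mean, ratio_sem_n = sn$sem,
    n_cycles_used_c = sc$n, n_cycles_used_n = sn$n,
    n_cycles_excluded_c = stack$n_cycles - sc$n,
    n_cycles_excluded_n = stack$n_cycles - sn$n,
    usable = usable,
    measurement = meas
  ), class = "roi_isotope_record")
}

#' Tabulate ROI isotope records
#'
#' @param records list of `roi_isotope_record`
#' @return data.frame with columns roi_id, f13C, f15N, ape13C, ape15N,
#'   c_net, n_net, ratio SEMs and cycle counts
#' @export
roi_records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    m <- r$measurement
    data.frame(roi_id = r$roi_id,
               f13C = if (r$usable) m$f13C else NA_real_,
               f15N = if (r$usable) m$f15N else NA_real_,
               ape13C = if (r$usable) m$ape13C else NA_real_,
               ape15N = if (r$usable) m$ape15N else NA_real_,
               c_net = if (r$usable) m$c_net else NA_real_,
               n_net = if (r$usable) m$n_net else NA_real_,
               ratio_sem_c = r$ratio_sem_c, ratio_sem_n = r$ratio_sem_n,
               n_cycles_used_c = r$n_cycles_used_c,
               n_cycles_used_n = r$n_cycles_used_n,
               usable = r$usable)
  }))
}

#' Serialize ROI pixel masks as run-length-encoded JSON
#'
#' @param rois list of `sims_roi`
#' @param path output JSON path
#' @param dim_px image dimensions (rows, cols)
#' @export
write_roi_masks_json <- function(rois, path, dim_px) {
  enc <- lapply(rois, function(r) {
    flat <- sort((r$pixels[, "col"] - 1L) * dim_px[1L] + r$pixels[, "row"])
    starts <- flat[c(1L, which(diff(flat) != 1L) + 1L)]
    breaks <- c(0L, which(diff(flat) != 1L), length(flat))
    lens <- diff(breaks)
    list(id = r$id, source = r$source, area_um2 = r$area_um2,
         rle = list(start = starts, length = lens))
  })
  jsonlite::write_json(list(dim = dim_px, rois = enc), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an ion image stack as multi-page TIFF + JSON sidecar
#'
#' Pages are mass-major, cycle-minor (all cycles of 12C2-, then 13C12C-,
#' ...). Counts are stored as 16-bit TIFF samples; the sidecar records mass
#' order, geometry, dwell and cycle count. Counts above 65535 per pixel per
#' cycle are rejected (far beyond realistic ion counts at 1 ms dwell).
#'
#' @param stack an `ion_image_stack`
#' @param tif_path,json_path output paths
#' @export
write_ion_stack <- function(stack, tif_path, json_path) {
  if (any(stack$counts > 65535, na.rm = TRUE))
    stop("counts exceed 16-bit TIFF range")
  nr <- stack$dim_px[1L]; nc <- stack$dim_px[2L]
  pages <- list()
  for (m in 1:4) for (j in seq_len(stack$n_cycles)) {
    pg <- matrix(stack$counts[m, j, , ], nr, nc)
    pg[is.na(pg)] <- 0
    pages[[length(pages) + 1L]] <- pg / 65535
  }
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(masses = c("C2", "C13C12", "CN14", "CN15"),
                            n_cycles = stack$n_cycles,
                            dim_px = stack$dim_px,
                            pixel_size_nm = stack$pixel_size_nm,
                            dwell_ms = stack$dwell_ms,
                            scale = 65535),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' @rdname write_ion_stack
#' @export
read_ion_stack <- function(tif_path, json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  nr <- meta$dim_px[1L]; nc <- meta$dim_px[2L]
  counts <- array(0, dim = c(4L, meta$n_cycles, nr, nc))
  i <- 1L
  for (m in 1:4) for (j in seq_len(meta$n_cycles)) {
    counts[m, j, , ] <- round(pages[[i]] * meta$scale)
    i <- i + 1L
  }
  ion_image_stack(counts, meta$pixel_size_nm, meta$dwell_ms)
}
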