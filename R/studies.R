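#' @title Validation studies
#' @description Drivers reproducing the two phantom validation programs —
#'   the expansion-size sweep at zero background and the
#'   background-ratio study — plus the acquisition/reconstruction
#'   bookkeeping of the physical experiment, emitting tidy tables.
#' @name studies
NULL

.ratio_label <- function(r) if (r == 0) "none" else sprintf("%g:1", r)

# Quantify all spheres of `spec` on `recon` at several expansions,
# returning tidy rows.
.sweep_rows <- function(recon, spec, expansions_mm, ring_mm, seed_label,
                        supersample, mask_mode) {
  ratio <- if (spec$background_concentration_bq_ml == 0) 0 else
    spec$spheres[[1]]$concentration_bq_ml / spec$background_concentration_bq_ml
  rows <- list()
  for (e in expansions_mm) {
    qt <- quantify_phantom(recon, spec, expansion_mm = e,
                           background_ring_mm = ring_mm,
                           supersample = supersample, mask_mode = mask_mode)
    rows[[length(rows) + 1L]] <- data.frame(
      system_label = "digital", recon_label = "gaussian-psf",
      ratio = .ratio_label(ratio),
      sphere_diameter_mm = qt$diameter_mm, expansion_mm = e,
      seed = seed_label, TF = qt$TF, A_corr = qt$A_corr,
      flags = qt$flags, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Expansion-size sweep
#'
#' Full factorial sweep of VOI diameter expansions over every sphere of
#' the phantom, noise-free or over a set of Poisson seeds, with a derived
#' summary: the smallest expansion at which TF meets a threshold for every
#' sphere at or above a minimum diameter. The default sweep grid
#' `{0, 10, 20, 30, 40}` mm brackets the published 0-2-3-4 cm points and
#' adds 1 cm for resolution of the threshold search; the default summary
#' restricts to spheres >= 20 mm because the smallest sphere of the
#' physical phantom was compromised by a filling artifact the simulator
#' deliberately does not model.
#'
#' @param spec A [phantom_spec()] (default: zero-background digital IEC
#'   phantom, the published design for this study).
#' @param fwhm_mm Effective PSF FWHM, mm (default 12).
#' @param expansions_mm Diameter increments to sweep; must include 0.
#' @param ring_mm Background-ring diameter increment (default 10).
#' @param tf_threshold TF threshold for the summary (default 0.97).
#' @param min_diameter_mm Smallest sphere diameter included in the summary
#'   (default 20).
#' @param noise,seeds `"none"` (default) or `"poisson"` with a vector of
#'   seeds; each seed contributes a full set of records.
#' @param cal [calibration_factor()] for the noisy counts round trip.
#' @param supersample,mask_mode Passed to the mask builder.
#' @return An object of class `expansion_sweep`: list with `table` (tidy
#'   records: system_label, recon_label, ratio, sphere_diameter_mm,
#'   expansion_mm, seed, TF, RC, A_corr, flags), `threshold_expansion_mm`
#'   (NA if no swept expansion qualifies), `tf_threshold`,
#'   `min_diameter_mm`.
#' @export
expansion_sweep <- function(spec = iec_phantom_spec(0), fwhm_mm = 12,
                            expansions_mm = c(0, 10, 20, 30, 40),
                            ring_mm = 10, tf_threshold = 0.97,
                            min_diameter_mm = 20,
                            noise = c("none", "poisson"), seeds = NULL,
                            cal = NULL, supersample = 4L,
                            mask_mode = c("fractional", "voxel")) {
  noise <- match.arg(noise)
  mask_mode <- match.arg(mask_mode)
  if (!0 %in% expansions_mm)
    stop("the sweep must include expansion 0 (the recovery coefficient)")
  expansions_mm <- sort(unique(expansions_mm))
  truth <- voxelize(spec, supersample)
  base <- apply_psf(truth, psf_model(fwhm_mm))
  tab <- if (noise == "none") {
    .sweep_rows(base, spec, expansions_mm, ring_mm, "noise-free",
                supersample, mask_mode)
  } else {
    if (is.null(seeds)) stop("poisson noise requires seeds")
    if (is.null(cal)) cal <- calibration_factor(10, 30)
    do.call(rbind, lapply(seeds, function(sd) {
      recon <- to_activity(add_poisson_noise(to_counts(base, cal), sd), cal)
      .sweep_rows(recon, spec, expansions_mm, ring_mm, as.character(sd),
                  supersample, mask_mode)
    }))
  }
  # attach the zero-expansion TF (the recovery coefficient) to every record
  rc <- tab[tab$expansion_mm == 0,
            c("sphere_diameter_mm", "seed", "TF")]
  names(rc)[3] <- "RC"
  tab <- merge(tab, rc, by = c("sphere_diameter_mm", "seed"), sort = FALSE)
  tab <- tab[order(match(tab$seed, unique(tab$seed)),
                   tab$sphere_diameter_mm, tab$expansion_mm), ]
  rownames(tab) <- NULL

  big <- tab[tab$sphere_diameter_mm >= min_diameter_mm, ]
  ok_e <- vapply(expansions_mm, function(e)
    all(big$TF[big$expansion_mm == e] >= tf_threshold), TRUE)
  threshold_expansion_mm <- if (any(ok_e)) min(expansions_mm[ok_e]) else NA_real_
  structure(list(table = tab,
                 threshold_expansion_mm = threshold_expansion_mm,
                 tf_threshold = tf_threshold,
                 min_diameter_mm = min_diameter_mm,
                 expansions_mm = expansions_mm, fwhm_mm = fwhm_mm,
                 ring_mm = ring_mm),
            class = "expansion_sweep")
}

#' @export
print.expansion_sweep <- function(x, ...) {
  cat(sprintf("<expansion_sweep> fwhm %g mm, expansions {%s} mm\n",
              x$fwhm_mm, paste(x$expansions_mm, collapse = ", ")))
  cat(sprintf("  smallest expansion with TF >= %g for all spheres >= %g mm: %s\n",
              x$tf_threshold, x$min_diameter_mm,
              if (is.na(x$threshold_expansion_mm)) "none in sweep" else
                sprintf("%g mm", x$threshold_expansion_mm)))
  invisible(x)
}

#' Background-ratio study
#'
#' Runs the phantom at several sphere-to-background concentration ratios
#' and reports, per sphere and ratio, both the expanded-VOI true fraction
#' and the traditional (zero-expansion) recovery coefficient, plus a
#' summary of mean TF per sphere averaged over the benign conditions
#' (no background, 8:1, 4:1 — the 2:1 condition is deliberately excluded
#' from the average, matching the published analysis where it is degraded
#' by unmodelled scanner physics).
#'
#' @param ratios Sphere:background ratios; 0 means no background activity.
#' @param fwhm_mm Effective PSF FWHM, mm.
#' @param expansion_mm Diameter expansion for the TF (default 20 mm).
#' @param ring_mm Background-ring increment (default 10 mm).
#' @param sphere_concentration_bq_ml Concentration in the spheres.
#' @param calibration_bias Uniform multiplicative bias applied to the
#'   reconstruction (default 1 = none); TF scales by exactly this factor.
#' @param noise,seeds,cal As in [expansion_sweep()].
#' @param average_ratios Ratios entering the mean-TF summary.
#' @param supersample,mask_mode Passed to the mask builder.
#' @return An object of class `background_study`: list with `table`
#'   (ratio, sphere_diameter_mm, seed, TF, RC, A_corr, flags) and
#'   `mean_tf` (per-sphere mean TF over `average_ratios`).
#' @export
background_study <- function(ratios = c(0, 8, 4, 2), fwhm_mm = 12,
                             expansion_mm = 20, ring_mm = 10,
                             sphere_concentration_bq_ml = 12 * BQ_PER_UCI,
                             calibration_bias = 1,
                             noise = c("none", "poisson"), seeds = NULL,
                             cal = NULL, average_ratios = c(0, 8, 4),
                             supersample = 4L,
                             mask_mode = c("fractional", "voxel")) {
  noise <- match.arg(noise)
  mask_mode <- match.arg(mask_mode)
  if (length(ratios) == 0) stop("at least one ratio is required")
  rows <- list()
  for (r in ratios) {
    spec <- iec_phantom_spec(r, sphere_concentration_bq_ml)
    truth <- voxelize(spec, supersample)
    base <- apply_psf(truth, psf_model(fwhm_mm))
    if (calibration_bias != 1)
      base <- apply_calibration_bias(base, calibration_bias)
    recons <- if (noise == "none") list(`noise-free` = base) else {
      if (is.null(seeds)) stop("poisson noise requires seeds")
      if (is.null(cal)) cal <- calibration_factor(10, 30)
      stats::setNames(lapply(seeds, function(sd)
        to_activity(add_poisson_noise(to_counts(base, cal), sd), cal)),
        as.character(seeds))
    }
    for (lab in names(recons)) {
      recon <- recons[[lab]]
      tf <- quantify_phantom(recon, spec, expansion_mm, ring_mm,
                             supersample, mask_mode)
      rc <- quantify_phantom(recon, spec, 0, ring_mm, supersample, mask_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        system_label = "digital", recon_label = "gaussian-psf",
        ratio = .ratio_label(r), ratio_value = r,
        sphere_diameter_mm = tf$diameter_mm, expansion_mm = expansion_mm,
        seed = lab, TF = tf$TF, RC = rc$TF, A_corr = tf$A_corr,
        flags = tf$flags, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  avg <- tab[tab$ratio_value %in% average_ratios, ]
  mean_tf <- stats::aggregate(TF ~ sphere_diameter_mm, data = avg, FUN = mean)
  names(mean_tf)[2] <- "mean_TF"
  structure(list(table = tab, mean_tf = mean_tf,
                 average_ratios = average_ratios,
                 expansion_mm = expansion_mm, ring_mm = ring_mm,
                 fwhm_mm = fwhm_mm),
            class = "background_study")
}

#' @export
print.background_study <- function(x, ...) {
  cat(sprintf("<background_study> fwhm %g mm, expansion +%g mm, ring +%g mm\n",
              x$fwhm_mm, x$expansion_mm, x$ring_mm))
  cat(sprintf("  ratios: %s\n", paste(unique(x$table$ratio), collapse = ", ")))
  cat("  mean TF over", paste(vapply(x$average_ratios, .ratio_label, ""),
                              collapse = ", "), "\n")
  print(x$mean_tf, row.names = FALSE)
  invisible(x)
}

#' Acquisition / reconstruction bookkeeping
#'
#' Enumerates the experiment matrix: one acquisition per system and
#' background ratio, and one reconstruction task per acquisition and
#' reconstruction package available for that system. The published design
#' (GE and Philips systems, four ratios, GE data reconstructed with two
#' packages and Philips with one) gives 8 acquisitions and 12
#' reconstruction sets.
#'
#' @param systems Character vector of system labels.
#' @param ratios Character or numeric vector of background conditions.
#' @param recon_packages Named list mapping each system to its
#'   reconstruction packages.
#' @return An object of class `experiment_matrix`: list with
#'   `acquisitions` and `reconstructions` data.frames and the counts
#'   `n_acquisitions`, `n_reconstructions`.
#' @examples
#' m <- experiment_matrix()
#' m$n_acquisitions      # 8
#' m$n_reconstructions   # 12
#' @export
experiment_matrix <- function(systems = c("GE", "Philips"),
                              ratios = c("none", "8:1", "4:1", "2:1"),
                              recon_packages = list(
                                GE = c("Hermes", "Q.Metrix"),
                                Philips = "Hermes")) {
  if (length(systems) == 0 || length(ratios) == 0)
    stop("systems and ratios must be non-empty")
  if (!all(systems %in% names(recon_packages)))
    stop("every system needs an entry in recon_packages")
  acq <- expand.grid(system = systems, ratio = ratios,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(seq_len(nrow(acq)), function(i) {
    pk <- recon_packages[[acq$system[i]]]
    if (length(pk) == 0) stop("system without reconstruction package")
    data.frame(system = acq$system[i], ratio = acq$ratio[i],
               package = pk, stringsAsFactors = FALSE)
  }))
  structure(list(acquisitions = acq, reconstructions = rec,
                 n_acquisitions = nrow(acq),
                 n_reconstructions = nrow(rec)),
            class = "experiment_matrix")
}

#' @export
print.experiment_matrix <- function(x, ...) {
  cat(sprintf("<experiment_matrix> %d acquisitions, %d reconstruction sets\n",
              x$n_acquisitions, x$n_reconstructions))
  invisible(x)
}
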