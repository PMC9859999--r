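# Shared fixtures, computed once per test run (everything is generated in
# code; nothing is stored on disk).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_truth <- function(ratio = 0) {
  cached(sprintf("truth_r%g", ratio), voxelize(iec_phantom_spec(ratio)))
}

default_recon <- function(ratio = 0, fwhm = 12) {
  cached(sprintf("recon_r%g_f%g", ratio, fwhm),
         apply_psf(default_truth(ratio), psf_model(fwhm)))
}

# Compact single-sphere phantom on its own small grid (sphere near the
# world origin, generic off-lattice centre), sized so that a 12 mm FWHM
# blur and the largest VOI expansions stay clear of the boundary.
single_sphere_spec <- function(diameter_mm, concentration = 444000,
                               background_ratio = 0, margin_mm = 40,
                               spacing = 3.2, body_size_mm = NULL) {
  center <- c(0.4, -0.9, 1.3)
  extent <- diameter_mm + 2 * margin_mm
  n <- as.integer(ceiling(extent / spacing))
  bg <- if (background_ratio == 0) 0 else concentration / background_ratio
  # when a blurred background is involved, pass a body_size_mm smaller
  # than the grid (>= ~5 sigma of margin) so the blur conserves counts
  if (is.null(body_size_mm)) body_size_mm <- extent
  s <- sphere_spec(sprintf("S%g", diameter_mm), center, diameter_mm,
                   concentration)
  phantom_spec(list(s), body_size_mm = rep(body_size_mm, 3),
               body_center_mm = c(0, 0, 0),
               background_concentration_bq_ml = bg,
               grid_shape = rep(n, 3L), voxel_spacing_mm = spacing)
}

single_sphere_recon <- function(diameter_mm, fwhm = 12, ...) {
  cached(sprintf("ss_recon_d%g_f%g", diameter_mm, fwhm), {
    spec <- single_sphere_spec(diameter_mm, ...)
    apply_psf(voxelize(spec), psf_model(fwhm))
  })
}

default_sweep <- function() {
  cached("sweep_default", expansion_sweep())
}

default_background_study <- function() {
  cached("bgstudy_default", background_study(ratios = c(0, 8, 4)))
}
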