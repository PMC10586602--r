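#' Generate a synthetic binary mussel-cover mask
#'
#' Rasterizes a phenomenological patch scene for one cage: a number of
#' filled circular clumps whose count and radius both grow with the
#' biomass density, placed uniformly at random, with overlap allowed.
#' At higher densities clumps are larger and coalesce more, so the
#' measured perimeter-to-area ratio declines with density, mirroring the
#' observed patch-shape pattern. Masks are not a movement model; they
#' reproduce the geometry the morphometry stage consumes, not the
#' behaviour that creates it.
#'
#' A density of exactly 0 returns an empty mask. `target_ptoa_m`
#' overrides the density-driven clump radius with r = 2 / PtoA (the
#' radius at which discs attain that perimeter-to-area ratio), so a mask
#' can be built to approximate a ratio drawn from the patch-shape model
#' by [gen_ptoa()]. `n_clumps` and `radius_px` force the clump count and
#' exact pixel radius, which is useful for analytic checks.
#'
#' @param density_kg_m2 biomass density (kg m^-2), >= 0.
#' @param params mask parameters from [mask_params()].
#' @param seed integer RNG seed.
#' @param target_ptoa_m optional target perimeter-to-area ratio (m^-1).
#' @param n_clumps optional forced clump count.
#' @param radius_px optional forced clump radius (pixels, no spread).
#' @return A logical matrix with attribute `scale_mm_per_px`.
#' @export
gen_patch_mask <- function(density_kg_m2, params = mask_params(), seed = 1L,
                           target_ptoa_m = NULL, n_clumps = NULL,
                           radius_px = NULL) {
  if (params$dim_px < 16) stop(errorCondition(
    "mask dimensions must be at least 16 x 16 px",
    class = c("musselpatch_config_error", "error")))
  if (density_kg_m2 < 0) stop("density must be >= 0")
  dim_px <- params$dim_px
  scale <- params$scale_mm_per_px
  mask <- matrix(FALSE, dim_px, dim_px)
  attr(mask, "scale_mm_per_px") <- scale
  if (density_kg_m2 == 0) return(mask)
  set.seed(seed)

  if (is.null(n_clumps)) {
    n_clumps <- max(1L, as.integer(round(
      params$clump_base + params$clump_per_density * density_kg_m2)))
  }
  if (is.null(radius_px)) {
    r_mm <- if (!is.null(target_ptoa_m)) 2000 / target_ptoa_m
            else params$radius_base_mm +
                 params$radius_per_density_mm * density_kg_m2
    r_mean_px <- r_mm / scale
    cv <- params$radius_cv
    radii <- if (cv > 0) stats::rgamma(n_clumps, shape = 1 / cv^2,
                                       scale = r_mean_px * cv^2)
             else rep(r_mean_px, n_clumps)
    radii <- pmax(1.5, radii)
  } else {
    radii <- rep(radius_px, n_clumps)
  }
  # keep each clump inside the plot so discs are not clipped at the border
  lo <- pmax(1 + params$margin_px, radii + 2)
  hi <- pmin(dim_px - params$margin_px, dim_px - radii - 1)
  mid <- (dim_px + 1) / 2
  bad <- lo >= hi
  cx <- ifelse(bad, mid, stats::runif(n_clumps, lo, hi))
  cy <- ifelse(bad, mid, stats::runif(n_clumps, lo, hi))
  rows <- row(mask); cols <- col(mask)
  for (k in seq_len(n_clumps)) {
    mask <- mask | ((rows - cx[k])^2 + (cols - cy[k])^2 <= radii[k]^2)
  }
  attr(mask, "scale_mm_per_px") <- scale
  mask
}
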