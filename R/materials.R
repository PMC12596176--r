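#' Phantom material specification
#'
#' Materials are defined by a nominal CT number and an intrinsic texture SD.
#' Uniform test materials (air, water, foams, plastics) have zero texture;
#' fixed lung-core samples are heterogeneous and carry a non-zero
#' `texture_sd` which the rasterizer realizes as a smoothed, seeded Gaussian
#' field.
#'
#' @param name material label.
#' @param nominal_hu nominal CT number in HU, within [-1024, 3000].
#' @param texture_sd intrinsic heterogeneity SD in HU (>= 0; 0 = uniform).
#' @return A `material_spec` list.
#' @export
material_spec <- function(name, nominal_hu, texture_sd = 0) {
  nominal_hu <- as.numeric(nominal_hu)
  if (!is.finite(nominal_hu) || nominal_hu < -1024 || nominal_hu > 3000)
    stopf("nominal_hu for '%s' must be in [-1024, 3000]", name)
  if (!is.finite(texture_sd) || texture_sd < 0)
    stopf("texture_sd for '%s' must be >= 0", name)
  structure(list(name = as.character(name), nominal_hu = nominal_hu,
                 texture_sd = texture_sd), class = "material_spec")
}

## Default material table.  Air and water are ground truth (-1000 / 0 HU);
## standardized foam and phantom-foam values follow a low-dose reference
## acquisition of the physical inserts; plastics use textbook CT numbers.
## Lung-core samples get a 130 HU texture so that low-attenuation-area
## fractions are non-trivial.
default_materials <- function() {
  specs <- list(
    material_spec("air",               -1000),
    material_spec("water",                 0),
    material_spec("lung_foam",          -629),
    material_spec("nist_4",             -934),
    material_spec("nist_8",             -883),
    material_spec("nist_12",            -821),
    material_spec("nist_14",            -778),
    material_spec("nist_20",            -683),
    material_spec("lung_sample",        -656, texture_sd = 130),
    material_spec("hdpe",                -80),
    material_spec("urethane",             60),
    material_spec("acrylic",             120),
    material_spec("pmp",                -180),
    material_spec("low_contrast",         15),
    material_spec("bone_20",             200),
    material_spec("bone_50",             500),
    material_spec("tissue",               25),
    material_spec("tungsten_carbide",   3000)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
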