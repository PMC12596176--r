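#' Phantom insert specification
#'
#' One physical object inside a phantom tube.  Cylinders always run along
#' the z (cranio-caudal) axis; the cube used for modulation-transfer
#' measurements may carry a small tilt, as physical inserts are never
#' perfectly aligned with the scanner axes.
#'
#' @param label unique insert label.
#' @param material a [material_spec()].
#' @param shape `"cylinder"` or `"cube"`.
#' @param center numeric length-3 centre in mm.
#' @param radius_or_halfedge cylinder radius or cube half-edge in mm.
#' @param length cylinder length in mm (ignored for cubes).
#' @param tilt numeric length-2: cube rotation about the z and x axes in
#'   radians (cylinders must be untilted).
#' @param role `"insert"` for labelled, measured payloads; `"carrier"` for
#'   unlabelled support geometry painted beneath the payloads.
#' @return An `insert_spec` list.
#' @export
insert_spec <- function(label, material, shape = c("cylinder", "cube"),
                        center, radius_or_halfedge, length = NULL,
                        tilt = c(0, 0), role = "insert") {
  shape <- match.arg(shape)
  if (!inherits(material, "material_spec")) stopf("material must be a material_spec")
  if (shape == "cylinder" && is.null(length))
    stopf("cylinder '%s' needs a length", label)
  if (shape == "cylinder" && any(tilt != 0))
    stopf("cylinders run along z and cannot be tilted")
  structure(list(label = as.character(label), material = material,
                 shape = shape, center = as.numeric(center),
                 radius_or_halfedge = as.numeric(radius_or_halfedge),
                 length = if (is.null(length)) NA_real_ else as.numeric(length),
                 tilt = as.numeric(tilt), role = role),
            class = "insert_spec")
}

## ---- fixed phantom geometry (mm) -------------------------------------
## The physical phantom provides no public blueprint; these placement
## constants are package-defined and documented in the methods vignette.
## Body cross-section 435 x 229 mm with one large tubular channel in the
## right lung and two smaller channels (anterior/posterior) in the left.
phantom_geometry <- function() {
  list(
    body_semi   = c(217.5, 114.5),
    lung_center = list(right = c(-95, 0), left = c(95, 0)),
    lung_semi   = c(72, 82),
    large_tube  = list(center = c(-95, 0), outer_r = 30, inner_r = 25),
    small_tubes = list(anterior  = list(center = c(95, -55), outer_r = 17, inner_r = 14),
                       posterior = list(center = c(95,  55), outer_r = 17, inner_r = 14)),
    segment_length = 40,     # z extent allotted to each stacked insert
    payload_r_large = 18,    # payload radius inside large-tube carriers
    carrier_r_large = 24,    # carrier radius in the large tube
    payload_r_small = 14,    # small-tube foam inserts fill the bore
    cube_half_edge  = 10,    # 2 cm MTF cube
    cube_tilt       = c(2, 2) * pi / 180
  )
}

## stacked insert contents per configuration; large tube mixes test
## objects, the two small tubes hold standardized foams and bone inserts
config_contents <- function() {
  list(
    i   = list(large = c("lung_sample_a", "mtf_cube", "air"),
               anterior = c("bone_50", "nist_8"),
               posterior = c("nist_4", "nist_12")),
    ii  = list(large = c("water", "lung_sample_b", "acrylic"),
               anterior = c("bone_20", "nist_14"),
               posterior = c("nist_20", "low_contrast")),
    iii = list(large = c("lung_sample_c", "pmp", "acrylic"),
               anterior = c("nist_12", "nist_4"),
               posterior = c("nist_14", "bone_20")),
    iv  = list(large = c("water", "air", "mtf_cube", "lung_sample_a"),
               anterior = "nist_8",
               posterior = "nist_12")
  )
}

label_material <- function(label) {
  if (grepl("^lung_sample", label)) return("lung_sample")
  if (grepl("^water", label)) return("water")
  label
}

## expand one z-segment of a tube into payload (and carrier) insert specs
build_segment <- function(label, tube_center, zc, geom, mats, large) {
  segs <- list()
  pr <- if (large) geom$payload_r_large else geom$payload_r_small
  cr <- geom$carrier_r_large
  plen <- geom$segment_length - 4
  at <- function(dz = 0) c(tube_center, zc + dz)
  if (label == "mtf_cube" && large) {
    ## HDPE cube glued to an HDPE end cap at its -z face; air around
    segs <- c(segs, list(
      insert_spec(paste0(label, "_cap"), mats$hdpe, "cylinder", at(-15),
                  cr, length = 6, role = "carrier"),
      insert_spec(label, mats$hdpe, "cube", at(-2), geom$cube_half_edge,
                  tilt = geom$cube_tilt)))
  } else if (label == "water" && large) {
    ## two 10 mL vials inside a urethane carrier, separated along z
    segs <- c(segs, list(
      insert_spec(paste0(label, "_carrier"), mats$urethane, "cylinder", at(),
                  cr, length = plen, role = "carrier"),
      insert_spec("water_vial_1", mats$water, "cylinder", at(-11), 11, length = 14),
      insert_spec("water_vial_2", mats$water, "cylinder", at(11), 11, length = 14)))
  } else if (large) {
    mat <- mats[[label_material(label)]]
    segs <- c(segs, list(
      insert_spec(paste0(label, "_carrier"), mats$hdpe, "cylinder", at(),
                  cr, length = plen, role = "carrier"),
      insert_spec(label, mat, "cylinder", at(), pr, length = plen)))
  } else {
    segs <- c(segs, list(
      insert_spec(label, mats[[label_material(label)]], "cylinder", at(),
                  pr, length = plen)))
  }
  segs
}

#' Build a phantom layout for one insert configuration
#'
#' Returns the declarative geometry of the chest phantom -- body, lung
#' foam, three tubular channels and the stacked labelled inserts -- for one
#' of the four insert configurations.  Configurations i-iii spread the test
#' objects over three series; configuration iv packs water, air, the MTF
#' cube and a lung sample into the large tube so that one series carries
#' all primary inserts.
#'
#' @param configuration one of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param materials named list of [material_spec()]s; defaults cover all
#'   standard inserts.
#' @return A `phantom_layout` with fields `configuration`, `body_extent`
#'   (mm, left-right and anterior-posterior), `inserts`, `lung_foam_hu`,
#'   `tube_wall_hu` and the internal geometry table.
#' @examples
#' lay <- build_layout("iv")
#' vapply(lay$inserts[vapply(lay$inserts, `[[`, "", "role") == "insert"],
#'        `[[`, "", "label")
#' @export
build_layout <- function(configuration, materials = default_materials()) {
  cfgs <- config_contents()
  configuration <- as.character(configuration)
  if (!configuration %in% names(cfgs))
    stopf("unknown configuration '%s'; valid options are: %s",
          configuration, paste(names(cfgs), collapse = ", "))
  geom <- phantom_geometry()
  cfg <- cfgs[[configuration]]
  inserts <- list()
  add_tube <- function(labels, tube_center, large) {
    n <- length(labels)
    zc <- (seq_len(n) - (n + 1) / 2) * geom$segment_length
    out <- list()
    for (i in seq_len(n))
      out <- c(out, build_segment(labels[i], tube_center, zc[i], geom,
                                  materials, large))
    out
  }
  inserts <- c(inserts,
               add_tube(cfg$large, geom$large_tube$center, TRUE),
               add_tube(cfg$anterior, geom$small_tubes$anterior$center, FALSE),
               add_tube(cfg$posterior, geom$small_tubes$posterior$center, FALSE))
  labs <- vapply(inserts, `[[`, "", "label")
  if (anyDuplicated(labs)) stopf("internal: duplicate insert labels")
  structure(list(configuration = configuration,
                 body_extent = c(435, 229),
                 inserts = inserts,
                 lung_foam_hu = materials$lung_foam$nominal_hu,
                 tube_wall_hu = materials$urethane$nominal_hu,
                 body_hu = materials$tissue$nominal_hu,
                 geometry = geom,
                 materials = materials),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  labs <- vapply(x$inserts[vapply(x$inserts, `[[`, "", "role") == "insert"],
                 `[[`, "", "label")
  cat(sprintf("<phantom_layout> configuration %s, body %g x %g mm\n",
              x$configuration, x$body_extent[1], x$body_extent[2]))
  cat("  inserts:", paste(labs, collapse = ", "), "\n")
  invisible(x)
}

layout_insert_labels <- function(layout) {
  ins <- layout$inserts[vapply(layout$inserts, `[[`, "", "role") == "insert"]
  vapply(ins, `[[`, "", "label")
}

#' Serialize a phantom layout to JSON
#'
#' Writes labels, shapes, centres (mm) and materials so that a layout can
#' be archived next to the simulated series it produced.
#'
#' @param layout a `phantom_layout`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  ins <- lapply(layout$inserts, function(s)
    list(label = s$label, material = s$material$name,
         nominal_hu = s$material$nominal_hu, shape = s$shape,
         center = s$center, radius_or_halfedge = s$radius_or_halfedge,
         length = s$length, tilt = s$tilt, role = s$role))
  jsonlite::write_json(
    list(configuration = layout$configuration,
         body_extent = layout$body_extent,
         lung_foam_hu = layout$lung_foam_hu,
         tube_wall_hu = layout$tube_wall_hu,
         inserts = ins),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
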