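# File formats: 32-bit TIFF for non-negative raw detector images,
# full-precision CSV for signed/dimensionless maps, YAML configs with
# explicit unit strings, JSON run summaries.

UNIT_TABLE <- list(
  m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9,
  keV = 1, kev = 1, rad = 1, px = NA_real_ # px resolved by caller
)

#' Parse a quantity with an explicit unit
#'
#' Config values carry their unit as a string (e.g. `"55 um"`, `"0.6 m"`,
#' `"20 keV"`) to prevent silent metre/micron mistakes. Bare numbers are
#' accepted as already being in the expected base unit.
#'
#' @param x A string like `"55 um"` or a bare number.
#' @param expect Base unit the result is returned in: `"m"`, `"keV"` or
#'   `"rad"`.
#' @return Numeric value in the base unit.
#' @export
#' @examples
#' parse_quantity("55 um", "m") # 5.5e-05
parse_quantity <- function(x, expect = "m") {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1) stop("quantity must be a number or a 'value unit' string")
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  val <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(val)) stop("cannot parse quantity '", x, "'")
  if (length(parts) == 1) return(val)
  unit <- parts[2]
  if (!unit %in% names(UNIT_TABLE)) stop("unknown unit '", unit, "' in '", x, "'")
  fac <- UNIT_TABLE[[unit]]
  base <- if (tolower(unit) == "kev") "keV" else if (unit == "rad") "rad" else "m"
  if (base != expect) stop("unit '", unit, "' is not a ", expect, " unit (in '", x, "')")
  if (is.na(fac)) stop("unit 'px' must be resolved by the caller")
  val * fac
}

#' Write an image matrix to disk
#'
#' Format follows the extension: `.tif`/`.tiff` writes single-page
#' uncompressed 32-bit TIFF (values must lie in `[0, 1]`, which all
#' length-unit detector images do; stored resolution is `2^-32` of full
#' scale); `.csv` writes a headerless full-precision (`%.17g`) matrix that
#' round-trips exactly.
#'
#' @param image A `detector_image`, or a plain numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  vals <- if (inherits(image, "detector_image")) image$values else image
  stopifnot(is.matrix(vals))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (any(!is.finite(vals)) || min(vals) < 0 || max(vals) > 1) {
      stop("TIFF output requires finite values in [0, 1]; write this image as .csv instead")
    }
    tiff::writeTIFF(vals, path, bits.per.sample = 32L, compression = "none")
  } else if (ext == "csv") {
    lines <- apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(lines, path)
  } else {
    stop("unsupported image extension '", ext, "' (use .tif or .csv)")
  }
  invisible(path)
}

#' Read an image matrix from disk
#'
#' Counterpart of [write_image()].
#'
#' @param path `.tif`/`.tiff` or `.csv` file.
#' @return A numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3) v <- v[, , 1]
    matrix(as.numeric(v), nrow(v), ncol(v))
  } else if (ext == "csv") {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    m
  } else {
    stop("unsupported image extension '", ext, "'")
  }
}

RUN_CONFIG_BLOCKS <- list(
  geometry = c("z", "pixel_size", "nx", "ny", "energy", "oversampling"),
  mask = c("type", "pixel_size", "offset", "open_fraction", "contrast",
           "harmonics", "coeffs"),
  phantom = c("type", "radius", "material", "center_x", "outer_r",
              "wall_thickness", "rod_r", "wall_material", "fill_material",
              "rod_material", "amplitude_phi", "amplitude_att", "sigma"),
  noise = c("counts", "seed"),
  retrieval = c("parity", "pairing", "epsilon"),
  validate = c("source_fwhm", "guard_periods", "rms_tolerance", "masks")
)

config_error <- function(...) {
  stop(structure(class = c("smpci_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Default run configuration
#'
#' The geometry block mirrors the reference table-top setup (0.6 m
#' propagation, 55 micron pixels, 20 keV design energy, 7 micron source);
#' the default phantom is a 3 mm PMMA rod behind a cosine mask.
#'
#' @return A named list (a valid run config).
#' @export
default_run_config <- function() {
  list(
    geometry = list(z = "0.6 m", pixel_size = "55 um", nx = 128L, ny = 8L,
                    energy = "20 keV", oversampling = 16L),
    mask = list(type = "cosine"),
    phantom = list(type = "cylinder", radius = "1.5 mm", material = "pmma"),
    noise = list(counts = 0, seed = 1L),
    retrieval = list(parity = 1L, pairing = "disjoint", epsilon = 1e-6),
    validate = list(source_fwhm = "7 um", guard_periods = 8L,
                    rms_tolerance = 0.05,
                    masks = list(
                      mask1 = list(type = "binary", open_fraction = 0.5, contrast = 1.0),
                      mask2 = list(type = "cosine")))
  )
}

validate_run_config <- function(cfg) {
  if (!is.list(cfg)) config_error("run config must be a mapping")
  unknown <- setdiff(names(cfg), names(RUN_CONFIG_BLOCKS))
  if (length(unknown)) {
    config_error("unknown config block(s): ", paste(unknown, collapse = ", "))
  }
  for (blk in names(cfg)) {
    if (blk == "validate") next # masks sub-blocks validated on use
    bad <- setdiff(names(cfg[[blk]]), RUN_CONFIG_BLOCKS[[blk]])
    if (length(bad)) {
      config_error("unknown key(s) in '", blk, "' block: ",
                   paste(bad, collapse = ", "))
    }
  }
  cfg
}

#' Read and validate a run configuration
#'
#' Reads a YAML run config, fills unset blocks from
#' [default_run_config()], and rejects unknown keys (naming the offender).
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) config_error("config file not found: ", path)
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
  def <- default_run_config()
  for (blk in names(def)) {
    if (is.null(cfg[[blk]])) {
      cfg[[blk]] <- def[[blk]]
    } else {
      for (key in names(def[[blk]])) {
        if (is.null(cfg[[blk]][[key]])) cfg[[blk]][[key]] <- def[[blk]][[key]]
      }
    }
  }
  cfg
}

geometry_from_config <- function(cfg) {
  g <- cfg$geometry
  imaging_geometry(
    z = parse_quantity(g$z, "m"),
    p = parse_quantity(g$pixel_size, "m"),
    nx = as.integer(g$nx), ny = as.integer(g$ny),
    energy = parse_quantity(g$energy, "keV"),
    s = as.integer(g$oversampling)
  )
}

material_from_config <- function(x) {
  if (is.character(x)) return(builtin_material(x))
  xray_material(x$name %||% "custom", x$delta, x$mu)
}

phantom_from_config <- function(cfg, geometry) {
  ph <- cfg$phantom
  cx <- if (!is.null(ph$center_x)) parse_quantity(ph$center_x, "m") else NULL
  switch(ph$type,
    cylinder = make_cylinder_phantom(parse_quantity(ph$radius, "m"),
                                     material_from_config(ph$material),
                                     geometry, center_x = cx),
    tube = make_tube_phantom(parse_quantity(ph$outer_r, "m"),
                             parse_quantity(ph$wall_thickness, "m"),
                             parse_quantity(ph$rod_r, "m"),
                             material_from_config(ph$wall_material %||% "polycarbonate"),
                             material_from_config(ph$fill_material %||% "water"),
                             material_from_config(ph$rod_material %||% "pmma"),
                             geometry, center_x = cx),
    gaussian = make_gaussian_phantom(parse_quantity(ph$amplitude_phi, "rad"),
                                     ph$amplitude_att %||% 0,
                                     parse_quantity(ph$sigma, "m"),
                                     geometry, center_x = cx),
    config_error("unknown phantom type '", ph$type, "'")
  )
}
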