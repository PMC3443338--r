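# YAML serialization of phantom and scanner specifications. Field names
# match the constructors; units are part of the field names where they are
# not cm (the package-internal length unit).

#' Read / write a phantom specification as YAML
#'
#' The file holds the `phantom_spec` fields verbatim (lengths in cm,
#' hole metadata in mm, density in g/cm^3).
#'
#' @param path YAML file path.
#' @param phantom A `phantom_spec`.
#' @return `read_phantom_config` returns a `phantom_spec`.
#' @export
read_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_spec(shape = y$shape,
               min_diameter = y$min_diameter,
               max_diameter = y$max_diameter,
               theta_deg = y$theta_deg,
               length = y$length,
               density = if (is.null(y$density)) 0.96 else y$density,
               hole_offsets_mm = unlist(y$hole_offsets_mm),
               hole_diameter_mm = if (is.null(y$hole_diameter_mm)) 4
                                  else y$hole_diameter_mm)
}

#' @rdname read_phantom_config
#' @export
write_phantom_config <- function(phantom, path) {
  yaml::write_yaml(unclass(phantom), path)
  invisible(path)
}

#' Read / write a scanner specification as YAML
#'
#' Users can define new scanners without code changes; presets for the
#' two modeled systems ship under `inst/extdata/scanners/`.
#'
#' @param path YAML file path.
#' @param scanner A `scanner_spec`.
#' @return `read_scanner_config` returns a `scanner_spec`.
#' @export
read_scanner_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scanner_spec, y)
}

#' @rdname read_scanner_config
#' @export
write_scanner_config <- function(scanner, path) {
  yaml::write_yaml(unclass(scanner)[setdiff(names(scanner),
                                            "crystal_axial_pitch_mm")],
                   path)
  invisible(path)
}

#' Load a shipped scanner preset by name
#'
#' @param name `"xpet"` or `"labpet8"`.
#' @return A `scanner_spec`.
#' @export
load_scanner_preset <- function(name = c("xpet", "labpet8")) {
  name <- match.arg(name)
  path <- system.file("extdata", "scanners", paste0(name, ".yaml"),
                      package = "conephantom", mustWork = TRUE)
  read_scanner_config(path)
}
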