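# Bundled material definitions: natron constituents, the bone reference,
# and beamline filter/scintillator materials.

#' Bundled materials
#'
#' Reads the packaged materials file and returns \code{material} /
#' \code{hydration_series} objects. Hydrated salts with a water range are
#' returned as hydration series carrying both endpoint densities; trona,
#' whose density is quoted as a range, uses the range midpoint by default.
#'
#' @param path Optional path to a materials CSV; defaults to the bundled one.
#' @inheritParams parse_formula
#' @return Named list of \code{material} and \code{hydration_series} objects,
#'   with the source row attached as attribute \code{"info"}.
#' @export
#' @examples
#' names(default_materials())
default_materials <- function(path = NULL, table = default_attenuation_table()) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.csv", package = "natronid",
                        mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    obj <- if (!is.na(r$n_water_max) && r$n_water_max > 0) {
      hydration_series(r$name, r$formula,
                       density_anhydrous = r$density_g_cm3,
                       density_hydrate = r$density_hydrate_g_cm3,
                       n_water = r$n_water_max, table = table)
    } else {
      material(r$name, r$formula, r$density_g_cm3, table = table)
    }
    attr(obj, "info") <- as.list(r)
    obj
  })
  names(out) <- raw$name
  out
}

#' Natron candidate minerals
#'
#' The five salts that make up natural natron: sodium carbonate (as a
#' hydration series from anhydrate to decahydrate), nahcolite, halite,
#' sodium sulphate (series) and trona.
#'
#' @inheritParams default_materials
#' @return Named list of candidate \code{material}/\code{hydration_series}
#'   objects.
#' @export
natron_candidates <- function(table = default_attenuation_table()) {
  mats <- default_materials(table = table)
  keep <- vapply(mats, function(m) identical(attr(m, "info")$group, "natron"),
                 logical(1))
  mats[keep]
}

# Resolve a material given by name (in the bundled set), or pass through
# material / hydration_series objects. Used by the beamline and pipeline
# layers so configs can name materials as strings.
resolve_material <- function(x, table = default_attenuation_table()) {
  if (inherits(x, "material") || inherits(x, "hydration_series")) return(x)
  if (is.character(x) && length(x) == 1L) {
    mats <- default_materials(table = table)
    if (!x %in% names(mats)) {
      stop("unknown material '", x, "'; bundled materials: ",
           paste(names(mats), collapse = ", "))
    }
    return(mats[[x]])
  }
  stop("cannot resolve a material from object of class ",
       paste(class(x), collapse = "/"))
}
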