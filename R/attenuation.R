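# Elemental attenuation table, chemical formula parsing, and compound
# mass/linear attenuation coefficients (Bragg additivity).

.natron_env <- new.env(parent = emptyenv())

#' Load the elemental mass-attenuation table
#'
#' Reads a table of elemental total mass attenuation coefficients
#' (photoelectric + coherent + incoherent, cm^2/g) on an ascending energy
#' grid. The bundled table covers H, C, N, O, Na, Mg, Al, P, S, Cl, Ca, Fe,
#' Cu, Ga, Mo, Gd and Lu from 10 to 500 keV, with extra grid nodes bracketing
#' the K absorption edges of Mo, Gd and Lu; see the package vignette for how
#' it was generated and validated.
#'
#' @param path Path to a CSV file with columns \code{element},
#'   \code{atomic_mass_g_mol}, \code{energy_keV}, \code{mu_over_rho_cm2_g}.
#'   Defaults to the bundled table.
#' @return An object of class \code{attenuation_table}: a named list with one
#'   entry per element, each holding \code{energy} (keV), \code{mu_over_rho}
#'   (cm^2/g) and \code{atomic_mass} (g/mol).
#' @export
#' @examples
#' tab <- attenuation_table()
#' names(tab)
attenuation_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "attenuation_elements.csv",
                        package = "natronid", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "atomic_mass_g_mol", "energy_keV", "mu_over_rho_cm2_g")
  if (!all(need %in% names(raw))) {
    stop("attenuation table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- lapply(split(raw, raw$element), function(d) {
    d <- d[order(d$energy_keV), ]
    if (any(d$mu_over_rho_cm2_g <= 0) || any(d$energy_keV <= 0)) {
      stop("attenuation values and energies must be strictly positive (element ",
           d$element[1], ")")
    }
    if (any(diff(d$energy_keV) <= 0)) {
      stop("energy grid must be strictly increasing (element ", d$element[1], ")")
    }
    list(energy = d$energy_keV, mu_over_rho = d$mu_over_rho_cm2_g,
         atomic_mass = d$atomic_mass_g_mol[1])
  })
  structure(tab, class = "attenuation_table")
}

default_attenuation_table <- function() {
  if (is.null(.natron_env$table)) .natron_env$table <- attenuation_table()
  .natron_env$table
}

#' @export
print.attenuation_table <- function(x, ...) {
  rng <- range(unlist(lapply(x, `[[`, "energy")))
  cat("<attenuation_table> ", length(x), " elements (",
      paste(names(x), collapse = ", "), "), ",
      rng[1], "-", rng[2], " keV\n", sep = "")
  invisible(x)
}

# ---- formula parsing --------------------------------------------------------

.tokenize_formula <- function(formula) {
  chars <- strsplit(formula, "")[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("^[A-Z]$", ch)) {
      sym <- ch
      if (i < length(chars) && grepl("^[a-z]$", chars[i + 1L])) {
        sym <- paste0(sym, chars[i + 1L]); i <- i + 1L
      }
      tokens[[length(tokens) + 1L]] <- list(type = "element", value = sym)
    } else if (grepl("^[0-9]$", ch)) {
      num <- ch
      while (i < length(chars) && grepl("^[0-9]$", chars[i + 1L])) {
        num <- paste0(num, chars[i + 1L]); i <- i + 1L
      }
      tokens[[length(tokens) + 1L]] <- list(type = "number", value = as.numeric(num))
    } else if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch)
    } else if (ch == "." || ch == "·") {  # hydrate / adduct separator
      tokens[[length(tokens) + 1L]] <- list(type = "dot", value = ".")
    } else {
      stop("cannot parse formula '", formula, "': unexpected token '", ch, "'")
    }
    i <- i + 1L
  }
  tokens
}

# parse one dot-separated fragment: [multiplier] (element [count] | '(' ... ')' [count])+
.parse_fragment <- function(tokens, formula) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  take <- function() { t <- tokens[[pos]]; pos <<- pos + 1L; t }

  parse_group <- function() {
    counts <- numeric(0)
    repeat {
      t <- peek()
      if (is.null(t) || t$type == ")") break
      if (t$type == "element") {
        take()
        n <- 1
        if (!is.null(peek()) && peek()$type == "number") n <- take()$value
        counts[t$value] <- (if (t$value %in% names(counts)) counts[[t$value]] else 0) + n
      } else if (t$type == "(") {
        take()
        inner <- parse_group()
        if (is.null(peek()) || peek()$type != ")") {
          stop("cannot parse formula '", formula, "': unbalanced '('")
        }
        take()
        n <- 1
        if (!is.null(peek()) && peek()$type == "number") n <- take()$value
        inner <- inner * n
        for (el in names(inner)) {
          counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + inner[[el]]
        }
      } else {
        stop("cannot parse formula '", formula, "': unexpected token '",
             t$value, "'")
      }
    }
    counts
  }

  mult <- 1
  if (!is.null(peek()) && peek()$type == "number") mult <- take()$value
  counts <- parse_group()
  if (!is.null(peek())) {
    stop("cannot parse formula '", formula, "': unexpected token '",
         peek()$value, "'")
  }
  if (length(counts) == 0) {
    stop("cannot parse formula '", formula, "': empty fragment")
  }
  counts * mult
}

#' Parse a chemical formula into an elemental composition
#'
#' Supports element symbols with integer counts, parenthesised groups and
#' dot-separated hydrate/adduct notation, e.g. \code{"Na2CO3.10H2O"} or
#' \code{"Ca10(PO4)6(OH)2"}. Counts are additive across dot-separated parts.
#'
#' @param formula Formula string.
#' @param table Attenuation table supplying atomic masses (defaults to the
#'   bundled table); parsing fails for elements it does not carry.
#' @return A \code{composition}: list with \code{counts} (named atom counts),
#'   \code{molar_mass} (g/mol) and \code{mass_fractions} (named, summing to 1).
#' @export
#' @examples
#' parse_formula("Na2CO3.10H2O")$counts
#' parse_formula("Ca10(PO4)6(OH)2")$molar_mass
parse_formula <- function(formula, table = default_attenuation_table()) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  tokens <- .tokenize_formula(formula)
  # split on dots
  is_dot <- vapply(tokens, function(t) t$type == "dot", logical(1))
  idx <- cumsum(is_dot)
  counts <- numeric(0)
  for (part in split(tokens[!is_dot], idx[!is_dot])) {
    frag <- .parse_fragment(part, formula)
    for (el in names(frag)) {
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + frag[[el]]
    }
  }
  composition(counts, table = table)
}

#' Build a composition from named atom counts
#'
#' @param counts Named numeric vector of positive atom counts per element.
#' @inheritParams parse_formula
#' @return A \code{composition} object; see [parse_formula()].
#' @export
composition <- function(counts, table = default_attenuation_table()) {
  if (inherits(counts, "composition")) return(counts)
  stopifnot(is.numeric(counts), length(counts) > 0, !is.null(names(counts)))
  if (any(counts <= 0)) stop("atom counts must be positive")
  unknown <- setdiff(names(counts), names(table))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         " (supported: ", paste(names(table), collapse = ", "), ")")
  }
  masses <- vapply(names(counts), function(el) table[[el]]$atomic_mass, 0)
  part <- counts * masses
  molar <- sum(part)
  structure(list(counts = counts, molar_mass = molar,
                 mass_fractions = part / molar),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ",
      paste0(names(x$counts), ifelse(x$counts == 1, "", x$counts), collapse = " "),
      "  (", format(x$molar_mass, digits = 6), " g/mol)\n", sep = "")
  invisible(x)
}

.as_composition <- function(x, table = default_attenuation_table()) {
  if (inherits(x, "composition")) return(x)
  if (inherits(x, "material")) return(x$composition)
  if (is.character(x)) return(parse_formula(x, table = table))
  if (is.numeric(x) && !is.null(names(x))) return(composition(x, table = table))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a composition")
}

# ---- attenuation coefficients -----------------------------------------------

# log-log interpolation of one element's mu/rho; strict range check
.element_mu_rho <- function(el, energy, table) {
  ent <- table[[el]]
  if (is.null(ent)) stop("no attenuation data for element ", el)
  rng <- range(ent$energy)
  if (any(energy < rng[1] | energy > rng[2])) {
    stop("energy out of tabulated range for ", el, " [", rng[1], ", ",
         rng[2], "] keV; no extrapolation is performed")
  }
  exp(stats::approx(log(ent$energy), log(ent$mu_over_rho), xout = log(energy),
                    method = "linear", ties = "ordered")$y)
}

#' Mass attenuation coefficient of a compound
#'
#' Bragg additivity: the compound coefficient is the mass-fraction-weighted
#' sum of elemental coefficients, each obtained by log-log interpolation on
#' the tabulated grid. Energies outside the grid raise an error (no
#' extrapolation).
#'
#' @param x A \code{composition}, \code{material}, formula string, or named
#'   count vector.
#' @param energy Photon energy in keV (vectorised).
#' @inheritParams parse_formula
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
#' @examples
#' mass_attenuation("H2O", 100)   # ~0.171 cm^2/g
mass_attenuation <- function(x, energy, table = default_attenuation_table()) {
  comp <- .as_composition(x, table)
  stopifnot(is.numeric(energy), all(is.finite(energy)), all(energy > 0))
  w <- comp$mass_fractions
  vals <- vapply(names(w), .element_mu_rho, numeric(length(energy)),
                 energy = energy, table = table)
  if (length(energy) == 1L) sum(w * vals) else drop(vals %*% w)
}

#' Define a material (composition + bulk density)
#'
#' @param name Material name.
#' @param formula Formula string or \code{composition}.
#' @param density Bulk density in g/cm^3 (> 0).
#' @inheritParams parse_formula
#' @return A \code{material} object.
#' @export
#' @examples
#' halite <- material("halite", "NaCl", 2.17)
#' linear_attenuation(halite, 146.1)
material <- function(name, formula, density, table = default_attenuation_table()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stop("density must be a single positive number (g/cm^3)")
  }
  structure(list(name = name, composition = .as_composition(formula, table),
                 density = density),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material> ", x$name, ": ", sep = "")
  cat(paste0(names(x$composition$counts),
             ifelse(x$composition$counts == 1, "", x$composition$counts),
             collapse = " "),
      " rho =", x$density, "g/cm^3\n")
  invisible(x)
}

#' Linear attenuation coefficient of a material
#'
#' \eqn{\mu = \rho \times (\mu/\rho)}; linear in density.
#'
#' @param mat A \code{material}.
#' @inheritParams mass_attenuation
#' @return Linear attenuation coefficient(s) in cm^-1.
#' @export
linear_attenuation <- function(mat, energy, table = default_attenuation_table()) {
  stopifnot(inherits(mat, "material"))
  mat$density * mass_attenuation(mat$composition, energy, table = table)
}

# ---- hydration series -------------------------------------------------------

#' Define a hydration series between an anhydrous salt and its hydrate
#'
#' Describes e.g. sodium carbonate from the anhydrate to the decahydrate.
#' Only the endpoint densities are carried: intermediate hydrate densities
#' are not linear in the water count, so a density for an intermediate
#' member must be supplied by the user explicitly.
#'
#' @param name Series name.
#' @param base Anhydrous composition (formula string or \code{composition}).
#' @param density_anhydrous,density_hydrate Endpoint densities in g/cm^3.
#' @param n_water Maximum water count (default 10, the decahydrate).
#' @inheritParams parse_formula
#' @return A \code{hydration_series} object.
#' @export
hydration_series <- function(name, base, density_anhydrous, density_hydrate,
                             n_water = 10L, table = default_attenuation_table()) {
  stopifnot(density_anhydrous > 0, density_hydrate > 0,
            n_water == as.integer(n_water), n_water >= 0, n_water <= 10)
  structure(list(name = name, base = .as_composition(base, table),
                 density_anhydrous = density_anhydrous,
                 density_hydrate = density_hydrate,
                 n_water = as.integer(n_water)),
            class = "hydration_series")
}

#' @export
print.hydration_series <- function(x, ...) {
  cat("<hydration_series> ", x$name, ": base + 0..", x$n_water,
      " H2O, rho ", x$density_anhydrous, "-", x$density_hydrate, " g/cm^3\n",
      sep = "")
  invisible(x)
}

# composition of base + n H2O
.hydrated_composition <- function(series, n, table = default_attenuation_table()) {
  counts <- series$base$counts
  if (n > 0) {
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0) + 2 * n
    counts["O"] <- (if ("O" %in% names(counts)) counts[["O"]] else 0) + n
  }
  composition(counts, table = table)
}

#' Linear attenuation at the endpoints of a hydration series
#'
#' @param series A \code{hydration_series}.
#' @param energy Photon energy in keV (scalar).
#' @inheritParams parse_formula
#' @return Named numeric vector \code{c(anhydrous =, hydrate =)} in cm^-1,
#'   each endpoint evaluated with its own composition and density.
#' @export
#' @examples
#' s <- hydration_series("sodium carbonate", "Na2CO3", 2.54, 1.44)
#' hydration_series_mu(s, 146.1)
hydration_series_mu <- function(series, energy,
                                table = default_attenuation_table()) {
  stopifnot(inherits(series, "hydration_series"), length(energy) == 1L)
  anh <- series$density_anhydrous *
    mass_attenuation(series$base, energy, table = table)
  hyd <- series$density_hydrate *
    mass_attenuation(.hydrated_composition(series, series$n_water, table),
                     energy, table = table)
  c(anhydrous = anh, hydrate = hyd)
}
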