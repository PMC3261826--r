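#' Standard element table
#'
#' Chemical symbols, atomic numbers and standard atomic masses (g/mol) for the
#' elements used by the packaged materials.
#'
#' @return A data.frame with columns `symbol`, `Z`, `A_r`.
#' @export
element_table <- function() {
  if (is.null(the$elements))
    the$elements <- read.delim(np_extdata("elements.tsv"), stringsAsFactors = FALSE)
  the$elements
}

parse_composition <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  v <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  names(v) <- vapply(parts, function(p) p[1], character(1))
  v
}

#' Convert mass fractions to atom fractions
#'
#' For elemental mass fractions w_i the atom fractions are
#' n_i = (w_i / A_i) / sum_j (w_j / A_j).
#'
#' @param composition Named numeric vector of elemental mass fractions
#'   (names are chemical symbols). Must sum to 1 within `tol`.
#' @param elements Element table, see [element_table()].
#' @param tol Tolerance on the input normalisation.
#' @return Named numeric vector of atom fractions summing to 1.
#' @export
atom_fractions <- function(composition, elements = element_table(), tol = 1e-6) {
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  unknown <- setdiff(names(composition), elements$symbol)
  if (length(unknown)) stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (abs(sum(composition) - 1) > tol)
    stop("mass fractions sum to ", format(sum(composition)), ", not 1")
  A <- elements$A_r[match(names(composition), elements$symbol)]
  n <- composition / A
  n / sum(n)
}

#' Convert integer atom ratios to mass fractions
#'
#' w_i = r_i A_i / sum_j r_j A_j, e.g. Perspex C5 O2 H8.
#'
#' @param atom_ratio Named numeric vector of positive atom ratios.
#' @param elements Element table.
#' @return Named numeric vector of mass fractions summing to 1.
#' @export
mass_fractions <- function(atom_ratio, elements = element_table()) {
  if (!length(atom_ratio)) stop("empty composition")
  stopifnot(is.numeric(atom_ratio), !is.null(names(atom_ratio)))
  if (any(atom_ratio <= 0)) stop("atom ratios must be positive")
  unknown <- setdiff(names(atom_ratio), elements$symbol)
  if (length(unknown)) stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  A <- elements$A_r[match(names(atom_ratio), elements$symbol)]
  w <- atom_ratio * A
  w / sum(w)
}

#' Per-element number densities of a material
#'
#' N_i = rho w_i N_A / A_i in atoms/cm^3.
#'
#' @param material A material object (see [load_materials()]), or a list with
#'   elements `density` (g/cm^3) and `mass` (named mass fractions).
#' @return Named numeric vector, atoms/cm^3.
#' @export
number_densities <- function(material) {
  if (is.null(material$density) || is.na(material$density))
    stop("material has no density")
  w <- material$mass
  elements <- element_table()
  A <- elements$A_r[match(names(w), elements$symbol)]
  material$density * w * .N_AVOGADRO / A
}

new_material <- function(id, name, density, state, comp_type, composition, tissue) {
  comp <- parse_composition(composition)
  if (comp_type == "atom") {
    mass <- mass_fractions(comp)
    atom <- comp / sum(comp)
  } else {
    if (abs(sum(comp) - 1) > 1e-9)
      stop("material ", name, ": mass fractions sum to ", format(sum(comp)))
    mass <- comp
    atom <- atom_fractions(comp)
  }
  structure(list(id = id, name = name, density = density, state = state,
                 mass = mass, atom = atom, tissue = tissue == 1),
            class = "np_material")
}

#' Load the packaged material table
#'
#' Reads the structured text table of materials (water, Perspex, aluminum,
#' concrete, air and 30 tissue materials) shipped with the package, or a
#' user-supplied table in the same format: tab-separated columns
#' `id name density_g_cm3 state comp_type tissue composition`, where
#' `composition` is `symbol:value` pairs separated by `;` and `comp_type` is
#' `mass` (mass fractions summing to 1) or `atom` (integer atom ratios).
#'
#' @param path Optional path to a material table; default: packaged table.
#' @return A `material_db` object: a list of materials indexed by id.
#' @export
load_materials <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$materials)) return(the$materials)
    path <- np_extdata("materials.tsv")
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.delim(path, stringsAsFactors = FALSE)
  mats <- lapply(seq_len(nrow(tab)), function(i)
    new_material(tab$id[i], tab$name[i], tab$density_g_cm3[i], tab$state[i],
                 tab$comp_type[i], tab$composition[i], tab$tissue[i]))
  names(mats) <- as.character(tab$id)
  db <- structure(list(materials = mats, ids = tab$id), class = "material_db")
  if (cache) the$materials <- db
  db
}

#' Look up a material by id or name
#' @param db A `material_db`.
#' @param id Integer material id or character name.
#' @return A material object.
#' @export
get_material <- function(db, id) {
  if (is.character(id)) {
    nm <- vapply(db$materials, `[[`, character(1), "name")
    i <- match(id, nm)
    if (is.na(i)) stop("no material named '", id, "'")
    return(db$materials[[i]])
  }
  m <- db$materials[[as.character(id)]]
  if (is.null(m)) stop("no material with id ", id)
  m
}

#' @export
print.material_db <- function(x, ...) {
  cat("<material_db> ", length(x$materials), " materials (",
      sum(vapply(x$materials, `[[`, logical(1), "tissue")), " tissue)\n", sep = "")
  invisible(x)
}

#' @export
print.np_material <- function(x, ...) {
  cat(sprintf("<material %d: %s>  rho = %g g/cm^3 (%s)\n", x$id, x$name,
              x$density, x$state))
  cat("  mass fractions:", paste(sprintf("%s %.4g", names(x$mass), x$mass),
                                 collapse = ", "), "\n")
  invisible(x)
}
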