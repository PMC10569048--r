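# LabeledStructure: a tibble of atoms (coordinates, names, residue labels,
# partial charges, masses, named groups) plus an orthorhombic box attribute.

.structure_cols <- c("atom", "name", "resname", "resid", "helix", "group",
                     "x", "y", "z", "charge", "mass")

#' Construct a labeled structure
#'
#' The central container for a single configuration: one row per atom with
#' coordinates (angstrom), partial charge (e), mass (amu), and labels that
#' resolve the named atom groups used downstream (phosphate backbone, groove
#' markers, water sites, ion species).
#'
#' @param atoms data frame with columns `atom`, `name`, `resname`, `resid`,
#'   `helix` (1, 2 or NA), `group`, `x`, `y`, `z`, `charge`, `mass`.
#' @param box numeric 3-vector, orthorhombic box edge lengths in angstrom.
#' @return a tibble of class `ha_structure` with a `box` attribute.
#' @seealso [build_duplex_pair()], [place_ions()], [select_group()]
#' @export
labeled_structure <- function(atoms, box) {
  atoms <- as_tibble(atoms)
  missing <- setdiff(.structure_cols, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("structure is missing columns: ", paste(missing, collapse = ", ")),
          class = "ha_format_error")
  }
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    abort("box must be 3 positive edge lengths (angstrom)", class = "ha_geometry_error")
  }
  structure(atoms, box = box,
            class = c("ha_structure", class(as_tibble(atoms))))
}

#' Box edge lengths of a structure or trajectory
#'
#' @param x an `ha_structure` or `ha_trajectory`.
#' @return numeric 3-vector c(Lx, Ly, Lz) in angstrom.
#' @export
ha_box <- function(x) {
  b <- attr(x, "box")
  if (is.null(b)) abort("object carries no box", class = "ha_geometry_error")
  b
}

#' @export
print.ha_structure <- function(x, ...) {
  b <- attr(x, "box")
  cat(sprintf("<ha_structure> %d atoms, box %.1f x %.1f x %.1f A\n",
              nrow(x), b[1], b[2], b[3]))
  grp <- table(x$group)
  cat("groups:", paste(sprintf("%s(%d)", names(grp), grp), collapse = " "), "\n")
  NextMethod()
}

#' Resolve a named atom group
#'
#' Group names follow the analysis vocabulary: `"phosphate_backbone"`,
#' `"major_groove"`, `"minor_groove"`, `"water"` (all sites), `"water_O"`
#' (oxygens only), `"ion:<species>"` (e.g. `"ion:Mg"`), `"helix1"`,
#' `"helix2"`, `"dna"` (both helices), or any literal value of the `group`
#' column. Resolution is pure: the same structure and name always return the
#' same atom set.
#'
#' @param x an `ha_structure` (or the `atoms` table of a trajectory).
#' @param group_name group label (see Details).
#' @param require_atoms error if the selection is empty (default TRUE).
#' @return integer vector of `atom` ids.
#' @export
select_group <- function(x, group_name, require_atoms = TRUE) {
  at <- as_tibble(x)
  ids <- switch(group_name,
    phosphate_backbone = at$atom[at$group == "phosphate"],
    major_groove = at$atom[at$group == "major_groove"],
    minor_groove = at$atom[at$group == "minor_groove"],
    water = at$atom[at$group == "water"],
    water_O = at$atom[at$group == "water" & at$name == "O"],
    water_H = at$atom[at$group == "water" & at$name != "O"],
    helix1 = at$atom[!is.na(at$helix) & at$helix == 1L],
    helix2 = at$atom[!is.na(at$helix) & at$helix == 2L],
    dna = at$atom[!is.na(at$helix)],
    at$atom[at$group == group_name]
  )
  if (require_atoms && length(ids) == 0) {
    abort(paste0("empty selection for group '", group_name, "'"),
          class = "ha_empty_selection")
  }
  sort(ids)
}

# coordinates of a structure as an n x 3 matrix
structure_coords <- function(x) as_coord_matrix(as_tibble(x))

# append atoms (tibble rows) to a structure, renumbering new atom ids
append_atoms <- function(structure, new_atoms) {
  new_atoms <- as_tibble(new_atoms)
  new_atoms$atom <- max(structure$atom, 0L) + seq_len(nrow(new_atoms))
  labeled_structure(bind_rows(as_tibble(structure), new_atoms), ha_box(structure))
}
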