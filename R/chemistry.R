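# Chemistry dictionaries: hydrogen-bond donors/acceptors, charged groups,
# aromatic rings and apolar carbons for the standard residues, plus the
# ligand-side declaration object.
#
# Ligand chemistry is declared, not perceived from connectivity: a
# LigandSpec lists the donor/acceptor/charged/ring/apolar atom names of one
# HETATM residue, which keeps the package free of a chemistry toolkit and
# makes the typing rules fully transparent.

# protein-side dictionary (heavy atoms only; backbone N is a donor except
# for proline, backbone O an acceptor, for every residue)
PROTEIN_CHEM <- list(
  ALA = list(apolar = "CB"),
  ARG = list(donors = c("NE", "NH1", "NH2"),
             charged = list(list(atoms = c("NE", "CZ", "NH1", "NH2"), sign = +1)),
             apolar = c("CB", "CG")),
  ASN = list(donors = "ND2", acceptors = "OD1", apolar = "CB"),
  ASP = list(acceptors = c("OD1", "OD2"),
             charged = list(list(atoms = c("CG", "OD1", "OD2"), sign = -1)),
             apolar = "CB"),
  CYS = list(donors = "SG", apolar = "CB"),
  GLN = list(donors = "NE2", acceptors = "OE1", apolar = c("CB", "CG")),
  GLU = list(acceptors = c("OE1", "OE2"),
             charged = list(list(atoms = c("CD", "OE1", "OE2"), sign = -1)),
             apolar = c("CB", "CG")),
  GLY = list(),
  HIS = list(donors = c("ND1", "NE2"), acceptors = c("ND1", "NE2"),
             rings = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
             apolar = "CB"),
  ILE = list(apolar = c("CB", "CG1", "CG2", "CD1")),
  LEU = list(apolar = c("CB", "CG", "CD1", "CD2")),
  LYS = list(donors = "NZ",
             charged = list(list(atoms = "NZ", sign = +1)),
             apolar = c("CB", "CG", "CD")),
  MET = list(apolar = c("CB", "CG", "CE")),
  PHE = list(rings = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
             apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  PRO = list(apolar = c("CB", "CG", "CD")),
  SER = list(donors = "OG", acceptors = "OG"),
  THR = list(donors = "OG1", acceptors = "OG1", apolar = "CG2"),
  TRP = list(donors = "NE1",
             rings = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                          c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
             apolar = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2",
                        "CZ3", "CH2")),
  TYR = list(donors = "OH", acceptors = "OH",
             rings = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
             apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  VAL = list(apolar = c("CB", "CG1", "CG2"))
)

protein_chem <- function(res_name, his_protonated = FALSE) {
  chem <- PROTEIN_CHEM[[res_name]]
  check_that(!is.null(chem), "unknown protein residue name '%s'", res_name)
  if (res_name == "HIS" && his_protonated) {
    # doubly protonated imidazolium: positively charged, no ring N acceptor
    chem$charged <- list(list(atoms = c("ND1", "CE1", "NE2"), sign = +1))
    chem$acceptors <- NULL
  }
  chem
}

#' Declare the interaction chemistry of a ligand
#'
#' @param res_name HETATM residue name of the ligand.
#' @param donors,acceptors Atom-name vectors of hydrogen-bond donors and
#'   acceptors (heavy atoms).
#' @param charged_groups Named list; each element
#'   `list(atoms = <names>, sign = +1/-1)`.
#' @param rings List of atom-name vectors, each a planar ring of >= 5
#'   atoms.
#' @param apolar Atom-name vector of apolar carbons.
#' @return A `ligand_spec` object.
#' @export
ligand_spec <- function(res_name, donors = character(), acceptors = character(),
                        charged_groups = list(), rings = list(),
                        apolar = character()) {
  check_that(is.character(res_name) && nzchar(res_name),
             "res_name must be a non-empty string")
  for (ring in rings) {
    check_that(length(ring) >= 5L, "ring lists need >= 5 atoms")
  }
  for (g in charged_groups) {
    check_that(is.list(g) && !is.null(g$atoms) && g$sign %in% c(-1, 1),
               "charged_groups elements need atoms and sign = +/-1")
  }
  structure(list(res_name = res_name, donors = donors, acceptors = acceptors,
                 charged_groups = charged_groups, rings = rings,
                 apolar = apolar),
            class = "ligand_spec")
}

#' @export
print.ligand_spec <- function(x, ...) {
  cat(sprintf(
    "ligand_spec '%s': %d donor(s), %d acceptor(s), %d charged group(s), %d ring(s), %d apolar atom(s)\n",
    x$res_name, length(x$donors), length(x$acceptors),
    length(x$charged_groups), length(x$rings), length(x$apolar)))
  invisible(x)
}

#' Read a ligand chemistry declaration from YAML
#'
#' Expected keys: `res_name`, optional `donors`, `acceptors`, `apolar`
#' (lists of atom names), `rings` (list of atom-name lists), and
#' `charged_groups` (named map of `{atoms: [...], sign: +/-1}`).
#'
#' @param path YAML file path.
#' @return A [ligand_spec()].
#' @export
read_ligand_spec <- function(path) {
  y <- yaml::read_yaml(path)
  ligand_spec(
    res_name = y$res_name,
    donors = as.character(y$donors %||% character()),
    acceptors = as.character(y$acceptors %||% character()),
    charged_groups = lapply(y$charged_groups %||% list(), function(g) {
      list(atoms = as.character(g$atoms), sign = as.numeric(g$sign))
    }),
    rings = lapply(y$rings %||% list(), as.character),
    apolar = as.character(y$apolar %||% character())
  )
}

#' Built-in ligand declaration for pyruvate
#'
#' Atom names: `C1` carboxylate carbon with `O1`/`O2` oxygens (the charged
#' carboxylate), `C2` ketone carbon with `O3`, `C3` methyl.
#'
#' @return A [ligand_spec()].
#' @export
pyruvate_spec <- function() {
  ligand_spec(
    res_name = "PYR",
    acceptors = c("O1", "O2", "O3"),
    charged_groups = list(carboxylate = list(atoms = c("C1", "O1", "O2"),
                                             sign = -1)),
    apolar = "C3"
  )
}
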