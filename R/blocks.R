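#' @title Building-block registry for the triazolopeptide notation
#'
#' @description
#' Every residue, glycyl-triazole unit and cap that can occur in a sequence is
#' described by a `BlockDefinition`: its elemental formula in the dehydrated
#' "residue" convention (one H2O is added per assembled molecule), a heavy-atom
#' fragment with per-atom hydrogen counts in the mid-chain amide state, the
#' bonds within the fragment, and the attachment atoms used by the assembly
#' junction rules.
#'
#' Conventions encoded here:
#' * `n_attach` is the backbone nitrogen acylated by the preceding block;
#'   it carries one hydrogen in the mid-chain state (zero for proline, whose
#'   nitrogen is part of the pyrrolidine ring) and gains one hydrogen when the
#'   block is amino-terminal.
#' * `c_attach` is the acyl carbon bonded to the next block's nitrogen. For
#'   the glycyl-1,2,3-triazole unit the outgoing connection is not an acyl
#'   bond: ring nitrogen N1 is *identified* with the next block's backbone
#'   nitrogen (the azide nitrogen that became N1 in the cycloaddition), so
#'   `c_attach` names N1 and the assembler merges rather than bonds.
#' * `side_attach` is the side-chain primary amine that can be acylated by a
#'   branch residue (lysine, diaminobutyric and diaminopropionic acid).
#' * `guanidine` names the guanidine carbon (the Arg/Har zeta carbon), the
#'   anchor atom of the guanidine-to-guanidine topological descriptor.
#'
#' @format A named list of block definitions, keyed by block code.
#' @keywords internal
#' @name block_registry
NULL

.frag <- function(labels, elements, h, bonds) {
  stopifnot(length(labels) == length(elements), length(labels) == length(h))
  list(atoms = data.frame(label = labels, element = elements, h = h,
                          stringsAsFactors = FALSE),
       bonds = bonds)
}

.alpha_bb <- function(extra_lab = character(), extra_el = character(),
                      extra_h = integer(), extra_bonds = list(),
                      ca_h = 1L, n_h = 1L) {
  .frag(c("N", "CA", "C", "O", extra_lab),
        c("N", "C", "C", "O", extra_el),
        c(n_h, ca_h, 0L, 0L, extra_h),
        c(list(c("N", "CA"), c("CA", "C"), c("C", "O")), extra_bonds))
}

.block <- function(name, kind, formula, frag, n_attach = "N", c_attach = "C",
                   side_attach = NA_character_, guanidine = NA_character_) {
  list(name = name, kind = kind,
       formula = c(C = formula[1], H = formula[2], N = formula[3], O = formula[4]),
       atoms = frag$atoms, bonds = frag$bonds,
       n_attach = n_attach, c_attach = c_attach,
       side_attach = side_attach, guanidine = guanidine)
}

# Dehydrated residue formulas; each is validated against the full printed
# compound panel by the golden-suite tests (additive formula = sum + H2O).
.block_registry <- local({
  r <- list()

  r$Gly <- .block("Gly", "alpha_amino_acid", c(2, 3, 1, 1), .alpha_bb(ca_h = 2L))
  r$Ala <- .block("Ala", "alpha_amino_acid", c(3, 5, 1, 1),
                  .alpha_bb("CB", "C", 3L, list(c("CA", "CB"))))
  r$Pro <- .block("Pro", "alpha_amino_acid", c(5, 7, 1, 1),
                  .alpha_bb(c("CB", "CG", "CD"), c("C", "C", "C"), c(2L, 2L, 2L),
                            list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                                 c("CD", "N")), n_h = 0L))
  r$Phe <- .block("Phe", "alpha_amino_acid", c(9, 9, 1, 1),
                  .alpha_bb(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                            rep("C", 7), c(2L, 0L, 1L, 1L, 1L, 1L, 1L),
                            list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"),
                                 c("CG", "CD2"), c("CD1", "CE1"), c("CD2", "CE2"),
                                 c("CE1", "CZ"), c("CE2", "CZ"))))
  r$Lys <- .block("Lys", "alpha_amino_acid", c(6, 12, 2, 1),
                  .alpha_bb(c("CB", "CG", "CD", "CE", "NZ"),
                            c("C", "C", "C", "C", "N"), c(2L, 2L, 2L, 2L, 2L),
                            list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                                 c("CD", "CE"), c("CE", "NZ"))),
                  side_attach = "NZ")
  r$Arg <- .block("Arg", "alpha_amino_acid", c(6, 12, 4, 1),
                  .alpha_bb(c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
                            c("C", "C", "C", "N", "C", "N", "N"),
                            c(2L, 2L, 2L, 1L, 0L, 1L, 2L),
                            list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                                 c("CD", "NE"), c("NE", "CZ"), c("CZ", "NH1"),
                                 c("CZ", "NH2"))),
                  guanidine = "CZ")
  r$Har <- .block("Har", "alpha_amino_acid", c(7, 14, 4, 1),
                  .alpha_bb(c("CB", "CG", "CD", "CE", "NZ", "CZ2", "NH1", "NH2"),
                            c("C", "C", "C", "C", "N", "C", "N", "N"),
                            c(2L, 2L, 2L, 2L, 1L, 0L, 1L, 2L),
                            list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"),
                                 c("CD", "CE"), c("CE", "NZ"), c("NZ", "CZ2"),
                                 c("CZ2", "NH1"), c("CZ2", "NH2"))),
                  guanidine = "CZ2")
  r$Dab <- .block("Dab", "alpha_amino_acid", c(4, 8, 2, 1),
                  .alpha_bb(c("CB", "CG", "ND"), c("C", "C", "N"), c(2L, 2L, 2L),
                            list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND"))),
                  side_attach = "ND")
  r$Dap <- .block("Dap", "alpha_amino_acid", c(3, 6, 2, 1),
                  .alpha_bb(c("CB", "NG"), c("C", "N"), c(2L, 2L),
                            list(c("CA", "CB"), c("CB", "NG"))),
                  side_attach = "NG")

  # omega-amino acids: no alpha amine, a plain methylene chain
  r$`6Ahx` <- .block("6Ahx", "omega_amino_acid", c(6, 11, 1, 1),
                     .frag(c("N", "CE", "CD", "CG", "CB", "CA", "C", "O"),
                           c("N", "C", "C", "C", "C", "C", "C", "O"),
                           c(1L, 2L, 2L, 2L, 2L, 2L, 0L, 0L),
                           list(c("N", "CE"), c("CE", "CD"), c("CD", "CG"),
                                c("CG", "CB"), c("CB", "CA"), c("CA", "C"),
                                c("C", "O"))))
  r$`5Ava` <- .block("5Ava", "omega_amino_acid", c(5, 9, 1, 1),
                     .frag(c("N", "CD", "CG", "CB", "CA", "C", "O"),
                           c("N", "C", "C", "C", "C", "C", "O"),
                           c(1L, 2L, 2L, 2L, 2L, 0L, 0L),
                           list(c("N", "CD"), c("CD", "CG"), c("CG", "CB"),
                                c("CB", "CA"), c("CA", "C"), c("C", "O"))))

  # Glycyl-1,2,3-triazole unit. N1 is the azide-derived ring nitrogen that the
  # assembler identifies with the next block's backbone nitrogen; the unit
  # formula C3H3N3 therefore already accounts for the hydrogen the next
  # block's amide nitrogen loses on identification.
  r$`GlyΨ[Trl]` <- .block("GlyΨ[Trl]", "triazole_unit", c(3, 3, 3, 0),
                          .frag(c("NAM", "CH2", "C4", "C5", "N1", "N2", "N3"),
                                c("N", "C", "C", "C", "N", "N", "N"),
                                c(1L, 2L, 0L, 1L, 0L, 0L, 0L),
                                list(c("NAM", "CH2"), c("CH2", "C4"),
                                     c("C4", "C5"), c("C5", "N1"),
                                     c("N1", "N2"), c("N2", "N3"),
                                     c("N3", "C4"))),
                          n_attach = "NAM", c_attach = "N1")

  # Fluorenylmethyloxycarbonyl cap: replaces one hydrogen on the capped
  # nitrogen; net composition change +C15H10O2.
  r$Fmoc <- .block("Fmoc", "cap", c(15, 10, 0, 2),
                   .frag(c("CC", "OC", "OE", "CM", "C9", "C9A", "C1", "C2",
                           "C3", "C4", "C4A", "C9B", "C8", "C7", "C6", "C5",
                           "C4B"),
                         c("C", "O", "O", "C", "C", "C", "C", "C", "C", "C",
                           "C", "C", "C", "C", "C", "C", "C"),
                         c(0L, 0L, 0L, 2L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L,
                           1L, 1L, 1L, 1L, 0L),
                         list(c("CC", "OC"), c("CC", "OE"), c("OE", "CM"),
                              c("CM", "C9"), c("C9", "C9A"), c("C9", "C9B"),
                              c("C9A", "C1"), c("C1", "C2"), c("C2", "C3"),
                              c("C3", "C4"), c("C4", "C4A"), c("C4A", "C9A"),
                              c("C9B", "C8"), c("C8", "C7"), c("C7", "C6"),
                              c("C6", "C5"), c("C5", "C4B"), c("C4B", "C9B"),
                              c("C4A", "C4B"))),
                   n_attach = NA_character_, c_attach = "CC")
  r
})

#' Look up a block definition
#'
#' @param code Block code as used in the sequence notation (e.g. `"Lys"`,
#'   `"GlyΨ[Trl]"`). ASCII aliases `"GlyPsi[Trl]"` and `"Gly[Trl]"` are
#'   accepted for the triazole unit.
#' @return A block definition list (see [block_registry]).
#' @export
get_block <- function(code) {
  code <- normalize_block_code(code)
  blk <- .block_registry[[code]]
  if (is.null(blk)) {
    stop("unknown block code: '", code, "' (registered: ",
         paste(names(.block_registry), collapse = ", "), ")", call. = FALSE)
  }
  blk
}

#' @rdname get_block
#' @export
block_codes <- function() names(.block_registry)

normalize_block_code <- function(code) {
  code <- gsub("Psi\\[", "Ψ[", code)
  if (code == "Gly[Trl]") code <- "GlyΨ[Trl]"
  code
}

is_triazole <- function(blk) identical(blk$kind, "triazole_unit")

# internal consistency: fragment atoms + hydrogens must reproduce the declared
# residue formula, except for the triazole unit whose formula convention
# pre-pays the -1 H / -1 N of the downstream nitrogen identification.
check_block_registry <- function() {
  for (blk in .block_registry) {
    el <- table(factor(blk$atoms$element, levels = c("C", "H", "N", "O")))
    got <- c(C = unname(el["C"]), H = sum(blk$atoms$h),
             N = unname(el["N"]), O = unname(el["O"]))
    want <- blk$formula
    if (is_triazole(blk)) want <- want + c(C = 0, H = 1, N = 1, O = 0)
    if (identical(blk$name, "Fmoc")) want <- want + c(C = 0, H = 1, N = 0, O = 0)
    if (!all(got == want)) {
      stop("registry fragment/formula mismatch for block ", blk$name)
    }
    for (at in c(blk$n_attach, blk$c_attach, blk$side_attach, blk$guanidine)) {
      if (!is.na(at) && !at %in% blk$atoms$label) {
        stop("attach atom ", at, " not in fragment of ", blk$name)
      }
    }
  }
  invisible(TRUE)
}
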