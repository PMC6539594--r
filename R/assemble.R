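#' Elemental formula by additive residue bookkeeping
#'
#' Sums the dehydrated residue formulas of all tokens (main chain and
#' branches), adds one H2O per molecule and C15H10O2 per Fmoc cap. Stereo
#' flags never change the composition. This is the fast bookkeeping route;
#' [formula_from_graph()] on the assembled graph is the independent
#' cross-check and the two must agree for every valid sequence.
#'
#' @param seq A `compound_seq` or a sequence string (parsed on the fly).
#' @return Named integer vector of class `elemental_formula` with counts
#'   `C`, `H`, `N`, `O`.
#' @examples
#' additive_formula("Lys(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg")  # C25H46N16O4
#' @export
additive_formula <- function(seq) {
  seq <- as_compound_seq(seq)
  toks <- seq$tokens
  validate_chain(toks)
  f <- c(C = 0, H = 2, N = 0, O = 1)  # the one H2O per assembled molecule
  add_tok <- function(tok) {
    f <<- f + get_block(tok$block)$formula
    if (identical(tok$cap, "Fmoc")) f <<- f + get_block("Fmoc")$formula
    if (!is.null(tok$branch)) add_tok(tok$branch)
  }
  for (tok in toks) add_tok(tok)
  structure(as.integer(f), names = names(f), class = "elemental_formula")
}

as_compound_seq <- function(seq) {
  if (inherits(seq, "compound_seq")) seq else parse_sequence(seq)
}

# chain-level structural validity shared by both formula routes
validate_chain <- function(toks) {
  if (is_triazole(get_block(toks[[length(toks)]]$block))) {
    stop("structural error: a triazole unit cannot terminate a sequence ",
         "(no carboxyl terminus)", call. = FALSE)
  }
  for (i in seq_along(toks)[-1]) {
    blk <- get_block(toks[[i]]$block)
    if (is_triazole(get_block(toks[[i - 1L]]$block)) && !is_triazole(blk) &&
        blk$atoms$h[blk$atoms$label == blk$n_attach] < 1L) {
      stop("structural error: '", blk$name, "' cannot follow a triazole ",
           "unit (ring N1 derives from a primary amine via diazotransfer; ",
           "a secondary backbone amine cannot form the azide)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(formula_string(x), "\n")
  invisible(x)
}

#' Format or parse a Hill-style formula string
#'
#' `formula_string()` prints counts in the fixed order C, H, N, O (elements
#' with zero count are omitted), matching the style of published compound
#' tables. `parse_formula()` is its inverse.
#'
#' @param f Named counts (`C`, `H`, `N`, `O`).
#' @param text A formula string such as `"C25H46N16O4"`.
#' @return A string, respectively a named integer vector of class
#'   `elemental_formula`.
#' @export
formula_string <- function(f) {
  els <- c("C", "H", "N", "O")
  n <- as.integer(f[els])
  n[is.na(n)] <- 0L
  paste0(ifelse(n > 0, paste0(els, n), ""), collapse = "")
}

#' @rdname formula_string
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(text)) {
    stop("cannot parse formula string '", text, "'", call. = FALSE)
  }
  f <- c(C = 0L, H = 0L, N = 0L, O = 0L)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    ct <- sub("^[A-Za-z]+", "", p)
    if (!el %in% names(f)) stop("unsupported element '", el, "'", call. = FALSE)
    f[el] <- f[el] + if (nzchar(ct)) as.integer(ct) else 1L
  }
  structure(f, class = "elemental_formula")
}

#' Assemble a parsed sequence into a heavy-atom molecular graph
#'
#' Builds the heavy-atom graph (hydrogens as per-atom counts) using the
#' junction chemistry implied by the solid-phase synthesis route:
#'
#' * consecutive standard residues are joined by an amide bond (acyl carbon
#'   to the next backbone nitrogen, which keeps one hydrogen);
#' * entering a glycyl-triazole unit from the N-terminal side is an ordinary
#'   acylation of its amide nitrogen;
#' * leaving a triazole unit toward the C-terminus, ring nitrogen N1 (the
#'   azide-derived nitrogen, zero hydrogens) *is* the next block's backbone
#'   nitrogen: the next residue contributes no separate N-H, and a following
#'   triazole unit contributes no separate amide nitrogen;
#' * a branch residue acylates the host side-chain amine (one hydrogen
#'   remains on it); the branch amino terminus is free unless Fmoc-capped;
#' * the amino terminus gains one hydrogen over the mid-chain state, the
#'   carboxy terminus gains a hydroxyl oxygen, and an Fmoc cap replaces one
#'   hydrogen on the capped nitrogen with the fluorenylmethyloxycarbonyl
#'   fragment.
#'
#' @param seq A `compound_seq` or sequence string.
#' @return An object of class `mol_graph`: list with `atoms` (data frame:
#'   `id`, `element`, `h`, `block`, `token`, `role`), `bonds` (data frame
#'   `from`, `to`) and `seq`.
#' @examples
#' g <- assemble_graph("Har-GlyΨ[Trl]GlyΨ[Trl]Arg")
#' formula_string(formula_from_graph(g))  # C19H34N14O3
#' @export
assemble_graph <- function(seq) {
  seq <- as_compound_seq(seq)
  toks <- seq$tokens
  n <- length(toks)
  validate_chain(toks)

  atoms <- list()
  bonds <- list()
  aid <- function(path, label) paste0(path, ":", label)

  add_fragment <- function(blk, path, token_idx, skip = character()) {
    keep <- !blk$atoms$label %in% skip
    at <- blk$atoms[keep, , drop = FALSE]
    role <- rep("", nrow(at))
    if (!is.na(blk$guanidine)) role[at$label == blk$guanidine] <- "guanidine_C"
    if (is_triazole(blk)) role[at$label == "C5"] <- "ring_C5"
    atoms[[length(atoms) + 1L]] <<- data.frame(
      id = aid(path, at$label), element = at$element, h = at$h,
      block = blk$name, token = token_idx, role = role,
      stringsAsFactors = FALSE)
    for (b in blk$bonds) {
      if (any(b %in% skip)) next
      bonds[[length(bonds) + 1L]] <<- c(aid(path, b[1]), aid(path, b[2]))
    }
  }
  add_bond <- function(a, b) bonds[[length(bonds) + 1L]] <<- c(a, b)
  bump_h <- function(id, by) {
    found <- FALSE
    for (k in seq_along(atoms)) {
      hit <- atoms[[k]]$id == id
      if (any(hit)) {
        found <- TRUE
        newh <- atoms[[k]]$h[hit] + by
        if (newh < 0) stop("hydrogen count would become negative on ", id,
                           call. = FALSE)
        atoms[[k]]$h[hit] <<- newh
      }
    }
    if (!found) stop("internal error: no atom ", id, call. = FALSE)
  }

  apply_cap <- function(host_n_id, path, token_idx) {
    fm <- get_block("Fmoc")
    bump_h(host_n_id, -1L)
    add_fragment(fm, path, token_idx)
    add_bond(aid(path, fm$c_attach), host_n_id)
  }

  prev_blk <- NULL
  prev_path <- NULL
  for (i in seq_len(n)) {
    tok <- toks[[i]]
    blk <- get_block(tok$block)
    path <- paste0("t", i)

    after_trz <- !is.null(prev_blk) && is_triazole(prev_blk)
    skip <- if (after_trz) blk$n_attach else character()
    add_fragment(blk, path, i, skip = skip)

    if (after_trz) {
      # identify the previous unit's ring N1 with this block's backbone N:
      # re-route every fragment bond that involved the skipped nitrogen
      n1 <- aid(prev_path, "N1")
      for (b in blk$bonds) {
        if (blk$n_attach %in% b) {
          other <- setdiff(b, blk$n_attach)
          if (length(other) == 1) add_bond(n1, aid(path, other))
        }
      }
    } else if (i > 1L) {
      add_bond(aid(prev_path, prev_blk$c_attach), aid(path, blk$n_attach))
    } else {
      bump_h(aid(path, blk$n_attach), +1L)  # free amino terminus
    }

    if (identical(tok$cap, "Fmoc")) {
      if (is_triazole(blk) || after_trz) {
        stop("structural error: cannot cap a nitrogen that is not an amine",
             call. = FALSE)
      }
      apply_cap(aid(path, blk$n_attach), paste0(path, ".cap"), i)
    }

    if (!is.null(tok$branch)) {
      if (is.na(blk$side_attach)) {
        stop("structural error: block '", blk$name,
             "' has no side-chain attachment point", call. = FALSE)
      }
      bblk <- get_block(tok$branch$block)
      bpath <- paste0(path, ".b")
      bump_h(aid(path, blk$side_attach), -1L)
      add_fragment(bblk, bpath, i)
      add_bond(aid(bpath, bblk$c_attach), aid(path, blk$side_attach))
      bump_h(aid(bpath, bblk$n_attach), +1L)  # branch amino terminus
      if (identical(tok$branch$cap, "Fmoc")) {
        apply_cap(aid(bpath, bblk$n_attach), paste0(bpath, ".cap"), i)
      }
    }

    prev_blk <- blk
    prev_path <- path
  }

  # free carboxyl terminus: the carbonyl gains a hydroxyl oxygen
  last_blk <- get_block(toks[[n]]$block)
  oxt <- paste0("t", n, ":OXT")
  atoms[[length(atoms) + 1L]] <- data.frame(
    id = oxt, element = "O", h = 1L, block = last_blk$name, token = n,
    role = "carboxyl_OH", stringsAsFactors = FALSE)
  add_bond(paste0("t", n, ":", last_blk$c_attach), oxt)

  atoms <- do.call(rbind, atoms)
  bonds <- as.data.frame(do.call(rbind, bonds), stringsAsFactors = FALSE)
  names(bonds) <- c("from", "to")
  if (anyDuplicated(atoms$id)) stop("internal error: duplicate atom ids")
  g <- structure(list(atoms = atoms, bonds = bonds, seq = seq),
                 class = "mol_graph")
  stopifnot(graph_connected(g))
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", canonical_string(x$seq), "\n  ", nrow(x$atoms),
      " heavy atoms, ", nrow(x$bonds), " bonds, formula ",
      formula_string(formula_from_graph(x)), "\n", sep = "")
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$bonds, directed = FALSE,
                                vertices = g$atoms$id)
}

graph_connected <- function(g) {
  igraph::is_connected(as_igraph(g))
}

#' Elemental formula from an assembled graph
#'
#' Counts atoms by element and sums the per-atom hydrogen counts. Must equal
#' [additive_formula()] of the same sequence — the central cross-check of the
#' assembly rules.
#'
#' @param g A `mol_graph`.
#' @return An `elemental_formula`.
#' @export
formula_from_graph <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  el <- table(factor(g$atoms$element, levels = c("C", "H", "N", "O")))
  structure(c(C = unname(el[["C"]]), H = sum(g$atoms$h),
              N = unname(el[["N"]]), O = unname(el[["O"]])),
            class = "elemental_formula")
}

# lightest-isotope masses (Da); proton mass for pseudomolecular ions
.isotope_mass <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196)
.proton_mass <- 1.007276

#' Monoisotopic mass and m/z of a protonated ion
#'
#' `monoisotopic_mass()` sums lightest-isotope masses over a neutral formula.
#' `monoisotopic_mz()` returns the [M + zH]^z+ value
#' `(M + z * 1.007276) / z`, conventionally reported to 4 decimal places.
#'
#' @param f An `elemental_formula`, formula string, `compound_seq` or
#'   sequence string.
#' @param z Charge state, a positive integer (published tables here use 1
#'   or 2).
#' @return `monoisotopic_mz()` returns a list with `mass` (neutral, Da),
#'   `z`, `mz` (exact) and `mz_4dp` (reported rounding).
#' @examples
#' monoisotopic_mz("Lys(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg", z = 1)$mz_4dp  # 635.3961
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(.isotope_mass[names(f)] * as.numeric(f))
}

#' @rdname monoisotopic_mass
#' @export
monoisotopic_mz <- function(f, z = 1) {
  if (!is.numeric(z) || length(z) != 1 || z != round(z) || z <= 0) {
    stop("charge z must be a positive integer", call. = FALSE)
  }
  mass <- monoisotopic_mass(f)
  mz <- (mass + z * .proton_mass) / z
  list(mass = mass, z = as.integer(z), mz = mz, mz_4dp = round_half_up(mz, 4))
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f) && grepl("^[A-Z]", f) && !grepl("[a-z]{2}", f) &&
      grepl("^([CHNO][0-9]*)+$", f)) {
    return(parse_formula(f))
  }
  additive_formula(f)
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
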