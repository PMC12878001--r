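#' SMILES tokenizer
#'
#' Splits a SMILES string into the standard atom-wise token stream used by
#' sequence models: bracket atoms (`[...]`) are single tokens, two-letter
#' organic-subset elements (`Cl`, `Br`) stay intact, and every ring-closure
#' digit, bond symbol, branch parenthesis and dot is its own token. Joining
#' the tokens reproduces the input.
#'
#' @param smiles SMILES string (may be empty).
#' @return Character vector of tokens; `character(0)` for the empty string.
#' @examples
#' tokenize_smiles("CC(=O)O")
#' tokenize_smiles("c1ccccc1Br")
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  rx <- paste0(
    "(\\[[^\\]]*\\]",        # bracket atom
    "|Cl|Br",                # two-letter organic subset
    "|[BCNOPSFI]",           # one-letter organic subset
    "|[bcnops]",             # aromatic organic subset
    "|%[0-9]{2}",            # two-digit ring closure
    "|[0-9]",                # ring closure digit
    "|[-=#:/\\\\().+*!~]",   # bonds, branches, dot, tag token
    "|>)"
  )
  m <- gregexpr(rx, smiles, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("tokenization error: no tokens in '", smiles, "'")
  toks <- regmatches(smiles, list(m))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    stop("tokenization error: unrecognized characters in '", smiles, "'")
  }
  if (any(grepl("^\\[[^]]*$", toks)) || grepl("\\[[^]]*$", smiles)) {
    stop("tokenization error: unclosed bracket in '", smiles, "'")
  }
  toks
}

# element inventory: organic subset + common hetero/metal atoms seen in
# reagents. Valence table used for implicit-H assignment and sanitization.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("B", "C", "N", "O", "P", "S", "Se", "As")

.DEFAULT_VALENCE <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L, Se = c(2L, 4L, 6L), Si = 4L
)

.KNOWN_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Ti", "Cr", "Mn", "Fe", "Co", "Ni",
  "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Zr", "Mo",
  "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te", "I", "Xe", "Cs",
  "Ba", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi"
)

.new_mol <- function() {
  list(
    elem = character(0), arom = logical(0), charge = integer(0),
    nH = integer(0), map = integer(0), iso = integer(0), chir = character(0),
    hexpl = logical(0),           # TRUE when H count was given in a bracket
    b1 = integer(0), b2 = integer(0), bo = numeric(0)
  )
}

.parse_bracket <- function(tok) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  if (!nzchar(body)) stop("unparsable bracket atom: ", tok)
  iso <- 0L
  m <- regmatches(body, regexpr("^[0-9]+", body))
  if (length(m)) {
    iso <- as.integer(m)
    body <- sub("^[0-9]+", "", body)
  }
  m <- regmatches(body, regexpr("^([A-Z][a-z]?|as|se|[bcnops]|\\*)", body))
  if (!length(m)) stop("unparsable bracket atom: ", tok)
  sym <- m
  body <- sub(paste0("^", gsub("\\*", "\\\\*", sym)), "", body)
  arom <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
  elem <- if (arom) {
    paste0(toupper(substr(sym, 1L, 1L)), substring(sym, 2L))
  } else {
    sym
  }
  if (elem != "*" && !(elem %in% .KNOWN_ELEMENTS)) {
    stop("unknown element '", elem, "' in ", tok)
  }
  chir <- ""
  m <- regmatches(body, regexpr("^@{1,2}", body))
  if (length(m)) {
    chir <- m
    body <- sub("^@{1,2}", "", body)
  }
  nH <- 0L
  m <- regmatches(body, regexpr("^H[0-9]*", body))
  if (length(m)) {
    nH <- if (nchar(m) == 1L) 1L else as.integer(substring(m, 2L))
    body <- sub("^H[0-9]*", "", body)
  }
  charge <- 0L
  m <- regmatches(body, regexpr("^(\\+{1,3}|-{1,3})([0-9]+)?", body))
  if (length(m)) {
    sgn <- if (substr(m, 1L, 1L) == "+") 1L else -1L
    digits <- sub("^[+-]+", "", m)
    charge <- if (nzchar(digits)) sgn * as.integer(digits) else
      sgn * nchar(gsub("[0-9]", "", m))
    body <- sub("^(\\+{1,3}|-{1,3})([0-9]+)?", "", body)
  }
  map <- 0L
  m <- regmatches(body, regexpr("^:[0-9]+", body))
  if (length(m)) {
    map <- as.integer(substring(m, 2L))
    body <- sub("^:[0-9]+", "", body)
  }
  if (nzchar(body)) stop("unparsable bracket atom: ", tok)
  list(elem = elem, arom = arom, charge = charge, nH = nH, map = map,
       iso = iso, chir = chir)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms with isotope / H-count /
#' charge / atom-map fields, branches, ring closures (including `%nn`),
#' aromatic atoms and bonds, and multi-fragment strings joined by `.`.
#' Implicit hydrogen counts are resolved at parse time from standard
#' valences; stereo descriptors are retained as atom labels.
#'
#' @param smiles SMILES string.
#' @return An object of class `rxmol`: parallel atom vectors (`elem`,
#'   `arom`, `charge`, `nH`, `map`, `iso`, `chir`) and bond vectors
#'   (`b1`, `b2`, `bo`; order 1.5 denotes aromatic).
#' @export
parse_smiles <- function(smiles) {
  toks <- tokenize_smiles(smiles)
  mol <- .new_mol()
  prev <- 0L                       # index of previous atom (0 = none)
  pend_bond <- NA_character_       # explicit bond symbol waiting for an atom
  stack <- integer(0)
  ring <- list()                   # digit -> list(atom, bondsym)
  add_atom <- function(a) {
    mol$elem <<- c(mol$elem, a$elem); mol$arom <<- c(mol$arom, a$arom)
    mol$charge <<- c(mol$charge, a$charge); mol$nH <<- c(mol$nH, a$nH)
    mol$map <<- c(mol$map, a$map); mol$iso <<- c(mol$iso, a$iso)
    mol$chir <<- c(mol$chir, a$chir); mol$hexpl <<- c(mol$hexpl, a$hexpl)
    length(mol$elem)
  }
  bond_order <- function(sym, i, j) {
    if (is.na(sym)) {
      if (mol$arom[i] && mol$arom[j]) 1.5 else 1
    } else {
      switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
             "/" = 1, "\\" = 1,
             stop("unsupported bond symbol: ", sym))
    }
  }
  add_bond <- function(i, j, sym) {
    mol$b1 <<- c(mol$b1, i); mol$b2 <<- c(mol$b2, j)
    mol$bo <<- c(mol$bo, bond_order(sym, i, j))
  }
  for (tok in toks) {
    if (grepl("^\\[", tok)) {
      a <- .parse_bracket(tok)
      a$hexpl <- TRUE
      idx <- add_atom(a)
      if (prev > 0L) add_bond(prev, idx, pend_bond)
      prev <- idx; pend_bond <- NA_character_
    } else if (tok %in% c(.ORGANIC_SUBSET, "b", "c", "n", "o", "p", "s")) {
      arom <- tok %in% c("b", "c", "n", "o", "p", "s")
      elem <- if (arom) toupper(tok) else tok
      idx <- add_atom(list(elem = elem, arom = arom, charge = 0L, nH = NA_integer_,
                           map = 0L, iso = 0L, chir = "", hexpl = FALSE))
      if (prev > 0L) add_bond(prev, idx, pend_bond)
      prev <- idx; pend_bond <- NA_character_
    } else if (grepl("^[0-9]$|^%[0-9]{2}$", tok)) {
      dig <- sub("^%", "", tok)
      if (prev == 0L) stop("ring closure before any atom in '", smiles, "'")
      if (!is.null(ring[[dig]])) {
        op <- ring[[dig]]
        sym <- if (!is.na(pend_bond)) pend_bond else op$sym
        add_bond(op$atom, prev, sym)
        ring[[dig]] <- NULL
      } else {
        ring[[dig]] <- list(atom = prev, sym = pend_bond)
      }
      pend_bond <- NA_character_
    } else if (tok == "(") {
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (!length(stack)) stop("unbalanced ')' in '", smiles, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_bond <- tok
    } else if (tok == ".") {
      prev <- 0L; pend_bond <- NA_character_
    } else {
      stop("unexpected token '", tok, "' in '", smiles, "'")
    }
  }
  if (length(stack)) stop("unbalanced '(' in '", smiles, "'")
  if (length(ring)) stop("unclosed ring bond in '", smiles, "'")
  mol <- .assign_implicit_h(mol)
  class(mol) <- "rxmol"
  mol
}

.bond_order_sum <- function(mol, i) {
  sel <- mol$b1 == i | mol$b2 == i
  s <- sum(mol$bo[sel])
  as.integer(ceiling(s))
}

.assign_implicit_h <- function(mol) {
  for (i in seq_along(mol$elem)) {
    if (!is.na(mol$nH[i])) next
    val <- .DEFAULT_VALENCE[[mol$elem[i]]]
    if (is.null(val)) { mol$nH[i] <- 0L; next }
    bs <- .bond_order_sum(mol, i)
    ok <- val[val >= bs]
    mol$nH[i] <- if (length(ok)) ok[1] - bs else 0L
  }
  mol$nH <- as.integer(mol$nH)
  mol
}

#' Number of atoms in a molecular graph
#' @param mol An `rxmol`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elem)

#' Validate atom valences of a molecular graph
#'
#' Checks, for every atom with a tabulated valence, that the bond-order sum
#' plus the hydrogen count matches an allowed valence for its element and
#' formal charge. Atoms of elements without a tabulated valence (metals,
#' noble-metal catalysts and the like) are not constrained.
#'
#' @param mol An `rxmol`.
#' @return `TRUE` if every constrained atom is valence-valid.
#' @export
sanitize_ok <- function(mol) {
  for (i in seq_along(mol$elem)) {
    elem <- mol$elem[i]
    val <- .DEFAULT_VALENCE[[elem]]
    if (is.null(val)) next
    chg <- mol$charge[i]
    allowed <- val
    # common charge-adjusted valences for the organic subset
    if (elem == "C") allowed <- if (chg == 0L) 4L else 3L
    if (elem == "N") allowed <- switch(as.character(chg),
                                       "0" = c(3L, 5L), "1" = 4L, "-1" = 2L, 0L)
    if (elem == "O") allowed <- switch(as.character(chg),
                                       "0" = 2L, "1" = 3L, "-1" = 1L, 0L)
    if (elem == "S") allowed <- switch(as.character(chg),
                                       "0" = c(2L, 4L, 6L), "1" = 3L, "-1" = 1L,
                                       c(2L, 4L, 6L))
    if (elem %in% c("F", "Cl", "Br", "I")) {
      allowed <- switch(as.character(chg), "0" = 1L, "-1" = 0L, 1L)
    }
    if (elem == "B") allowed <- if (chg == -1L) 4L else 3L
    if (elem == "H") allowed <- if (chg == 0L) 1L else 0L
    tot <- .bond_order_sum(mol, i) + mol$nH[i]
    if (!(tot %in% allowed)) return(FALSE)
  }
  TRUE
}

# connected components of an rxmol; returns integer component id per atom
.mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  nb <- .neighbor_list(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in nb[[a]]) if (comp[b] == 0L) { comp[b] <- cid; queue <- c(queue, b) }
    }
  }
  comp
}

.neighbor_list <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  for (k in seq_along(mol$b1)) {
    i <- mol$b1[k]; j <- mol$b2[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# extract the sub-molecule induced on atom indices `idx` (preserving order)
.mol_subset <- function(mol, idx) {
  sub <- .new_mol()
  for (f in c("elem", "arom", "charge", "nH", "map", "iso", "chir", "hexpl")) {
    sub[[f]] <- mol[[f]][idx]
  }
  old2new <- integer(n_atoms(mol))
  old2new[idx] <- seq_along(idx)
  keep <- mol$b1 %in% idx & mol$b2 %in% idx
  sub$b1 <- old2new[mol$b1[keep]]
  sub$b2 <- old2new[mol$b2[keep]]
  sub$bo <- mol$bo[keep]
  class(sub) <- "rxmol"
  sub
}

#' Split a multi-fragment molecular graph into fragments
#' @param mol An `rxmol`.
#' @return List of single-fragment `rxmol` objects.
#' @export
split_fragments <- function(mol) {
  comp <- .mol_components(mol)
  lapply(seq_len(max(comp, 0L)), function(cid) {
    .mol_subset(mol, which(comp == cid))
  })
}

#' @export
print.rxmol <- function(x, ...) {
  cat("<rxmol> ", n_atoms(x), " atoms, ", length(x$b1), " bonds: ",
      write_smiles(x)$smiles, "\n", sep = "")
  invisible(x)
}
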