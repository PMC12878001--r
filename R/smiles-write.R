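# Canonical atom ranking and SMILES emission.
#
# Canonicalization is refinement-based: atoms start from an invariant tuple
# (element, aromaticity, charge, H count, isotope, stereo label — atom maps
# deliberately excluded so mapped and unmapped copies share a skeleton
# ranking), ranks are refined by iterated neighborhood sorting, and residual
# ties are resolved by individualizing each member of the first tied cell and
# keeping the lexicographically smallest emitted string. The minimum over
# candidates makes the result independent of input atom order.

.initial_ranks <- function(mol) {
  key <- paste(mol$elem, mol$arom, mol$charge, mol$nH, mol$iso, mol$chir,
               sep = "\r")
  match(key, sort(unique(key)))
}

.refine_ranks <- function(mol, ranks) {
  n <- n_atoms(mol)
  if (n == 0L) return(ranks)
  nb <- vector("list", n)
  for (k in seq_along(mol$b1)) {
    i <- mol$b1[k]; j <- mol$b2[k]; o <- mol$bo[k]
    nb[[i]] <- rbind(nb[[i]], c(j, o))
    nb[[j]] <- rbind(nb[[j]], c(i, o))
  }
  repeat {
    key <- vapply(seq_len(n), function(i) {
      e <- nb[[i]]
      env <- if (is.null(e)) "" else
        paste(sort(paste0(e[, 2L], "|", formatC(ranks[e[, 1L]], width = 6,
                                                flag = "0"))), collapse = ",")
      paste0(formatC(ranks[i], width = 6, flag = "0"), ";", env)
    }, character(1))
    new <- match(key, sort(unique(key)))
    if (identical(new, as.integer(ranks))) return(new)
    ranks <- new
  }
}

.bond_token <- function(mol, o, i, j) {
  if (o == 2) return("=")
  if (o == 3) return("#")
  if (o == 1.5) return(if (mol$arom[i] && mol$arom[j]) "" else ":")
  if (o == 1 && mol$arom[i] && mol$arom[j]) return("-")
  ""
}

.plain_implied_h <- function(mol, i) {
  val <- .DEFAULT_VALENCE[[mol$elem[i]]]
  if (is.null(val)) return(NA_integer_)
  bs <- .bond_order_sum(mol, i)
  ok <- val[val >= bs]
  if (length(ok)) ok[1] - bs else 0L
}

.atom_token <- function(mol, i, with_maps) {
  elem <- mol$elem[i]
  sym <- if (mol$arom[i]) tolower(elem) else elem
  plain_ok <- elem %in% .ORGANIC_SUBSET &&
    (!mol$arom[i] || elem %in% c("B", "C", "N", "O", "P", "S")) &&
    mol$charge[i] == 0L && mol$iso[i] == 0L && !nzchar(mol$chir[i]) &&
    !(with_maps && mol$map[i] > 0L)
  if (plain_ok) {
    ih <- .plain_implied_h(mol, i)
    if (!is.na(ih) && ih == mol$nH[i]) return(sym)
  }
  h <- mol$nH[i]
  htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  chg <- mol$charge[i]
  ctok <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-" else
    sprintf("%+d", chg)
  mtok <- if (with_maps && mol$map[i] > 0L) paste0(":", mol$map[i]) else ""
  itok <- if (mol$iso[i] > 0L) as.character(mol$iso[i]) else ""
  paste0("[", itok, sym, mol$chir[i], htok, ctok, mtok, "]")
}

# emit one fragment given a total order; returns list(tokens, token_atom)
# atom_fn/bond_fn allow pattern graphs to reuse the same emission machinery
.emit_fragment <- function(mol, atoms, ranks, with_maps,
                           atom_fn = .atom_token, bond_fn = .bond_token) {
  nbr <- lapply(seq_len(n_atoms(mol)), function(i) integer(0))
  bord <- new.env(parent = emptyenv())
  bkey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  for (k in seq_along(mol$b1)) {
    i <- mol$b1[k]; j <- mol$b2[k]
    if (i %in% atoms && j %in% atoms) {
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
      assign(bkey(i, j), mol$bo[k], envir = bord)
    }
  }
  for (a in atoms) nbr[[a]] <- nbr[[a]][order(ranks[nbr[[a]]])]
  deg <- lengths(nbr[atoms])
  term <- atoms[deg == 1L]
  start <- if (length(term)) term[which.min(ranks[term])] else
    atoms[which.min(ranks[atoms])]

  # pass 1: DFS tree / ring (back) edges
  visited <- rep(FALSE, n_atoms(mol))
  tree_children <- lapply(seq_len(n_atoms(mol)), function(i) integer(0))
  ring_partners <- lapply(seq_len(n_atoms(mol)), function(i) integer(0))
  dfs <- function(u, parent) {
    visited[u] <<- TRUE
    for (v in nbr[[u]]) {
      if (v == parent) next
      if (visited[v]) {
        # back edge: record once, at the later-visited endpoint's partner list
        if (!(u %in% ring_partners[[v]]) && !(v %in% ring_partners[[u]])) {
          ring_partners[[u]] <<- c(ring_partners[[u]], v)
          ring_partners[[v]] <<- c(ring_partners[[v]], u)
        }
      } else {
        tree_children[[u]] <<- c(tree_children[[u]], v)
        dfs(v, u)
      }
    }
  }
  dfs(start, 0L)

  # pass 2: emission with ring-digit bookkeeping
  tokens <- character(0)
  token_atom <- integer(0)
  open_digit <- new.env(parent = emptyenv())  # bond key -> digit label
  used <- rep(FALSE, 99L)
  alloc <- function() {
    d <- which(!used)[1L]
    used[d] <<- TRUE
    d
  }
  dig_tok <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)
  emitted <- rep(FALSE, n_atoms(mol))
  put <- function(tok, atom = 0L) {
    tokens <<- c(tokens, tok)
    token_atom <<- c(token_atom, atom)
  }
  emit <- function(u, parent) {
    put(atom_fn(mol, u, with_maps), u)
    emitted[u] <<- TRUE
    for (v in ring_partners[[u]][order(ranks[ring_partners[[u]]])]) {
      k <- bkey(u, v)
      if (!is.null(open_digit[[k]])) {
        d <- open_digit[[k]]
        put(dig_tok(d))
        used[d] <<- FALSE
        rm(list = k, envir = open_digit)
      } else {
        d <- alloc()
        open_digit[[k]] <- d
        bt <- bond_fn(mol, get(k, envir = bord), u, v)
        if (nzchar(bt)) put(bt)
        put(dig_tok(d))
      }
    }
    ch <- tree_children[[u]]
    if (!length(ch)) return(invisible())
    for (idx in seq_along(ch)) {
      v <- ch[idx]
      bt <- bond_fn(mol, get(bkey(u, v), envir = bord), u, v)
      if (idx < length(ch)) {
        put("(")
        if (nzchar(bt)) put(bt)
        emit(v, u)
        put(")")
      } else {
        if (nzchar(bt)) put(bt)
        emit(v, u)
      }
    }
  }
  emit(start, 0L)
  list(tokens = tokens, token_atom = token_atom)
}

.emit_mol <- function(mol, ranks, with_maps,
                      atom_fn = .atom_token, bond_fn = .bond_token) {
  if (n_atoms(mol) == 0L) {
    return(list(smiles = "", tokens = character(0), token_atom = integer(0)))
  }
  comp <- .mol_components(mol)
  frags <- lapply(seq_len(max(comp)), function(cid) {
    f <- .emit_fragment(mol, which(comp == cid), ranks, with_maps,
                        atom_fn = atom_fn, bond_fn = bond_fn)
    f$smiles <- paste(f$tokens, collapse = "")
    f
  })
  ord <- order(vapply(frags, `[[`, character(1), "smiles"))
  tokens <- character(0); token_atom <- integer(0)
  for (k in seq_along(ord)) {
    if (k > 1L) { tokens <- c(tokens, "."); token_atom <- c(token_atom, 0L) }
    tokens <- c(tokens, frags[[ord[k]]]$tokens)
    token_atom <- c(token_atom, frags[[ord[k]]]$token_atom)
  }
  list(smiles = paste(tokens, collapse = ""), tokens = tokens,
       token_atom = token_atom)
}

# resolve remaining rank ties by individualization; min over emitted strings
.canon_emit <- function(mol, with_maps, max_leaves = 2000L,
                        atom_fn = .atom_token, bond_fn = .bond_token,
                        init_ranks = .initial_ranks) {
  best <- NULL
  leaves <- 0L
  rec <- function(ranks) {
    if (leaves > max_leaves) return(invisible())
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1L])
    if (!length(tied)) {
      leaves <<- leaves + 1L
      out <- .emit_mol(mol, ranks, with_maps, atom_fn = atom_fn,
                       bond_fn = bond_fn)
      if (is.null(best) || out$smiles < best$smiles) best <<- out
      return(invisible())
    }
    cls <- which(ranks == min(tied))
    for (a in cls) {
      r2 <- ranks
      r2[a] <- r2[a] - 0.5
      r2 <- match(r2, sort(unique(r2)))
      rec(.refine_ranks(mol, r2))
      if (leaves > max_leaves) break
    }
  }
  rec(.refine_ranks(mol, init_ranks(mol)))
  best
}

#' Write a molecular graph as canonical SMILES with token positions
#'
#' @param mol An `rxmol`.
#' @param with_maps Emit atom-map numbers (`[CH3:1]`) when present.
#' @return List with `smiles` (string), `tokens` (character vector) and
#'   `token_atom` (integer vector, 0 for non-atom tokens, otherwise the atom
#'   index in `mol` that the token represents).
#' @export
write_smiles <- function(mol, with_maps = TRUE) {
  stopifnot(inherits(mol, "rxmol"))
  .canon_emit(mol, with_maps = with_maps)
}

#' Canonical SMILES of a molecule
#'
#' Canonicalization is idempotent and invariant to input atom and fragment
#' order. Stereo descriptors are carried through as atom labels (two inputs
#' differing only in stereo remain distinct).
#'
#' @param x SMILES string or `rxmol`.
#' @param with_maps Keep atom-map numbers in the output.
#' @return Canonical SMILES string.
#' @examples
#' canonical_smiles("OCC")   # "CCO"
#' canonical_smiles("[CH3:1][OH:6]", with_maps = FALSE)  # "CO"
#' @export
canonical_smiles <- function(x, with_maps = TRUE) {
  mol <- if (inherits(x, "rxmol")) x else parse_smiles(x)
  write_smiles(mol, with_maps = with_maps)$smiles
}

#' Remove atom-map numbers from a molecule
#'
#' @param mol An `rxmol` or SMILES string.
#' @return An `rxmol` with every atom-map number set to 0. Idempotent.
#' @export
strip_maps <- function(mol) {
  if (!inherits(mol, "rxmol")) mol <- parse_smiles(mol)
  mol$map <- rep(0L, n_atoms(mol))
  mol
}

#' Map-stripped canonical SMILES (the deduplication key for one species)
#'
#' @param x SMILES string or `rxmol`.
#' @param stereo Keep stereo descriptors (default). With `FALSE`, stereo
#'   labels are dropped, so records differing only in stereochemistry
#'   collapse to one key.
#' @return Canonical SMILES without atom maps.
#' @export
plain_smiles <- function(x, stereo = TRUE) {
  mol <- strip_maps(x)
  if (!stereo) mol$chir <- rep("", n_atoms(mol))
  canonical_smiles(mol, with_maps = FALSE)
}
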