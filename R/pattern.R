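# Substructure pattern graphs for retrosynthesis templates.
#
# A pattern atom constrains element, aromaticity and formal charge always;
# hydrogen count (changed atoms) and degree (radius-1 shell atoms) only when
# specified. Patterns are serialized in a bracket notation of the form
# [C;+0;H0;!:2] ("!": changed atom) with explicit bond symbols, fragments
# joined by ".". This is the package's own pattern dialect; fidelity to any
# particular SMARTS flavor is not a goal — templates are defined by their
# behavior under matching and application.

.new_pattern <- function() {
  structure(list(
    elem = character(0), arom = logical(0), charge = integer(0),
    nH = integer(0), deg = integer(0), map = integer(0), changed = logical(0),
    b1 = integer(0), b2 = integer(0), bo = numeric(0)
  ), class = "rxpattern")
}

.pattern_add_atom <- function(pat, elem, arom, charge, nH, deg, map, changed) {
  pat$elem <- c(pat$elem, elem); pat$arom <- c(pat$arom, arom)
  pat$charge <- c(pat$charge, as.integer(charge))
  pat$nH <- c(pat$nH, as.integer(nH)); pat$deg <- c(pat$deg, as.integer(deg))
  pat$map <- c(pat$map, as.integer(map))
  pat$changed <- c(pat$changed, changed)
  pat
}

.pattern_n <- function(pat) length(pat$elem)

.pattern_token <- function(pat, i, map_override = NULL) {
  sym <- if (pat$arom[i]) tolower(pat$elem[i]) else pat$elem[i]
  parts <- c(sym, sprintf("%+d", pat$charge[i]))
  if (!is.na(pat$nH[i])) parts <- c(parts, paste0("H", pat$nH[i]))
  if (!is.na(pat$deg[i])) parts <- c(parts, paste0("D", pat$deg[i]))
  if (pat$changed[i]) parts <- c(parts, "!")
  mp <- if (is.null(map_override)) pat$map[i] else map_override[i]
  paste0("[", paste(parts, collapse = ";"), ":", mp, "]")
}

.pattern_bond_token <- function(o) {
  switch(as.character(o), "1" = "-", "2" = "=", "3" = "#", "1.5" = ":",
         stop("bad pattern bond order ", o))
}

#' Parse the package's template pattern notation
#'
#' Inverse of the pattern serializer: bracket atoms
#' `[elem;charge;Hn;Dn;!:map]` with explicit bonds (`-`, `=`, `#`, `:`),
#' branches, ring-closure digits and `.`-separated fragments.
#'
#' @param txt Pattern text.
#' @return An `rxpattern`.
#' @export
parse_pattern <- function(txt) {
  rx <- "(\\[[^\\]]+\\]|[-=#:().]|%[0-9]{2}|[0-9])"
  m <- gregexpr(rx, txt, perl = TRUE)[[1]]
  toks <- regmatches(txt, list(m))[[1]]
  if (paste(toks, collapse = "") != txt) {
    stop("unparsable pattern: ", txt)
  }
  pat <- .new_pattern()
  prev <- 0L; pend <- NA_character_
  stack <- integer(0); ring <- list()
  for (tok in toks) {
    if (grepl("^\\[", tok)) {
      body <- substr(tok, 2L, nchar(tok) - 1L)
      mp <- sub("^.*:", "", body)
      body <- sub(":[0-9]+$", "", body)
      parts <- strsplit(body, ";", fixed = TRUE)[[1]]
      sym <- parts[1]
      arom <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
      elem <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
      charge <- as.integer(parts[2])
      rest <- parts[-(1:2)]
      nH <- NA_integer_; deg <- NA_integer_; changed <- FALSE
      for (p in rest) {
        if (grepl("^H[0-9]+$", p)) nH <- as.integer(substring(p, 2))
        else if (grepl("^D[0-9]+$", p)) deg <- as.integer(substring(p, 2))
        else if (p == "!") changed <- TRUE
        else stop("bad pattern atom field '", p, "' in ", tok)
      }
      pat <- .pattern_add_atom(pat, elem, arom, charge, nH, deg,
                               as.integer(mp), changed)
      idx <- .pattern_n(pat)
      if (prev > 0L) {
        if (is.na(pend)) stop("missing bond symbol in pattern: ", txt)
        pat$b1 <- c(pat$b1, prev); pat$b2 <- c(pat$b2, idx)
        pat$bo <- c(pat$bo, switch(pend, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5))
      }
      prev <- idx; pend <- NA_character_
    } else if (tok %in% c("-", "=", "#", ":")) {
      pend <- tok
    } else if (tok == "(") {
      stack <- c(stack, prev)
    } else if (tok == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- 0L; pend <- NA_character_
    } else {  # ring digit
      dig <- sub("^%", "", tok)
      if (!is.null(ring[[dig]])) {
        op <- ring[[dig]]
        sym <- if (!is.na(pend)) pend else op$sym
        if (is.na(sym)) stop("ring bond without symbol in pattern: ", txt)
        pat$b1 <- c(pat$b1, op$atom); pat$b2 <- c(pat$b2, prev)
        pat$bo <- c(pat$bo, switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5))
        ring[[dig]] <- NULL
      } else {
        ring[[dig]] <- list(atom = prev, sym = pend)
      }
      pend <- NA_character_
    }
  }
  pat
}

# --- matching ---------------------------------------------------------------

.pattern_atom_ok <- function(pat, p, mol, v, moldeg) {
  pat$elem[p] == mol$elem[v] &&
    pat$arom[p] == mol$arom[v] &&
    pat$charge[p] == mol$charge[v] &&
    (is.na(pat$nH[p]) || pat$nH[p] == mol$nH[v]) &&
    (is.na(pat$deg[p]) || pat$deg[p] == moldeg[v])
}

#' Find substructure matches of a pattern in a molecule
#'
#' Induced subgraph matching: every pattern bond must map to a molecule bond
#' of the same order, and matched atoms must carry no molecule bond absent
#' from the pattern. Matches are returned in a deterministic order (by the
#' canonical ranks of the matched atoms).
#'
#' @param pat An `rxpattern`.
#' @param mol An `rxmol`.
#' @param max_matches Stop after this many matches (e.g. 1 for a boolean
#'   screen).
#' @return List of integer vectors mapping pattern atom index to molecule
#'   atom index.
#' @export
match_pattern <- function(pat, mol, max_matches = Inf) {
  np <- .pattern_n(pat)
  nm <- n_atoms(mol)
  if (np == 0L || nm < np) return(list())
  nb <- .neighbor_list(mol)
  moldeg <- lengths(nb)
  bord <- new.env(parent = emptyenv())
  bkey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  for (k in seq_along(mol$b1)) {
    assign(bkey(mol$b1[k], mol$b2[k]), mol$bo[k], envir = bord)
  }
  pnb <- vector("list", np)
  pbo <- new.env(parent = emptyenv())
  for (k in seq_along(pat$b1)) {
    i <- pat$b1[k]; j <- pat$b2[k]
    pnb[[i]] <- c(pnb[[i]], j); pnb[[j]] <- c(pnb[[j]], i)
    assign(bkey(i, j), pat$bo[k], envir = pbo)
  }
  # order pattern atoms: BFS within components so each atom (after the first
  # of its component) has an already-ordered neighbor
  ordseq <- integer(0)
  seen <- rep(FALSE, np)
  for (s in seq_len(np)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      ordseq <- c(ordseq, a)
      for (b in pnb[[a]]) if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
    }
  }
  matches <- list()
  assign_vec <- rep(NA_integer_, np)
  used <- rep(FALSE, nm)
  extend <- function(pos) {
    if (length(matches) >= max_matches) return(invisible())
    if (pos > np) {
      matches[[length(matches) + 1L]] <<- assign_vec
      return(invisible())
    }
    p <- ordseq[pos]
    anchored <- pnb[[p]][!is.na(assign_vec[pnb[[p]]])]
    cands <- if (length(anchored)) {
      nb[[assign_vec[anchored[1L]]]]
    } else {
      seq_len(nm)
    }
    for (v in cands) {
      if (used[v]) next
      if (!.pattern_atom_ok(pat, p, mol, v, moldeg)) next
      ok <- TRUE
      for (q in seq_len(np)) {
        u <- assign_vec[q]
        if (is.na(u) || q == p) next
        pb <- pbo[[bkey(p, q)]]
        mb <- bord[[bkey(v, u)]]
        if (is.null(pb)) {
          if (!is.null(mb)) { ok <- FALSE; break }   # induced: no extra bond
        } else {
          if (is.null(mb) || mb != pb) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign_vec[p] <<- v; used[v] <<- TRUE
      extend(pos + 1L)
      assign_vec[p] <<- NA_integer_; used[v] <<- FALSE
      if (length(matches) >= max_matches) return(invisible())
    }
  }
  extend(1L)
  if (length(matches) > 1L) {
    ranks <- .refine_ranks(mol, .initial_ranks(mol))
    keyfun <- function(m) paste(formatC(ranks[m], width = 6, flag = "0"),
                                collapse = ",")
    matches <- matches[order(vapply(matches, keyfun, character(1)))]
  }
  matches
}

# --- canonical serialization ------------------------------------------------

.pattern_init_ranks <- function(pat, link = NULL) {
  lk <- if (is.null(link)) rep(0L, .pattern_n(pat)) else link
  key <- paste(pat$elem, pat$arom, pat$charge,
               ifelse(is.na(pat$nH), "?", pat$nH),
               ifelse(is.na(pat$deg), "?", pat$deg),
               pat$changed, lk, sep = "\r")
  match(key, sort(unique(key)))
}

# canonical emission of a pattern graph; `link` carries externally-assigned
# map numbers (0 = to be assigned), which both constrain the ranking and are
# printed. Unassigned maps print as "0" in pass 1 and are then numbered in
# token order starting at `next_map`.
.pattern_canon <- function(pat, link = NULL, next_map = 1L) {
  n <- .pattern_n(pat)
  if (n == 0L) return(list(text = "", map_assign = integer(0)))
  lk <- if (is.null(link)) rep(0L, n) else as.integer(link)
  atom_fn <- function(p, i, with_maps) .pattern_token(p, i, map_override = lk)
  bond_fn <- function(p, o, i, j) .pattern_bond_token(o)
  out <- .canon_emit(pat, with_maps = TRUE, atom_fn = atom_fn,
                     bond_fn = bond_fn,
                     init_ranks = function(p) .pattern_init_ranks(p, lk))
  map_assign <- lk
  atom_order <- out$token_atom[out$token_atom > 0L]
  for (a in atom_order) {
    if (map_assign[a] == 0L) {
      map_assign[a] <- next_map
      next_map <- next_map + 1L
    }
  }
  # re-emit tokens with final maps (same atom order; only map digits change)
  tokens <- out$tokens
  ai <- which(out$token_atom > 0L)
  for (k in ai) {
    tokens[k] <- .pattern_token(pat, out$token_atom[k],
                                map_override = map_assign)
  }
  list(text = paste(tokens, collapse = ""), map_assign = map_assign,
       next_map = next_map)
}

#' @export
print.rxpattern <- function(x, ...) {
  cat("<rxpattern> ", .pattern_n(x), " atoms: ",
      .pattern_canon(x, link = x$map)$text, "\n", sep = "")
  invisible(x)
}
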