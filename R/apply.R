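# Retro and forward application of retrosynthesis templates.

.as_mol <- function(x) if (inherits(x, "rxmol")) x else parse_smiles(x)

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

.append_atom <- function(g, elem, arom, charge, nH, map) {
  g$elem <- c(g$elem, elem); g$arom <- c(g$arom, arom)
  g$charge <- c(g$charge, as.integer(charge))
  g$nH <- c(g$nH, as.integer(nH)); g$map <- c(g$map, as.integer(map))
  g$iso <- c(g$iso, 0L); g$chir <- c(g$chir, ""); g$hexpl <- c(g$hexpl, TRUE)
  g
}

#' Molecules from a pool that match a template's product pattern
#'
#' @param t A `retro_template`.
#' @param pool List of molecules (`rxmol` or SMILES), canonical and
#'   unmapped.
#' @return The matching molecules, preserving pool order.
#' @export
match_products <- function(t, pool) {
  pool[vapply(pool, function(m) {
    length(match_pattern(t$prod, .as_mol(m), max_matches = 1L)) > 0L
  }, logical(1))]
}

#' Apply a retrosynthesis template to a product molecule
#'
#' One starting-material set is generated per distinct match site of the
#' product pattern: the bonds among matched atoms are rewritten to the
#' reactant-side bonding, reactant-only atoms (leaving groups) are
#' instantiated, and changed atoms take their reactant-side charge and
#' hydrogen count. Starting materials are map-annotated with the template's
#' reactant-side atom maps so changed atoms can be located for tagging.
#' Unsanitizable outcomes are dropped (counted in the `dropped` attribute),
#' and duplicate SM-sets are collapsed by canonical key.
#'
#' @param t A `retro_template`.
#' @param product Product molecule (`rxmol` or SMILES).
#' @param max_sets Stop after this many distinct SM-sets.
#' @return List of `sm_set` objects (`mols`: list of mapped `rxmol`; `key`:
#'   sorted canonical map-stripped SM key), with attribute `dropped`.
#' @export
apply_retro <- function(t, product, max_sets = Inf) {
  product <- .as_mol(product)
  prod_maps <- t$prod$map
  matches <- match_pattern(t$prod, product)
  out <- list()
  seen <- character(0)
  dropped <- 0L
  changed_maps <- sort(unique(unlist(
    lapply(t$reactants, function(rp) rp$map[rp$changed])
  )))
  for (mt in matches) {
    g <- product
    g$map <- rep(0L, n_atoms(g))
    inm <- rep(FALSE, n_atoms(g)); inm[mt] <- TRUE
    keep <- !(inm[g$b1] & inm[g$b2])
    g$b1 <- g$b1[keep]; g$b2 <- g$b2[keep]; g$bo <- g$bo[keep]
    m2a <- stats::setNames(mt, as.character(prod_maps))
    ok <- TRUE
    for (rp in t$reactants) {
      loc <- integer(.pattern_n(rp))
      for (a in seq_len(.pattern_n(rp))) {
        mp <- as.character(rp$map[a])
        if (!is.na(m2a[mp])) {
          v <- m2a[[mp]]
          g$charge[v] <- rp$charge[a]
          if (!is.na(rp$nH[a])) g$nH[v] <- rp$nH[a]
          g$arom[v] <- rp$arom[a]
          g$map[v] <- rp$map[a]
          loc[a] <- v
        } else {
          g <- .append_atom(g, rp$elem[a], rp$arom[a], rp$charge[a],
                            if (is.na(rp$nH[a])) 0L else rp$nH[a],
                            rp$map[a])
          loc[a] <- n_atoms(g)
        }
      }
      if (length(rp$b1)) {
        g$b1 <- c(g$b1, loc[rp$b1])
        g$b2 <- c(g$b2, loc[rp$b2])
        g$bo <- c(g$bo, rp$bo)
      }
    }
    frags <- split_fragments(g)
    # each reactant pattern describes one species: applications that fuse
    # two patterns into a single fragment (intramolecular variants) do not
    # realize this template and are dropped
    if (length(frags) != length(t$reactants)) {
      dropped <- dropped + 1L
      next
    }
    if (!all(vapply(frags, sanitize_ok, logical(1)))) {
      dropped <- dropped + 1L
      next
    }
    key <- paste(sort(vapply(frags, plain_smiles, character(1))),
                 collapse = ".")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- structure(
      list(mols = frags, key = key, changed_maps = changed_maps),
      class = "sm_set"
    )
    if (length(out) >= max_sets) break
  }
  attr(out, "dropped") <- dropped
  out
}

#' Apply a template in the forward direction
#'
#' Matches each reactant-side pattern in one starting-material species
#' (over all assignments), rewrites the matched bonds to the product-side
#' bonding, deletes reactant-only atoms, and returns the product when
#' exactly one distinct sanitizable product results over all match
#' combinations; otherwise `NULL`. Stray fragments (starting material not
#' consumed by the template) invalidate a combination.
#'
#' @param t A `retro_template`.
#' @param sms List of starting-material molecules (`rxmol` or SMILES), or
#'   an `sm_set`.
#' @return An `rxmol` (product, map-annotated with the template's
#'   product-side maps) or `NULL`.
#' @export
apply_forward <- function(t, sms) {
  if (inherits(sms, "sm_set")) sms <- sms$mols
  combos <- .forward_combos(t, sms, keep_maps = FALSE, first_only = FALSE)
  keys <- unique(vapply(combos, `[[`, character(1), "key"))
  if (length(keys) == 1L) combos[[1L]]$product else NULL
}

# enumerate forward-application outcomes; keep_maps preserves the input
# molecules' atom maps on the product (used by the fixture generator, which
# needs a fully mapped product); first_only stops at the first valid combo
.forward_combos <- function(t, sms, keep_maps = FALSE, first_only = FALSE) {
  sms <- lapply(sms, .as_mol)
  np <- length(t$reactants)
  if (length(sms) != np) return(list())
  prod_maps <- as.character(t$prod$map)
  results <- list()
  for (perm in .perms(seq_len(np))) {
    mls <- lapply(seq_len(np), function(i) {
      match_pattern(t$reactants[[i]], sms[[perm[i]]])
    })
    if (any(lengths(mls) == 0L)) next
    grid <- do.call(expand.grid, lapply(mls, seq_along))
    for (gi in seq_len(nrow(grid))) {
      # combined graph over species in pattern order
      g <- .new_mol(); class(g) <- "rxmol"
      offs <- integer(np)
      for (i in seq_len(np)) {
        s <- sms[[perm[i]]]
        offs[i] <- n_atoms(g)
        for (f in c("elem", "arom", "charge", "nH", "map", "iso", "chir",
                    "hexpl")) {
          g[[f]] <- c(g[[f]], s[[f]])
        }
        g$b1 <- c(g$b1, s$b1 + offs[i])
        g$b2 <- c(g$b2, s$b2 + offs[i])
        g$bo <- c(g$bo, s$bo)
      }
      if (!keep_maps) g$map <- rep(0L, n_atoms(g))
      loc_of <- list()   # reactant-pattern map -> combined atom index
      matched_atoms <- integer(0)
      del_atoms <- integer(0)
      changed_r_maps <- integer(0)   # input maps of changed reactant atoms
      for (i in seq_len(np)) {
        rp <- t$reactants[[i]]
        mt <- mls[[i]][[grid[gi, i]]] + offs[i]
        matched_atoms <- c(matched_atoms, mt)
        for (a in seq_len(.pattern_n(rp))) {
          mp <- as.character(rp$map[a])
          loc_of[[mp]] <- mt[a]
          if (!(mp %in% prod_maps)) del_atoms <- c(del_atoms, mt[a])
          if (keep_maps && rp$changed[a]) {
            changed_r_maps <- c(changed_r_maps, g$map[mt[a]])
          }
        }
      }
      if (!all(prod_maps %in% names(loc_of))) next
      inm <- rep(FALSE, n_atoms(g)); inm[matched_atoms] <- TRUE
      keep <- !(inm[g$b1] & inm[g$b2])
      g$b1 <- g$b1[keep]; g$b2 <- g$b2[keep]; g$bo <- g$bo[keep]
      changed_p_maps <- integer(0)
      for (a in seq_len(.pattern_n(t$prod))) {
        mp <- prod_maps[a]
        v <- loc_of[[mp]]
        g$charge[v] <- t$prod$charge[a]
        if (!is.na(t$prod$nH[a])) g$nH[v] <- t$prod$nH[a]
        g$arom[v] <- t$prod$arom[a]
        if (keep_maps) {
          if (t$prod$changed[a]) changed_p_maps <- c(changed_p_maps, g$map[v])
        } else {
          g$map[v] <- t$prod$map[a]
        }
      }
      pb1 <- vapply(prod_maps[t$prod$b1], function(m) loc_of[[m]], integer(1))
      pb2 <- vapply(prod_maps[t$prod$b2], function(m) loc_of[[m]], integer(1))
      g$b1 <- c(g$b1, pb1); g$b2 <- c(g$b2, pb2); g$bo <- c(g$bo, t$prod$bo)
      keep_idx <- setdiff(seq_len(n_atoms(g)), del_atoms)
      gk <- .mol_subset(g, keep_idx)
      comp <- .mol_components(gk)
      core_old <- setdiff(unlist(loc_of, use.names = FALSE), del_atoms)
      core_new <- match(core_old, keep_idx)
      core_new <- core_new[!is.na(core_new)]
      if (!length(core_new)) next
      cids <- unique(comp[core_new])
      if (length(cids) != 1L) next
      if (max(comp) > 1L) next          # unconsumed stray fragment
      cand <- gk
      if (!sanitize_ok(cand)) next
      results[[length(results) + 1L]] <- list(
        product = cand, key = plain_smiles(cand),
        changed_reactant_maps = sort(unique(changed_r_maps)),
        changed_product_maps = sort(unique(changed_p_maps))
      )
      if (first_only) return(results)
    }
  }
  results
}
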