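# Reaction-center detection from atom mapping.

# per-map environment descriptors for one side of a reaction
.map_env <- function(mols) {
  env <- list()
  for (m in mols) {
    nb <- .neighbor_list(m)
    for (i in seq_along(m$elem)) {
      mp <- m$map[i]
      if (mp == 0L) next
      key <- as.character(mp)
      if (!is.null(env[[key]])) {
        .rxn_error("ambiguous_mapping",
                   paste0("atom-map number ", mp, " occurs twice on one side"))
      }
      nbr_desc <- character(0)
      for (k in seq_along(m$b1)) {
        j <- if (m$b1[k] == i) m$b2[k] else if (m$b2[k] == i) m$b1[k] else next
        nbr_desc <- c(nbr_desc, paste0(m$map[j], "|", m$bo[k]))
      }
      env[[key]] <- list(
        elem = m$elem[i], charge = m$charge[i], nH = m$nH[i],
        nbrs = paste(sort(nbr_desc), collapse = ",")
      )
    }
  }
  env
}

#' Detect atoms whose environment changes across a reaction
#'
#' Compares, per atom-map number, the reactant-side and product-side
#' occurrence of the atom. An atom is changed iff any of these differ: the
#' multiset of (neighbor map number, bond order) pairs, the formal charge,
#' or the total hydrogen count. Atoms present on only one side are changed
#' on that side. Unmapped atoms cannot be traced and are treated as
#' unchanged environment; an unmapped product atom bonded to a changed atom
#' raises an ambiguous-mapping error.
#'
#' @param rxn A role-partitioned `mapped_rxn`.
#' @return Object of class `changed_atoms`: list with integer vectors
#'   `reactant_side` and `product_side` of changed atom-map numbers.
#' @export
detect_changed_atoms <- function(rxn) {
  stopifnot(inherits(rxn, "mapped_rxn"))
  renv <- .map_env(rxn$sm)
  penv <- .map_env(list(rxn$product))
  rmaps <- as.integer(names(renv))
  pmaps <- as.integer(names(penv))
  both <- intersect(rmaps, pmaps)
  changed_both <- both[vapply(both, function(mp) {
    a <- renv[[as.character(mp)]]
    b <- penv[[as.character(mp)]]
    a$charge != b$charge || a$nH != b$nH || a$nbrs != b$nbrs
  }, logical(1))]
  reactant_side <- sort(unique(c(changed_both, setdiff(rmaps, pmaps))))
  product_side <- sort(unique(c(changed_both, setdiff(pmaps, rmaps))))
  # guard: unmapped product heavy atom adjacent to a change cannot be placed
  p <- rxn$product
  if (any(p$map == 0L)) {
    nb <- .neighbor_list(p)
    for (i in which(p$map == 0L)) {
      if (any(p$map[nb[[i]]] %in% product_side)) {
        .rxn_error("ambiguous_mapping",
                   "unmapped product atom adjacent to a changed atom")
      }
    }
  }
  structure(list(reactant_side = as.integer(reactant_side),
                 product_side = as.integer(product_side)),
            class = "changed_atoms")
}

#' @export
print.changed_atoms <- function(x, ...) {
  cat("<changed_atoms> reactant side {",
      paste(x$reactant_side, collapse = ","), "}, product side {",
      paste(x$product_side, collapse = ","), "}\n", sep = "")
  invisible(x)
}
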