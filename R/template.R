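# Retrosynthesis template extraction, canonicalization and correction.
#
# A radius-0 template covers exactly the atoms whose environment changed
# (element, aromaticity and charge constrained, plus hydrogen count);
# a radius-1 template additionally covers their first-shell neighbors,
# constrained by element, aromaticity, charge and degree. The template is
# stored product-side -> reactant-side (retro direction) with canonical,
# renumbering-invariant atom maps linking the two sides.

.md5_string <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

# build one side's pattern from a molecule graph
.build_pattern <- function(mol, sel, changed_idx) {
  pat <- .new_pattern()
  nb <- .neighbor_list(mol)
  deg <- lengths(nb)
  for (i in sel) {
    ch <- i %in% changed_idx
    pat <- .pattern_add_atom(
      pat,
      elem = mol$elem[i], arom = mol$arom[i], charge = mol$charge[i],
      nH = if (ch) mol$nH[i] else NA_integer_,
      deg = if (ch) NA_integer_ else deg[i],
      map = mol$map[i], changed = ch
    )
  }
  old2new <- integer(n_atoms(mol))
  old2new[sel] <- seq_along(sel)
  keep <- mol$b1 %in% sel & mol$b2 %in% sel
  pat$b1 <- old2new[mol$b1[keep]]
  pat$b2 <- old2new[mol$b2[keep]]
  pat$bo <- mol$bo[keep]
  pat
}

# relabel template maps canonically (renumbering-invariant) and compute the
# canonical text form "product>>reactant.reactant"
.template_canonicalize2 <- function(prod, reactants) {
  old_maps <- prod$map
  pc <- .pattern_canon(prod, link = NULL, next_map = 1L)
  tr <- stats::setNames(pc$map_assign, old_maps)
  prod$map <- pc$map_assign
  link <- lapply(reactants, function(rp) {
    vapply(rp$map, function(m) {
      v <- tr[as.character(m)]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  })
  prov <- vapply(seq_along(reactants), function(i) {
    .pattern_canon(reactants[[i]], link = link[[i]], next_map = 9999L)$text
  }, character(1))
  ord <- order(prov)
  nm <- pc$next_map
  texts <- character(length(reactants))
  new_reactants <- vector("list", length(reactants))
  for (k in seq_along(ord)) {
    i <- ord[k]
    rc <- .pattern_canon(reactants[[i]], link = link[[i]], next_map = nm)
    nm <- rc$next_map
    rp <- reactants[[i]]
    rp$map <- rc$map_assign
    new_reactants[[k]] <- rp
    texts[k] <- .pattern_canon(rp, link = rp$map)$text
  }
  ptext <- .pattern_canon(prod, link = prod$map)$text
  list(prod = prod, reactants = new_reactants,
       prod_text = ptext, react_texts = texts,
       full = paste0(ptext, ">>", paste(texts, collapse = ".")))
}

#' Extract a retrosynthesis template from a mapped reaction
#'
#' Changed atoms are detected from the atom mapping
#' (see [detect_changed_atoms()]); the product-side pattern covers exactly
#' the changed product atoms (radius 0) or additionally their first-shell
#' neighbors (radius 1), and the reactant-side patterns cover the
#' corresponding starting-material atoms plus any reactant-only atoms (e.g.
#' leaving groups). Extraction verifies self-consistency: applying the
#' template to the source product regenerates the recorded starting
#' materials.
#'
#' @param rxn A role-partitioned `mapped_rxn` with fully mapped starting
#'   materials.
#' @param radius `"r0"` or `"r1"`.
#' @param check Verify the retro round-trip on the source reaction.
#' @return A `retro_template`.
#' @export
extract_template <- function(rxn, radius = c("r0", "r1"), check = TRUE) {
  radius <- match.arg(radius)
  stopifnot(inherits(rxn, "mapped_rxn"))
  if (any(vapply(rxn$sm, function(m) any(m$map == 0L), logical(1)))) {
    .rxn_error("extraction_error",
               paste0("unmapped starting-material atom in ", rxn$source_id))
  }
  ch <- detect_changed_atoms(rxn)
  if (!length(ch$product_side)) {
    .rxn_error("no_reaction",
               paste0("no atom changes its environment in ", rxn$source_id))
  }
  p <- rxn$product
  nbp <- .neighbor_list(p)
  core_p <- which(p$map %in% ch$product_side)
  sel_p <- core_p
  if (radius == "r1") {
    shell <- setdiff(unique(unlist(nbp[core_p])), core_p)
    sel_p <- c(core_p, shell)
  }
  prod_pat <- .build_pattern(p, sel_p, core_p)
  prod_sel_maps <- p$map[sel_p]

  reactants <- list()
  for (s in rxn$sm) {
    core_s <- which(s$map %in% ch$reactant_side)
    linked <- which(s$map %in% prod_sel_maps)
    sel_s <- union(linked, core_s)
    if (radius == "r1" && length(core_s)) {
      nbs <- .neighbor_list(s)
      sel_s <- union(sel_s, unlist(nbs[core_s]))
    }
    sel_s <- sort(sel_s)
    if (!length(sel_s)) next
    reactants[[length(reactants) + 1L]] <- .build_pattern(s, sel_s, core_s)
  }
  if (!length(reactants)) {
    .rxn_error("extraction_error",
               paste0("empty reactant pattern in ", rxn$source_id))
  }
  cano <- .template_canonicalize2(prod_pat, reactants)
  hash <- .md5_string(paste0(radius, "::", cano$full))
  parent <- if (radius == "r1") {
    extract_template(rxn, "r0", check = FALSE)$hash
  } else {
    hash
  }
  t <- structure(list(
    template_id = paste0(radius, "_", substr(hash, 1, 10)),
    radius = radius,
    prod = cano$prod,
    reactants = cano$reactants,
    n_tags = length(ch$product_side),
    parent_r0_hash = parent,
    hash = hash,
    n_examples = 1L,
    example_ids = rxn$source_id,
    pattern_text = cano$full
  ), class = "retro_template")
  if (check) {
    want <- paste(sort(vapply(rxn$sm, plain_smiles, character(1))),
                  collapse = ".")
    got <- vapply(apply_retro(t, rxn$product), `[[`, character(1), "key")
    if (!(want %in% got)) {
      .rxn_error("extraction_error",
                 paste0("template round-trip failed for ", rxn$source_id))
    }
  }
  t
}

#' Stable hash of a template's canonical pattern form
#'
#' Equal for templates extracted from atom-renumbered copies of the same
#' reaction; distinct across radii.
#'
#' @param t A `retro_template`.
#' @return Hex digest text.
#' @export
template_hash <- function(t) t$hash

#' @export
print.retro_template <- function(x, ...) {
  cat("<retro_template ", x$template_id, "> radius ", x$radius,
      ", ", x$n_tags, " tags, ", x$n_examples, " example(s)\n  ",
      x$pattern_text, "\n", sep = "")
  invisible(x)
}

#' Extract and deduplicate templates from a reaction corpus
#'
#' @param reactions List of `mapped_rxn`.
#' @param radius `"r0"` or `"r1"`.
#' @param min_examples Drop templates with fewer source reactions.
#' @return List with `templates` (unique by hash, `n_examples` counted),
#'   and `errors` (data.frame source_id/message for failed extractions).
#' @export
extract_templates <- function(reactions, radius = c("r0", "r1"),
                              min_examples = 1L) {
  radius <- match.arg(radius)
  by_hash <- list()
  err_id <- character(0); err_msg <- character(0)
  for (rxn in reactions) {
    t <- tryCatch(extract_template(rxn, radius),
                  rxnforge_error = function(e) e)
    if (!inherits(t, "retro_template")) {
      err_id <- c(err_id, rxn$source_id)
      err_msg <- c(err_msg, conditionMessage(t))
      next
    }
    h <- t$hash
    if (is.null(by_hash[[h]])) {
      by_hash[[h]] <- t
    } else {
      by_hash[[h]]$n_examples <- by_hash[[h]]$n_examples + 1L
      by_hash[[h]]$example_ids <- c(by_hash[[h]]$example_ids, t$example_ids)
    }
  }
  templates <- unname(by_hash)
  templates <- templates[vapply(templates, `[[`, integer(1), "n_examples") >=
                           min_examples]
  list(templates = templates,
       errors = data.frame(source_id = err_id, message = err_msg,
                           stringsAsFactors = FALSE))
}

.pattern_spec_count <- function(pat) {
  3L * .pattern_n(pat) + sum(!is.na(pat$nH)) + sum(!is.na(pat$deg))
}

.template_spec_count <- function(t) {
  .pattern_spec_count(t$prod) +
    sum(vapply(t$reactants, .pattern_spec_count, integer(1)))
}

# does template t regenerate the recorded SM set of reaction rxn?
.template_covers <- function(t, rxn) {
  want <- paste(sort(vapply(rxn$sm, plain_smiles, character(1))),
                collapse = ".")
  got <- vapply(apply_retro(t, rxn$product), `[[`, character(1), "key")
  want %in% got
}

#' Hierarchical correction of radius-1 templates
#'
#' Within each group of radius-1 templates sharing a parent radius-0 hash,
#' templates are merged iff they are behaviorally equivalent: each one's
#' retro application regenerates the recorded starting materials for every
#' example reaction of the other. A merged class is represented by the
#' member whose pattern has the fewest specified atom properties (ties
#' broken by the lexicographically smallest canonical pattern), with
#' example counts summed. Non-equivalent templates pass through unchanged.
#'
#' @param templates List of radius-1 `retro_template`s.
#' @param reactions_by_template Named list mapping template hash to the list
#'   of `mapped_rxn` examples it was extracted from.
#' @return List of corrected `retro_template`s.
#' @export
correct_templates <- function(templates, reactions_by_template) {
  if (!length(templates)) return(templates)
  parents <- vapply(templates, `[[`, character(1), "parent_r0_hash")
  out <- list()
  for (par in unique(parents)) {
    idx <- which(parents == par)
    if (length(idx) == 1L) {
      out[[length(out) + 1L]] <- templates[[idx]]
      next
    }
    k <- length(idx)
    covers <- matrix(FALSE, k, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j) { covers[i, j] <- TRUE; next }
        exs <- reactions_by_template[[templates[[idx[j]]]$hash]]
        covers[i, j] <- length(exs) > 0L &&
          all(vapply(exs, function(r) .template_covers(templates[[idx[i]]], r),
                     logical(1)))
      }
    }
    # union-find over mutual-equivalence edges
    comp <- seq_len(k)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        if (covers[i, j] && covers[j, i]) {
          comp[find(j)] <- find(i)
        }
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    for (r in unique(roots)) {
      members <- idx[roots == r]
      ts <- templates[members]
      spec <- vapply(ts, .template_spec_count, integer(1))
      txt <- vapply(ts, `[[`, character(1), "pattern_text")
      best <- order(spec, txt)[1L]
      rep_t <- ts[[best]]
      rep_t$n_examples <- sum(vapply(ts, `[[`, integer(1), "n_examples"))
      rep_t$example_ids <- unlist(lapply(ts, `[[`, "example_ids"))
      out[[length(out) + 1L]] <- rep_t
    }
  }
  out
}

#' Template table as a data.frame
#' @param templates List of `retro_template`.
#' @return data.frame with one row per template (TSV-ready).
#' @export
template_table <- function(templates) {
  data.frame(
    template_id = vapply(templates, `[[`, character(1), "template_id"),
    radius = vapply(templates, `[[`, character(1), "radius"),
    product_pattern = vapply(templates, function(t)
      .pattern_canon(t$prod, link = t$prod$map)$text, character(1)),
    reactant_patterns = vapply(templates, function(t)
      paste(vapply(t$reactants, function(rp)
        .pattern_canon(rp, link = rp$map)$text, character(1)),
        collapse = "."), character(1)),
    n_tags = vapply(templates, `[[`, integer(1), "n_tags"),
    parent_r0_hash = vapply(templates, `[[`, character(1), "parent_r0_hash"),
    hash = vapply(templates, `[[`, character(1), "hash"),
    n_examples = vapply(templates, `[[`, integer(1), "n_examples"),
    stringsAsFactors = FALSE
  )
}

#' Write templates to TSV
#' @param templates List of `retro_template`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_template_tsv <- function(templates, path) {
  utils::write.table(template_table(templates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read templates from TSV
#'
#' Rebuilds `retro_template` objects from the serialized pattern notation.
#' Each `.`-separated fragment of `reactant_patterns` is read as one
#' starting-material species.
#'
#' @param path TSV written by [write_template_tsv()].
#' @return List of `retro_template`.
#' @export
read_template_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    prod <- parse_pattern(df$product_pattern[i])
    rparts <- strsplit(df$reactant_patterns[i], ".", fixed = TRUE)[[1]]
    # re-group fragments belonging to one species: a species boundary is a
    # fragment whose atoms introduce no open linkage; serialized species are
    # connected in this package, so each fragment is one species
    reactants <- lapply(rparts, parse_pattern)
    structure(list(
      template_id = df$template_id[i], radius = df$radius[i],
      prod = prod, reactants = reactants, n_tags = df$n_tags[i],
      parent_r0_hash = df$parent_r0_hash[i], hash = df$hash[i],
      n_examples = df$n_examples[i], example_ids = character(0),
      pattern_text = paste0(df$product_pattern[i], ">>",
                            df$reactant_patterns[i])
    ), class = "retro_template")
  })
}
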