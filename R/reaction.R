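# Atom-mapped reaction records: parsing, role partitioning, dedup keys.

.rxn_error <- function(class, msg) {
  stop(structure(
    list(message = msg, call = NULL),
    class = c(class, "rxnforge_error", "error", "condition")
  ))
}

#' Parse an atom-mapped reaction SMILES line
#'
#' Expects the `reactants>agents>products` convention (one reaction per
#' line). Species are parsed, canonicalized and role-partitioned: a
#' precursor is a starting material (SM) iff at least one of its atom-map
#' numbers occurs in the product, otherwise it is a reagent (R). The record
#' must have exactly one product species and 2-10 precursor species.
#'
#' @param line Reaction SMILES text.
#' @param source_id Identifier carried through to the record.
#' @param line_no Optional line number included in error messages.
#' @return A `mapped_rxn`: list with `sm`, `reagents` (lists of `rxmol`),
#'   `product` (`rxmol`) and `source_id`.
#' @export
parse_reaction <- function(line, source_id = "", line_no = NA_integer_) {
  where <- if (is.na(line_no)) "" else paste0(" (line ", line_no, ")")
  parts <- strsplit(line, ">", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    .rxn_error("malformed_record",
               paste0("expected 'reactants>agents>products'", where))
  }
  parse_side <- function(txt) {
    if (!nzchar(txt)) return(list())
    specs <- strsplit(txt, ".", fixed = TRUE)[[1]]
    lapply(specs, function(s) {
      tryCatch(parse_smiles(s), error = function(e) {
        .rxn_error("rejected_record",
                   paste0("unparsable SMILES '", s, "'", where, ": ",
                          conditionMessage(e)))
      })
    })
  }
  # a product written as a multi-fragment salt is one species; precursor
  # fields list one species per "."-separated fragment (USPTO convention)
  prods <- parse_side(parts[3])
  if (length(prods) != 1L) {
    .rxn_error("malformed_record",
               paste0("expected exactly one product species, got ",
                      length(prods), where))
  }
  precursors <- c(parse_side(parts[1]), parse_side(parts[2]))
  if (length(precursors) < 2L || length(precursors) > 10L) {
    .rxn_error("rejected_record",
               paste0("expected 2-10 precursor species, got ",
                      length(precursors), where))
  }
  rxn <- structure(
    list(sm = precursors, reagents = list(), product = prods[[1]],
         source_id = source_id),
    class = "mapped_rxn"
  )
  partition_roles(rxn)
}

.mol_maps <- function(mol) mol$map[mol$map > 0L]

#' Partition precursors into starting materials and reagents
#'
#' A precursor species contributing at least one atom-map number found in
#' the product is a starting material; all others are reagents. The
#' classification is deterministic and stable under permutation of the
#' input species. Duplicate species appearing on both sides are kept once,
#' with SM priority.
#'
#' @param rxn A `mapped_rxn`.
#' @return The reaction with `sm` / `reagents` reassigned.
#' @export
partition_roles <- function(rxn) {
  stopifnot(inherits(rxn, "mapped_rxn"))
  pmaps <- .mol_maps(rxn$product)
  if (!length(pmaps)) {
    .rxn_error("cannot_partition", "product has no mapped atoms")
  }
  if (anyDuplicated(pmaps)) {
    .rxn_error("malformed_record",
               "duplicate atom-map number on the product side")
  }
  all_prec <- c(rxn$sm, rxn$reagents)
  is_sm <- vapply(all_prec, function(m) any(.mol_maps(m) %in% pmaps),
                  logical(1))
  if (!any(is_sm)) {
    .rxn_error("cannot_partition",
               "no precursor maps into the product")
  }
  sm <- all_prec[is_sm]
  rg <- all_prec[!is_sm]
  sm_maps <- unlist(lapply(sm, .mol_maps))
  if (!all(pmaps %in% sm_maps)) {
    .rxn_error("malformed_record",
               "product atom-map number missing from starting materials")
  }
  # species listed among both SM and reagents: keep the SM copy
  sm_keys <- vapply(sm, plain_smiles, character(1))
  rg_keys <- vapply(rg, plain_smiles, character(1))
  rg <- rg[!(rg_keys %in% sm_keys)]
  rxn$sm <- sm
  rxn$reagents <- rg
  rxn
}

#' Deduplication key for a reaction view
#'
#' Mode `"sm_p"` keys on the map-stripped, fragment-sorted starting
#' materials plus the product (`SM -> P`); mode `"smrp"` additionally
#' includes the sorted reagents (`SM + R -> P`). Equal keys identify the
#' same reaction under that view, independent of input atom or species
#' order.
#'
#' @param rxn A `mapped_rxn` (or a list with `sm`, `reagents`, `product`).
#' @param mode `"sm_p"` or `"smrp"`.
#' @param stereo Stereo-aware keys (default): records differing only in
#'   stereo descriptors stay distinct. See [plain_smiles()].
#' @return List with `mode` and `key` (character).
#' @export
reaction_key <- function(rxn, mode = c("sm_p", "smrp"), stereo = TRUE) {
  mode <- match.arg(mode)
  ps <- function(m) plain_smiles(m, stereo = stereo)
  sm <- paste(sort(vapply(rxn$sm, ps, character(1))), collapse = ".")
  p <- ps(rxn$product)
  key <- if (mode == "sm_p") {
    paste0(sm, ">>", p)
  } else {
    rg <- paste(sort(vapply(rxn$reagents, ps, character(1))),
                collapse = ".")
    paste0(sm, ">", rg, ">", p)
  }
  list(mode = mode, key = key)
}

#' Serialize a mapped reaction back to reaction SMILES
#' @param rxn A `mapped_rxn`.
#' @return `reactants>agents>products` text with atom maps.
#' @export
reaction_smiles <- function(rxn) {
  paste0(
    paste(vapply(rxn$sm, canonical_smiles, character(1)), collapse = "."),
    ">",
    paste(vapply(rxn$reagents, canonical_smiles, character(1)),
          collapse = "."),
    ">",
    canonical_smiles(rxn$product)
  )
}

#' @export
print.mapped_rxn <- function(x, ...) {
  cat("<mapped_rxn> ", length(x$sm), " SM + ", length(x$reagents),
      " R -> P  [", x$source_id, "]\n  ", reaction_smiles(x), "\n", sep = "")
  invisible(x)
}

#' Read reactions from a file of reaction SMILES lines
#'
#' Unparsable or invalid records are collected, not fatal.
#'
#' @param path File with one `reactants>agents>products` line each.
#' @param source_ids Optional identifiers, recycled from line numbers.
#' @return List with `reactions` (list of `mapped_rxn`) and `rejected`
#'   (data.frame of line numbers and messages).
#' @export
read_reactions <- function(path, source_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(source_ids)) source_ids <- sprintf("rxn%06d", seq_along(lines))
  out <- vector("list", length(lines))
  rej_line <- integer(0); rej_msg <- character(0)
  for (i in seq_along(lines)) {
    r <- tryCatch(parse_reaction(lines[i], source_ids[i], line_no = i),
                  rxnforge_error = function(e) e)
    if (inherits(r, "mapped_rxn")) {
      out[[i]] <- r
    } else {
      rej_line <- c(rej_line, i)
      rej_msg <- c(rej_msg, conditionMessage(r))
    }
  }
  list(reactions = Filter(Negate(is.null), out),
       rejected = data.frame(line = rej_line, message = rej_msg,
                             stringsAsFactors = FALSE))
}

#' Write reaction records as JSONL
#'
#' One JSON object per line: `source_id`, `sm`, `reagents`, `product`
#' (mapped canonical SMILES) and both deduplication keys.
#'
#' @param reactions List of `mapped_rxn`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reactions_jsonl <- function(reactions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rxn in reactions) {
    rec <- list(
      source_id = rxn$source_id,
      sm = vapply(rxn$sm, canonical_smiles, character(1)),
      reagents = vapply(rxn$reagents, canonical_smiles, character(1)),
      product = canonical_smiles(rxn$product),
      keys = list(sm_p = reaction_key(rxn, "sm_p")$key,
                  smrp = reaction_key(rxn, "smrp")$key)
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
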