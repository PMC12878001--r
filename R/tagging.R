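# SM* representation: "!"-tagged token sequences marking changed atoms.

#' Tag changed atoms in starting materials
#'
#' Produces the SM* representation: each starting material is written as
#' its canonical (untagged) token stream, and a `"!"` token is inserted
#' immediately after the token of every atom whose map number is in the
#' changed set. Ring-closure digits following a tagged atom come after the
#' `"!"`. Species with no changed atoms carry zero tags.
#'
#' @param sm An `sm_set` (from [apply_retro()]) or list of map-annotated
#'   `rxmol`.
#' @param changed Changed atom-map numbers: integer vector, a
#'   `changed_atoms` object (its `reactant_side` is used), or `NULL` to use
#'   the `changed_maps` recorded in an `sm_set`.
#' @param tag_before_ring_digits Serialization order for tagged ring atoms:
#'   atom token, then `"!"`, then ring-closure digits (default). With
#'   `FALSE` the digits precede the tag.
#' @return List of `tagged_mol`: `tokens` (with `"!"`), `tag_positions`
#'   (indices of `"!"` tokens), `plain` (canonical untagged SMILES).
#' @export
tag_changed_atoms <- function(sm, changed = NULL,
                              tag_before_ring_digits = TRUE) {
  if (inherits(sm, "sm_set")) {
    if (is.null(changed)) changed <- sm$changed_maps
    sm <- sm$mols
  }
  if (inherits(changed, "changed_atoms")) changed <- changed$reactant_side
  changed <- as.integer(changed)
  all_maps <- unlist(lapply(sm, function(m) m$map[m$map > 0L]))
  missing <- setdiff(changed, all_maps)
  if (length(missing)) {
    .rxn_error("tagging_error",
               paste0("changed atom-map number(s) ",
                      paste(missing, collapse = ","),
                      " absent from starting materials"))
  }
  is_ring_digit <- function(tok) grepl("^[0-9]$|^%[0-9]{2}$", tok)
  lapply(sm, function(m) {
    w <- write_smiles(m, with_maps = FALSE)
    toks <- character(0)
    tag_pos <- integer(0)
    pending <- FALSE
    flush_tag <- function() {
      toks <<- c(toks, "!")
      tag_pos <<- c(tag_pos, length(toks))
      pending <<- FALSE
    }
    for (k in seq_along(w$tokens)) {
      if (pending && !is_ring_digit(w$tokens[k])) flush_tag()
      toks <- c(toks, w$tokens[k])
      a <- w$token_atom[k]
      if (a > 0L && m$map[a] %in% changed) {
        if (tag_before_ring_digits) flush_tag() else pending <- TRUE
      }
    }
    if (pending) flush_tag()
    structure(list(tokens = toks, tag_positions = tag_pos,
                   plain = w$smiles),
              class = "tagged_mol")
  })
}

#' Remove "!" tags and recover the molecule
#'
#' Inverse of [tag_changed_atoms()]: strips every `"!"` token and parses
#' the remainder. A `"!"` not immediately following an atom token (e.g. a
#' doubled tag) is a parse error.
#'
#' @param t A `tagged_mol`, or a tagged string / token vector.
#' @return An `rxmol`.
#' @export
untag <- function(t) {
  toks <- if (inherits(t, "tagged_mol")) t$tokens
  else if (is.character(t) && length(t) == 1L) tokenize_smiles(t)
  else as.character(t)
  is_tag <- toks == "!"
  if (any(is_tag)) {
    pos <- which(is_tag)
    prev_ok <- pos > 1L & !is_tag[pmax(pos - 1L, 1L)] &
      !(toks[pmax(pos - 1L, 1L)] %in% c("(", ")", ".", "-", "=", "#", ":"))
    if (!all(prev_ok)) {
      .rxn_error("tag_parse_error",
                 "'!' token not immediately after an atom token")
    }
  }
  parse_smiles(paste(toks[!is_tag], collapse = ""))
}

#' Serialize a tagged molecule
#' @param t A `tagged_mol`.
#' @param spaced Space-join tokens (sequence-model convention) instead of
#'   compact concatenation.
#' @return Character string; both forms round-trip via [tagged_from_string()].
#' @export
tagged_to_string <- function(t, spaced = FALSE) {
  paste(t$tokens, collapse = if (spaced) " " else "")
}

#' Parse a tagged-molecule string back into a `tagged_mol`
#' @param s Compact or space-joined tagged token string.
#' @return A `tagged_mol`.
#' @export
tagged_from_string <- function(s) {
  toks <- if (grepl(" ", s, fixed = TRUE)) {
    strsplit(s, " ", fixed = TRUE)[[1]]
  } else {
    tokenize_smiles(s)
  }
  plain_mol <- untag(toks)
  structure(list(tokens = toks, tag_positions = which(toks == "!"),
                 plain = canonical_smiles(plain_mol, with_maps = FALSE)),
            class = "tagged_mol")
}

#' @export
print.tagged_mol <- function(x, ...) {
  cat("<tagged_mol> ", tagged_to_string(x), " (", length(x$tag_positions),
      " tag(s))\n", sep = "")
  invisible(x)
}
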