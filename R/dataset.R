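# Dataset operations: template equilibration, template-grouped splitting,
# overlap / novelty analysis, tag-count and reagent-element distributions,
# and printed-percentage reporting.

#' Equilibrate a dataset per template
#'
#' Per template, keeps all reactions when the count is at most `cap`,
#' otherwise a seeded uniform sample without replacement of size `cap`.
#' Output row order is deterministic (original order of the kept rows).
#'
#' @param dataset Data.frame with a `template_id` column.
#' @param cap Maximum reactions per template.
#' @param seed Seed for the per-template sampling.
#' @return The equilibrated data.frame.
#' @export
equilibrate <- function(dataset, cap = 100L, seed = 1L) {
  stopifnot(cap >= 1L)
  keep <- logical(nrow(dataset))
  for (tid in unique(dataset$template_id)) {
    idx <- which(dataset$template_id == tid)
    if (length(idx) <= cap) {
      keep[idx] <- TRUE
    } else {
      sel <- .with_seed(.sub_seed(seed, paste0("equilibrate::", tid)),
                        sample(idx, cap))
      keep[sort(sel)] <- TRUE
    }
  }
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Template-grouped train/validation/test split
#'
#' Assigns whole templates to splits so no template straddles a split
#' (avoiding leakage of a transformation between training and test).
#' Templates are taken in descending reaction count (seeded shuffle breaks
#' ties) and greedily assigned to the most-underfilled split relative to
#' the target ratios.
#'
#' @param dataset Data.frame with `template_id`.
#' @param ratios Numeric vector of target fractions, must sum to 1.
#'   Default the conventional 80:10:10.
#' @param seed Seed for tie-breaking.
#' @param split_names Names for the splits.
#' @return List with `assignment` (data.frame template_id/split),
#'   `counts` (reactions per split) and `realized` (achieved fractions).
#' @export
split_by_template <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                              split_names = NULL) {
  if (is.null(split_names)) {
    split_names <- if (length(ratios) == 3L) c("train", "valid", "test") else
      sprintf("split%d", seq_along(ratios))
  }
  stopifnot(abs(sum(ratios) - 1) < 1e-8, length(ratios) == length(split_names))
  tab <- table(dataset$template_id)
  if (length(tab) < length(ratios)) {
    .rxn_error("split_error", "fewer templates than splits")
  }
  tids <- names(tab)
  cnts <- as.integer(tab)
  shuffle <- .with_seed(.sub_seed(seed, "split"), sample.int(length(tids)))
  ord <- order(-cnts[shuffle])
  tids <- tids[shuffle][ord]
  cnts <- cnts[shuffle][ord]
  total <- sum(cnts)
  filled <- numeric(length(ratios))
  assign_to <- integer(length(tids))
  for (i in seq_along(tids)) {
    deficit <- ratios * total - filled
    s <- which.max(deficit)
    assign_to[i] <- s
    filled[s] <- filled[s] + cnts[i]
  }
  assignment <- data.frame(template_id = tids,
                           split = split_names[assign_to],
                           n = cnts, stringsAsFactors = FALSE)
  counts <- stats::setNames(vapply(seq_along(ratios), function(s)
    sum(cnts[assign_to == s]), integer(1)), split_names)
  list(assignment = assignment, counts = counts,
       realized = counts / total)
}

.distinct_keys <- function(dataset, col) unique(dataset[[col]])

#' Overlap analysis between two reaction datasets
#'
#' Shared reactions are counted on distinct deduplication keys, under the
#' `SM -> P` view (`sm_p_key`) and the `SM + R -> P` view (`smrp_key`).
#' Reactions shared as `SM -> P` but not as `SM + R -> P` are "shared under
#' different reaction conditions". Fractions are reported relative to each
#' dataset's distinct-key counts, in both directions.
#'
#' @param A,B Data.frames with `sm_p_key` and `smrp_key` columns.
#' @param distinct Count distinct keys (default) rather than raw rows.
#' @return An `overlap_report` list.
#' @export
overlap_analysis <- function(A, B, distinct = TRUE) {
  get_keys <- function(d, col) {
    k <- d[[col]]
    if (distinct) unique(k) else k
  }
  a_sp <- get_keys(A, "sm_p_key"); b_sp <- get_keys(B, "sm_p_key")
  a_sr <- get_keys(A, "smrp_key"); b_sr <- get_keys(B, "smrp_key")
  shared_sp_keys <- intersect(unique(a_sp), unique(b_sp))
  shared_sr_keys <- intersect(unique(a_sr), unique(b_sr))
  shared_sp <- length(shared_sp_keys)
  shared_sr <- length(shared_sr_keys)
  # "different conditions" = shared as SM->P but never with identical
  # reagents: SM_P keys shared minus the SM_P projections of SMRP-shared keys
  smrp_to_smp <- function(k) {
    parts <- strsplit(k, ">", fixed = TRUE)
    vapply(parts, function(p) paste0(p[1], ">>", p[3]), character(1))
  }
  shared_exact_sp <- if (shared_sr > 0) {
    unique(smrp_to_smp(shared_sr_keys))
  } else {
    character(0)
  }
  diff_cond <- length(setdiff(shared_sp_keys, shared_exact_sp))
  structure(list(
    sm_p_shared = shared_sp,
    smrp_shared = shared_sr,
    different_conditions = diff_cond,
    frac_of_A = c(sm_p = shared_sp / max(length(unique(a_sp)), 1L),
                  smrp = shared_sr / max(length(unique(a_sr)), 1L)),
    frac_of_B = c(sm_p = shared_sp / max(length(unique(b_sp)), 1L),
                  smrp = shared_sr / max(length(unique(b_sr)), 1L)),
    n_A = c(sm_p = length(unique(a_sp)), smrp = length(unique(a_sr))),
    n_B = c(sm_p = length(unique(b_sp)), smrp = length(unique(b_sr)))
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> SM->P shared: ", x$sm_p_shared,
      ", SM+R->P shared: ", x$smrp_shared,
      ", different conditions: ", x$different_conditions, "\n",
      "  of A: sm_p ", round(100 * x$frac_of_A["sm_p"], 1), "%, smrp ",
      round(100 * x$frac_of_A["smrp"], 1), "%\n",
      "  of B: sm_p ", round(100 * x$frac_of_B["sm_p"], 1), "%, smrp ",
      round(100 * x$frac_of_B["smrp"], 1), "%\n", sep = "")
  invisible(x)
}

.species_of <- function(dataset, col) {
  unique(unlist(strsplit(dataset[[col]][nzchar(dataset[[col]])], ".",
                         fixed = TRUE)))
}

#' Novelty analysis of starting materials and reagents
#'
#' Over distinct canonical map-stripped species: the fraction of `A`'s
#' starting materials absent from `B`'s (novelty), the same for reagents,
#' and the reverse coverage (fraction of `B`'s species regenerated in `A`).
#'
#' @param A Data.frame with `sm` and `reagents` columns
#'   (`.`-joined canonical species).
#' @param B Reference data.frame, same columns.
#' @return List of novelty and coverage fractions with species counts.
#' @export
novelty_analysis <- function(A, B) {
  res <- list()
  for (col in c("sm", "reagents")) {
    a <- .species_of(A, col)
    b <- .species_of(B, col)
    res[[col]] <- list(
      n_A = length(a), n_B = length(b),
      novel_in_A = length(setdiff(a, b)),
      novelty = if (length(a)) length(setdiff(a, b)) / length(a) else NA_real_,
      coverage_of_B = if (length(b)) length(intersect(a, b)) / length(b)
      else NA_real_
    )
  }
  res
}

#' Tag-count distribution
#'
#' Histogram of the number of tagged (changed) product atoms, over
#' templates or reactions.
#'
#' @param x List of `retro_template`s, or a data.frame with an `n_tags`
#'   column.
#' @return Data.frame with `n_tags`, `count`, `percent` (percentages sum
#'   to 100 within rounding).
#' @export
tag_count_distribution <- function(x) {
  n_tags <- if (is.data.frame(x)) x$n_tags else
    vapply(x, `[[`, integer(1), "n_tags")
  if (!length(n_tags)) {
    return(data.frame(n_tags = integer(0), count = integer(0),
                      percent = numeric(0)))
  }
  tab <- table(n_tags)
  data.frame(n_tags = as.integer(names(tab)),
             count = as.integer(tab),
             percent = as.numeric(100 * tab / sum(tab)),
             row.names = NULL)
}

#' Reagent element frequencies
#'
#' For each element symbol, the fraction of reactions having at least one
#' reagent species containing an atom of that element. Matching is on
#' parsed atoms, never substrings ("Na" does not match the N of an amine
#' nor the "Sn" of a stannane).
#'
#' @param dataset Data.frame with a `reagents` column (`.`-joined SMILES;
#'   empty string for reagent-free reactions, which count toward the
#'   denominator only).
#' @param elements Character vector of element symbols.
#' @return Named numeric vector of fractions.
#' @export
element_frequency <- function(dataset, elements) {
  bad <- setdiff(elements, .KNOWN_ELEMENTS)
  if (length(bad)) {
    .rxn_error("element_error",
               paste0("unknown element symbol(s): ",
                      paste(bad, collapse = ", ")))
  }
  n <- nrow(dataset)
  hits <- stats::setNames(numeric(length(elements)), elements)
  if (n == 0L) return(hits)
  cache <- new.env(parent = emptyenv())
  elems_of <- function(sp) {
    v <- cache[[sp]]
    if (is.null(v)) {
      v <- tryCatch(unique(parse_smiles(sp)$elem), error = function(e)
        character(0))
      cache[[sp]] <- v
    }
    v
  }
  for (i in seq_len(n)) {
    rg <- dataset$reagents[i]
    if (!nzchar(rg)) next
    present <- unique(unlist(lapply(strsplit(rg, ".", fixed = TRUE)[[1]],
                                    elems_of)))
    for (e in elements) if (e %in% present) hits[e] <- hits[e] + 1
  }
  hits / n
}

#' Percentage with the reporting convention of printed tables
#'
#' `100 * numerator / denominator`, rounded half-away-from-zero to one
#' decimal place.
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @return Percentage with one decimal.
#' @examples
#' as_percentage(934688, 1100773)  # 84.9
#' @export
as_percentage <- function(numerator, denominator) {
  if (length(denominator) != 1L || denominator <= 0) {
    .rxn_error("percentage_error", "denominator must be positive")
  }
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}
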