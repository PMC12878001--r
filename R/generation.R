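# The fictive-reaction campaign: shard the product pool, scan subsets in
# seeded random order per template, generate SM by retro application, obtain
# reagents, tag SM*, forward-validate behind the confidence gate, stop at
# the per-template cap.

#' Campaign configuration
#'
#' Defaults mirror the published campaign design: up to 5000 validated
#' reactions per template, a strictly-greater-than 0.95 confidence gate,
#' the molecule pool split into 1000 subsets scanned in random order, and a
#' single top reagent prediction per candidate.
#'
#' @param cap_per_template Stop a template after this many accepted
#'   reactions.
#' @param confidence_threshold Gate: accept iff confidence is strictly
#'   greater.
#' @param n_pool_subsets Number of pool shards.
#' @param seed Master seed; every random choice derives from it.
#' @param max_reagent_candidates Reagent predictions considered per SM-set.
#' @return A `generation_config`.
#' @export
generation_config <- function(cap_per_template = 5000L,
                              confidence_threshold = 0.95,
                              n_pool_subsets = 1000L,
                              seed = 1L,
                              max_reagent_candidates = 1L) {
  stopifnot(cap_per_template >= 1L,
            confidence_threshold > 0, confidence_threshold < 1,
            n_pool_subsets >= 1L, max_reagent_candidates >= 1L)
  structure(list(cap_per_template = as.integer(cap_per_template),
                 confidence_threshold = confidence_threshold,
                 n_pool_subsets = as.integer(n_pool_subsets),
                 seed = as.integer(seed),
                 max_reagent_candidates = as.integer(max_reagent_candidates)),
            class = "generation_config")
}

#' Shard a molecule pool into balanced subsets
#'
#' Deterministic seeded partition: subset sizes differ by at most one, the
#' union is the pool and subsets are disjoint.
#'
#' @param pool List (or character vector) of molecules.
#' @param n Number of subsets; shrunk with a warning if it exceeds the pool
#'   size.
#' @param seed Seed for the permutation.
#' @return List of `n` subsets (same element type as `pool`).
#' @export
shard_pool <- function(pool, n, seed = 1L) {
  stopifnot(n >= 1L)
  np <- length(pool)
  if (n > np) {
    warning("n_pool_subsets exceeds pool size; shrinking to ", np)
    n <- np
  }
  perm <- .with_seed(.sub_seed(seed, "shard"), sample.int(np))
  sizes <- rep(np %/% n, n)
  extra <- np %% n
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  out <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    # membership is random, but each subset preserves the pool's order
    out[[i]] <- pool[sort(perm[seq.int(pos + 1L, pos + sizes[i])])]
    pos <- pos + sizes[i]
  }
  out
}

#' Validate one candidate fictive reaction through the confidence gate
#'
#' Accepted iff the validator's product (map-stripped canonical) equals the
#' target product AND the confidence is strictly greater than the
#' threshold. The confidence is recorded regardless of acceptance.
#'
#' @param fr Draft fictive-reaction record (list with `sm_star`,
#'   `reagents`, `product_plain`, `template_id`).
#' @param validator A forward predictor (see [predict_product()]).
#' @param threshold Confidence gate.
#' @return `fr` with `pred_product`, `confidence`, `forward_consistent`
#'   and `accepted` filled in.
#' @export
validate_candidate <- function(fr, validator, threshold = 0.95) {
  pred <- predict_product(validator, fr$sm_star, fr$reagents,
                          template_id = fr$template_id)
  fr$pred_product <- if (is.null(pred$product)) NA_character_ else
    plain_smiles(pred$product)
  fr$confidence <- pred$confidence
  fr$forward_consistent <- !is.na(fr$pred_product) &&
    fr$pred_product == fr$product_plain
  fr$accepted <- fr$forward_consistent && fr$confidence > threshold
  fr
}

.fictive_row <- function(fr) {
  data.frame(
    template_id = fr$template_id,
    n_tags = fr$n_tags,
    sm = paste(vapply(fr$sm, plain_smiles, character(1)), collapse = "."),
    sm_star = paste(vapply(fr$sm_star, tagged_to_string, character(1),
                           spaced = TRUE), collapse = " . "),
    reagents = paste(fr$reagents, collapse = "."),
    product = fr$product_plain,
    confidence = fr$confidence,
    forward_consistent = fr$forward_consistent,
    accepted = fr$accepted,
    sm_p_key = fr$sm_p_key,
    smrp_key = fr$smrp_key,
    stringsAsFactors = FALSE
  )
}

.empty_fictive_df <- function() {
  data.frame(template_id = character(0), n_tags = integer(0),
             sm = character(0), sm_star = character(0),
             reagents = character(0), product = character(0),
             confidence = numeric(0), forward_consistent = logical(0),
             accepted = logical(0), sm_p_key = character(0),
             smrp_key = character(0), stringsAsFactors = FALSE)
}

#' Generate fictive reactions for one template
#'
#' Visits the pool subsets in a seeded random order; within a subset,
#' matching products are processed in subset order. Each retro SM-set gives
#' one candidate per reagent prediction; candidates are deduplicated by
#' their SM + R -> P key before counting toward the cap. The loop halts at
#' the per-template cap of accepted reactions or pool exhaustion.
#'
#' @param t A `retro_template`.
#' @param subsets Pool shards from [shard_pool()].
#' @param predictors List with elements `reagent` and `forward` (predictor
#'   objects; `reagent` may be `NULL` for reagent-free candidates).
#' @param config A [generation_config()].
#' @return List with `reactions` (data.frame, accepted and rejected rows)
#'   and `stats` (one-row data.frame: candidates, forward_consistent,
#'   accepted).
#' @export
generate_for_template <- function(t, subsets, predictors, config) {
  order_seed <- .sub_seed(config$seed, paste0("subset_order::", t$hash))
  visit <- .with_seed(order_seed, sample.int(length(subsets)))
  rows <- list()
  seen_keys <- character(0)
  n_candidates <- 0L
  n_consistent <- 0L
  n_accepted <- 0L
  for (si in visit) {
    if (n_accepted >= config$cap_per_template) break
    for (molx in subsets[[si]]) {
      if (n_accepted >= config$cap_per_template) break
      mol <- .as_mol(molx)
      sets <- tryCatch(apply_retro(t, mol), error = function(e) list())
      if (!length(sets)) next
      pplain <- plain_smiles(mol)
      for (s in sets) {
        if (n_accepted >= config$cap_per_template) break
        rg_preds <- if (is.null(predictors$reagent)) list() else
          tryCatch(
            predict_reagents(predictors$reagent, s, mol,
                             k = config$max_reagent_candidates,
                             template_id = t$template_id),
            error = function(e) list()
          )
        if (!length(rg_preds)) rg_preds <- list(list(reagents = character(0),
                                                     score = 1))
        for (rp in rg_preds) {
          if (n_accepted >= config$cap_per_template) break
          reag <- rp$reagents
          smrp_key <- paste0(s$key, ">",
                             paste(sort(vapply(reag, plain_smiles,
                                               character(1))), collapse = "."),
                             ">", pplain)
          if (smrp_key %in% seen_keys) next
          seen_keys <- c(seen_keys, smrp_key)
          fr <- list(
            template_id = t$template_id,
            n_tags = t$n_tags,
            sm = s$mols,
            sm_star = tag_changed_atoms(s),
            reagents = reag,
            product_plain = pplain,
            sm_p_key = paste0(s$key, ">>", pplain),
            smrp_key = smrp_key
          )
          fr <- tryCatch(
            validate_candidate(fr, predictors$forward,
                               config$confidence_threshold),
            error = function(e) {
              fr$pred_product <- NA_character_
              fr$confidence <- 0
              fr$forward_consistent <- FALSE
              fr$accepted <- FALSE
              fr
            }
          )
          n_candidates <- n_candidates + 1L
          if (fr$forward_consistent) n_consistent <- n_consistent + 1L
          if (fr$accepted) n_accepted <- n_accepted + 1L
          rows[[length(rows) + 1L]] <- .fictive_row(fr)
        }
      }
    }
  }
  reactions <- if (length(rows)) do.call(rbind, rows) else .empty_fictive_df()
  list(
    reactions = reactions,
    stats = data.frame(template_id = t$template_id,
                       candidates = n_candidates,
                       forward_consistent = n_consistent,
                       accepted = n_accepted,
                       stringsAsFactors = FALSE)
  )
}

.campaign_version <- "rxnforge-campaign-1"

#' Run a fictive-reaction generation campaign
#'
#' Applies [generate_for_template()] to every template over a sharded pool.
#' With `checkpoint_dir` set, per-template results are written as they
#' complete and an interrupted campaign resumes from the completed set,
#' yielding the same final dataset as an uninterrupted run.
#'
#' @param templates List of `retro_template`.
#' @param pool List (or character vector) of product molecules.
#' @param predictors List with `reagent` and `forward` predictors.
#' @param config A [generation_config()].
#' @param checkpoint_dir Optional directory for resumable state.
#' @return List with `dataset` (data.frame of all candidate rows;
#'   accepted rows form the fictive dataset) and `stats` (per-template
#'   data.frame).
#' @export
run_campaign <- function(templates, pool, predictors, config,
                         checkpoint_dir = NULL) {
  subsets <- shard_pool(pool, config$n_pool_subsets, seed = config$seed)
  done <- character(0)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    vfile <- file.path(checkpoint_dir, "version.json")
    stamp <- list(version = .campaign_version, seed = config$seed,
                  cap = config$cap_per_template,
                  threshold = config$confidence_threshold,
                  n_subsets = config$n_pool_subsets)
    if (file.exists(vfile)) {
      old <- jsonlite::fromJSON(vfile)
      if (!identical(old$version, stamp$version) ||
          old$seed != stamp$seed || old$cap != stamp$cap ||
          old$threshold != stamp$threshold ||
          old$n_subsets != stamp$n_subsets) {
        .rxn_error("checkpoint_mismatch",
                   "checkpoint was written with a different configuration")
      }
    } else {
      writeLines(jsonlite::toJSON(stamp, auto_unbox = TRUE), vfile)
    }
    dfile <- file.path(checkpoint_dir, "completed.txt")
    if (file.exists(dfile)) done <- readLines(dfile, warn = FALSE)
  }
  res <- list(); sts <- list()
  for (t in templates) {
    ck <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, paste0("t_", t$hash, ".rds.tsv"))
    }
    if (t$hash %in% done && !is.null(ck) && file.exists(ck)) {
      r <- utils::read.table(ck, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = .fictive_col_classes())
      s <- utils::read.table(paste0(ck, ".stats"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    } else {
      out <- generate_for_template(t, subsets, predictors, config)
      r <- out$reactions; s <- out$stats
      if (!is.null(ck)) {
        utils::write.table(r, ck, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(s, paste0(ck, ".stats"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        cat(t$hash, "\n", sep = "",
            file = file.path(checkpoint_dir, "completed.txt"), append = TRUE)
      }
    }
    res[[length(res) + 1L]] <- r
    sts[[length(sts) + 1L]] <- s
  }
  dataset <- if (length(res)) do.call(rbind, res) else .empty_fictive_df()
  rownames(dataset) <- NULL
  list(dataset = dataset, stats = do.call(rbind, sts))
}

.fictive_col_classes <- function() {
  c(template_id = "character", n_tags = "integer", sm = "character",
    sm_star = "character", reagents = "character", product = "character",
    confidence = "numeric", forward_consistent = "logical",
    accepted = "logical", sm_p_key = "character", smrp_key = "character")
}

#' Write a fictive-reaction dataset as JSONL
#' @param dataset Data.frame from [run_campaign()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fictive_jsonl <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(dataset))) {
    writeLines(jsonlite::toJSON(as.list(dataset[i, ]), auto_unbox = TRUE),
               con)
  }
  invisible(path)
}

#' Read a fictive-reaction JSONL dataset
#' @param path File written by [write_fictive_jsonl()].
#' @return Data.frame.
#' @export
read_fictive_jsonl <- function(path) {
  rows <- lapply(readLines(path, warn = FALSE), function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
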