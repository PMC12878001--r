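# Round-trip accuracy (RTA) and template-averaged round-trip accuracy
# (TA-RTA) over prediction records.

#' Construct an evaluation record
#'
#' One test product with its ranked predicted precursor sets and their
#' forward-predicted products.
#'
#' @param record_id Identifier.
#' @param template_id Template the test reaction belongs to.
#' @param n_tags Number of tagged (changed) product atoms.
#' @param target_product_key Map-stripped canonical product SMILES.
#' @param predictions List (ranked) of `list(precursors, product_key,
#'   confidence)`; may be empty.
#' @return An `eval_record`.
#' @export
eval_record <- function(record_id, template_id, n_tags, target_product_key,
                        predictions = list()) {
  structure(list(record_id = record_id, template_id = template_id,
                 n_tags = as.integer(n_tags),
                 target_product_key = target_product_key,
                 predictions = predictions),
            class = "eval_record")
}

#' Is a record a round-trip success at top-N?
#'
#' `TRUE` iff any of the first `top_n` predictions has a forward-predicted
#' product key equal to the target product key. By default the validator's
#' confidence is not consulted; with `require_confidence`, a success must
#' also clear the given confidence threshold.
#'
#' @param rec An `eval_record`.
#' @param top_n Number of top predictions considered.
#' @param require_confidence Optional confidence threshold (default `NULL`:
#'   product-key match only).
#' @return Logical flag.
#' @export
record_success <- function(rec, top_n = 1L, require_confidence = NULL) {
  stopifnot(top_n >= 1L)
  preds <- rec$predictions
  if (!length(preds)) return(FALSE)
  n <- min(top_n, length(preds))
  for (i in seq_len(n)) {
    p <- preds[[i]]
    ok <- identical(p$product_key, rec$target_product_key)
    if (ok && !is.null(require_confidence)) {
      ok <- !is.null(p$confidence) && p$confidence > require_confidence
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.success_vec <- function(records, top_n, require_confidence = NULL) {
  vapply(records, record_success, logical(1), top_n = top_n,
         require_confidence = require_confidence)
}

#' Round-trip accuracy averaged across all reactions
#'
#' @param records List of `eval_record` (non-empty).
#' @param top_n Number of top predictions considered.
#' @param require_confidence Optional confidence threshold.
#' @return RTA in `[0, 1]`.
#' @export
round_trip_accuracy <- function(records, top_n = 1L,
                                require_confidence = NULL) {
  if (!length(records)) .rxn_error("metric_error", "no evaluation records")
  mean(.success_vec(records, top_n, require_confidence))
}

#' Template-averaged round-trip accuracy
#'
#' Per-template mean of [record_success()], then the unweighted mean over
#' templates — independent of the number of examples per template.
#'
#' @inheritParams round_trip_accuracy
#' @return TA-RTA in `[0, 1]`.
#' @export
template_averaged_rta <- function(records, top_n = 1L,
                                  require_confidence = NULL) {
  if (!length(records)) .rxn_error("metric_error", "no evaluation records")
  succ <- .success_vec(records, top_n, require_confidence)
  tid <- vapply(records, `[[`, character(1), "template_id")
  mean(tapply(succ, tid, mean))
}

#' RTA / TA-RTA stratified by tag count
#'
#' Metrics computed within each `n_tags` bucket, with the per-bucket record
#' count and the standard deviation of the per-template means (0 for a
#' single-template bucket). Empty buckets are omitted.
#'
#' @param records List of `eval_record`.
#' @param top_n_list Integer vector of top-N values.
#' @return Data.frame: `n_tags`, `top_n`, `rta`, `ta_rta`, `n`,
#'   `n_templates`, `sd_template`.
#' @export
stratify_by_tag_count <- function(records, top_n_list = c(1L, 2L, 3L)) {
  tags <- vapply(records, `[[`, integer(1), "n_tags")
  out <- list()
  for (nt in sort(unique(tags))) {
    sub <- records[tags == nt]
    tid <- vapply(sub, `[[`, character(1), "template_id")
    for (tn in top_n_list) {
      succ <- .success_vec(sub, tn)
      per_t <- tapply(succ, tid, mean)
      sd_t <- if (length(per_t) > 1L) stats::sd(per_t) else 0
      out[[length(out) + 1L]] <- data.frame(
        n_tags = nt, top_n = tn, rta = mean(succ), ta_rta = mean(per_t),
        n = length(sub), n_templates = length(per_t), sd_template = sd_t
      )
    }
  }
  if (!length(out)) {
    return(data.frame(n_tags = integer(0), top_n = integer(0),
                      rta = numeric(0), ta_rta = numeric(0), n = integer(0),
                      n_templates = integer(0), sd_template = numeric(0)))
  }
  do.call(rbind, out)
}

#' Full metric report (RTA and TA-RTA across top-N)
#'
#' @param records List of `eval_record`.
#' @param top_n_list Integer vector of top-N values.
#' @return List with `rta`, `ta_rta` (named numeric vectors by top-N) and
#'   `by_tag_count` (from [stratify_by_tag_count()]).
#' @export
metric_report <- function(records, top_n_list = c(1L, 2L, 3L)) {
  nm <- paste0("top", top_n_list)
  list(
    rta = stats::setNames(vapply(top_n_list, function(tn)
      round_trip_accuracy(records, tn), numeric(1)), nm),
    ta_rta = stats::setNames(vapply(top_n_list, function(tn)
      template_averaged_rta(records, tn), numeric(1)), nm),
    by_tag_count = stratify_by_tag_count(records, top_n_list)
  )
}

#' Write evaluation records as JSONL
#' @param records List of `eval_record`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(unclass(r), auto_unbox = TRUE, null = "null"),
               con)
  }
  invisible(path)
}

#' Read evaluation records from JSONL
#' @param path File written by [write_eval_jsonl()].
#' @return List of `eval_record`.
#' @export
read_eval_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), function(l) {
    x <- jsonlite::fromJSON(l, simplifyDataFrame = FALSE)
    eval_record(x$record_id, x$template_id, x$n_tags, x$target_product_key,
                x$predictions)
  })
}
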