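# Pluggable prediction contracts: reagent predictor (T2 role) and forward
# validator (T3* role), plus the deterministic template-oracle test double
# and the external text-model adapter.

#' Confidence score from token log-probabilities
#'
#' The standard confidence score of an autoregressive sequence model: the
#' product of the top-beam token probabilities, `exp(sum(logprobs))`,
#' clipped to `[0, 1]`.
#'
#' @param logprobs Numeric vector of per-token log-probabilities (finite,
#'   non-positive).
#' @return Confidence in `[0, 1]`.
#' @examples
#' confidence_from_token_logprobs(c(log(0.5), log(0.5)))  # 0.25
#' @export
confidence_from_token_logprobs <- function(logprobs) {
  if (!length(logprobs)) {
    .rxn_error("contract_error", "empty log-probability vector")
  }
  if (any(!is.finite(logprobs))) {
    .rxn_error("contract_error", "non-finite log-probability")
  }
  min(max(exp(sum(logprobs)), 0), 1)
}

# run expr with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# derive a deterministic 31-bit sub-seed from a base seed and a string label
.sub_seed <- function(seed, label) {
  h <- .md5_string(paste0(seed, "::", label))
  (strtoi(substr(h, 1, 7), base = 16L) + as.integer(seed)) %% 2147483647L
}

#' Deterministic template-oracle predictor
#'
#' A test double standing in for the trained reagent (T2) and forward
#' validation (T3*) models: reagents come from a fixed per-template table,
#' and the forward prediction untags SM*, applies the generating template
#' with [apply_forward()], and reports a configured confidence
#' (`base_confidence` plus optional Gaussian noise, clipped to `[0, 1]`).
#' Identical inputs and seed give identical outputs.
#'
#' @param templates List of `retro_template` (indexed by `template_id`).
#' @param reagent_table Named list: `template_id` -> list of reagent sets
#'   (each a character vector of SMILES), ranked.
#' @param base_confidence Confidence reported for a successful forward
#'   application.
#' @param noise_sd Standard deviation of Gaussian noise added to the
#'   confidence (0 = none).
#' @param seed Seed for the noise stream.
#' @return An `oracle_predictor`.
#' @export
oracle_predictor <- function(templates, reagent_table = list(),
                             base_confidence = 1.0, noise_sd = 0,
                             seed = 1L) {
  ids <- vapply(templates, `[[`, character(1), "template_id")
  structure(list(
    templates = stats::setNames(templates, ids),
    reagent_table = reagent_table,
    base_confidence = base_confidence,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = c("oracle_predictor", "rxn_predictor"))
}

#' Predict reagents for an SM -> P conversion
#'
#' @param predictor A predictor object.
#' @param sm Starting materials (list of `rxmol`/SMILES or `sm_set`).
#' @param product Product molecule.
#' @param k Maximum number of ranked predictions.
#' @param template_id Generating template (used by the oracle's table).
#' @return List of up to `k` predictions, each
#'   `list(reagents = character vector of SMILES, score)` sorted by
#'   non-increasing score.
#' @export
predict_reagents <- function(predictor, sm, product, k = 1L,
                             template_id = NULL) {
  UseMethod("predict_reagents")
}

#' @export
predict_reagents.oracle_predictor <- function(predictor, sm, product, k = 1L,
                                              template_id = NULL) {
  stopifnot(k >= 1L)
  entry <- if (!is.null(template_id)) {
    predictor$reagent_table[[template_id]]
  } else {
    NULL
  }
  if (is.null(entry)) return(list())
  if (is.character(entry)) entry <- list(entry)
  n <- min(k, length(entry))
  lapply(seq_len(n), function(i) {
    list(reagents = entry[[i]], score = 1 / i)
  })
}

#' Forward-validate SM* + R, returning product and confidence
#'
#' @param predictor A predictor object.
#' @param sm_star List of `tagged_mol` (the SM* representation).
#' @param reagents Reagent SMILES (character vector), may be empty.
#' @param template_id Generating template id (used by the oracle).
#' @return `list(product = rxmol or NULL, confidence)`; a failed prediction
#'   has `product = NULL` and confidence 0.
#' @export
predict_product <- function(predictor, sm_star, reagents = character(0),
                            template_id = NULL) {
  UseMethod("predict_product")
}

#' @export
predict_product.oracle_predictor <- function(predictor, sm_star,
                                             reagents = character(0),
                                             template_id = NULL) {
  t <- predictor$templates[[template_id %||% ""]]
  if (is.null(t)) return(list(product = NULL, confidence = 0))
  sms <- lapply(sm_star, function(x) {
    if (inherits(x, "tagged_mol")) untag(x) else .as_mol(x)
  })
  p <- apply_forward(t, sms)
  if (is.null(p)) return(list(product = NULL, confidence = 0))
  conf <- predictor$base_confidence
  if (predictor$noise_sd > 0) {
    key <- paste(vapply(sms, plain_smiles, character(1)), collapse = ".")
    conf <- conf + .with_seed(.sub_seed(predictor$seed, key),
                              stats::rnorm(1, 0, predictor$noise_sd))
  }
  list(product = p, confidence = min(max(conf, 0), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' External text-model adapter
#'
#' Line-oriented protocol for hooking a trained sequence model into the
#' pipeline: each input line is `tagged-SM-tokens [SEP] reagent-tokens`
#' (space-joined), each output line is `product-SMILES<TAB>confidence`.
#' `command` is executed with the input file as its first argument and must
#' print one output line per input line.
#'
#' @param command Path to an executable implementing the protocol.
#' @return An `external_predictor`.
#' @export
external_predictor <- function(command) {
  structure(list(command = command),
            class = c("external_predictor", "rxn_predictor"))
}

#' Write a forward-prediction batch file (adapter protocol)
#' @param sm_star_list List of SM* (each a list of `tagged_mol`).
#' @param reagents_list List of reagent SMILES vectors, parallel to
#'   `sm_star_list`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_forward_batch <- function(sm_star_list, reagents_list, path) {
  lines <- vapply(seq_along(sm_star_list), function(i) {
    sm <- paste(vapply(sm_star_list[[i]], tagged_to_string, character(1),
                       spaced = TRUE), collapse = " . ")
    rg <- paste(unlist(lapply(reagents_list[[i]], function(r) {
      paste(tokenize_smiles(r), collapse = " ")
    })), collapse = " . ")
    paste(sm, "[SEP]", rg)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a forward-prediction batch result (adapter protocol)
#' @param path File of `product-SMILES<TAB>confidence` lines.
#' @return List of `list(product, confidence)` per line (`product = NULL`
#'   for an unparsable prediction).
#' @export
read_forward_batch <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    conf <- min(max(suppressWarnings(as.numeric(parts[2])), 0), 1)
    if (is.na(conf)) conf <- 0
    mol <- tryCatch(parse_smiles(parts[1]), error = function(e) NULL)
    if (is.null(mol)) conf <- 0
    list(product = mol, confidence = conf)
  })
}

#' @export
predict_product.external_predictor <- function(predictor, sm_star,
                                               reagents = character(0),
                                               template_id = NULL) {
  fin <- tempfile(fileext = ".txt")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)))
  write_forward_batch(list(sm_star), list(reagents), fin)
  status <- system2(predictor$command, args = fin, stdout = fout)
  if (status != 0L) {
    .rxn_error("predictor_error",
               paste0("external predictor exited with status ", status))
  }
  read_forward_batch(fout)[[1L]]
}
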