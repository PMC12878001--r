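# A self-contained toy chemistry world: hand-coded retrosynthesis templates
# applied to enumerated small molecules, yielding atom-mapped reactions with
# known ground truth (template identity, changed-atom sets, SM/R partition)
# for every other module's tests. Valence-valid, not chemically ambitious.

.make_toy_template <- function(id, prod_txt, react_txts, n_tags) {
  prod <- parse_pattern(prod_txt)
  reactants <- lapply(react_txts, parse_pattern)
  cano <- .template_canonicalize2(prod, reactants)
  hash <- .md5_string(paste0("r0::", cano$full))
  structure(list(
    template_id = id, radius = "r0",
    prod = cano$prod, reactants = cano$reactants,
    n_tags = as.integer(n_tags),
    parent_r0_hash = hash, hash = hash, n_examples = 0L,
    example_ids = character(0), pattern_text = cano$full
  ), class = "retro_template")
}

#' The toy chemistry world
#'
#' Six hand-coded template families over a small substituent library:
#' esterification, amide coupling, Williamson ether synthesis and
#' aryl-aryl coupling (2 product tags each), epoxide aminolysis (3 tags)
#' and alkene dihydroxylation (4 tags), so tag-count stratification has
#' multiple buckets. Each family has a fixed reagent list, mirroring a
#' reagent predictor that returns the most probable reagents.
#'
#' @param seed Seed recorded in the world (used by its generators).
#' @return A `toy_world` list: `templates`, `reagent_table`,
#'   `substituents`, `seed`.
#' @export
toy_world <- function(seed = 42L) {
  templates <- list(
    .make_toy_template(
      "toy_ester",
      "[C;+0;H0;!:1]-[O;+0;H0;!:2]",
      c("[C;+0;H0;!:1]-[O;+0;H1;!:3]", "[O;+0;H1;!:2]"),
      n_tags = 2L
    ),
    .make_toy_template(
      "toy_amide",
      "[C;+0;H0;!:1]-[N;+0;H1;!:2]",
      c("[C;+0;H0;!:1]-[O;+0;H1;!:3]", "[N;+0;H2;!:2]"),
      n_tags = 2L
    ),
    .make_toy_template(
      "toy_ether",
      "[C;+0;H2;!:1]-[O;+0;H0;!:2]",
      c("[C;+0;H2;!:1]-[Br;+0;H0;!:3]", "[O;+0;H1;!:2]"),
      n_tags = 2L
    ),
    .make_toy_template(
      "toy_biaryl",
      "[c;+0;H0;!:1]-[c;+0;H0;!:2]",
      c("[c;+0;H0;!:1]-[Br;+0;H0;!:3]",
        "[c;+0;H0;!:2]-[B;+0;H0;!:4](-[O;+0;H1;!:5])-[O;+0;H1;!:6]"),
      n_tags = 2L
    ),
    .make_toy_template(
      "toy_aminol",
      "[N;+0;H1;!:1]-[C;+0;H2;!:2].[O;+0;H1;!:3]",
      c("[C;+0;H2;!:2]-[O;+0;H0;!:3]", "[N;+0;H2;!:1]"),
      n_tags = 3L
    ),
    .make_toy_template(
      "toy_diol",
      "[O;+0;H1;!:3]-[C;+0;H1;!:1](-[C;+0;H2;!:2]-[O;+0;H1;!:4])",
      c("[C;+0;H1;!:1]=[C;+0;H2;!:2]", "[O;+0;H1;!:3]-[O;+0;H1;!:4]"),
      n_tags = 4L
    )
  )
  names(templates) <- vapply(templates, `[[`, character(1), "template_id")
  list(
    templates = templates,
    reagent_table = list(
      toy_ester = list("O=S(=O)(O)O"),
      toy_amide = list("CCN=C=NCC"),
      toy_ether = list(c("[K+].[OH-]")),
      toy_biaryl = list(c("O=C([O-])[O-].[K+].[K+]")),
      toy_aminol = list("CCO"),
      toy_diol = list("O=[Os](=O)(=O)=O")
    ),
    substituents = list(
      acid = paste0("OC(=O)", c("C", "CC", "CCC", "C(C)C", "Cc1ccccc1",
                                "CCc1ccccc1", "CCCC", "CC(C)C", "CCCCC",
                                "CCCCCC", "CCC(C)C", "CC(C)(C)C")),
      alcohol = paste0("O", c("C", "CC", "CCC", "CC(C)C", "Cc1ccccc1",
                              "CCCC", "CCc1ccccc1", "CCCCC", "CCCCCC",
                              "CC(C)CC", "CCC(C)C", "CCCCCCC")),
      amine = paste0("N", c("C", "CC", "CCC", "Cc1ccccc1", "CCCC",
                            "CC(C)C", "CCc1ccccc1", "CCCCC")),
      halide = paste0("BrC", c("C", "CC", "CCC", "c1ccccc1", "CCCC",
                               "CC(C)C", "Cc1ccccc1", "CCCCC")),
      aryl_br = sprintf("Brc1ccc%scc1", c("", "(C)", "(CC)", "(OC)",
                                          "(CCC)", "(F)")),
      boronic = sprintf("OB(O)c1ccc%scc1", c("", "(C)", "(OC)", "(CC)",
                                             "(F)", "(CCC)")),
      alkene = paste0("C=C", c("C", "CC", "CCC", "Cc1ccccc1", "CCCC",
                               "CC(C)C")),
      epoxide = paste0("C1OC1", c("C", "CC", "CCC", "Cc1ccccc1", "CCCC",
                                  "CC(C)C"))
    ),
    seed = as.integer(seed)
  )
}

# SM species combinations feeding each template family, in a deterministic
# enumeration order (row-major over the two substituent lists)
.toy_sm_lists <- function(world, family) {
  s <- world$substituents
  switch(family,
         toy_ester = list(s$acid, s$alcohol),
         toy_amide = list(s$acid, s$amine),
         toy_ether = list(s$halide, s$alcohol),
         toy_biaryl = list(s$aryl_br, s$boronic),
         toy_aminol = list(s$epoxide, s$amine),
         toy_diol = list(s$alkene, list("OO")),
         stop("unknown toy family: ", family))
}

.toy_combos <- function(world, family) {
  ls <- .toy_sm_lists(world, family)
  out <- list()
  for (a in seq_along(ls[[1]])) {
    for (b in seq_along(ls[[2]])) {
      out[[length(out) + 1L]] <- c(ls[[1]][[a]], ls[[2]][[b]])
    }
  }
  out
}

#' Enumerate a pool of toy product molecules
#'
#' Deterministically combines substituents through each template family's
#' forward application; products are canonical, distinct, in a fixed
#' family-major enumeration order.
#'
#' @param world A [toy_world()].
#' @param n Number of molecules; if it exceeds the enumerable space, all
#'   are returned with a warning.
#' @param families Template families to draw from (default all).
#' @return Character vector of canonical SMILES.
#' @export
enumerate_pool <- function(world, n = 100L,
                           families = names(world$templates)) {
  stopifnot(n >= 1L)
  seen <- character(0)
  per_family <- lapply(families, function(fam) {
    t <- world$templates[[fam]]
    lapply(.toy_combos(world, fam), function(sm) {
      p <- apply_forward(t, as.list(sm))
      if (is.null(p)) NA_character_ else plain_smiles(p)
    })
  })
  # interleave families so a truncated pool still spans all of them
  out <- character(0)
  idx <- rep(1L, length(per_family))
  repeat {
    advanced <- FALSE
    for (f in seq_along(per_family)) {
      if (idx[f] <= length(per_family[[f]])) {
        p <- per_family[[f]][[idx[f]]]
        idx[f] <- idx[f] + 1L
        advanced <- TRUE
        if (!is.na(p) && !(p %in% out)) {
          out <- c(out, p)
          if (length(out) >= n) return(out)
        }
      }
    }
    if (!advanced) break
  }
  warning("requested ", n, " molecules but the toy world enumerates only ",
          length(out))
  out
}

#' Generate atom-mapped toy reactions with ground truth
#'
#' For each template family, substituent combinations are sampled
#' (seeded), the starting materials are fully atom-mapped, and the product
#' is built by forward template application preserving the maps — so the
#' true changed-atom sets, template identity and SM/R partition are known
#' at construction. Reagents come from the world's fixed per-template
#' lists (unmapped, hence partitioned as R).
#'
#' @param world A [toy_world()].
#' @param n_per_template Reactions per family.
#' @param seed Seed (default the world's).
#' @param families Families to generate from (default all).
#' @return List with `reactions` (list of `mapped_rxn`) and `truth`
#'   (list of ground-truth records: `template_id`, `n_tags`,
#'   `changed_reactant`, `changed_product`, `sm_key`).
#' @export
generate_toy_reactions <- function(world, n_per_template = 5L, seed = NULL,
                                   families = names(world$templates)) {
  seed <- seed %||% world$seed
  reactions <- list()
  truth <- list()
  for (fam in families) {
    t <- world$templates[[fam]]
    combos <- .toy_combos(world, fam)
    if (n_per_template < 1L) next
    pick <- if (n_per_template >= length(combos)) {
      rep(seq_along(combos), length.out = n_per_template)
    } else {
      .with_seed(.sub_seed(seed, paste0("toyrxn::", fam)),
                 sample(seq_along(combos), n_per_template))
    }
    for (j in seq_along(pick)) {
      sm_smiles <- combos[[pick[j]]]
      sms <- lapply(sm_smiles, parse_smiles)
      # assign maps sequentially across species
      nxt <- 1L
      for (i in seq_along(sms)) {
        k <- n_atoms(sms[[i]])
        sms[[i]]$map <- seq.int(nxt, nxt + k - 1L)
        nxt <- nxt + k
      }
      fw <- .forward_combos(t, sms, keep_maps = TRUE, first_only = TRUE)
      if (!length(fw)) next
      reagent <- world$reagent_table[[fam]][[1L]]
      rid <- sprintf("%s_%03d", fam, j)
      rxn <- structure(list(
        sm = sms,
        reagents = lapply(reagent, parse_smiles),
        product = fw[[1L]]$product,
        source_id = rid
      ), class = "mapped_rxn")
      reactions[[length(reactions) + 1L]] <- rxn
      truth[[length(truth) + 1L]] <- list(
        source_id = rid,
        template_id = fam,
        n_tags = t$n_tags,
        changed_reactant = fw[[1L]]$changed_reactant_maps,
        changed_product = fw[[1L]]$changed_product_maps,
        sm_key = paste(sort(vapply(sms, plain_smiles, character(1))),
                       collapse = ".")
      )
    }
  }
  list(reactions = reactions, truth = truth)
}

#' Build a dataset pair with a controlled key overlap
#'
#' Ground truth for [overlap_analysis()]: returns two datasets sharing
#' exactly `round(overlap_fraction * n)` SM + R -> P keys, plus a
#' controlled number of pairs sharing SM -> P but differing in reagents
#' ("different conditions"), plus fully disjoint rows.
#'
#' @param dataset Data.frame of fictive-reaction rows with distinct
#'   `smrp_key`s (`sm`, `reagents`, `product`, `sm_p_key`, `smrp_key`).
#' @param overlap_fraction Fraction of `A`'s rows shared exactly with `B`.
#' @param seed Seed for row selection.
#' @param n_diff_conditions Rows of `B` sharing `A`'s SM -> P key with
#'   altered reagents.
#' @return List with `A`, `B` (data.frames) and the realized counts
#'   (`n_shared`, `n_diff_conditions`, `n_disjoint`).
#' @export
perturb_dataset <- function(dataset, overlap_fraction, seed = 1L,
                            n_diff_conditions = 0L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  if (anyDuplicated(dataset$smrp_key)) {
    stop("perturb_dataset requires distinct smrp keys")
  }
  n <- nrow(dataset)
  n_shared <- round(overlap_fraction * n)
  ord <- .with_seed(.sub_seed(seed, "perturb"), sample.int(n))
  shared_idx <- ord[seq_len(n_shared)]
  rest <- setdiff(ord, shared_idx)
  n_diff <- min(n_diff_conditions, length(rest))
  diff_idx <- rest[seq_len(n_diff)]
  disj_idx <- setdiff(rest, diff_idx)
  alter_reagents <- function(rows) {
    if (!nrow(rows)) return(rows)
    extra <- "CC(C)(C)O"   # never in the toy reagent lists
    for (i in seq_len(nrow(rows))) {
      species <- strsplit(rows$reagents[i], ".", fixed = TRUE)[[1]]
      species <- sort(unique(c(species[nzchar(species)], extra)))
      rows$reagents[i] <- paste(species, collapse = ".")
      parts <- strsplit(rows$smrp_key[i], ">", fixed = TRUE)[[1]]
      rows$smrp_key[i] <- paste0(parts[1], ">",
                                 paste(species, collapse = "."), ">",
                                 parts[3])
    }
    rows
  }
  add_inert_sm <- function(rows) {
    if (!nrow(rows)) return(rows)
    for (i in seq_len(nrow(rows))) {
      species <- sort(c(strsplit(rows$sm[i], ".", fixed = TRUE)[[1]], "O"))
      rows$sm[i] <- paste(species, collapse = ".")
      smp <- strsplit(rows$sm_p_key[i], ">>", fixed = TRUE)[[1]]
      rows$sm_p_key[i] <- paste0(paste(species, collapse = "."), ">>",
                                 smp[2])
      parts <- strsplit(rows$smrp_key[i], ">", fixed = TRUE)[[1]]
      rows$smrp_key[i] <- paste0(paste(species, collapse = "."), ">",
                                 parts[2], ">", parts[3])
    }
    rows
  }
  B <- rbind(
    dataset[sort(shared_idx), , drop = FALSE],
    alter_reagents(dataset[sort(diff_idx), , drop = FALSE]),
    add_inert_sm(dataset[sort(disj_idx), , drop = FALSE])
  )
  rownames(B) <- NULL
  list(A = dataset, B = B, n_shared = n_shared,
       n_diff_conditions = n_diff, n_disjoint = length(disj_idx))
}

#' Write toy fixtures to disk
#'
#' Emits the pool (`pool.smi`), atom-mapped reactions (`reactions.txt`,
#' reaction-SMILES lines) and ground truth (`truth.jsonl`).
#'
#' @param world A [toy_world()].
#' @param dir Output directory (created).
#' @param n_pool Pool size.
#' @param n_per_template Reactions per family.
#' @param seed Seed.
#' @return `dir`, invisibly.
#' @export
write_toy_fixtures <- function(world, dir, n_pool = 60L,
                               n_per_template = 5L, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(enumerate_pool(world, n_pool), file.path(dir, "pool.smi"))
  gen <- generate_toy_reactions(world, n_per_template, seed)
  writeLines(vapply(gen$reactions, reaction_smiles, character(1)),
             file.path(dir, "reactions.txt"))
  con <- file(file.path(dir, "truth.jsonl"), "w")
  on.exit(close(con))
  for (tr in gen$truth) {
    writeLines(jsonlite::toJSON(tr, auto_unbox = TRUE), con)
  }
  invisible(dir)
}
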