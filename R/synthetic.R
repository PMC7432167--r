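#' Specification of a synthetic reaction dataset
#'
#' A generator spec bundles everything needed to produce a seeded synthetic
#' dataset: reaction-type templates (atom-mapped reaction SMILES scaffolds
#' with substituent slots), substituent alphabets, a linear property model
#' over fragment counts and condition descriptors with Gaussian noise,
#' a planted Y-outlier fraction, and the condition sampling pools. The same
#' spec and seed always produce a byte-identical dataset.
#'
#' Templates use `{i}` for substituent slot `i` rendered as a chain prefix and
#' `{is}` (e.g. `{1s}`) for the same slot rendered as a suffix/branch; the two
#' renderings carry identical atom-map numbers, so a slot may appear on both
#' reaction sides. Slot `i` uses atom maps `10*i .. 10*i + 9`; template atoms
#' use maps 1-9.
#'
#' @param name suite name.
#' @param templates list of templates, each `list(smirks =, slots = list(...))`
#'   where each slot is a character vector of substituent names from the
#'   built-in substituent library (`methyl`, `ethyl`, `propyl`, `butyl`,
#'   `hydroxymethyl`, `hydroxyethyl`, `phenyl`, `glycinyl`, `methylamino`).
#' @param n number of reactions.
#' @param seed integer RNG seed.
#' @param n_features number of fragment-count features carrying property
#'   weight (linearly independent ones are selected by decreasing variance).
#' @param weight_sd standard deviation of the fragment weights.
#' @param interaction_weight weight of the product of the first two selected
#'   fragment features. The interaction makes the property locally nonlinear,
#'   so an ensemble's prediction variance carries information about how well a
#'   region is supported by training data — the structure that
#'   variance-based AD definitions presuppose. Set to 0 for a purely additive
#'   property.
#' @param cond_weights named weights of `inv_T` (K) and `molar_ratio` (1/%).
#' @param intercept property intercept.
#' @param noise_sd Gaussian noise standard deviation (property units).
#' @param substituent_decay ratio between the sampling probabilities of
#'   consecutive substituents in each alphabet (default 0.5): the first
#'   substituent of an alphabet is the most common, later ones are
#'   progressively rarer, as in real reaction databases where a few reagents
#'   dominate. Set to 1 for uniform sampling.
#' @param outlier_fraction fraction of reactions planted as gross Y-outliers.
#'   Outlier rows are drawn with probability proportional to the rarity of
#'   their substituent combination, emulating the tendency of gross errors to
#'   concentrate in sparsely characterized chemistry — the structure that
#'   makes Y-outliers detectable by data-density and ensemble-variance AD
#'   definitions.
#' @param outlier_offset magnitude added to planted outliers (random sign);
#'   the default is more than ten noise standard deviations, so planted
#'   outliers exceed the 3xRMSE rule with high probability.
#' @param cluster_shift constant added to every property of the suite
#'   (used by the leaving-group-shift suite to emulate a systematically
#'   mispredicted novel cluster).
#' @param solvents solvent-name pool to sample from.
#' @param temperature_range Kelvin range to sample uniformly.
#' @param molar_ratio_pool molar-ratio values to sample from (percent).
#' @return object of class `generator_spec`.
#' @seealso [generate_reactions()], [builtin_suites()]
#' @export
generator_spec <- function(name, templates, n = 100L, seed = 1L,
                           n_features = 4L, weight_sd = 0.8,
                           interaction_weight = 0.6,
                           cond_weights = c(inv_T = -1200, molar_ratio = 0.01),
                           intercept = 2, noise_sd = 0.3,
                           substituent_decay = 0.5,
                           outlier_fraction = 0.05, outlier_offset = 5,
                           cluster_shift = 0,
                           solvents = c("water", "methanol", "ethanol",
                                        "acetonitrile", "acetone", "dmso"),
                           temperature_range = c(283, 353),
                           molar_ratio_pool = c(100, 90, 75, 50)) {
  stopifnot(length(templates) >= 1L, n >= 1L,
            outlier_fraction >= 0, outlier_fraction < 1)
  for (tp in templates) {
    smi <- render_template(tp, lapply(tp$slots, `[[`, 1L))
    parse_reaction(smi)  # spec error surfaces here, naming the template
  }
  structure(list(name = name, templates = templates, n = as.integer(n),
                 seed = as.integer(seed), n_features = as.integer(n_features),
                 weight_sd = weight_sd, interaction_weight = interaction_weight,
                 cond_weights = cond_weights,
                 intercept = intercept, noise_sd = noise_sd,
                 substituent_decay = substituent_decay,
                 outlier_fraction = outlier_fraction,
                 outlier_offset = outlier_offset,
                 cluster_shift = cluster_shift,
                 solvents = solvents,
                 temperature_range = temperature_range,
                 molar_ratio_pool = molar_ratio_pool),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> '%s': %d template(s), n=%d, seed=%d, noise sd=%.2g, outliers=%.0f%%\n",
              x$name, length(x$templates), x$n, x$seed, x$noise_sd,
              100 * x$outlier_fraction))
  invisible(x)
}

# substituent library: chains of atom tokens, '%d' = atom map slot;
# prefix rendering attaches via the last token, suffix via the first
SUBSTITUENTS <- list(
  methyl        = "[CH3:%d]",
  ethyl         = c("[CH3:%d]", "[CH2:%d]"),
  propyl        = c("[CH3:%d]", "[CH2:%d]", "[CH2:%d]"),
  butyl         = c("[CH3:%d]", "[CH2:%d]", "[CH2:%d]", "[CH2:%d]"),
  hydroxymethyl = c("[OH:%d]", "[CH2:%d]"),
  hydroxyethyl  = c("[OH:%d]", "[CH2:%d]", "[CH2:%d]"),
  phenyl        = "[cH:%d]7[cH:%d][cH:%d][cH:%d][cH:%d][c:%d]7",
  glycinyl      = c("[OH:%d]", "[C:%d](=[O:%d])", "[CH2:%d]", "[NH:%d]"),
  methylamino   = c("[CH3:%d]", "[NH:%d]")
)

render_substituent <- function(name, base_map, suffix = FALSE) {
  tokens <- SUBSTITUENTS[[name]]
  if (is.null(tokens)) stop("unknown substituent ", sQuote(name), call. = FALSE)
  rendered <- character(length(tokens))
  m <- base_map
  for (i in seq_along(tokens)) {
    k <- lengths(regmatches(tokens[i], gregexpr("%d", tokens[i], fixed = TRUE)))
    rendered[i] <- do.call(sprintf, c(list(tokens[i]), as.list(m + seq_len(k) - 1L)))
    m <- m + k
  }
  if (suffix) rendered <- rev(rendered)
  paste(rendered, collapse = "")
}

render_template <- function(template, choice) {
  smi <- template$smirks
  for (i in seq_along(template$slots)) {
    smi <- gsub(paste0("{", i, "}"),
                render_substituent(choice[[i]], 10L * i, suffix = FALSE),
                smi, fixed = TRUE)
    smi <- gsub(paste0("{", i, "s}"),
                render_substituent(choice[[i]], 10L * i, suffix = TRUE),
                smi, fixed = TRUE)
  }
  smi
}

#' Generate a synthetic reaction dataset
#'
#' Samples reactions by substituent substitution into the spec's templates,
#' samples conditions, and computes the property as a linear function of
#' selected fragment counts and condition descriptors plus Gaussian noise.
#' A seeded fraction of reactions receives an additional gross offset of
#' random sign (planted Y-outliers). Hidden per-reaction flags (template id,
#' planted-outlier flag) are attached as the `flags` attribute — a sidecar for
#' tests and audits, never an input to fitted models. The generating weights
#' are attached as the `truth` attribute.
#'
#' @param spec a [generator_spec()].
#' @param n,seed optional overrides of the spec values.
#' @param truth optional `truth` attribute of a previously generated dataset:
#'   reuse its property law (feature weights, condition weights, intercept) so
#'   that a companion test set follows the same model as its training set;
#'   fragments absent from the new reactions count as zero. The spec's own
#'   `cluster_shift` still applies, so a shifted suite generated under a
#'   training set's truth emulates a systematically mispredicted cluster.
#' @return dataset data frame (`id`, `reaction`, `property`, `solvent`,
#'   `temperature_K`, `molar_ratio`) with attributes `flags` and `truth`.
#' @examples
#' d <- generate_reactions(builtin_suites()$substitution, n = 5)
#' d$reaction[1]
#' @export
generate_reactions <- function(spec, n = NULL, seed = NULL, truth = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- as.integer(n %||% spec$n)
  seed <- as.integer(seed %||% spec$seed)
  set.seed(seed)
  tpl_id <- sample.int(length(spec$templates), n, replace = TRUE)
  reaction <- character(n)
  rarity <- numeric(n)
  for (i in seq_len(n)) {
    tp <- spec$templates[[tpl_id[i]]]
    p_row <- 1
    choice <- lapply(tp$slots, function(a) {
      pr <- spec$substituent_decay^(seq_along(a) - 1)
      pr <- pr / sum(pr)
      j <- sample.int(length(a), 1L, prob = pr)
      p_row <<- p_row * pr[j]
      a[j]
    })
    rarity[i] <- 1 / p_row
    reaction[i] <- render_template(tp, choice)
  }
  solvent <- sample(spec$solvents, n, replace = TRUE)
  temperature_K <- round(stats::runif(n, spec$temperature_range[1],
                                      spec$temperature_range[2]), 1)
  molar_ratio <- sample(spec$molar_ratio_pool, n, replace = TRUE)

  frs <- lapply(reaction, cached_fragments)
  vocab <- sort(unique(unlist(lapply(frs, names))))
  counts <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) counts[i, names(frs[[i]])] <- frs[[i]]
  inv_T <- 1 / temperature_K

  if (is.null(truth)) {
    # property features: high-variance fragment counts, kept only while they
    # increase the rank of the design (so the weights are identifiable)
    vars <- apply(counts, 2L, stats::var)
    cand <- colnames(counts)[order(-vars, colnames(counts))]
    cand <- cand[vars[cand] > 0]
    base <- cbind(1, inv_T, molar_ratio)
    feats <- character(0)
    for (f in cand) {
      if (length(feats) >= spec$n_features) break
      trial <- cbind(base, counts[, c(feats, f), drop = FALSE])
      if (qr(trial)$rank == ncol(trial)) feats <- c(feats, f)
    }
    w <- stats::rnorm(length(feats), 0, spec$weight_sd)
    names(w) <- feats
    intercept <- spec$intercept
    cond_w <- spec$cond_weights
    # interaction term: the first pair of selected features whose product is
    # identifiable next to the main effects; absent if no such pair exists
    int_pair <- NULL
    w_int <- 0
    if (spec$interaction_weight != 0 && length(feats) >= 2L) {
      sel <- cbind(base, counts[, feats, drop = FALSE])
      for (ij in utils::combn(seq_along(feats), 2L, simplify = FALSE)) {
        prod_col <- counts[, feats[ij[1]]] * counts[, feats[ij[2]]]
        if (qr(cbind(sel, prod_col))$rank == ncol(sel) + 1L) {
          int_pair <- feats[ij]
          w_int <- spec$interaction_weight
          break
        }
      }
    }
  } else {
    feats <- truth$features
    w <- truth$weights
    intercept <- truth$intercept
    cond_w <- truth$cond_weights
    w_int <- truth$interaction_weight
    int_pair <- truth$interaction_features
  }
  fcounts <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  hit <- match(feats, colnames(counts))
  ok <- !is.na(hit)
  fcounts[, ok] <- counts[, hit[ok], drop = FALSE]
  y0 <- intercept + as.numeric(fcounts %*% w) +
    cond_w[["inv_T"]] * inv_T +
    cond_w[["molar_ratio"]] * molar_ratio +
    spec$cluster_shift
  if (!is.null(int_pair) && w_int != 0)
    y0 <- y0 + w_int * fcounts[, int_pair[1]] * fcounts[, int_pair[2]]
  noise <- stats::rnorm(n, 0, spec$noise_sd)
  n_out <- round(spec$outlier_fraction * n)
  planted <- rep(FALSE, n)
  if (n_out > 0L) {
    idx <- sample.int(n, n_out, prob = rarity)
    planted[idx] <- TRUE
    y0[idx] <- y0[idx] + spec$outlier_offset * sample(c(-1, 1), n_out, replace = TRUE)
  }
  d <- data.frame(id = sprintf("%s_%04d", spec$name, seq_len(n)),
                  reaction = reaction, property = y0 + noise,
                  solvent = solvent, temperature_K = temperature_K,
                  molar_ratio = molar_ratio, stringsAsFactors = FALSE)
  attr(d, "flags") <- data.frame(id = d$id, type = spec$name,
                                 template = tpl_id, planted_outlier = planted,
                                 stringsAsFactors = FALSE)
  attr(d, "truth") <- list(features = feats, weights = w,
                           cond_weights = cond_w,
                           intercept = intercept,
                           interaction_weight = w_int,
                           interaction_features = int_pair,
                           cluster_shift = spec$cluster_shift,
                           noise_sd = spec$noise_sd, seed = seed)
  d
}

#' Built-in synthetic suites
#'
#' Named generator specs mirroring the study design: a bimolecular
#' substitution suite, an elimination suite (whose substituent alphabet
#' includes a glycine-like chain, so its CGRs contain the static amino-acid
#' fragments), a cycloaddition suite, a zwitterion-tautomer suite whose CGRs
#' have charge changes but no dynamic bonds, and a leaving-group-shift suite:
#' substitution-scaffold reactions carrying a structurally novel first-shell
#' substituent at the reaction centre plus a constant property shift,
#' emulating an external test cluster of native type that a structure-blind
#' model mispredicts.
#'
#' @return named list of [generator_spec()] objects
#'   (`substitution`, `elimination`, `cycloaddition`, `zwitterion`,
#'   `leaving_group_shift`).
#' @export
builtin_suites <- function() {
  subst_tpl <- list(
    smirks = "{1}[CH2:1][Cl:2].[O-:3]{2s}>>{1}[CH2:1][O:3]{2s}.[Cl-:2]",
    slots = list(c("methyl", "ethyl", "propyl", "butyl", "phenyl"),
                 c("methyl", "ethyl")))
  elim_tpl <- list(
    smirks = paste0("{1}[CH2:4][CH2:1][CH2:2][Br:3].[O-:5]{2s}>>",
                    "{1}[CH2:4][CH:1]=[CH2:2].[Br-:3].[OH:5]{2s}"),
    slots = list(c("methyl", "ethyl", "propyl", "glycinyl"),
                 c("methyl", "ethyl")))
  cyclo_tpl <- list(
    smirks = paste0("[CH2:1]=[CH:2][CH:3]=[CH2:4].{1}[CH:5]=[CH2:6]>>",
                    "[CH2:1]1[CH:2]=[CH:3][CH2:4][CH:5]({1s})[CH2:6]1"),
    slots = list(c("methyl", "ethyl", "propyl", "hydroxymethyl")))
  zwit_plain <- list(
    smirks = "[NH3+:1][CH2:2][C:3](=[O:4])[O-:5]>>[NH2:1][CH2:2][C:3](=[O:4])[OH:5]",
    slots = list())
  zwit_sub <- list(
    smirks = paste0("[NH3+:1][CH:2]({1s})[C:3](=[O:4])[O-:5]>>",
                    "[NH2:1][CH:2]({1s})[C:3](=[O:4])[OH:5]"),
    slots = list(c("methyl", "ethyl")))
  lgs_tpl <- list(
    smirks = "{1}[CH2:1][Cl:2].[O-:3]{2s}>>{1}[CH2:1][O:3]{2s}.[Cl-:2]",
    slots = list("methylamino", c("methyl", "ethyl")))
  list(
    substitution = generator_spec("substitution", list(subst_tpl), seed = 101L),
    elimination = generator_spec("elimination", list(elim_tpl), seed = 102L),
    cycloaddition = generator_spec("cycloaddition", list(cyclo_tpl), seed = 103L),
    zwitterion = generator_spec("zwitterion", list(zwit_plain, zwit_sub),
                                seed = 104L),
    leaving_group_shift = generator_spec("leaving_group_shift", list(lgs_tpl),
                                         seed = 105L, cluster_shift = 3,
                                         outlier_fraction = 0)
  )
}
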