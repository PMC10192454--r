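# Seeded simulator of sporophytic self-incompatibility crossing trials.
#
# The simulator produces datasets with the statistical structure the analysis
# modules assume: an S-locus under a strict dominance hierarchy (pollen
# phenotype determined by the pollen parent's diploid genotype), binomial pod
# set with a higher success probability for S-compatible crosses, pseudo-pod
# leakage concentrated in incompatible pollinations, and trait values with an
# additive + dominance architecture so that heterosis is recoverable from the
# output.

# Genotype-level trait means used when drawing additive values. Scales are
# anchored loosely on published kola self-cross tables (pod weight in g,
# lengths in cm, nut weights in g, outturn/brix/potential alcohol/firmness in
# their usual units). `outturn` and `weight_unpeeled` are primary; peeled nut
# weight is derived from them so that outturn stays an additive trait.
SIM_TRAIT_MEANS <- c(
  pod_weight = 150, pod_length = 20, pod_width = 7,
  nuts_per_pod = 6, nut_length = 4.5, nut_width = 3,
  weight_unpeeled = 60, outturn = 75,
  brix = 12, potential_alcohol = 7, firmness = 14
)

#' Simulation parameters for a crossing trial
#'
#' Defaults mirror the crossing design of kola compatibility trials: 20
#' pollinations per cross, replicated by 3 pollinators. Pod-set probabilities
#' default to 0.7 for S-compatible crosses (placing them mostly in
#' compatibility class 4, the class found predominant among hybrid crosses)
#' and 0.25 leakage for incompatible ones (the central tendency of printed
#' self-cross pod sets, emulating partial self-compatibility without S-allele
#' loss). Pseudo-pod probabilities are higher for incompatible crosses.
#'
#' @param n_genotypes number of genotypes in the simulated germplasm.
#' @param n_s_alleles number of S-alleles in the dominance hierarchy (>= 2).
#' @param p_compat per-flower pod probability for compatible crosses.
#' @param p_leak per-flower pod probability for incompatible crosses.
#' @param p_pseudo_incompat,p_pseudo_compat per-remaining-flower pseudo-pod
#'   probabilities (incompatible >= compatible).
#' @param dominance_gain proportional F1 dominance deviation, either a single
#'   number applied to all traits or a named vector by trait.
#' @param env_cv coefficient of variation of the per-pod multiplicative
#'   measurement noise on traits.
#' @param gen_cv coefficient of variation of genotype additive values around
#'   the trait means.
#' @param n_pollinated flowers pollinated per replicate.
#' @param n_replicates pollinator replicates per cross.
#' @param si_model \code{"dominance"} (strict hierarchy, default) or
#'   \code{"codominance"} (both alleles expressed in the phenotype).
#' @param seed integer seed for the whole trial.
#' @return a list of class \code{"sim_params"}.
#' @export
sim_params <- function(n_genotypes = 24, n_s_alleles = 6,
                       p_compat = 0.7, p_leak = 0.25,
                       p_pseudo_incompat = 0.15, p_pseudo_compat = 0.03,
                       dominance_gain = 0.2, env_cv = 0.1, gen_cv = 0.2,
                       n_pollinated = 20, n_replicates = 3,
                       si_model = c("dominance", "codominance"), seed = 1L) {
  si_model <- match.arg(si_model)
  probs <- c(p_compat = p_compat, p_leak = p_leak,
             p_pseudo_incompat = p_pseudo_incompat,
             p_pseudo_compat = p_pseudo_compat)
  if (any(probs < 0 | probs > 1)) {
    stop_kola("probabilities must lie in [0, 1]", class = "kola_param_error")
  }
  if (p_compat <= p_leak) {
    stop_kola("p_compat must exceed p_leak", class = "kola_param_error")
  }
  if (p_pseudo_incompat < p_pseudo_compat) {
    stop_kola("p_pseudo_incompat must be >= p_pseudo_compat",
              class = "kola_param_error")
  }
  if (n_pollinated < 1) {
    stop_kola("n_pollinated must be >= 1", class = "kola_param_error")
  }
  if (n_s_alleles < 2) {
    stop_kola("n_s_alleles must be >= 2 (no compatible crosses otherwise)",
              class = "kola_param_error")
  }
  gain <- dominance_gain
  if (is.null(names(gain))) {
    gain <- stats::setNames(rep(gain[1], length(SIM_TRAIT_MEANS)),
                            names(SIM_TRAIT_MEANS))
  } else {
    full <- stats::setNames(rep(0, length(SIM_TRAIT_MEANS)),
                            names(SIM_TRAIT_MEANS))
    full[names(gain)] <- gain
    gain <- full
  }
  structure(
    list(n_genotypes = as.integer(n_genotypes),
         n_s_alleles = as.integer(n_s_alleles),
         p_compat = p_compat, p_leak = p_leak,
         p_pseudo_incompat = p_pseudo_incompat,
         p_pseudo_compat = p_pseudo_compat,
         dominance_gain = gain, env_cv = env_cv, gen_cv = gen_cv,
         n_pollinated = as.integer(n_pollinated),
         n_replicates = as.integer(n_replicates),
         si_model = si_model, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' S-locus pollen/stigma phenotype
#'
#' Under sporophytic self-incompatibility the pollen's incompatibility
#' phenotype is determined by the diploid genotype of the pollen-producing
#' plant. With a strict dominance hierarchy (allele 1 most dominant) only the
#' more dominant allele of the pair is expressed; under codominance both are.
#'
#' @param alleles integer vector of length 2 (allele ranks; may be equal).
#' @param model \code{"dominance"} or \code{"codominance"}.
#' @return integer vector of expressed allele ranks.
#' @export
si_phenotype <- function(alleles, model = c("dominance", "codominance")) {
  model <- match.arg(model)
  stopifnot(length(alleles) == 2L, all(alleles >= 1))
  if (model == "dominance") min(alleles) else sort(unique(alleles))
}

#' Is a cross S-compatible?
#'
#' A pollination succeeds only when stigma and pollen phenotypes share no
#' S-specificity: the cross is compatible iff the expressed allele sets of the
#' two parents are disjoint. Any genotype selfed is therefore incompatible.
#'
#' @param stigma_alleles,pollen_alleles length-2 integer allele pairs of the
#'   seed (stigma) parent and the pollen parent.
#' @inheritParams si_phenotype
#' @return logical.
#' @export
is_cross_compatible <- function(stigma_alleles, pollen_alleles,
                                model = c("dominance", "codominance")) {
  model <- match.arg(model)
  !any(si_phenotype(stigma_alleles, model) %in%
         si_phenotype(pollen_alleles, model))
}

#' Draw a simulated germplasm
#'
#' Each genotype receives two S-alleles drawn uniformly (homozygosity allowed)
#' and an additive value per trait drawn around the package's trait means with
#' genotype-level coefficient of variation \code{gen_cv} (truncated below at
#' 10\% of the mean so weight and count traits stay positive). Deterministic
#' under the seed in \code{params}.
#'
#' @param params a [sim_params()] object.
#' @return data.frame of class \code{"sim_population"}: one row per genotype,
#'   columns \code{id}, \code{s1}, \code{s2}, and one column per trait.
#' @export
make_population <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(substream_seed(params$seed, "population"))
  n <- params$n_genotypes
  ids <- paste0("SIM/", seq_len(n))
  s <- matrix(sample.int(params$n_s_alleles, 2L * n, replace = TRUE),
              ncol = 2L)
  pop <- data.frame(id = ids, s1 = s[, 1], s2 = s[, 2],
                    stringsAsFactors = FALSE)
  for (trait in names(SIM_TRAIT_MEANS)) {
    m <- SIM_TRAIT_MEANS[[trait]]
    v <- m * (1 + params$gen_cv * stats::rnorm(n))
    pop[[trait]] <- pmax(v, 0.1 * m)
  }
  # keep additive outturn physically meaningful
  pop$outturn <- pmin(pop$outturn, 95)
  class(pop) <- c("sim_population", "data.frame")
  pop
}

#' Build a crossing design over a simulated germplasm
#'
#' Returns labels for all genotype self-crosses, plus random single crosses
#' and random double hybrid crosses (two disjoint F1 parent pairs). For each
#' double cross the two parental double-selfs are appended when
#' \code{parent_selfs} is \code{TRUE}, so that heterosis is computable from
#' the simulated dataset alone.
#'
#' @param pop a \code{sim_population}.
#' @param n_singles,n_doubles numbers of hybrid crosses to draw.
#' @param selfs include all genotype selfs (needed as single-cross parents).
#' @param parent_selfs include double-selfs of every F1 entity used.
#' @param seed integer seed for the design draw.
#' @return character vector of cross labels.
#' @export
make_crossing_design <- function(pop, n_singles = 20, n_doubles = 0,
                                 selfs = TRUE, parent_selfs = TRUE,
                                 seed = 1L) {
  set.seed(substream_seed(seed, "design"))
  ids <- pop$id
  design <- character(0)
  if (selfs) design <- paste(ids, ids, sep = " × ")
  if (n_singles > 0) {
    pairs <- unique(t(replicate(4L * n_singles, sample(ids, 2L))))
    pairs <- pairs[seq_len(min(n_singles, nrow(pairs))), , drop = FALSE]
    design <- c(design, paste(pairs[, 1], pairs[, 2], sep = " × "))
  }
  if (n_doubles > 0) {
    for (i in seq_len(n_doubles)) {
      quad <- sample(ids, 4L)
      lab <- paste(quad, collapse = " × ")
      design <- c(design, lab)
      if (parent_selfs) {
        f <- paste(quad[1:2], collapse = " × ")
        m <- paste(quad[3:4], collapse = " × ")
        design <- c(design, paste(f, f, sep = " × "), paste(m, m, sep = " × "))
      }
    }
  }
  design[!duplicated(vapply(design, cross_key, ""))]
}

# Resolve a cross entity (genotype or hybrid pair) against the population:
# its S-allele pair and additive trait values. F1 hybrid entities inherit one
# allele from each member (seeded draw keyed by the entity, so the same F1
# tree is identical wherever it appears) and a mid-parent additive value
# inflated by the dominance gain.
resolve_entity <- function(entity, pop, params) {
  keys <- canonical_id(pop$id)
  idx <- match(canonical_id(entity$members), keys)
  if (anyNA(idx)) {
    stop_kola("unknown genotype in design: ",
              paste(entity$members[is.na(idx)], collapse = ", "),
              class = "kola_lookup_error")
  }
  traits <- names(SIM_TRAIT_MEANS)
  if (entity$kind == "genotype") {
    row <- pop[idx, ]
    list(alleles = c(row$s1, row$s2),
         values = unlist(row[traits]))
  } else {
    set.seed(substream_seed(params$seed, "entity", canonical_entity(entity)))
    a <- pop[idx[1], ]
    b <- pop[idx[2], ]
    alleles <- c(sample(c(a$s1, a$s2), 1L), sample(c(b$s1, b$s2), 1L))
    mid <- (unlist(a[traits]) + unlist(b[traits])) / 2
    list(alleles = alleles,
         values = mid * (1 + params$dominance_gain[traits]))
  }
}

#' Simulate a controlled-pollination crossing trial
#'
#' For each cross and pollinator replicate, pods are drawn per flower with
#' probability \code{p_compat} (S-compatible cross) or \code{p_leak}
#' (incompatible, including every self); pseudo-pods are then drawn from the
#' remaining flowers with the corresponding pseudo-pod probability, and the
#' rest are recorded as dropped, so counts always conserve the flowers
#' pollinated. Per-flower uniforms are compared to the probability, which
#' makes pod counts monotone in the probability under a fixed seed.
#'
#' Trait expectations are mid-parent values inflated by
#' \code{1 + dominance_gain} for compatible non-self crosses; the recorded
#' per-cross trait value is the mean of per-pod measurements over all pods
#' harvested across replicates, each with unit-mean lognormal noise of
#' coefficient of variation \code{env_cv}. Crosses that set no pods get
#' missing trait values. Randomness is keyed by (seed, cross, replicate), so
#' extending a design never perturbs existing crosses.
#'
#' @param pop a \code{sim_population} from [make_population()].
#' @param design character vector of cross labels (see
#'   [make_crossing_design()]).
#' @param params a [sim_params()] object.
#' @return object of class \code{"kola_sim"}: list with \code{dataset} (a
#'   [kola_dataset()]), \code{truth} (per-cross compatibility flags, expected
#'   trait values and success probabilities) and \code{params}.
#' @export
simulate_crossing_trial <- function(pop, design, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  specs <- lapply(design, parse_cross_label)
  labels <- vapply(specs, format, "")
  traits <- names(SIM_TRAIT_MEANS)

  poll <- list()
  trait_rows <- list()
  truth_rows <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    lab <- labels[[i]]
    type <- classify_cross_type(spec)
    fem <- resolve_entity(spec$female, pop, params)
    mal <- resolve_entity(spec$male, pop, params)
    is_self <- type %in% c("SCS", "DCS")
    compat <- is_cross_compatible(fem$alleles, mal$alleles, params$si_model)
    p_pod <- if (compat) params$p_compat else params$p_leak
    p_pseudo <- if (compat) params$p_pseudo_compat else params$p_pseudo_incompat

    pods_by_rep <- integer(params$n_replicates)
    for (r in seq_len(params$n_replicates)) {
      set.seed(substream_seed(params$seed, "cross", cross_key(spec), r))
      u_pod <- stats::runif(params$n_pollinated)
      n_pod <- sum(u_pod < p_pod)
      u_pseudo <- stats::runif(params$n_pollinated)
      rem <- params$n_pollinated - n_pod
      n_pseudo <- sum(u_pseudo[seq_len(rem)] < p_pseudo)
      pods_by_rep[r] <- n_pod
      poll[[length(poll) + 1L]] <- data.frame(
        cross_label = lab, replicate = r,
        n_pollinated = params$n_pollinated, n_pod = n_pod,
        n_pseudo = n_pseudo, n_dropped = rem - n_pseudo,
        stringsAsFactors = FALSE
      )
    }

    mid <- (fem$values + mal$values) / 2
    mult <- if (compat && !is_self) 1 + params$dominance_gain[traits] else
      rep(1, length(traits))
    expected <- mid * mult
    expected["outturn"] <- min(expected[["outturn"]], 100)

    total_pods <- sum(pods_by_rep)
    set.seed(substream_seed(params$seed, "traits", cross_key(spec)))
    observed <- rep(NA_real_, length(traits))
    names(observed) <- traits
    if (total_pods > 0) {
      s2 <- log(1 + params$env_cv^2)
      for (t in traits) {
        noise <- mean(stats::rlnorm(total_pods, -s2 / 2, sqrt(s2)))
        observed[[t]] <- expected[[t]] * noise
      }
      observed[["outturn"]] <- min(observed[["outturn"]], 100)
    }
    tr <- as.data.frame(as.list(observed), stringsAsFactors = FALSE)
    tr <- cbind(data.frame(cross_label = lab, stringsAsFactors = FALSE), tr)
    tr$number_of_pods <- total_pods
    tr$weight_peeled <- tr$weight_unpeeled * tr$outturn / 100
    trait_rows[[length(trait_rows) + 1L]] <- tr

    truth <- data.frame(cross_label = lab, cross_type = type,
                        is_self = is_self, compatible = compat,
                        p_pod = p_pod, p_pseudo = p_pseudo,
                        stringsAsFactors = FALSE)
    for (t in traits) truth[[paste0("expected_", t)]] <- expected[[t]]
    truth_rows[[length(truth_rows) + 1L]] <- truth
  }

  pollinations <- do.call(rbind, poll)
  trait_df <- do.call(rbind, trait_rows)
  trait_df <- trait_df[, c("cross_label", "number_of_pods",
                           setdiff(names(trait_df),
                                   c("cross_label", "number_of_pods")))]
  dataset <- kola_dataset(
    pollinations = validate_cross_table(pollinations, "pollination",
                                        source = "<simulated>"),
    traits = validate_cross_table(trait_df, "trait", source = "<simulated>"),
    metadata = list(genebank = "SIM", simulated = TRUE, seed = params$seed)
  )
  structure(
    list(dataset = dataset, truth = do.call(rbind, truth_rows),
         params = params),
    class = "kola_sim"
  )
}

#' @export
print.kola_sim <- function(x, ...) {
  cat("<kola_sim> simulated crossing trial, seed ", x$params$seed, "\n",
      sep = "")
  tab <- table(x$truth$cross_type)
  cat("  crosses: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  compatible: ", sum(x$truth$compatible), " / ", nrow(x$truth), "\n",
      sep = "")
  invisible(x)
}
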