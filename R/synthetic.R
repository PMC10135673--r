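# Synthetic survey generator with known ground truth.
#
# Emulates a dry-season lowland river survey: ~80-88 sites spanning
# gradients of flow velocity (m/s), turbidity (NTU) and elevation
# (m a.s.l.), a family-level taxa pool with fuzzy-coded trait affinities,
# and per-trait counts drawn from negative-binomial models whose log
# means are flat, linear, quadratic or broken-linear in one predictor.
# Ground truth lives on the trait scale of one "generative" grouping
# feature (where the response models operate); taxa counts are obtained
# by disaggregating trait counts over the pool so that re-running the
# allocation stage recovers the generated trait counts exactly.

# inverse-CDF samplers for range-bounded predictors
r_truncnorm <- function(n, mean, sd, min, max) {
  pl <- stats::pnorm(min, mean, sd); pu <- stats::pnorm(max, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}
r_trunclnorm <- function(n, meanlog, sdlog, min, max) {
  pl <- stats::plnorm(min, meanlog, sdlog); pu <- stats::plnorm(max, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, pl, pu), meanlog, sdlog)
}

#' Define a synthetic survey scenario
#'
#' A scenario bundles everything needed to generate a survey: number of
#' sites, environmental sampling distributions (range-bounded), the taxa
#' pool with its fuzzy affinity table, and the true response model of
#' every trait in the generative grouping feature.  [survey_scenario()]
#' returns the bundled survey-scale default.
#'
#' @param n_sites number of sites (>= 20).
#' @param n_incomplete number of sites whose environmental record is made
#'   incomplete (one predictor set missing), emulating field gaps.
#' @param env named list of predictor specs; each is a list with `dist`
#'   (`"truncnorm"` or `"trunclnorm"`), its parameters, and `min` < `max`.
#' @param affinity a [trait_affinity()] table for the taxa pool.
#' @param responses named list (one per generative trait) of true response
#'   models: list with `predictor`, `form` (`"flat"`, `"linear"`,
#'   `"quadratic"`, `"broken"`), coefficients `a`, `b1`, `b2` (quadratic
#'   coefficient or difference-in-slopes), `psi` (broken only) and
#'   dispersion `k > 0`. Coefficients act on the predictor's original
#'   scale.
#' @param generative_feature grouping feature whose traits carry the
#'   ground truth.
#' @param mixed_fraction share of each trait count routed through
#'   mixed-affinity taxa before pure carriers absorb the remainder.
#' @return object of class `"eco_scenario"`.
#' @export
synthetic_scenario <- function(n_sites, env, affinity, responses,
                               generative_feature, n_incomplete = 0,
                               mixed_fraction = 0.25) {
  if (n_sites < 20) abort("scenarios need n_sites >= 20")
  if (n_incomplete < 0 || n_incomplete >= n_sites)
    abort("`n_incomplete` must be in [0, n_sites)")
  for (v in names(env)) {
    e <- env[[v]]
    if (is.null(e$min) || is.null(e$max) || e$min >= e$max)
      abort("environmental range for '%s' needs min < max", v)
  }
  stopifnot(inherits(affinity, "trait_affinity"))
  gen_traits <- colnames(affinity$scores)[affinity$feature == generative_feature]
  if (!length(gen_traits)) abort("generative feature '%s' has no traits", generative_feature)
  for (tr in names(responses)) {
    r <- responses[[tr]]
    if (!tr %in% gen_traits)
      abort("response spec for '%s' is outside the generative feature", tr)
    if (!r$predictor %in% names(env))
      abort("response '%s' uses unknown predictor '%s'", tr, r$predictor)
    if (is.null(r$k) || r$k <= 0) abort("dispersion k must be > 0 for '%s'", tr)
    if (identical(r$form, "broken")) {
      e <- env[[r$predictor]]
      if (is.null(r$psi) || r$psi <= e$min || r$psi >= e$max)
        abort("breakpoint for '%s' must lie strictly inside the %s range",
              tr, r$predictor)
    }
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_incomplete = as.integer(n_incomplete),
                 env = env, affinity = affinity, responses = responses,
                 generative_feature = generative_feature,
                 mixed_fraction = mixed_fraction),
            class = "eco_scenario")
}

#' @export
print.eco_scenario <- function(x, ...) {
  cat(sprintf("Synthetic survey scenario: %d sites (%d incomplete), %d taxa, %d traits\n",
              x$n_sites, x$n_incomplete, nrow(x$affinity$scores),
              ncol(x$affinity$scores)))
  cat(sprintf("  generative feature: %s (%d modelled traits)\n",
              x$generative_feature, length(x$responses)))
  invisible(x)
}

# Deterministic affinity pattern for the non-generative grouping features:
# taxon i gets a primary affinity 4 and (for even i) a secondary 2.
default_pool_affinity <- function() {
  cat_ <- trait_catalogue()
  taxa <- c(
    # pure feeding carriers
    Chironomidae = "deposit_feeder", Simuliidae = "filter_feeder",
    Ancylidae = "scraper", Tipulidae = "shredder",
    Libellulidae = "predator", Corixidae = "piercer",
    Glossiphoniidae = "parasite", Naididae = "absorber",
    # mixed feeders
    Baetidae = NA, Hydropsychidae = NA, Caenidae = NA, Leptophlebiidae = NA,
    Elmidae = NA, Physidae = NA, Leptohyphidae = NA, Hydroptilidae = NA,
    Philopotamidae = NA, Ceratopogonidae = NA, Psephenidae = NA,
    Dytiscidae = NA, Gyrinidae = NA, Hydrophilidae = NA, Naucoridae = NA,
    Veliidae = NA, Gerridae = NA, Gomphidae = NA, Coenagrionidae = NA,
    Calopterygidae = NA, Planorbidae = NA, Palaemonidae = NA)
  traits <- unlist(cat_, use.names = FALSE)
  feature <- rep(names(cat_), lengths(cat_))
  scores <- matrix(0L, length(taxa), length(traits),
                   dimnames = list(names(taxa), traits))
  feats <- names(cat_)
  coded <- matrix(TRUE, length(taxa), length(feats),
                  dimnames = list(names(taxa), feats))

  # feeding: pure carriers score 5 on their trait
  for (i in seq_along(taxa)) if (!is.na(taxa[i])) scores[i, taxa[i]] <- 5L
  # mixed feeders: fixed two-trait fuzzy codes (Baetidae is the canonical
  # deposit feeder 1 / scraper 3 example)
  mixed <- list(
    Baetidae = c(deposit_feeder = 1, scraper = 3),
    Hydropsychidae = c(filter_feeder = 4, predator = 1),
    Caenidae = c(deposit_feeder = 3, scraper = 1),
    Leptophlebiidae = c(deposit_feeder = 2, scraper = 2),
    Elmidae = c(scraper = 3, shredder = 1),
    Physidae = c(scraper = 3, deposit_feeder = 1),
    Leptohyphidae = c(deposit_feeder = 4, scraper = 1),
    Hydroptilidae = c(piercer = 3, scraper = 1),
    Philopotamidae = c(filter_feeder = 5),
    Ceratopogonidae = c(predator = 3, deposit_feeder = 1),
    Psephenidae = c(scraper = 5),
    Dytiscidae = c(predator = 5),
    Gyrinidae = c(predator = 4, shredder = 1),
    Hydrophilidae = c(shredder = 2, predator = 2),
    Naucoridae = c(predator = 5),
    Veliidae = c(predator = 5),
    Gerridae = c(predator = 5),
    Gomphidae = c(predator = 5),
    Coenagrionidae = c(predator = 5),
    Calopterygidae = c(predator = 5),
    Planorbidae = c(scraper = 4, deposit_feeder = 1))
  for (tx in names(mixed)) scores[tx, names(mixed[[tx]])] <- as.integer(mixed[[tx]])
  # one taxon with no fuzzy information for feeding: equal coding over the
  # two traits it is recorded to possess
  scores["Palaemonidae", c("shredder", "predator")] <- 1L
  coded["Palaemonidae", "feeding"] <- FALSE

  # remaining grouping features: deterministic rotation so every taxon is
  # fully coded and traits differ in prevalence
  for (fi in seq_along(feats)[-1]) {
    tr <- cat_[[fi]]
    for (i in seq_along(taxa)) {
      primary <- tr[1 + (i * 3 + fi) %% length(tr)]
      scores[i, primary] <- 4L
      if (i %% 2 == 0) {
        secondary <- tr[1 + (i + 2 * fi) %% length(tr)]
        if (secondary != primary) scores[i, secondary] <- 2L
      }
    }
  }
  trait_affinity(scores, feature, coded)
}

#' The bundled survey-scale scenario
#'
#' The default synthetic scenario at the scale of a dry-season river-basin
#' survey: 88 sites of which 8 have an incomplete environmental record
#' (80 analysable), a 30-family taxa pool over the full
#' [trait_catalogue()], velocity ~ truncated Normal(0.3, 0.29) on
#' [0, 1.5] m/s, turbidity ~ truncated LogNormal(log 2, 1.2) on
#' [0.02, 34.7] NTU (median well below the mean), elevation ~ truncated
#' LogNormal(log 86, 1.15) on [2, 1075] m a.s.l.  Feeding-style traits
#' carry the ground truth (dispersion k = 2 throughout); the scraper
#' responds to turbidity through a broken-linear log mean rising at 0.35
#' per NTU up to a tipping point at 5 NTU and falling at 0.10 per NTU
#' beyond it.
#'
#' @param n_sites,n_incomplete override the survey size (default 88 / 8).
#' @return an `"eco_scenario"`.
#' @export
survey_scenario <- function(n_sites = 88, n_incomplete = 8) {
  env <- list(
    velocity  = list(dist = "truncnorm", mean = 0.3, sd = 0.29, min = 0, max = 1.5),
    turbidity = list(dist = "trunclnorm", meanlog = log(2), sdlog = 1.2,
                     min = 0.02, max = 34.7),
    elevation = list(dist = "trunclnorm", meanlog = log(86), sdlog = 1.15,
                     min = 2, max = 1075))
  responses <- list(
    scraper        = list(predictor = "turbidity", form = "broken",
                          a = 2.0, b1 = 0.35, b2 = -0.45, psi = 5, k = 2),
    deposit_feeder = list(predictor = "turbidity", form = "linear",
                          a = 2.2, b1 = -0.08, k = 2),
    filter_feeder  = list(predictor = "velocity", form = "linear",
                          a = 1.2, b1 = 1.6, k = 2),
    predator       = list(predictor = "velocity", form = "linear",
                          a = 2.0, b1 = 0.8, k = 2),
    shredder       = list(predictor = "elevation", form = "quadratic",
                          a = 1.0, b1 = 6.0e-3, b2 = -5.5e-6, k = 2),
    piercer        = list(predictor = "turbidity", form = "flat", a = 1.0, k = 2),
    parasite       = list(predictor = "elevation", form = "flat", a = 0.6, k = 2),
    absorber       = list(predictor = "velocity", form = "flat", a = -1.2, k = 2))
  synthetic_scenario(n_sites = n_sites, n_incomplete = n_incomplete,
                     env = env, affinity = default_pool_affinity(),
                     responses = responses, generative_feature = "feeding",
                     mixed_fraction = 0.25)
}

#' Generate the environmental table of a scenario
#'
#' @param scenario an `"eco_scenario"`.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with `site_id` and one column per predictor, all
#'   values inside the configured ranges; complete (missingness is applied
#'   later by [simulate_survey()]).
#' @export
gen_environment <- function(scenario, seed) {
  stopifnot(inherits(scenario, "eco_scenario"))
  with_seed(seed, {
    n <- scenario$n_sites
    out <- data.frame(site_id = sprintf("S%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (v in names(scenario$env)) {
      e <- scenario$env[[v]]
      out[[v]] <- switch(e$dist,
        truncnorm  = r_truncnorm(n, e$mean, e$sd, e$min, e$max),
        trunclnorm = r_trunclnorm(n, e$meanlog, e$sdlog, e$min, e$max),
        abort("unknown distribution '%s' for predictor '%s'", e$dist, v))
    }
    out
  })
}

# true mean on the response scale for one trait spec
true_mean <- function(spec, x) {
  eta <- switch(spec$form,
    flat      = rep(spec$a, length(x)),
    linear    = spec$a + spec$b1 * x,
    quadratic = spec$a + spec$b1 * x + spec$b2 * x^2,
    broken    = piecewise_predict(spec$a, spec$b1, spec$b2, spec$psi, x),
    abort("unknown response form '%s'", spec$form))
  exp(eta)
}

#' Generate trait-level counts from the true response models
#'
#' Draws, for every modelled trait, site counts from a negative-binomial
#' distribution with mean `exp(linear predictor)` and variance
#' `mu + mu^2/k` evaluated on the generated environment.
#'
#' @param env environmental table from [gen_environment()].
#' @param scenario the `"eco_scenario"` holding the response specs.
#' @param seed integer seed.
#' @return integer matrix (sites x modelled traits) with the ground truth
#'   attached as attribute `"truth"`.
#' @export
gen_trait_counts <- function(env, scenario, seed) {
  stopifnot(inherits(scenario, "eco_scenario"))
  with_seed(seed, {
    traits <- names(scenario$responses)
    out <- matrix(0L, nrow(env), length(traits),
                  dimnames = list(env$site_id, traits))
    for (tr in traits) {
      spec <- scenario$responses[[tr]]
      mu <- true_mean(spec, env[[spec$predictor]])
      bad <- which(!is.finite(mu))
      if (length(bad))
        abort("non-finite mean for trait '%s' at site %s", tr, env$site_id[bad[1]])
      out[, tr] <- as.integer(stats::rnbinom(nrow(env), size = spec$k, mu = mu))
    }
    attr(out, "truth") <- scenario$responses
    out
  })
}

#' Disaggregate trait counts into a taxa count table
#'
#' Inverse of the allocation stage: distributes each site's trait counts
#' (generative grouping feature) over the taxa pool.  A seeded share of
#' each trait's count is routed through mixed-affinity taxa (their whole
#' coefficient vector is honoured), and each trait's pure carrier (a taxon
#' whose generative-feature coefficient for that trait is 1) absorbs the
#' exact remainder.  Because mixed shares are rounded with the same rule
#' the allocation stage uses, re-running [build_trait_abundance_matrix()]
#' on the output reproduces `trait_counts` exactly on the generative
#' traits.
#'
#' @param trait_counts matrix from [gen_trait_counts()] (sites x traits).
#' @param affinity the pool's [trait_affinity()] table.
#' @param seed integer seed.
#' @param generative_feature grouping feature the trait columns belong to.
#' @param mixed_fraction target share routed through mixed taxa.
#' @return data.frame (`site_id`, `taxon`, `count`) with zero-count rows
#'   dropped.
#' @export
gen_taxa_from_traits <- function(trait_counts, affinity, seed,
                                 generative_feature = "feeding",
                                 mixed_fraction = 0.25) {
  stopifnot(inherits(affinity, "trait_affinity"))
  traits <- colnames(trait_counts)
  idx <- which(affinity$feature == generative_feature)
  co <- coefficient_matrix(affinity)[, idx, drop = FALSE]
  missing <- setdiff(traits, colnames(co))
  if (length(missing))
    abort("affinity table lacks generative traits: %s", paste(missing, collapse = ", "))
  co <- co[, traits, drop = FALSE]
  pure <- apply(co, 2, function(cc) {
    j <- which(cc == 1)
    if (length(j)) j[1] else NA_integer_
  })
  no_carrier <- traits[is.na(pure) & colSums(trait_counts) > 0]
  if (length(no_carrier))
    abort("no pure carrier taxon for trait(s): %s", paste(no_carrier, collapse = ", "))
  mixed_taxa <- which(apply(co, 1, function(cc) any(cc > 0 & cc < 1)))

  with_seed(seed, {
    recs <- vector("list", nrow(trait_counts))
    for (s in seq_len(nrow(trait_counts))) {
      g <- stats::setNames(as.integer(trait_counts[s, ]), traits)
      counts <- stats::setNames(rep(0L, nrow(co)), rownames(co))
      for (j in mixed_taxa) {
        cc <- co[j, ]
        carried <- cc > 0
        cap <- suppressWarnings(min(g[carried] / cc[carried]))
        if (!is.finite(cap) || cap < 1) next
        m <- floor(cap * mixed_fraction * stats::runif(1, 0.5, 1))
        if (m < 1) next
        alloc <- round_half_away(m * cc)
        if (any(alloc > g)) next
        counts[j] <- counts[j] + as.integer(m)
        g <- g - alloc
      }
      for (tr in traits[g > 0]) counts[pure[tr]] <- counts[pure[tr]] + as.integer(g[tr])
      keep <- counts > 0
      if (any(keep))
        recs[[s]] <- data.frame(site_id = rownames(trait_counts)[s],
                                taxon = names(counts)[keep],
                                count = unname(counts[keep]),
                                stringsAsFactors = FALSE)
    }
    recs <- recs[!vapply(recs, is.null, TRUE)]
    if (!length(recs))
      return(data.frame(site_id = character(), taxon = character(),
                        count = integer(), stringsAsFactors = FALSE))
    do.call(rbind, c(recs, list(make.row.names = FALSE)))
  })
}

#' Simulate a complete survey from a scenario
#'
#' Runs [gen_environment()], [gen_trait_counts()] and
#' [gen_taxa_from_traits()] with seeds derived from `seed`, then masks
#' `n_incomplete` environmental records (one predictor each, rotating) to
#' emulate field gaps.  Counts are generated from the complete
#' environment; only the reported environmental table carries the gaps.
#'
#' @param scenario an `"eco_scenario"`.
#' @param seed integer seed controlling every stage.
#' @return list with `env` (with missing values where masked), `taxa`,
#'   `trait_counts` (generated ground-truth counts), `affinity` and
#'   `truth` (the scenario's response specs).
#' @export
simulate_survey <- function(scenario, seed) {
  stopifnot(inherits(scenario, "eco_scenario"))
  env <- gen_environment(scenario, seed)
  counts <- gen_trait_counts(env, scenario, seed + 1L)
  taxa <- gen_taxa_from_traits(counts, scenario$affinity, seed + 2L,
                               generative_feature = scenario$generative_feature,
                               mixed_fraction = scenario$mixed_fraction)
  if (scenario$n_incomplete > 0) {
    miss <- with_seed(seed + 3L,
                      sample(scenario$n_sites, scenario$n_incomplete))
    vars <- setdiff(names(env), "site_id")
    for (i in seq_along(miss))
      env[miss[i], vars[1 + (i - 1) %% length(vars)]] <- NA_real_
  }
  list(env = env, taxa = taxa, trait_counts = counts,
       affinity = scenario$affinity, truth = scenario$responses)
}

#' Write / read a scenario configuration
#'
#' Scenarios serialize to a human-readable JSON configuration and
#' round-trip losslessly.
#'
#' @param scenario an `"eco_scenario"`.
#' @param path file path.
#' @return `read_scenario()` returns the reconstructed `"eco_scenario"`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "eco_scenario"))
  aff <- scenario$affinity
  cfg <- list(
    n_sites = scenario$n_sites, n_incomplete = scenario$n_incomplete,
    env = scenario$env, responses = scenario$responses,
    generative_feature = scenario$generative_feature,
    mixed_fraction = scenario$mixed_fraction,
    affinity = list(taxa = rownames(aff$scores), traits = colnames(aff$scores),
                    feature = aff$feature,
                    scores = unname(apply(aff$scores, 1, as.integer, simplify = FALSE)),
                    coded_features = colnames(aff$coded),
                    coded = unname(apply(aff$coded, 1, as.logical, simplify = FALSE))))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, mode) {
    if (is.list(x)) x <- do.call(rbind, x)
    storage.mode(x) <- mode
    x
  }
  scores <- as_mat(cfg$affinity$scores, "integer")
  dimnames(scores) <- list(cfg$affinity$taxa, cfg$affinity$traits)
  coded <- as_mat(cfg$affinity$coded, "logical")
  dimnames(coded) <- list(cfg$affinity$taxa, cfg$affinity$coded_features)
  aff <- trait_affinity(scores, cfg$affinity$feature, coded)
  responses <- lapply(cfg$responses, as.list)
  synthetic_scenario(n_sites = cfg$n_sites, n_incomplete = cfg$n_incomplete,
                     env = lapply(cfg$env, as.list), affinity = aff,
                     responses = responses,
                     generative_feature = cfg$generative_feature,
                     mixed_fraction = cfg$mixed_fraction)
}
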