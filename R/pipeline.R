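# End-to-end orchestration: validate -> complete-case filter -> allocate
# -> diversity -> response curves -> tipping points, with CSV inputs and
# outputs and a reproducibility manifest.

#' Read pipeline input tables
#'
#' CSV dialects: UTF-8, comma-delimited, header row, `site_id` as join
#' key.  Taxa counts: columns `site_id`, `taxon`, `count`.  Environment:
#' `site_id` plus one numeric column per predictor.  Affinity: one row
#' per taxon (column `taxon`), one column per trait named
#' `"<feature>::<trait>"` with integer scores 0-5; an all-blank block for
#' a grouping feature marks the taxon uncoded for it, in which case a
#' column `"<feature>::possessed"` may list the possessed traits
#' (`;`-separated) that receive the equal-coding fallback.
#'
#' @param path CSV file path.
#' @return `read_taxa_csv()` / `read_env_csv()`: a data.frame;
#'   `read_affinity_csv()`: a [trait_affinity()] object.
#' @export
read_taxa_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "taxon", "count") %in% names(d)))
    abort("taxa CSV must have columns site_id, taxon, count")
  d
}

#' @rdname read_taxa_csv
#' @export
read_env_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(d)) abort("environment CSV must have a site_id column")
  d
}

#' @rdname read_taxa_csv
#' @export
read_affinity_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"taxon" %in% names(d)) abort("affinity CSV must have a taxon column")
  cols <- setdiff(names(d), "taxon")
  parts <- strsplit(cols, "::", fixed = TRUE)
  if (any(lengths(parts) != 2))
    abort("affinity columns must be named <feature>::<trait>")
  feature_all <- vapply(parts, `[[`, "", 1)
  trait_all <- vapply(parts, `[[`, "", 2)
  poss <- trait_all == "possessed"
  score_cols <- cols[!poss]
  feature <- feature_all[!poss]
  trait <- trait_all[!poss]
  scores <- matrix(0L, nrow(d), length(score_cols),
                   dimnames = list(d$taxon, trait))
  feats <- unique(feature)
  coded <- matrix(TRUE, nrow(d), length(feats), dimnames = list(d$taxon, feats))
  for (j in seq_along(score_cols)) scores[, j] <- suppressWarnings(as.integer(d[[score_cols[j]]]))
  for (f in feats) {
    block <- which(feature == f)
    blank <- rowSums(!is.na(scores[, block, drop = FALSE])) == 0
    coded[blank, f] <- FALSE
    sc <- scores[, block, drop = FALSE]; sc[is.na(sc)] <- 0L
    scores[, block] <- sc
    pcol <- paste0(f, "::possessed")
    if (pcol %in% cols) {
      for (i in which(blank)) {
        tr <- trimws(strsplit(d[[pcol]][i], ";")[[1]])
        tr <- tr[nzchar(tr)]
        unknown <- setdiff(tr, trait[block])
        if (length(unknown))
          abort("taxon '%s': possessed trait(s) not in feature '%s': %s",
                d$taxon[i], f, paste(unknown, collapse = ", "))
        scores[i, tr] <- 1L
      }
    }
  }
  trait_affinity(scores, feature, coded)
}

#' Write a trait-affinity table as CSV
#'
#' Inverse of [read_affinity_csv()].
#' @param affinity a [trait_affinity()] object.
#' @param path CSV file path.
#' @export
write_affinity_csv <- function(affinity, path) {
  stopifnot(inherits(affinity, "trait_affinity"))
  d <- data.frame(taxon = rownames(affinity$scores), stringsAsFactors = FALSE,
                  check.names = FALSE)
  for (j in seq_len(ncol(affinity$scores))) {
    f <- affinity$feature[j]
    col <- ifelse(affinity$coded[, f], affinity$scores[, j], NA_integer_)
    d[[paste0(f, "::", colnames(affinity$scores)[j])]] <- col
  }
  for (f in unique(affinity$feature)) {
    if (all(affinity$coded[, f])) next
    idx <- which(affinity$feature == f)
    d[[paste0(f, "::possessed")]] <- vapply(seq_len(nrow(affinity$scores)),
      function(i) {
        if (affinity$coded[i, f]) return("")
        paste(colnames(affinity$scores)[idx][affinity$scores[i, idx] > 0],
              collapse = ";")
      }, "")
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Complete-case filtering of survey sites
#'
#' Removes every site with a missing value in any environmental predictor
#' from both the environmental and the taxa table (listwise deletion),
#' and reports what was removed.  Sites present in the environment but
#' absent from the taxa table are retained (they become all-zero rows at
#' allocation) and noted in the report.
#'
#' @param env environmental data.frame with `site_id`.
#' @param taxa taxa count data.frame with `site_id`.
#' @return list with filtered `env` and `taxa` plus `report`
#'   (data.frame: `site_id`, `reason`).
#' @export
filter_complete_cases <- function(env, taxa) {
  vars <- setdiff(names(env), "site_id")
  incomplete <- env$site_id[rowSums(is.na(env[vars])) > 0]
  report <- data.frame(site_id = character(), reason = character(),
                       stringsAsFactors = FALSE)
  if (length(incomplete))
    report <- rbind(report, data.frame(
      site_id = incomplete,
      reason = "missing environmental value; removed (listwise deletion)",
      stringsAsFactors = FALSE))
  env_f <- env[!env$site_id %in% incomplete, , drop = FALSE]
  taxa_f <- taxa[!taxa$site_id %in% incomplete, , drop = FALSE]
  if (nrow(env_f) == 0) abort("no complete sites remain after filtering")
  no_taxa <- setdiff(env_f$site_id, unique(taxa_f$site_id))
  if (length(no_taxa))
    report <- rbind(report, data.frame(
      site_id = no_taxa,
      reason = "no taxa records; retained with zero abundances",
      stringsAsFactors = FALSE))
  list(env = env_f, taxa = taxa_f, report = report)
}

#' Run the full trait-based analysis pipeline
#'
#' Executes, in order: input validation, complete-case filtering, trait
#' allocation, sparsity filtering, diversity indices, backward-selected
#' response curves (negative-binomial per retained trait, Gaussian per
#' diversity metric, against every predictor), and tipping-point
#' detection.  Every stage writes a CSV under `out_dir`; a manifest
#' records inputs, configuration, seed and stage checksums so that
#' identical configuration reproduces identical outputs.
#'
#' @param taxa taxa counts (data.frame or CSV path).
#' @param affinity [trait_affinity()] object or affinity CSV path.
#' @param env environmental table (data.frame or CSV path).
#' @param out_dir output directory (created if needed).
#' @param alpha significance level for model selection and existence
#'   tests (default 0.05).
#' @param max_zero_fraction sparsity threshold for
#'   [filter_sparse_traits()].
#' @param exclude explicit trait exclusion list (optional).
#' @param predictors predictor columns to model (default: all numeric
#'   columns of `env`).
#' @param traits trait subset to model (default: all retained traits).
#' @param K candidate breakpoints for existence tests.
#' @param run_tipping set `FALSE` to stop after the response-curve stage.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return invisibly, the run manifest (list); side effect: CSVs and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(taxa, affinity, env, out_dir,
                         alpha = 0.05, max_zero_fraction = 0.9,
                         exclude = NULL, predictors = NULL, traits = NULL,
                         K = 10, run_tipping = TRUE, seed = 1L) {
  if (is.character(taxa)) taxa <- read_taxa_csv(taxa)
  if (is.character(affinity)) affinity <- read_affinity_csv(affinity)
  if (is.character(env)) env <- read_env_csv(env)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }

  ## stage 1: complete cases
  fc <- filter_complete_cases(env, taxa)
  emit(fc$report, "removed_sites.csv")
  n_sites <- nrow(fc$env)

  ## stage 2: allocation
  mat <- build_trait_abundance_matrix(fc$taxa, affinity, sites = fc$env$site_id)
  mat <- mat[fc$env$site_id, , drop = FALSE]
  class(mat) <- c("trait_abundance", "matrix", "array")
  attr(mat, "feature") <- stats::setNames(affinity$feature, colnames(mat))
  attr(mat, "excluded") <- stats::setNames(rep(FALSE, ncol(mat)), colnames(mat))
  emit(data.frame(site_id = rownames(mat), as.data.frame(unclass(mat)),
                  check.names = FALSE), "trait_abundance.csv")

  ## stage 3: sparsity filter
  mat <- filter_sparse_traits(mat, max_zero_fraction, exclude)
  emit(data.frame(trait = colnames(mat),
                  zero_fraction = colMeans(mat == 0),
                  excluded = attr(mat, "excluded")), "trait_exclusions.csv")

  ## stage 4: diversity (uses all traits; sparsity filter applies to models)
  div <- trait_diversity(mat)
  emit(div, "diversity.csv")

  ## stage 5: response curves
  if (is.null(predictors))
    predictors <- names(env)[vapply(env, is.numeric, TRUE)]
  model_traits <- intersect(traits %||% retained_traits(mat), retained_traits(mat))
  fits <- list(); rows <- list(); curves <- list()
  add_fit <- function(fit) {
    rows[[length(rows) + 1]] <<- data.frame(
      response = fit$response, predictor = fit$predictor, family = fit$family,
      form = fit$form,
      intercept = fit$coefficients[["intercept"]],
      linear = if ("linear" %in% names(fit$coefficients)) fit$coefficients[["linear"]] else NA,
      quadratic = if ("quadratic" %in% names(fit$coefficients)) fit$coefficients[["quadratic"]] else NA,
      k = fit$theta, center = fit$center, logLik = fit$logLik,
      converged = fit$converged, stringsAsFactors = FALSE)
    grid <- seq(min(fit$x), max(fit$x), length.out = 50)
    curves[[length(curves) + 1]] <<- data.frame(
      response = fit$response, predictor = fit$predictor, x = grid,
      mean = as.numeric(predict(fit, grid)), stringsAsFactors = FALSE)
    fits[[paste(fit$response, fit$predictor, sep = "|")]] <<- fit
  }
  for (p in predictors) {
    for (tr in model_traits) {
      y <- as.integer(mat[, tr])
      if (all(y == 0)) next
      f <- tryCatch(trait_response(y, fc$env[[p]], family = "negbin",
                                   alpha = alpha, response = tr, predictor = p),
                    error = function(e) NULL)
      if (!is.null(f)) add_fit(f)
    }
    for (m in diversity_metrics()) {
      y <- div[[m]]
      ok <- !is.na(y)
      if (sum(ok) < 10) next
      f <- tryCatch(trait_response(y[ok], fc$env[[p]][ok], family = "gaussian",
                                   alpha = alpha, response = m, predictor = p),
                    error = function(e) NULL)
      if (!is.null(f)) add_fit(f)
    }
  }
  emit(do.call(rbind, rows), "response_fits.csv")
  emit(do.call(rbind, curves), "response_curves.csv")

  ## stage 6: tipping points
  if (run_tipping) {
    tp_rows <- lapply(names(fits), function(key) {
      fit <- fits[[key]]
      tp <- tryCatch(
        tipping_point(fit$y, fit$x,
                      family = if (fit$family == "negbin") "negbin" else "gaussian",
                      K = K, alpha = alpha,
                      response = fit$response, predictor = fit$predictor),
        error = function(e) NULL)
      if (is.null(tp)) return(NULL)
      data.frame(response = tp$response, predictor = tp$predictor,
                 family = tp$family, psi = tp$psi, se_psi = tp$se_psi,
                 slope_left = if (tp$estimable) tp$fit$slope_left else NA,
                 slope_right = if (tp$estimable) tp$fit$slope_right else NA,
                 test = tp$test, statistic = tp$statistic, p_value = tp$p_value,
                 significant = tp$significant,
                 warnings = paste(tp$warnings, collapse = "; "),
                 stringsAsFactors = FALSE)
    })
    tp_rows <- tp_rows[!vapply(tp_rows, is.null, TRUE)]
    emit(do.call(rbind, tp_rows), "tipping_points.csv")
  }

  manifest <- list(
    config = list(alpha = alpha, max_zero_fraction = max_zero_fraction,
                  exclude = exclude, predictors = predictors, K = K,
                  run_tipping = run_tipping, seed = seed),
    n_sites_analysed = n_sites,
    n_sites_removed = sum(grepl("removed", fc$report$reason)),
    n_traits_modelled = length(model_traits),
    stages = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
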