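# Trait allocation: fuzzy-coded affinities -> per-trait integer abundances.
#
# Taxa are scored 0-5 for each trait within a grouping feature (fuzzy
# coding).  Scores are normalized to allocation coefficients in [0,1] per
# grouping feature, a taxon's count is split across traits by those
# coefficients, and per-trait shares are rounded and summed over the taxa
# present at each site.

#' Canonical grouping features and traits
#'
#' The default trait catalogue: five grouping features (feeding style,
#' respiration mode, locomotion mode, reproduction mode, body size classes)
#' and their member traits, as used for lowland stream macroinvertebrate
#' communities.
#'
#' @return named list mapping grouping feature to a character vector of
#'   trait names.
#' @export
trait_catalogue <- function() {
  list(
    feeding = c("absorber", "deposit_feeder", "filter_feeder", "parasite",
                "piercer", "predator", "scraper", "shredder"),
    respiration = c("gill", "plastron", "spiracle", "tegument"),
    locomotion = c("burrower", "crawler", "flier", "full_water_swimmer",
                   "interstitial", "surface_swimmer", "temp_attached"),
    reproduction = c("clutches_cemented", "clutches_free",
                     "clutches_terrestrial", "clutches_vegetation",
                     "eggs_cemented", "eggs_free", "ovoviviparity"),
    size = c("size_le_0.25", "size_0.25_0.5", "size_0.5_1", "size_1_2",
             "size_2_4", "size_4_8", "size_gt_8")
  )
}

#' Construct a fuzzy trait-affinity table
#'
#' @param scores integer matrix, taxa in rows (rownames = taxon names),
#'   traits in columns (colnames = trait names); entries are affinity
#'   scores in 0..5.
#' @param feature character vector, one entry per column of `scores`,
#'   naming the grouping feature each trait belongs to.
#' @param coded logical matrix, taxa x grouping features (colnames =
#'   feature names): `TRUE` where the taxon was fuzzy coded for that
#'   feature, `FALSE` where only trait possession is recorded (positive
#'   entries then mark possessed traits and receive equal coefficients).
#'   Defaults to all-`TRUE`.
#' @return an object of class `"trait_affinity"`.
#' @export
trait_affinity <- function(scores, feature, coded = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    abort("affinity scores need taxon rownames and trait colnames")
  if (length(feature) != ncol(scores))
    abort("`feature` must name a grouping feature for every trait column")
  bad <- which(is.na(scores) | scores < 0 | scores > 5 | scores != floor(scores),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort("invalid affinity score for taxon '%s', trait '%s' (must be an integer in 0..5)",
          rownames(scores)[bad[1, 1]], colnames(scores)[bad[1, 2]])
  feats <- unique(feature)
  if (is.null(coded)) {
    coded <- matrix(TRUE, nrow(scores), length(feats),
                    dimnames = list(rownames(scores), feats))
  } else {
    coded <- as.matrix(coded)
    if (!all(feats %in% colnames(coded)) || nrow(coded) != nrow(scores))
      abort("`coded` must be a taxa x grouping-feature logical matrix")
    coded <- coded[, feats, drop = FALSE]
  }
  structure(list(scores = scores, feature = as.character(feature), coded = coded),
            class = "trait_affinity")
}

#' @export
print.trait_affinity <- function(x, ...) {
  cat(sprintf("Fuzzy trait-affinity table: %d taxa, %d traits, %d grouping features\n",
              nrow(x$scores), ncol(x$scores), length(unique(x$feature))))
  for (f in unique(x$feature))
    cat(sprintf("  %-14s %d traits, %d taxa coded\n", f, sum(x$feature == f),
                sum(x$coded[, f])))
  invisible(x)
}

#' Normalize fuzzy affinities to allocation coefficients
#'
#' Converts one taxon's affinity scores within a single grouping feature
#' into allocation coefficients in [0,1].  Coded taxa get scores
#' normalized to sum 1 (affinities 1 and 3 become 0.25 and 0.75); a coded
#' taxon with all-zero scores contributes nothing (all-zero coefficients).
#' Uncoded taxa (no fuzzy information) get the equal-coding fallback:
#' 1/T for each of the T traits they are recorded to possess (any positive
#' entry marks possession), e.g. 0.5 each for two traits.
#'
#' @param affinities integer vector of scores in 0..5 for the traits of one
#'   grouping feature.
#' @param coded logical scalar; `FALSE` invokes the equal-coding fallback.
#' @return numeric vector of coefficients, summing to 1 (or all zero).
#' @export
#' @examples
#' affinity_coefficients(c(deposit_feeder = 1, scraper = 3))     # 0.25, 0.75
#' affinity_coefficients(c(1, 1), coded = FALSE)                 # 0.5, 0.5
affinity_coefficients <- function(affinities, coded = TRUE) {
  if (length(affinities) < 1)
    abort("affinity vector must have length >= 1")
  if (anyNA(affinities) || any(affinities < 0 | affinities > 5 |
                               affinities != floor(affinities)))
    abort("affinities must be integers in 0..5 (got: %s)",
          paste(affinities, collapse = ", "))
  if (!coded) {
    possessed <- affinities > 0
    if (!any(possessed)) return(affinities * 0)
    return(possessed / sum(possessed))
  }
  tot <- sum(affinities)
  if (tot == 0) return(affinities * 0)
  affinities / tot
}

#' Allocate a taxon's count across traits
#'
#' Multiplies a taxon's abundance by its allocation coefficients and rounds
#' each share to the nearest whole number (halves away from zero; see
#' [round_half_away()]).  A count of 8 with coefficients (0.25, 0.75)
#' yields abundances 2 and 6.
#'
#' @param count non-negative integer abundance of the taxon.
#' @param coefficients allocation coefficients (see
#'   [affinity_coefficients()]).
#' @param rounding rounding function applied to each share.
#' @return integer vector of per-trait abundances.
#' @export
allocate_taxon_abundance <- function(count, coefficients,
                                     rounding = round_half_away) {
  if (length(count) != 1 || is.na(count) || count < 0 || count != floor(count))
    abort("`count` must be a single non-negative integer")
  if (anyNA(coefficients) || any(coefficients < 0 | coefficients > 1))
    abort("coefficients must lie in [0, 1]")
  out <- rounding(count * coefficients)
  names(out) <- names(coefficients)
  out
}

# Coefficient matrix (taxa x traits) for a whole affinity table.
coefficient_matrix <- function(affinity) {
  stopifnot(inherits(affinity, "trait_affinity"))
  co <- affinity$scores * 0
  for (f in unique(affinity$feature)) {
    idx <- which(affinity$feature == f)
    for (i in seq_len(nrow(co)))
      co[i, idx] <- affinity_coefficients(affinity$scores[i, idx],
                                          coded = affinity$coded[i, f])
  }
  co
}

#' Build the site-by-trait abundance matrix
#'
#' Allocates every taxon record to traits and sums allocated abundances
#' over the taxa present at each site.  Rounding happens per taxon before
#' summing.
#'
#' @param taxa data.frame with columns `site_id`, `taxon`, `count`
#'   (non-negative integers; one row per site/taxon pair).
#' @param affinity a [trait_affinity()] table covering the taxa.
#' @param unknown_taxa `"error"` (default) to fail on taxa absent from the
#'   affinity table, `"skip"` to drop them with a warning.
#' @param sites optional character vector of site ids to include even when
#'   they have no taxa records (they get all-zero rows).
#' @return an integer matrix of class `"trait_abundance"` (sites x traits)
#'   with attributes `feature` (grouping feature per column) and `excluded`
#'   (logical per column, set by [filter_sparse_traits()]).
#' @export
build_trait_abundance_matrix <- function(taxa, affinity,
                                         unknown_taxa = c("error", "skip"),
                                         sites = NULL) {
  unknown_taxa <- match.arg(unknown_taxa)
  stopifnot(inherits(affinity, "trait_affinity"))
  req <- c("site_id", "taxon", "count")
  if (!all(req %in% names(taxa)))
    abort("`taxa` must have columns site_id, taxon, count")
  if (!is_count_vector(taxa$count))
    abort("taxa counts must be non-negative integers")
  if (anyDuplicated(taxa[c("site_id", "taxon")]))
    abort("duplicate (site_id, taxon) records")

  missing <- setdiff(unique(taxa$taxon), rownames(affinity$scores))
  if (length(missing) > 0) {
    if (unknown_taxa == "error")
      abort("taxa missing from the affinity table: %s",
            paste(missing, collapse = ", "))
    warning("skipping taxa missing from the affinity table: ",
            paste(missing, collapse = ", "), call. = FALSE)
    taxa <- taxa[!taxa$taxon %in% missing, , drop = FALSE]
  }

  sites <- unique(c(as.character(taxa$site_id), as.character(sites)))
  co <- coefficient_matrix(affinity)
  mat <- matrix(0L, length(sites), ncol(co),
                dimnames = list(sites, colnames(co)))
  for (r in seq_len(nrow(taxa))) {
    alloc <- allocate_taxon_abundance(taxa$count[r],
                                      co[as.character(taxa$taxon[r]), ])
    s <- as.character(taxa$site_id[r])
    mat[s, ] <- mat[s, ] + as.integer(alloc)
  }
  structure(mat,
            feature = stats::setNames(affinity$feature, colnames(co)),
            excluded = stats::setNames(rep(FALSE, ncol(co)), colnames(co)),
            class = c("trait_abundance", class(mat)))
}

#' Flag sparse traits for exclusion from response modelling
#'
#' Traits with zero abundance at more than `max_zero_fraction` of sites
#' are flagged excluded (count data that are almost all zero cannot be
#' expected to follow a negative-binomial response).  Data are preserved;
#' only the `excluded` attribute is set.  An explicit `exclude` list can
#' replicate a fixed exclusion set exactly.
#'
#' @param mat a `"trait_abundance"` matrix.
#' @param max_zero_fraction traits whose zero fraction exceeds this are
#'   excluded; must lie in (0, 1]. Default 0.9.
#' @param exclude optional character vector of trait names to exclude
#'   regardless of sparsity.
#' @return `mat` with its `excluded` attribute updated.
#' @export
filter_sparse_traits <- function(mat, max_zero_fraction = 0.9, exclude = NULL) {
  stopifnot(inherits(mat, "trait_abundance"))
  if (!is.numeric(max_zero_fraction) || length(max_zero_fraction) != 1 ||
      max_zero_fraction <= 0 || max_zero_fraction > 1)
    abort("`max_zero_fraction` must lie in (0, 1]")
  zf <- colMeans(mat == 0)
  excl <- zf > max_zero_fraction
  if (!is.null(exclude)) {
    unknown <- setdiff(exclude, colnames(mat))
    if (length(unknown) > 0)
      abort("exclude list names unknown traits: %s", paste(unknown, collapse = ", "))
    excl[exclude] <- TRUE
  }
  attr(mat, "excluded") <- excl
  mat
}

#' Trait names retained after sparsity filtering
#'
#' @param mat a `"trait_abundance"` matrix.
#' @return character vector of retained trait names.
#' @export
retained_traits <- function(mat) {
  stopifnot(inherits(mat, "trait_abundance"))
  colnames(mat)[!attr(mat, "excluded")]
}

#' @export
print.trait_abundance <- function(x, ...) {
  cat(sprintf("Trait-abundance matrix: %d sites x %d traits (%d excluded)\n",
              nrow(x), ncol(x), sum(attr(x, "excluded"))))
  invisible(x)
}
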