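# Functional diversity indices computed per site from trait abundances.
#
# With p_i the proportion of trait i at a site:
#   H  = -sum p_i ln p_i          (Shannon-Weaver, nats)
#   D1 = 1 - sum p_i^2            (Simpson)
#   D2 = 1 / sum p_i^2            (inverse Simpson, effective trait count)
#   S  = number of traits with positive abundance (trait richness)
#   J  = H / ln S                 (Pielou's evenness; undefined at S <= 1)
# Natural logarithms throughout, so J = 1 exactly at perfect evenness.
# The 0 * ln 0 = 0 convention applies. Shannon, Simpson and inverse
# Simpson are delegated to vegan::diversity.

#' Per-site functional diversity profile
#'
#' Computes Shannon-Weaver (`H`), Simpson (`D1`), inverse Simpson (`D2`),
#' trait richness (`S`) and Pielou's evenness (`J`) for each row of a
#' site-by-trait abundance matrix.  All-zero rows are retained with all
#' metrics `NA` and flagged; `J` is `NA` whenever `S <= 1` (the evenness
#' of a single trait is undefined, never 0 or 1).
#'
#' @param mat non-negative abundance matrix (sites x traits), e.g. from
#'   [build_trait_abundance_matrix()]. A single site may be given as a
#'   vector.
#' @return data.frame with columns `site_id`, `H`, `D1`, `D2`, `S`, `J`,
#'   `defined` (FALSE for all-zero sites).
#' @export
#' @examples
#' trait_diversity(rbind(us17 = c(deposit_feeder = 2, scraper = 6)))
trait_diversity <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, 1, dimnames = list("site1", names(mat)))
  mat <- as.matrix(unclass(mat))
  if (anyNA(mat) || any(mat < 0))
    abort("abundances must be non-negative and complete")
  tot <- rowSums(mat)
  S <- as.integer(rowSums(mat > 0))
  H <- suppressWarnings(vegan::diversity(mat, index = "shannon"))
  D1 <- suppressWarnings(vegan::diversity(mat, index = "simpson"))
  D2 <- suppressWarnings(vegan::diversity(mat, index = "invsimpson"))
  defined <- tot > 0
  H[!defined] <- NA_real_
  D1[!defined] <- NA_real_
  D2[!defined] <- NA_real_
  J <- ifelse(S > 1, H / log(S), NA_real_)
  data.frame(site_id = rownames(mat) %||% paste0("site", seq_len(nrow(mat))),
             H = as.numeric(H), D1 = as.numeric(D1), D2 = as.numeric(D2),
             S = S, J = as.numeric(J), defined = defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diversity metric names
#'
#' The five per-site metrics produced by [trait_diversity()], in order.
#' @return character vector.
#' @export
diversity_metrics <- function() c("H", "D1", "D2", "S", "J")
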