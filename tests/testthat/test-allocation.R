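# Fuzzy-coded trait allocation.

test_that("affinity scores normalize to allocation coefficients", {
  expect_equal(affinity_coefficients(c(deposit_feeder = 1, scraper = 3)),
               c(deposit_feeder = 0.25, scraper = 0.75))
  expect_equal(unname(affinity_coefficients(c(5, 0, 0))), c(1, 0, 0))
  expect_equal(unname(affinity_coefficients(c(0, 0))), c(0, 0))
  # equal-coding fallback for taxa without fuzzy information
  expect_equal(unname(affinity_coefficients(c(1, 1), coded = FALSE)), c(0.5, 0.5))
  expect_equal(unname(affinity_coefficients(c(2, 0, 5), coded = FALSE)),
               c(0.5, 0, 0.5))
  expect_error(affinity_coefficients(c(1, 6)), "0..5")
  expect_error(affinity_coefficients(c(1.5, 2)), "0..5")
  expect_error(affinity_coefficients(numeric(0)), "length")
})

test_that("coefficients sum to one (or zero) for random affinity vectors", {
  set.seed(101)
  for (i in 1:200) {
    a <- sample(0:5, sample(2:8, 1), replace = TRUE)
    co <- affinity_coefficients(a)
    if (sum(a) == 0) expect_identical(sum(co), 0)
    else expect_lt(abs(sum(co) - 1), 1e-12)
    expect_true(all(co >= 0 & co <= 1))
  }
})

test_that("taxon counts allocate by coefficient with half-away rounding", {
  expect_equal(unname(allocate_taxon_abundance(8, c(0.25, 0.75))), c(2, 6))
  expect_equal(unname(allocate_taxon_abundance(0, c(0.3, 0.7))), c(0, 0))
  # 7 * 0.25 = 1.75 -> 2 ; 7 * 0.75 = 5.25 -> 5
  expect_equal(unname(allocate_taxon_abundance(7, c(0.25, 0.75))), c(2, 5))
  expect_error(allocate_taxon_abundance(-1, c(1)), "non-negative")
  # rounding rule itself: halves go away from zero
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
})

test_that("allocation conserves counts within the rounding slack", {
  set.seed(202)
  for (i in 1:200) {
    a <- sample(0:5, sample(2:6, 1), replace = TRUE)
    if (sum(a) == 0) next
    co <- affinity_coefficients(a)
    n <- sample(0:500, 1)
    al <- allocate_taxon_abundance(n, co)
    Tn <- sum(co > 0)
    expect_lte(abs(sum(al) - n), Tn / 2)
    if (all(n * co == floor(n * co))) expect_identical(sum(al), as.numeric(n))
  }
})

test_that("site-by-trait matrix sums allocations over taxa", {
  aff <- tiny_affinity()
  taxa <- data.frame(site_id = "US17", taxon = "Baetidae", count = 8)
  mat <- build_trait_abundance_matrix(taxa, aff)
  expect_equal(mat["US17", "deposit_feeder"], 2L, ignore_attr = TRUE)
  expect_equal(mat["US17", "scraper"], 6L, ignore_attr = TRUE)
  expect_equal(mat["US17", "gill"], 8L, ignore_attr = TRUE)  # affinity 5 alone
  # a site with no records yields an all-zero row
  mat2 <- build_trait_abundance_matrix(taxa, aff, sites = c("US17", "EMPTY"))
  expect_true(all(mat2["EMPTY", ] == 0))
  expect_error(
    build_trait_abundance_matrix(
      data.frame(site_id = "a", taxon = "Unknownidae", count = 1), aff),
    "Unknownidae")
  expect_warning(
    m3 <- build_trait_abundance_matrix(
      rbind(taxa, data.frame(site_id = "US17", taxon = "Unknownidae", count = 3)),
      aff, unknown_taxa = "skip"),
    "Unknownidae")
  expect_equal(unclass(m3), unclass(mat), ignore_attr = TRUE)
})

test_that("matrix building is additive over record subsets and deterministic", {
  aff <- tiny_affinity()
  set.seed(303)
  taxa <- expand.grid(site_id = paste0("s", 1:6),
                      taxon = rownames(aff$scores),
                      stringsAsFactors = FALSE)
  taxa$count <- sample(0:50, nrow(taxa), replace = TRUE)
  full <- build_trait_abundance_matrix(taxa, aff)
  part1 <- taxa[taxa$taxon == "Baetidae", ]
  part2 <- taxa[taxa$taxon != "Baetidae", ]
  m1 <- build_trait_abundance_matrix(part1, aff, sites = rownames(full))
  m2 <- build_trait_abundance_matrix(part2, aff, sites = rownames(full))
  expect_equal(unclass(full),
               unclass(m1)[rownames(full), ] + unclass(m2)[rownames(full), ],
               ignore_attr = TRUE)
  expect_identical(unclass(build_trait_abundance_matrix(taxa, aff)), unclass(full))
  expect_error(
    build_trait_abundance_matrix(rbind(taxa, taxa[1, ]), aff), "duplicate")
})

test_that("sparse traits are flagged, never dropped", {
  aff <- tiny_affinity()
  mat <- build_trait_abundance_matrix(
    data.frame(site_id = paste0("s", 1:10),
               taxon = "Ancylidae",
               count = c(5, rep(0, 9))),  # scraper zero at 9/10 sites
    aff)
  out <- filter_sparse_traits(mat, max_zero_fraction = 0.85)
  expect_true(attr(out, "excluded")[["scraper"]])
  expect_false("deposit_feeder" %in% retained_traits(out) &&
                 attr(out, "excluded")[["scraper"]] == FALSE)
  expect_identical(dim(out), dim(mat))            # data preserved
  # vacuous threshold keeps everything
  all_kept <- filter_sparse_traits(mat, max_zero_fraction = 1)
  expect_false(any(attr(all_kept, "excluded")))
  # explicit exclude list overrides sparsity
  forced <- filter_sparse_traits(mat, 1, exclude = "gill")
  expect_true(attr(forced, "excluded")[["gill"]])
  expect_error(filter_sparse_traits(mat, 0), "0, 1")
  expect_error(filter_sparse_traits(mat, 1.2), "0, 1")
})
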