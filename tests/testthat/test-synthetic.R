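# Synthetic survey generator.

test_that("environmental tables honour ranges, seeds and skewness", {
  sc <- survey_scenario()
  env <- gen_environment(sc, 42)
  expect_identical(nrow(env), 88L)
  expect_true(all(env$velocity >= 0 & env$velocity <= 1.5))
  expect_true(all(env$turbidity >= 0 & env$turbidity <= 34.7))
  expect_true(all(env$elevation >= 2 & env$elevation <= 1075))
  expect_identical(env, gen_environment(sc, 42))
  expect_false(identical(env, gen_environment(sc, 43)))
  # right-skewed turbidity and elevation: median well below mean
  big <- survey_scenario(n_sites = 10000, n_incomplete = 0)
  envb <- gen_environment(big, 1)
  expect_lt(median(envb$turbidity), mean(envb$turbidity))
  expect_lt(median(envb$elevation), mean(envb$elevation))
})

test_that("trait counts follow the configured response models", {
  sc <- survey_scenario(n_sites = 10000, n_incomplete = 0)
  # Poisson limit: flat mean with enormous k gives variance ~ mean
  sc$responses <- list(piercer = list(predictor = "turbidity", form = "flat",
                                      a = log(5), k = 1e6))
  env <- gen_environment(sc, 2)
  cts <- gen_trait_counts(env, sc, 3)
  expect_lt(abs(var(cts[, "piercer"]) / mean(cts[, "piercer"]) - 1), 0.1)
  # no effect: counts independent of the predictor
  sc$responses <- list(piercer = list(predictor = "turbidity", form = "linear",
                                      a = 1, b1 = 0, k = 2))
  cts <- gen_trait_counts(env, sc, 4)
  expect_lt(abs(cor(cts[, "piercer"], env$turbidity)), 0.05)
  # broken line with b2 < 0: mean rises before psi, falls after
  sc$responses <- list(scraper = list(predictor = "turbidity", form = "broken",
                                      a = 2, b1 = 0.35, b2 = -0.45, psi = 5, k = 2))
  cts <- gen_trait_counts(env, sc, 5)
  xx <- env$turbidity; yy <- cts[, "scraper"]
  expect_gt(mean(yy[xx > 3 & xx < 5]), mean(yy[xx < 2]))
  expect_gt(mean(yy[xx > 3 & xx < 7]), mean(yy[xx > 15]))
})

test_that("trait counts disaggregate to taxa and re-allocate exactly", {
  sc <- survey_scenario(n_sites = 30, n_incomplete = 0)
  env <- gen_environment(sc, 6)
  cts <- gen_trait_counts(env, sc, 7)
  taxa <- gen_taxa_from_traits(cts, sc$affinity, 8)
  mat <- build_trait_abundance_matrix(taxa, sc$affinity, sites = rownames(cts))
  expect_equal(max(abs(unclass(mat)[rownames(cts), colnames(cts)] - cts)), 0)
})

test_that("single pure-carrier pools are identity round-trips", {
  scores <- rbind(Ancylidae = c(scraper = 5L, deposit_feeder = 0L))
  aff <- trait_affinity(scores, c("feeding", "feeding"))
  cts <- matrix(c(4L, 9L, 0L), 3, 1,
                dimnames = list(paste0("s", 1:3), "scraper"))
  taxa <- gen_taxa_from_traits(cts, aff, 1)
  expect_identical(taxa$count, c(4L, 9L))
  expect_true(all(taxa$taxon == "Ancylidae"))
  # empty counts give an empty table
  empty <- gen_taxa_from_traits(cts * 0L, aff, 1)
  expect_identical(nrow(empty), 0L)
  # infeasible: a trait with counts but no carrying taxon
  cts2 <- matrix(5L, 1, 1, dimnames = list("s1", "deposit_feeder"))
  expect_error(gen_taxa_from_traits(cts2, aff, 1), "no pure carrier")
})

test_that("scenario validation enforces its invariants", {
  sc <- survey_scenario()
  expect_error(survey_scenario(n_sites = 10), "n_sites")
  bad <- sc
  expect_error(
    synthetic_scenario(80, modifyList(sc$env, list(turbidity = list(
      dist = "trunclnorm", meanlog = 1, sdlog = 1, min = 5, max = 5))),
      sc$affinity, sc$responses, "feeding"),
    "min < max")
  resp <- sc$responses
  resp$scraper$psi <- 50          # outside the turbidity range
  expect_error(synthetic_scenario(80, sc$env, sc$affinity, resp, "feeding"),
               "strictly inside")
  resp <- sc$responses
  resp$scraper$k <- 0
  expect_error(synthetic_scenario(80, sc$env, sc$affinity, resp, "feeding"),
               "k must be")
})

test_that("scenarios round-trip through their config file", {
  sc <- survey_scenario()
  path <- tempfile(fileext = ".json")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_identical(sc2$n_sites, sc$n_sites)
  expect_identical(sc2$affinity$scores, sc$affinity$scores)
  expect_identical(sc2$affinity$coded, sc$affinity$coded)
  expect_equal(sc2$responses, sc$responses)
  expect_equal(sc2$env, sc$env)
  # and the reloaded scenario generates identical data
  expect_identical(simulate_survey(sc, 9)$taxa, simulate_survey(sc2, 9)$taxa)
  unlink(path)
})

test_that("survey simulation masks the configured number of records", {
  sv <- simulate_survey(survey_scenario(), 10)
  vars <- setdiff(names(sv$env), "site_id")
  expect_identical(sum(rowSums(is.na(sv$env[vars])) > 0), 8L)
  expect_identical(nrow(sv$env), 88L)
  # ground-truth counts exist for every site, generated pre-masking
  expect_identical(nrow(sv$trait_counts), 88L)
  expect_false(anyNA(sv$trait_counts))
})
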