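test_that("missing-value vocabulary matches INSDC reporting practice", {
  expect_true(all(is_missing(c("not collected", "   ", "NA", "n/a", "-",
                               "Not Provided", "unknown"))))
  expect_false(any(is_missing(c("Homo sapiens gut metagenome", "0", "female"))))
})

test_that("harmonization renames synonyms, passes unknowns, and is idempotent", {
  r <- data.frame(sample_id = "S1",
                  attribute = c("User_sample_ID", "novel_attribute_x"),
                  value = c("S1", "7"), stringsAsFactors = FALSE)
  h <- harmonize_attributes(r)
  expect_identical(h$attribute, c("sample_name", "novel_attribute_x"))
  expect_identical(harmonize_attributes(h)$attribute, h$attribute)
  ## case/separator-insensitive matching
  r2 <- data.frame(sample_id = "S1", attribute = "SAMPLE  name", value = "x")
  expect_identical(harmonize_attributes(r2)$attribute, "sample_name")
})

test_that("synonym collisions keep the first non-missing value and are logged", {
  r <- data.frame(sample_id = c("S1", "S1"),
                  attribute = c("sample name", "User_sample_ID"),
                  value = c("not collected", "stool_A"),
                  stringsAsFactors = FALSE)
  h <- harmonize_attributes(r)
  expect_equal(nrow(h), 1L)
  expect_identical(h$value, "stool_A")
  expect_identical(attr(h, "collisions"), 1L)
  ## both non-missing: first wins
  r2 <- data.frame(sample_id = c("S1", "S1"),
                   attribute = c("sample name", "User_sample_ID"),
                   value = c("first", "second"), stringsAsFactors = FALSE)
  expect_identical(harmonize_attributes(r2)$value, "first")
})

test_that("harmonization never increases the attribute-union size", {
  g <- generate_metadata_studies(metadata_profile(
    n_studies = 6L, attribute_vocabulary = default_metadata_vocabulary(30L),
    planted_population_rate = stats::setNames(rep(0.5, 30),
                                              default_metadata_vocabulary(30L)),
    seed = 9L))
  union_size <- function(studies) {
    length(unique(unlist(lapply(studies, function(s) s$records$attribute))))
  }
  raw <- union_size(g$studies)
  harmonized <- union_size(lapply(g$studies, harmonize_attributes))
  expect_lte(harmonized, raw)
})

test_that("tier evaluation awards the highest fully satisfied cumulative tier", {
  cl <- metadata_checklist()
  bronze_study <- make_tier_study(cl$cumulative$bronze)
  a <- evaluate_metadata_tier(bronze_study, cl)
  expect_identical(a$tier_awarded, "bronze")
  expect_identical(a$blocking_fields[1], "seq_meth")

  silver_study <- make_tier_study(cl$cumulative$silver)
  expect_identical(evaluate_metadata_tier(silver_study, cl)$tier_awarded,
                   "silver")

  gold_study <- make_tier_study(cl$cumulative$gold)
  ag <- evaluate_metadata_tier(gold_study, cl)
  expect_identical(ag$tier_awarded, "gold")
  expect_length(ag$blocking_fields, 0L)

  ## collection date missing in every sample: a mandatory bronze field fails
  no_date <- make_tier_study(setdiff(cl$cumulative$bronze, "collection_date"))
  an <- evaluate_metadata_tier(no_date, cl)
  expect_identical(an$tier_awarded, "none")
  expect_true("collection_date" %in% an$blocking_fields)
})

test_that("tier evaluation respects the completeness threshold and monotonicity", {
  cl <- metadata_checklist()
  study <- make_tier_study(cl$cumulative$bronze, n_samples = 4L)
  ## knock one sample's collection_date out to a missing token
  idx <- which(study$records$attribute == "collection_date")[1]
  study$records$value[idx] <- "not collected"
  expect_identical(evaluate_metadata_tier(study, cl)$tier_awarded, "none")
  expect_identical(evaluate_metadata_tier(study, cl, threshold = 0.75)$tier_awarded,
                   "bronze")
  ## restoring the value can only raise the tier
  study$records$value[idx] <- "2021-04-01"
  expect_identical(evaluate_metadata_tier(study, cl)$tier_awarded, "bronze")
  expect_error(evaluate_metadata_tier(study_metadata("E"), cl),
               class = "seqbadge_unevaluable")
})

test_that("population matrix counts a study when any sample is non-missing", {
  mk <- function(id, attrs, values) {
    study_metadata(id, records = data.frame(
      sample_id = "s1", attribute = attrs, value = values,
      stringsAsFactors = FALSE))
  }
  studies <- list(mk("A", c("x", "y"), c("1", "2")),
                  mk("B", "y", "3"),
                  mk("C", c("y", "z"), c("4", "not collected")))
  pm <- population_matrix(studies)
  expect_equal(unname(pm$proportion["x"]), 1 / 3)
  expect_equal(unname(pm$proportion["y"]), 1)
  ## attribute present only as missing tokens counts as unpopulated
  expect_equal(unname(pm$proportion["z"]), 0)
  expect_equal(pm$proportion, rowMeans(pm$matrix))
  expect_error(population_matrix(list()), class = "seqbadge_unevaluable")
})

test_that("sparsity histogram bins left-open right-closed and conserves counts", {
  pm <- structure(list(matrix = matrix(TRUE, 3, 1,
                                       dimnames = list(c("a", "b", "c"), "S")),
                       proportion = c(a = 0.05, b = 0.5, c = 1.0)),
                  class = "population_matrix")
  h <- sparsity_histogram(pm, c(0, 0.1, 0.5, 1.0))
  expect_equal(unname(h), c(1L, 1L, 1L))
  ## all-1 proportions land in the last bin
  pm$proportion[] <- 1
  expect_equal(unname(sparsity_histogram(pm, c(0, 0.5, 1))), c(0L, 3L))
  ## conservation on random matrices
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    pm$proportion <- stats::setNames(round(runif(n), 3), seq_len(n))
    edges <- sort(unique(c(0, runif(3), 1)))
    expect_equal(sum(sparsity_histogram(pm, edges)), n)
  }
  expect_error(sparsity_histogram(pm, c(0.2, 0.5, 1)), "span")
  expect_error(sparsity_histogram(pm, c(0, 0.5, 0.5, 1)), "increasing")
})

test_that("median population follows the even/odd median rules", {
  mk_pm <- function(p) structure(list(matrix = NULL, proportion = p),
                                 class = "population_matrix")
  expect_equal(median_population(mk_pm(rep(1 / 42, 5))), 1 / 42)
  expect_equal(median_population(mk_pm(c(0, 1))), 0.5)
  expect_equal(median_population(mk_pm(c(0.2, 0.4, 0.9))), 0.4)
})
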