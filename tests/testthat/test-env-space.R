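test_that("environment counting matches closed-form binomial sums", {
  expect_equal(countEnvironments(20, 4, "upto", includeEmpty = TRUE), 6196)
  expect_equal(countEnvironments(154, 3, "exact", includeEmpty = FALSE), 596904)
  expect_equal(countEnvironments(5, 1, "exact", includeEmpty = FALSE), 5)
  expect_equal(countEnvironments(20, 20, "upto", includeEmpty = TRUE), 2^20)
  expect_equal(countEnvironments(20, 4, "upto", includeEmpty = FALSE), 6195)
  expect_error(countEnvironments(5, 6), "outside")
})

test_that("enumeration agrees with counting and is canonical", {
  pool <- NutrientPool(c("a", "b"), carbon_atoms = c(1, 1))
  envs <- enumerateEnvironments(EnvironmentSpace(pool, 2))
  expect_identical(envs, list(character(0), "a", "b", c("a", "b")))

  # oracle equivalence over a grid of small spaces
  for (n in c(4, 6, 8)) {
    bigPool <- NutrientPool(sprintf("x%02d", seq_len(n)),
                            carbon_atoms = rep(3, n))
    for (k in 1:3) for (rule in c("upto", "exact"))
      for (empty in c(TRUE, FALSE)) {
        space <- EnvironmentSpace(bigPool, k, rule, empty)
        envs <- enumerateEnvironments(space)
        expect_length(envs, countEnvironments(n, k, rule, empty))
        ids <- vapply(envs, environmentId, character(1))
        expect_false(anyDuplicated(ids) > 0)
        # canonical: non-decreasing sizes
        expect_true(!is.unsorted(lengths(envs)))
      }
  }
})

test_that("enumeration refuses spaces above the cap", {
  pool <- NutrientPool(sprintf("c%03d", 1:154), carbon_atoms = rep(4, 154))
  space <- EnvironmentSpace(pool, 3, "exact", includeEmpty = FALSE)
  expect_error(enumerateEnvironments(space, cap = 100), "cap")
  # counting the same space is instantaneous and exact
  expect_equal(countEnvironments(154, 3, "exact", FALSE), 596904)
})

test_that("random environments are admissible, non-empty and reproducible", {
  pool <- NutrientPool(sprintf("n%02d", 1:20), carbon_atoms = rep(3, 20))
  space <- EnvironmentSpace(pool, 4)
  set.seed(42)
  draws <- replicate(500, randomEnvironment(space), simplify = FALSE)
  sizes <- lengths(draws)
  expect_true(all(sizes >= 1 & sizes <= 4))
  expect_true(all(unlist(draws) %in% nutrientIds(pool)))
  expect_true(all(vapply(draws, function(e) !anyDuplicated(e), logical(1))))

  set.seed(7); a <- replicate(50, randomEnvironment(space), simplify = FALSE)
  set.seed(7); b <- replicate(50, randomEnvironment(space), simplify = FALSE)
  expect_identical(a, b)

  one <- EnvironmentSpace(pool, 1)
  set.seed(1)
  expect_true(all(lengths(replicate(20, randomEnvironment(one),
                                    simplify = FALSE)) == 1L))
})

test_that("environment ids are order-free and stable", {
  expect_identical(environmentId(c("b", "a")), environmentId(c("a", "b")))
  expect_identical(environmentId(character(0)), "empty")
  expect_identical(environmentId(c("a", "a", "b")), "a+b")
})

test_that("equimolar medium construction preserves total carbon", {
  pool <- NutrientPool(c("glucose", "acetate"), carbon_atoms = c(6, 2))
  glc <- buildMedium("glucose", MediumSpec(), pool)
  expect_equal(unname(glc), 0.02 / 6)
  both <- buildMedium(c("glucose", "acetate"), MediumSpec(), pool)
  expect_equal(unname(both), c(0.0025, 0.0025), tolerance = 1e-12)
  expect_length(buildMedium(character(0), MediumSpec(), pool), 0)

  over <- buildMedium(c("glucose", "acetate"), MediumSpec(overrideMmol = 5e-4),
                      pool)
  expect_equal(unname(over), c(5e-4, 5e-4))

  # carbon closure across random environments of a larger pool
  big <- NutrientPool(sprintf("n%02d", 1:12), carbon_atoms = sample(1:12))
  space <- EnvironmentSpace(big, 4)
  set.seed(11)
  for (i in 1:50) {
    env <- randomEnvironment(space)
    med <- buildMedium(env, MediumSpec(), big)
    expect_equal(sum(med * carbonAtoms(big, env)), 0.02, tolerance = 1e-12)
  }
})

test_that("pool CSV and enumerate-to-CSV round trip", {
  pool <- NutrientPool(c("glc", "ace", "cit"), c("glucose", "acetate", "citrate"),
                       carbon_atoms = c(6, 2, 6))
  f <- withr::local_tempfile(fileext = ".csv")
  writeNutrientPool(pool, f)
  back <- readNutrientPool(f)
  expect_identical(back@nutrients, pool@nutrients)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,name\nglc,glucose", bad)
  expect_error(readNutrientPool(bad), "carbon_atoms")

  out <- withr::local_tempfile(fileext = ".csv")
  res <- enumerateToCsv(pool, 2, "upto", TRUE, file = out)
  expect_equal(res$count, 7)
  expect_equal(nrow(read.csv(out)), 7)
  countRes <- enumerateToCsv(pool, 3, "exact", FALSE, countOnly = TRUE)
  expect_equal(countRes$count, 1)
})
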