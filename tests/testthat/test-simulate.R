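test_that("generator output is reproducible and truth-consistent", {
  pg <- generate_pangenome(n_genomes = 15, core_size = 60,
                           accessory_pool_size = 120, seed = 8)
  pg2 <- generate_pangenome(n_genomes = 15, core_size = 60,
                            accessory_pool_size = 120, seed = 8)
  expect_identical(unclass(pg$matrix), unclass(pg2$matrix))
  expect_identical(pg$completeness, pg2$completeness)
  # a genome only carries traits it was assigned before rarefaction
  obs <- unclass(pg$matrix)
  expect_true(all(!obs | pg$assigned[, colnames(obs)]))
  # emitted traits plus dropped traits cover the constructed pool
  expect_setequal(c(trait_ids(pg$matrix), pg$dropped),
                  c(pg$true_core, pg$accessory_ids))
})

test_that("fully complete genomes carry the whole core", {
  pg <- generate_pangenome(n_genomes = 6, core_size = 40,
                           accessory_pool_size = 80,
                           completeness = rep(1, 6), seed = 2)
  inter <- Reduce(intersect, lapply(genome_ids(pg$matrix), function(g)
    trait_ids(pg$matrix)[unclass(pg$matrix)[g, ]]))
  expect_true(all(pg$true_core %in% inter))
})

test_that("realized genome sizes match the construction moments", {
  n <- 200
  pg <- generate_pangenome(n_genomes = n, core_size = 100,
                           accessory_pool_size = 200,
                           completeness = rep(0.8, n), seed = 13)
  expected <- 0.8 * (100 + sum(pg$carriage))
  sizes <- genome_sizes(pg$matrix)
  se <- stats::sd(sizes) / sqrt(n)
  expect_lt(abs(mean(sizes) - expected), 3 * se + 1)
  # per-genome retention of assigned traits is binomial at the true fraction
  assigned_n <- rowSums(pg$assigned)
  ret <- sizes / assigned_n
  expect_lt(abs(mean(ret) - 0.8), 3 * stats::sd(ret) / sqrt(n) + 0.01)
})

test_that("degenerate generator parameters error", {
  expect_error(generate_pangenome(3, 1, 1, completeness = rep(1e-6, 3),
                                  seed = 1), "empty genome")
  expect_error(generate_pangenome(2, 10, 5, carriage = rep(2, 5)))
})

test_that("strict baseline takes traits above the presence threshold", {
  m <- trait_matrix(list(g1 = c("u", "v", "w"), g2 = c("u", "v"),
                         g3 = c("u", "w")))
  expect_identical(strict_core(m), "u")
  expect_setequal(strict_core(m, threshold = 0.6), c("u", "v", "w"))
  # single genome: its whole trait set
  m1 <- trait_matrix(list(g1 = c("a", "b")))
  expect_setequal(strict_core(m1), c("a", "b"))
})

test_that("normalized residue is the difference over the mean, antisymmetric", {
  expect_equal(normalized_residue(110, 90), 0.2)
  expect_equal(normalized_residue(90, 110), -0.2)
  expect_equal(normalized_residue(42, 42), 0)
  expect_error(normalized_residue(0, 0), "undefined")
})

test_that("core fraction uses completeness-scaled sizes above the floor", {
  m <- trait_matrix(list(
    g1 = sprintf("t%02d", 1:60), g2 = sprintf("t%02d", 1:80),
    g3 = sprintf("t%02d", 1:10)))
  pri <- c(g1 = 0.6, g2 = 0.8, g3 = 0.2)
  # mean(60/0.6, 80/0.8) = 100; g3 sits below the 0.40 floor
  expect_equal(core_fraction(50, m, pri), 0.5)
  expect_equal(core_fraction(50, m, pri, floor = 0.1),
               50 / mean(c(100, 100, 50)))
  expect_error(core_fraction(50, m, pri, floor = 0.9), "floor")
})

test_that("robustness harness tables are reproducible and complete", {
  r1 <- robustness_experiment("strata", n_runs = 2, n_genomes = 10,
                              core_size = 50, accessory_pool_size = 100,
                              seed = 21)
  r2 <- robustness_experiment("strata", n_runs = 2, n_genomes = 10,
                              core_size = 50, accessory_pool_size = 100,
                              seed = 21)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 6L)
  expect_setequal(unique(r1$config), c("70-100%", "50-70%", "10-50%"))
  expect_true(all(r1$sensitivity >= 0 & r1$sensitivity <= 1))
  gb <- robustness_experiment("goodbad", n_runs = 1, core_size = 50,
                              accessory_pool_size = 100, n_bad = c(2, 4),
                              boot_reps = 1, seed = 3)
  expect_identical(nrow(gb), 2L)
  expect_true(all(c("boot_fdr", "boot_sensitivity") %in% names(gb)))
})

test_that("extra incomplete genomes help sensitivity without exploding FDR", {
  gb <- robustness_experiment("goodbad", n_runs = 10, n_bad = c(4, 39),
                              seed = 7)
  a <- aggregate(cbind(sensitivity, fdr) ~ config, gb, mean)
  few <- a[a$config == "bad_4", ]
  many <- a[a$config == "bad_39", ]
  expect_gte(many$sensitivity, few$sensitivity)
  expect_lte(many$fdr, few$fdr + 0.1)
})
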