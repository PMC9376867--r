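test_that("identical complete genomes converge with every trait core", {
  m <- trait_matrix(lapply(setNames(nm = sprintf("g%d", 1:5)),
                           function(g) sprintf("t%d", 1:20)))
  fit <- corepan(m, completeness = 1)
  expect_setequal(fit$core, trait_ids(m))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2 + 1)   # one extra pass detects convergence
  expect_true(all(fit$completeness$posterior == 1))
  expect_true(all(fit$completeness$clamped))  # prior 1 clipped to 0.99
})

test_that("completeness update is the carried core fraction", {
  m <- trait_matrix(list(g1 = c("t1", "t3", "acc1"),
                         g2 = c("t1", "t2", "t3", "t4"),
                         g3 = "acc1"))
  post <- update_completeness(m, core = c("t1", "t2", "t3", "t4"))
  expect_equal(unname(post), c(0.5, 1, 0))
  expect_error(update_completeness(m, character()), "empty core")
  expect_error(update_completeness(m, c("t1", "ghost")), "absent")
})

test_that("seed-core rule thresholds prevalence at half the mean prior", {
  m <- trait_matrix(list(g1 = c("a", "b"), g2 = c("a", "c"),
                         g3 = c("b", "d"), g4 = c("c", "d")))
  # mean prior 1 -> cutoff 0.5; every trait has prevalence exactly 0.5
  expect_setequal(initial_core(m, setNames(rep(1, 4), genome_ids(m))),
                  trait_ids(m))
  # mean prior 0.8 -> cutoff 0.4 under the full-mean rule; prevalence 0.1 fails
  m2 <- trait_matrix(c(list(g1 = c("rare", "common")),
                       lapply(setNames(nm = sprintf("g%d", 2:10)),
                              function(g) "common")))
  seeded <- initial_core(m2, setNames(rep(0.8, 10), genome_ids(m2)))
  expect_false("rare" %in% seeded)
  expect_true("common" %in% seeded)
})

test_that("final partition is insensitive to the prevalence seed rules", {
  # the "all" seed is excluded: core = every trait is a fixed point of the
  # update (the accessory exponent vanishes for all genomes), so it cannot
  # prune and is only useful as a diagnostic
  pg <- generate_pangenome(n_genomes = 25, core_size = 120,
                           accessory_pool_size = 240, seed = 11)
  fits <- lapply(c("half-mean-prior", "mean-prior"), function(rule)
    corepan(pg$matrix, completeness = pg$completeness, seed_core = rule))
  expect_setequal(fits[[1]]$core, fits[[2]]$core)
  all_fit <- corepan(pg$matrix, completeness = pg$completeness,
                     seed_core = "all")
  expect_setequal(all_fit$core, trait_ids(pg$matrix))
})

test_that("max_iter = 1 classifies once with the priors only", {
  pg <- generate_pangenome(n_genomes = 15, core_size = 80,
                           accessory_pool_size = 160, seed = 5)
  fit1 <- corepan(pg$matrix, completeness = 0.7, max_iter = 1)
  expect_identical(fit1$iterations, 1L)
  expect_false(fit1$converged)
  # single-pass oracle: score all traits at the clamped prior and the seed core
  priors <- setNames(rep(0.7, nrow(pg$matrix)), genome_ids(pg$matrix))
  seed_core <- initial_core(pg$matrix, priors)
  sc <- corepan:::.score_all(pg$matrix, priors, length(seed_core))
  expect_setequal(fit1$core, sc$trait_id[sc$category == "core"])
  # posterior is reported from that single core, not fed back
  expect_equal(fit1$completeness$posterior,
               unname(update_completeness(pg$matrix, fit1$core)))
  expect_false(isTRUE(all.equal(fit1$completeness$posterior,
                                fit1$completeness$prior)))
})

test_that("fits are deterministic and the convergence flag is truthful", {
  pg <- generate_pangenome(n_genomes = 20, core_size = 100,
                           accessory_pool_size = 200, seed = 3)
  f1 <- corepan(pg$matrix, completeness = pg$completeness)
  f2 <- corepan(pg$matrix, completeness = pg$completeness)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$core, f2$core)
  expect_lte(f1$iterations, f1$config$max_iter)
  # replay one extra pass from the converged state
  expect_true(f1$converged)
  cw <- pmin(pmax(setNames(f1$completeness$posterior,
                           f1$completeness$genome_id), 0.01), 0.99)
  replay <- corepan:::.score_all(pg$matrix, cw, length(f1$core))
  expect_setequal(replay$trait_id[replay$category == "core"], f1$core)
})

test_that("strict-core limit: near-complete genomes recover the intersection", {
  # constructed so every accessory trait is absent from >= 1 genome and each
  # genome carries enough accessory content that the accessory draw count
  # stays positive (likelihoods well separated)
  core30 <- sprintf("core%d", 1:30)
  m <- trait_matrix(list(
    g1 = c(core30, sprintf("a1_%d", 1:8)),
    g2 = c(core30, sprintf("a2_%d", 1:8)),
    g3 = c(core30, sprintf("a3_%d", 1:8)),
    g4 = c(core30, sprintf("a4_%d", 1:8))))
  fit <- corepan(m, completeness = 1)
  inter <- Reduce(intersect, lapply(rownames(m), function(g)
    trait_ids(m)[unclass(m)[g, ]]))
  expect_setequal(fit$core, inter)
})

test_that("prior reconciliation and scale conventions are enforced", {
  m <- trait_matrix(list(g1 = c("a", "b"), g2 = "a"))
  expect_error(corepan(m, completeness = c(g1 = 0.9)), "no completeness prior")
  expect_warning(
    corepan(m, completeness = c(g1 = 0.9, g2 = 0.9, ghost = 0.9)),
    "absent from the matrix")
  expect_error(corepan(m, completeness = 150), "above 100")
  # percent scale divided by 100
  fit <- corepan(m, completeness = c(g1 = 90, g2 = 60), max_iter = 1)
  expect_equal(fit$completeness$prior, c(0.9, 0.6))
})

test_that("merged disjoint subclades trigger the completeness-drop warning", {
  half1 <- sprintf("h1_%02d", 1:40)
  half2 <- sprintf("h2_%02d", 1:40)
  lst <- c(lapply(setNames(nm = sprintf("a%d", 1:8)), function(g) half1),
           lapply(setNames(nm = sprintf("b%d", 1:3)), function(g) half2))
  fit <- corepan(trait_matrix(lst), completeness = 0.95)
  expect_true(length(fit$warnings) > 0)
  expect_match(fit$warnings[1], "subclade")
  # single-clade control stays silent
  ctrl <- corepan(trait_matrix(lapply(setNames(nm = sprintf("a%d", 1:8)),
                                      function(g) half1)),
                  completeness = 0.95)
  expect_identical(ctrl$warnings, character(0))
})

test_that("methods expose the fit: print, summary, coef, core_traits, plot", {
  pg <- generate_pangenome(n_genomes = 10, core_size = 40,
                           accessory_pool_size = 80, seed = 2)
  fit <- corepan(pg$matrix, completeness = pg$completeness)
  expect_output(print(fit), "core \\d+")
  expect_output(print(summary(fit)), "trace")
  cf <- coef(fit)
  expect_identical(names(cf), fit$scores$trait_id)
  expect_identical(core_traits(fit), fit$core)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
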