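test_that("birth-death trees honor the tip count and clock", {
  tr2 <- simulate_bd_tree(0.4, 0, 2, seed = 1)
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(tr2$Nnode, 1L)  # a single cherry

  for (s in 1:4) {
    tr <- simulate_bd_tree(0.3, 0.1, 15, seed = s)
    expect_equal(length(tr$tip.label), 15L)
    expect_true(is_ultrametric_tol(tr, 1e-9))
  }
  ## pure functions of (parameters, seed)
  expect_identical(write_phylo(simulate_bd_tree(0.3, 0.1, 10, seed = 9)),
                   write_phylo(simulate_bd_tree(0.3, 0.1, 10, seed = 9)))
})

test_that("Yule lineage growth matches the exponential expectation", {
  b <- 0.5; t_stop <- 4
  set.seed(5)
  counts <- replicate(200, stripemorph:::bd_forward(b, 0,
                                                    stop_t = t_stop)$n_extant)
  ## crown start with 2 lineages: E[N(t)] = 2 exp(b t)
  expected <- 2 * exp(b * t_stop)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("character simulation reproduces the CTMC transition kernel", {
  tr <- parse_phylo("((A:1,B:1):1,(C:1,D:1):1);")
  ## zero rates: everything inherits the root state
  simz <- simulate_mk(tr, matrix(0, 2, 2), levels = c("x", "y"),
                      root_state = "y", seed = 1)
  expect_true(all(unlist(simz$coding) == "y"))
  expect_true(all(vapply(simz$segments, nrow, 0L) == 1L))

  ## tip-state frequencies across replicates match exp(Q depth) from root
  Q <- matrix(c(-0.4, 0.4, 0.25, -0.25), 2, byrow = TRUE)
  tipA <- vapply(1:1000, function(s)
    simulate_mk(tr, Q, levels = c("x", "y"), root_state = "x",
                seed = s)$coding[["A"]], "")
  p_emp <- mean(tipA == "x")
  p_theo <- expm_pade(Q * 2)[1, 1]  # depth 2 from root to tip A
  expect_lt(abs(p_emp - p_theo), 3 * sqrt(p_theo * (1 - p_theo) / 1000))

  ## per-branch transition counts match the bridge expectation oracle,
  ## aggregated over histories whose endpoints match
  set.seed(7)
  sims <- lapply(1:800, function(s)
    simulate_mk(tr, Q, levels = c("x", "y"), root_state = "x", seed = s))
  tr_post <- ape::reorder.phylo(tr, "postorder")
  eA <- which(tr_post$edge[, 2L] == which(tr_post$tip.label == "A"))
  pick <- vapply(sims, function(sm) {
    sg <- sm$segments[[eA]]
    a <- sg[1L, "state"]; b <- sg[nrow(sg), "state"]
    a == 1L && b == 2L
  }, TRUE)
  jumps <- vapply(sims[pick], function(sm)
    sum(diff(sm$segments[[eA]][, "state"]) != 0), 0)
  t_eA <- tr_post$edge.length[eA]
  expected <- branch_expected_transitions(Q, t_eA, 1L, 2L, 1L, 2L,
                                          n_grid = 400L) +
              branch_expected_transitions(Q, t_eA, 1L, 2L, 2L, 1L,
                                          n_grid = 400L)
  se <- sd(jumps) / sqrt(length(jumps))
  expect_lt(abs(mean(jumps) - expected), 3 * se + 0.02)
})

test_that("Brownian traits carry the tree covariance and the set slope", {
  tre <- simulate_bd_tree(0.3, 0, 20, seed = 3)
  C <- phylo_vcv(tre)
  X <- vapply(1:2000, function(r)
    simulate_bm_traits(tre, sigma2 = 1e-12, slope = 0,
                       predictor_sigma2 = 0.5, seed = r)$x, numeric(20))
  S <- tcrossprod(X - rowMeans(X)) / (ncol(X) - 1)
  expect_lt(norm(S - 0.5 * C, "F") / norm(0.5 * C, "F"), 0.05)

  ## noiseless limit: the regression is exact
  sim <- simulate_bm_traits(tre, sigma2 = 0, slope = 2, intercept = 0.5,
                            seed = 11)
  expect_equal(unname(pgls_fit(tre, sim$y, sim$x)$coefficients),
               c(0.5, 2), tolerance = 1e-8)
})

test_that("pool generation controls polymorphism and assembly bias", {
  pc0 <- simulate_pool_and_communities(polymorphic_fraction = 0, seed = 2)
  expect_true(all(lengths(pc0$pool) == 1L))
  ## without polymorphism the maximum equals the plain count
  for (loc in unique(pc0$communities$location)) {
    sp <- pc0$communities$species[pc0$communities$location == loc]
    expect_equal(max_identical_pairs(sp, pc0$pool),
                 identical_pairs(vapply(pc0$pool[sp], `[`, "", 1L)))
  }
  pc3 <- simulate_pool_and_communities(polymorphic_fraction = 0.3,
                                       seed = 2)
  expect_equal(sum(lengths(pc3$pool) > 1L), 3L)

  ## strong dissimilarity bias produces self-dissimilar communities
  set.seed(13)
  obs <- replicate(30, {
    s <- sample.int(1e6, 1)
    pc <- simulate_pool_and_communities(richness_list = 4L,
                                        morph_probs = c(A = 0.25, B = 0.25,
                                                        C = 0.25, D = 0.25),
                                        polymorphic_fraction = 0,
                                        assembly = "dissimilar",
                                        strength = 8, seed = s)
    max_identical_pairs(pc$communities$species, pc$pool)
  })
  rand <- replicate(30, {
    s <- sample.int(1e6, 1)
    pc <- simulate_pool_and_communities(richness_list = 4L,
                                        morph_probs = c(A = 0.25, B = 0.25,
                                                        C = 0.25, D = 0.25),
                                        polymorphic_fraction = 0,
                                        assembly = "random", seed = s)
    max_identical_pairs(pc$communities$species, pc$pool)
  })
  expect_lt(mean(obs), mean(rand))

  ## reproducibility
  expect_identical(simulate_pool_and_communities(seed = 77),
                   simulate_pool_and_communities(seed = 77))
})

test_that("the packaged demonstration dataset regenerates from its seed", {
  demo <- demo_data()
  expect_equal(length(demo$tree$tip.label), 27L)
  expect_true(is_ultrametric_tol(demo$tree, 1e-8))
  expect_equal(sum(lengths(demo$stripes) > 1L), 3L)
  expect_length(enumerate_codings(demo$stripes), 8L)
  expect_equal(length(demo$pool), 10L)
  expect_equal(as.integer(table(factor(
    demo$communities$location,
    levels = unique(demo$communities$location)))),
    c(4L, 3L, 3L, 3L, 3L, 5L, 3L, 6L))
  ## the installed fixture files match a regeneration
  paths <- demo_file_paths()
  if (all(file.exists(paths))) {
    tr_file <- read_phylo(paths[["tree"]])
    expect_identical(write_phylo(tr_file), write_phylo(demo$tree))
    cd_file <- read_character_tsv(paths[["stripes"]],
                                  levels = stripe_levels())
    expect_identical(vapply(cd_file, paste, "", collapse = ","),
                     vapply(demo$stripes, paste, "", collapse = ","))
  }
})
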