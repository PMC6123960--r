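test_that("near-zero rates with uniform data give change-free histories", {
  tr <- parse_phylo("((A:1,B:1):1,(C:1,D:1):1);")
  cd <- morph_coding(setNames(rep("D", 4), c("A", "B", "C", "D")),
                     levels = stripe_levels())
  Q <- make_rate_matrix(1e-8, build_model_matrix("ER", 4))
  ens <- sample_histories(tr, cd, Q, n_maps = 200, seed = 1)
  sm <- summarize_simmap(ens)
  expect_equal(sum(sm$transitions), 0)
  expect_true(all(sm$n_transitions == 0L))
})

test_that("node-state frequencies agree with the marginal reconstruction", {
  set.seed(61)
  tre <- simulate_bd_tree(0.35, 0.1, 12, seed = 61)
  Q <- rand_Q(2, 0.05, 0.3)
  cd <- simulate_mk(tre, Q, levels = c("x", "y"), seed = 62)$coding
  n_maps <- 4000L
  ens <- sample_histories(tre, cd, Q, n_maps = n_maps, seed = 63)
  sm <- summarize_simmap(ens)
  post <- marginal_asr(tre, cd, Q)
  se <- sqrt(post * (1 - post) / n_maps)
  se[se < 1e-9] <- 1e-9
  expect_lt(max(abs(sm$node_freq - post) / se), 4)
  ## tips are pinned to their data
  nt <- length(tre$tip.label)
  expect_equal(unname(sm$node_freq[seq_len(nt), ]),
               unname(post[seq_len(nt), ]))
})

test_that("empirical root states match the analytic posterior at 10k maps", {
  tr <- parse_phylo("((A:1,B:1):1,(C:1,D:1):1);")
  Q <- rand_Q(2, 0.1, 0.4)
  cd <- morph_coding(c(A = "x", B = "y", C = "y", D = "x"),
                     levels = c("x", "y"))
  ens <- sample_histories(tr, cd, Q, n_maps = 10000L, seed = 64)
  freq <- mean(ens$node_states[, 5L] == 1L)
  p <- marginal_asr(tr, cd, Q)["root", 1L]
  ## binomial 99% bound
  expect_lt(abs(freq - p), 2.58 * sqrt(p * (1 - p) / 10000))
})

test_that("uniformization bridge matches rejection sampling and the
           integral expectation on a single branch", {
  Q <- matrix(c(-0.5, 0.5, 0.3, -0.3), 2, byrow = TRUE)
  t_e <- 1.4
  set.seed(71)
  n_draw <- 3000L
  ## endpoint pair (1, 2): count jumps under both samplers
  n_unif <- replicate(n_draw,
    length(stripemorph:::sample_path_unif(Q, t_e, 1L, 2L)$time))
  n_rej <- replicate(n_draw,
    length(stripemorph:::sample_path_rejection(Q, t_e, 1L, 2L)$time))
  expect_gt(stats::t.test(n_unif, n_rej)$p.value, 1e-4)
  ## expected 1->2 transition count against dense numerical integration
  e12 <- branch_expected_transitions(Q, t_e, 1L, 2L, 1L, 2L, n_grid = 400L)
  obs12 <- mean(vapply(seq_len(n_draw), function(r) {
    p <- stripemorph:::sample_path_unif(Q, t_e, 1L, 2L)
    sum(p$from == 1L & p$to == 2L)
  }, 0))
  expect_lt(abs(obs12 - e12), 4 * sd(n_unif) / sqrt(n_draw) + 0.02)
})

test_that("ensemble summaries conserve dwell time and recount transitions", {
  set.seed(81)
  tre <- simulate_bd_tree(0.35, 0.05, 8, seed = 81)
  Q <- rand_Q(2, 0.1, 0.4)
  cd <- simulate_mk(tre, Q, levels = c("x", "y"), seed = 82)$coding
  ens <- sample_histories(tre, cd, Q, n_maps = 400, seed = 83)
  sm <- summarize_simmap(ens)
  total_len <- sum(ens$tree$edge.length)
  ## dwell conservation per history, and in the ensemble mean
  for (m in c(1L, 57L, 400L)) {
    h <- get_history(ens, m)
    expect_equal(sum(vapply(h$segments, function(s) sum(s[, "duration"]),
                            0)), total_len, tolerance = 1e-9)
    ## segment endpoints agree with the sampled node states
    for (e in seq_along(h$segments)) {
      sg <- h$segments[[e]]
      expect_equal(unname(sg[1L, "state"]),
                   unname(h$node_states[ens$tree$edge[e, 1L]]))
      expect_equal(unname(sg[nrow(sg), "state"]),
                   unname(h$node_states[ens$tree$edge[e, 2L]]))
      if (nrow(sg) > 1L)
        expect_true(all(diff(sg[, "state"]) != 0))
    }
  }
  expect_equal(sum(sm$dwell), total_len, tolerance = 1e-9)
  ## independent recount of per-history transitions from the segments
  recount <- vapply(seq_len(400L), function(m)
    sum(vapply(get_history(ens, m)$segments, nrow, 0L) - 1L), 0L)
  expect_equal(unname(sm$n_transitions), recount)
  expect_equal(sum(sm$transitions), mean(recount), tolerance = 1e-9)
})

test_that("summaries are stable across seeds and tighten with more maps", {
  set.seed(91)
  tre <- simulate_bd_tree(0.35, 0, 6, seed = 91)
  Q <- rand_Q(2, 0.1, 0.3)
  cd <- simulate_mk(tre, Q, levels = c("x", "y"), seed = 92)$coding
  root <- length(tre$tip.label) + 1L
  f1 <- summarize_simmap(sample_histories(tre, cd, Q, n_maps = 2000,
                                          seed = 1))
  f2 <- summarize_simmap(sample_histories(tre, cd, Q, n_maps = 2000,
                                          seed = 2))
  p <- marginal_asr(tre, cd, Q)[root, 1L]
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(f1$node_freq[root, 1L] - f2$node_freq[root, 1L]), 4 * se)

  ## 10x more maps shrink the root-frequency SE by about sqrt(10)
  est <- function(n_maps, seeds) vapply(seeds, function(s)
    mean(sample_histories(tre, cd, Q, n_maps = n_maps,
                          seed = s)$node_states[, root] == 1L), 0)
  sd_small <- sd(est(100L, 1:25))
  sd_big <- sd(est(1000L, 26:50))
  expect_gt(sd_small / sd_big, 1.8)
  expect_lt(sd_small / sd_big, 5.5)
})

test_that("trajectory transition counting recovers a single clade shift", {
  ## a shallow (c,d,e) clade in state y at the end of a long stem, in an
  ## x background: the shift is pinned to the stem branch
  tr <- parse_phylo("((a:4,b:4):1,((c:0.5,d:0.5):0.5,e:1):4);")
  cd <- morph_coding(c(a = "x", b = "x", c = "y", d = "y", e = "y"),
                     levels = c("x", "y"))
  Q <- make_rate_matrix(0.08, build_model_matrix("ER", 2))
  ens <- sample_histories(tr, cd, Q, n_maps = 2000, seed = 5)
  sm <- summarize_simmap(ens)
  hits <- count_trajectory_transitions(sm, threshold = 0.5)
  ## exactly the stem branch of the y clade
  stem_child <- ape::getMRCA(tr, c("c", "d", "e"))
  expect_equal(attr(hits, "count"), 1L)
  expect_equal(hits$child, stem_child)
  ## a stricter threshold can only drop branches
  strict <- count_trajectory_transitions(sm, threshold = 0.95)
  expect_true(all(strict$edge %in% hits$edge))
  ## uniform data: no transitions
  cdu <- morph_coding(setNames(rep("x", 5), letters[1:5]),
                      levels = c("x", "y"))
  ensu <- sample_histories(tr, cdu, make_rate_matrix(
    1e-8, build_model_matrix("ER", 2)), n_maps = 200, seed = 6)
  expect_equal(attr(count_trajectory_transitions(
    summarize_simmap(ensu)), "count"), 0L)
  ## defined for binary characters only
  expect_error(count_trajectory_transitions(structure(
    list(levels = stripe_levels()), class = "simmap_summary")), "binary")
})

test_that("histories export as annotated Newick and summary TSVs", {
  tr <- parse_phylo("((A:1,B:1):1,C:2);")
  cd <- morph_coding(c(A = "x", B = "y", C = "x"), levels = c("x", "y"))
  Q <- rand_Q(2, 0.2, 0.5)
  ens <- sample_histories(tr, cd, Q, n_maps = 20, seed = 9)
  nwk <- write_history_newick(ens, 3L)
  expect_match(nwk, "^\\(.*\\);$")
  expect_match(nwk, "\\{[xy],")
  tmp <- tempfile()
  paths <- write_simmap_summary(summarize_simmap(ens), tmp)
  expect_true(all(file.exists(paths)))
  nf <- read.table(paths[1L], header = TRUE, sep = "\t")
  expect_equal(nrow(nf), 5L)
})
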