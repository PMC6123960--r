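test_that("matrix exponential meets its series and conservation contracts", {
  set.seed(31)
  for (r in 1:5) {
    Q <- rand_Q(4)
    t_e <- runif(1, 0.1, 10 / max(abs(Q)))
    A <- Q * t_e
    expect_lt(max(abs(expm_pade(A) - series_expm(A))), 1e-10)
    expect_lt(max(abs(expm_pade(A) - as.matrix(Matrix::expm(A)))), 1e-9)
  }
  ## probability conservation across a wide time range
  Q <- rand_Q(4, 0.01, 0.2)
  for (t_e in c(0, 0.01, 1, 10, 100))
    expect_lt(max(abs(rowSums(expm_pade(Q * t_e)) - 1)), 1e-12)
})

test_that("constraint structures encode models i-iv", {
  m_i <- build_model_matrix("i", 4)
  expect_equal(attr(m_i, "n_classes"), 12L)

  m_ii <- build_model_matrix("ii", 4)
  expect_equal(attr(m_ii, "n_classes"), 6L)
  expect_true(all(m_ii == t(m_ii), na.rm = TRUE))
  expect_equal(attr(build_model_matrix("ii", 2), "n_classes"), 1L)

  m_iii <- build_model_matrix("iii", 4)
  zero <- rbind(c(3, 1), c(4, 1), c(4, 2), c(1, 3), c(1, 4), c(2, 4))
  expect_true(all(m_iii[zero] == 0L))
  expect_equal(attr(m_iii, "n_classes"), 6L)

  m_iv <- build_model_matrix("iv", 4)
  expect_equal(attr(m_iv, "n_classes"), 3L)
  expect_true(all(m_iv[zero] == 0L))
  expect_equal(m_iv[1, 2], m_iv[2, 1])  # A<->B shares one class
  expect_equal(m_iv[2, 3], m_iv[3, 2])
  expect_equal(m_iv[3, 4], m_iv[4, 3])

  expect_error(build_model_matrix("v", 4))
  expect_error(build_model_matrix("iii", 3), "k = 4")
  Q <- make_rate_matrix(c(0.12, 0.10, 0.05), m_iv)
  expect_equal(Q[1, 2], 0.12)
  expect_equal(Q[4, 3], 0.05)
  expect_equal(rowSums(Q), rep(0, 4))
})

test_that("pruning likelihood matches direct cases and the enumeration oracle", {
  tr <- parse_phylo("((A:1,B:1):1,C:2);")
  ## zero rates: likelihood is the prior mass of the shared state
  cdB <- morph_coding(setNames(rep("B", 3), c("A", "B", "C")),
                      levels = stripe_levels())
  expect_equal(mk_loglik(tr, cdB, matrix(0, 4, 4)), log(1 / 4))

  ## impossible history: different states joined by zero-length branches
  tr0 <- parse_phylo("(A:0,B:0);")
  cd0 <- morph_coding(c(A = "x", B = "y"), levels = c("x", "y"))
  expect_identical(mk_loglik(tr0, cd0, rand_Q(2)), -Inf)

  ## enumeration oracle on small random trees, k = 2 and k = 4
  set.seed(41)
  for (r in 1:6) {
    k <- if (r %% 2) 2L else 4L
    n <- sample(3:5, 1)
    tre <- ape::rtree(n)
    lv <- letters[seq_len(k)]
    cd <- rand_coding(tre, lv)
    Q <- rand_Q(k)
    expect_equal(mk_loglik(tre, cd, Q), enum_mk_loglik(tre, cd, Q),
                 tolerance = 1e-10)
  }

  ## invariance under joint relabeling of states and Q
  set.seed(42)
  tre <- ape::rtree(6)
  lv <- c("A", "B", "C", "D")
  cd <- rand_coding(tre, lv)
  Q <- rand_Q(4)
  perm <- c(3L, 1L, 4L, 2L)
  cd_p <- morph_coding(setNames(lv[perm][match(unlist(cd), lv)],
                                names(cd)), levels = lv)
  Q_p <- Q
  Q_p[perm, perm] <- Q
  expect_equal(mk_loglik(tre, cd, Q), mk_loglik(tre, cd_p, Q_p),
               tolerance = 1e-12)

  ## errors: uncoded tip, non-stochastic Q
  expect_error(mk_loglik(tre, morph_coding(c(t1 = "A"), levels = lv), Q),
               "absent")
  bad <- Q; bad[1, 2] <- bad[1, 2] + 1
  expect_error(mk_loglik(tre, cd, bad), "sum to zero")
})

test_that("polymorphic tips require enumeration unless ambiguity is requested", {
  tr <- parse_phylo("((A:1,B:1):1,C:2);")
  cd <- morph_coding(c(A = "C,D", B = "D", C = "C"),
                     levels = stripe_levels())
  Q <- rand_Q(4, 0.05, 0.2)
  expect_error(mk_loglik(tr, cd, Q), "polymorphic")
  ll_amb <- mk_loglik(tr, cd, Q, ambiguous = TRUE)
  ## ambiguity partial = sum of the two resolved likelihoods
  parts <- vapply(enumerate_codings(cd), function(c2)
    exp(mk_loglik(tr, c2, Q)), 0)
  expect_equal(ll_amb, log(sum(parts)), tolerance = 1e-10)
})

test_that("coding enumeration expands the polymorphism Cartesian product", {
  cd3 <- morph_coding(c(s1 = "C,D", s2 = "B,C", s3 = "A,B", s4 = "D"),
                      levels = stripe_levels())
  expect_length(enumerate_codings(cd3), 8L)
  expect_length(enumerate_codings(morph_coding(c(s1 = "A", s2 = "B"),
                                               levels = stripe_levels())),
                1L)
  cd2 <- morph_coding(c(s1 = "C,D", s2 = "A,B"), levels = stripe_levels())
  ec <- enumerate_codings(cd2)
  expect_length(ec, 4L)
  ## deterministic order and all resolutions distinct
  expect_identical(ec, enumerate_codings(cd2))
  expect_equal(anyDuplicated(names(ec)), 0L)
  expect_true(all(vapply(ec, function(x) all(lengths(x) == 1L), TRUE)))
})

test_that("ML fitting recovers a known symmetric rate and is reproducible", {
  spec <- build_model_matrix("ER", 4)
  Q_true <- make_rate_matrix(0.1, spec)
  hits <- 0L
  for (r in 1:20) {
    tre <- simulate_bd_tree(0.3, 0, 300, seed = 500 + r)
    cd <- simulate_mk(tre, Q_true, levels = stripe_levels(),
                      seed = 600 + r)$coding
    ft <- fit_mk(tre, cd, spec, n_starts = 2, seed = r)
    if (abs(ft$rates - 0.1) / 0.1 <= 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90% of replicates within 50% relative error

  ## bit-for-bit reproducibility under a fixed seed
  tre <- simulate_bd_tree(0.3, 0, 40, seed = 7)
  cd <- simulate_mk(tre, Q_true, levels = stripe_levels(), seed = 8)$coding
  f1 <- fit_mk(tre, cd, spec, n_starts = 3, seed = 5)
  f2 <- fit_mk(tre, cd, spec, n_starts = 3, seed = 5)
  expect_identical(f1, f2)

  ## single observed state: rates collapse and lnL = log prior mass
  cd1 <- morph_coding(setNames(rep("D", 40), tre$tip.label),
                      levels = stripe_levels())
  fs <- fit_mk(tre, cd1, spec, n_starts = 2, seed = 1)
  expect_lt(fs$rates, 1e-6)
  expect_equal(fs$loglik, log(1 / 4), tolerance = 1e-4)

  ## nesting: ER lnL cannot exceed ARD lnL
  fe <- fit_mk(tre, cd, build_model_matrix("ER", 4), n_starts = 2, seed = 2)
  fa <- fit_mk(tre, cd, build_model_matrix("ARD", 4), n_starts = 2,
               seed = 3)
  expect_lte(fe$loglik, fa$loglik + 1e-6)
})

test_that("likelihood-ratio test and AICc table follow their formulas", {
  mkf <- function(ll, k) structure(list(loglik = ll, k_params = k,
                                        model_id = paste0("m", k)),
                                   class = "mk_fit")
  eq <- likelihood_ratio_test(mkf(-10, 1), mkf(-10, 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  lr <- likelihood_ratio_test(mkf(-11.9205, 1), mkf(-10, 2))
  expect_equal(lr$df, 1L)
  expect_equal(lr$statistic, 3.841, tolerance = 1e-4)
  expect_equal(lr$p.value, pchisq(3.841, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(likelihood_ratio_test(mkf(-10, 1), mkf(-9, 12))$df, 11L)
  expect_error(likelihood_ratio_test(mkf(-9, 1), mkf(-10, 2)), "negative")

  expect_equal(aicc_table(list(mkf(-10, 2)), 30)$weight, 1)
  tw <- aicc_table(list(mkf(-10, 2), mkf(-10, 2)), 30)
  expect_equal(tw$weight, c(0.5, 0.5))
  ## AICc values {100, 104}: weights from the exp(-delta/2) formula
  half <- function(a) (a - 2 * 2 - 2 * 2 * 3 / (30 - 3)) / -2
  tb <- aicc_table(list(mkf(half(100), 2), mkf(half(104), 2)), 30)
  expect_equal(tb$delta_AICc, c(0, 4), tolerance = 1e-9)
  expect_equal(tb$weight, c(0.8808, 0.1192), tolerance = 1e-4)
  expect_lt(abs(sum(tb$weight) - 1), 1e-12)
  expect_error(aicc_table(list(mkf(-10, 5)), 6), "n must exceed")
})

test_that("marginal reconstruction matches symmetry and the joint enumeration", {
  ## two tips in different states under a symmetric model: root is 50/50
  tr2 <- parse_phylo("(A:1,B:1);")
  cd2 <- morph_coding(c(A = "x", B = "y"), levels = c("x", "y"))
  Qer <- make_rate_matrix(0.3, build_model_matrix("ER", 2))
  post2 <- marginal_asr(tr2, cd2, Qer)
  expect_equal(unname(post2["root", ]), c(0.5, 0.5))
  ## singleton tips carry a point mass
  expect_equal(unname(post2["A", ]), c(1, 0))

  set.seed(55)
  for (r in 1:3) {
    tre <- ape::rtree(4)
    k <- if (r == 2) 4L else 2L
    lv <- letters[seq_len(k)]
    cd <- rand_coding(tre, lv)
    Q <- rand_Q(k)
    expect_equal(unname(marginal_asr(tre, cd, Q)),
                 unname(enum_mk_asr(tre, cd, Q)), tolerance = 1e-9)
  }
})
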