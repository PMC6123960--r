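## Independent oracles used across the suite.  They deliberately avoid the
## package's own computational paths: matrix exponentials come from
## Matrix::expm (or a truncated Taylor series), likelihoods from exhaustive
## enumeration over internal-node states, and bridge expectations from
## dense numerical integration.

## matrix exponential by truncated Taylor series (plain summation)
series_expm <- function(A, terms = 60L) {
  n <- nrow(A)
  out <- diag(n)
  term <- diag(n)
  for (j in seq_len(terms)) {
    term <- term %*% A / j
    out <- out + term
  }
  out
}

## exhaustive Mk likelihood: sum over every internal-node state assignment
enum_mk_loglik <- function(tree, coding, Q, prior = NULL) {
  k <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / k, k)
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  lv <- attr(coding, "levels")
  tip_state <- vapply(tr$tip.label, function(s) match(coding[[s]], lv)[1L],
                      0L)
  P <- lapply(tr$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    s <- c(tip_state, grid[r, ])
    pr <- prior[s[nt + 1L]]
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * P[[e]][s[tr$edge[e, 1L]], s[tr$edge[e, 2L]]]
    total <- total + pr
  }
  log(total)
}

## exhaustive marginal posteriors at every node, from the same enumeration
enum_mk_asr <- function(tree, coding, Q, prior = NULL) {
  k <- nrow(Q)
  if (is.null(prior)) prior <- rep(1 / k, k)
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  lv <- attr(coding, "levels")
  tip_state <- vapply(tr$tip.label, function(s) match(coding[[s]], lv)[1L],
                      0L)
  P <- lapply(tr$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  post <- matrix(0, nt + nn, k)
  for (r in seq_len(nrow(grid))) {
    s <- c(tip_state, grid[r, ])
    pr <- prior[s[nt + 1L]]
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * P[[e]][s[tr$edge[e, 1L]], s[tr$edge[e, 2L]]]
    for (v in seq_len(nt + nn)) post[v, s[v]] <- post[v, s[v]] + pr
  }
  post / rowSums(post)
}

## random rate matrix with all off-diagonal rates positive
rand_Q <- function(k, lo = 0.05, hi = 0.6) {
  Q <- matrix(runif(k * k, lo, hi), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

## random singleton coding over a tree's tips
rand_coding <- function(tree, levels) {
  morph_coding(setNames(sample(levels, length(tree$tip.label),
                               replace = TRUE), tree$tip.label),
               levels = levels)
}

## expected number of i->j transitions on one branch with fixed endpoints,
## by dense numerical integration of q_ij P_ai(s) P_jb(t - s) / P_ab(t)
branch_expected_transitions <- function(Q, t_e, a, b, i, j, n_grid = 2000L) {
  Pt <- as.matrix(Matrix::expm(Q * t_e))
  s <- seq(0, t_e, length.out = n_grid)
  f <- vapply(s, function(u) {
    as.matrix(Matrix::expm(Q * u))[a, i] *
      as.matrix(Matrix::expm(Q * (t_e - u)))[j, b]
  }, 0)
  Q[i, j] * sum((f[-1L] + f[-n_grid]) / 2 * diff(s)) / Pt[a, b]
}

## shared demo dataset (generated once per test session)
demo_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_clownfish_demo()
    cache
  }
})
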