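## Multi-state speciation-extinction (MuSSE) likelihoods with a shared
## speciation rate lambda and extinction rate mu across character states
## (the constraint that keeps the stripe models identifiable on a 30-species
## radiation), a constrained transition matrix Q, and a global sampling
## fraction f correcting for species missing at random from the tree.

#' MuSSE log-likelihood
#'
#' Joint likelihood of tree shape and a multi-state character under a
#' birth-death process with state transitions.  Extinction (E) and data (D)
#' ODEs are integrated tip-to-root along every branch with an adaptive
#' Runge-Kutta scheme; daughter D vectors are multiplied with one speciation
#' rate at each node.  With shared lambda/mu the character cannot affect
#' diversification, so differences of this likelihood across Q matrices
#' reduce to differences of the Mk likelihood (an identity the test suite
#' exploits).
#'
#' @inheritParams mk_loglik
#' @param lambda speciation rate (events/Myr), shared across states.
#' @param mu extinction rate (events/Myr), shared across states.
#' @param f sampling fraction in (0, 1]: the probability that an extant
#'   species is present in the tree.
#' @param root_mode `"obs"` (likelihood-weighted root state combination,
#'   the default), `"flat"`, or `"given"` with weights in `root_p`.
#' @param root_p root state weights when `root_mode = "given"`.
#' @param condition_surv condition the likelihood on survival of the two
#'   root lineages (division by `lambda (1 - E_root)^2`).
#' @param atol,rtol ODE tolerances.
#' @param ultra_tol relative tolerance for the ultrametricity check.
#' @return The log-likelihood.
#' @export
musse_loglik <- function(tree, coding, lambda, mu, Q, f = 1,
                         root_mode = c("obs", "flat", "given"),
                         root_p = NULL, condition_surv = TRUE,
                         ambiguous = FALSE, atol = 1e-8, rtol = 1e-8,
                         ultra_tol = 1e-3) {
  root_mode <- match.arg(root_mode)
  stopifnot(length(lambda) == 1L, length(mu) == 1L)
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (!is.finite(mu) || mu < 0) stop("mu must be >= 0")
  if (!is.numeric(f) || f <= 0 || f > 1) stop("f must be in (0, 1]")
  check_rate_matrix(Q)
  if (!is_ultrametric_tol(tree, ultra_tol))
    stop("MuSSE requires an ultrametric tree")
  k <- nrow(Q)
  lv <- coding_levels(coding)
  if (length(lv) != k) stop("Q dimension does not match coding levels")
  rp <- rep(1 / k, k)
  if (root_mode == "given") {
    stopifnot(is.numeric(root_p), length(root_p) == k,
              abs(sum(root_p) - 1) < 1e-8)
    rp <- root_p
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  tipD <- tip_indicator(tr, coding, ambiguous = ambiguous) * f
  out <- musse_loglik_cpp(tr$edge, tr$edge.length,
                          length(tr$tip.label), tr$Nnode, tipD, 1 - f,
                          rep(lambda, k), rep(mu, k), Q,
                          match(root_mode, c("obs", "flat", "given")) - 1L,
                          rp, condition_surv, atol, rtol)
  out$loglik
}

musse_model_labels <- c(
  i = "free",
  ii = "symmetric rates of transition among states",
  iii = "loss or gain of two stripes forced to 0",
  iv = "model ii + model iii")

#' Maximum-likelihood MuSSE fit under a constrained transition structure
#'
#' Optimizes shared `lambda`, `mu` and the free transition-rate classes of
#' the chosen model (i: 12 classes, ii: 6, iii: 6, iv: 3; parameter counts
#' 14, 8, 8 and 5 including lambda and mu) on the log scale with seeded
#' multi-start L-BFGS-B.
#'
#' @inheritParams musse_loglik
#' @param model_id `"i"`, `"ii"`, `"iii"` or `"iv"`.
#' @param n_starts optimizer starts.
#' @param seed integer seed.
#' @return An object of class `"musse_fit"`: `lambda`, `mu`, `rates`, `Q`,
#'   `loglik`, `k_params`, `AIC`, `AICc`, `n`, `model_id`.
#' @export
fit_musse <- function(tree, coding, model_id, f = 1, n_starts = 5L,
                      seed = 1L, root_mode = "obs",
                      condition_surv = TRUE, ambiguous = FALSE,
                      atol = 1e-8, rtol = 1e-8) {
  spec <- build_model_matrix(model_id, length(coding_levels(coding)))
  ncl <- attr(spec, "n_classes")
  n <- length(tree$tip.label)
  depth <- max(tip_depths(tree))
  lb <- log(1e-9); ub <- log(1e3)
  nll <- function(par) {
    Q <- make_rate_matrix(exp(par[-(1:2)]), spec)
    ll <- tryCatch(
      musse_loglik(tree, coding, exp(par[1L]), exp(par[2L]), Q, f = f,
                   root_mode = root_mode, condition_surv = condition_surv,
                   ambiguous = ambiguous, atol = atol, rtol = rtol),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  ## heuristic start: Yule-ish lambda, small mu, moderate q
  lam0 <- max(log(n / 2) / depth, 1e-3)
  base <- c(log(lam0), log(lam0 / 10), rep(log(0.5 / depth), ncl))
  set.seed(seed)
  starts <- matrix(rep(base, each = n_starts), n_starts)
  if (n_starts > 1L)
    starts[-1L, ] <- starts[-1L, ] +
      rnorm((n_starts - 1L) * length(base), 0, 1)
  starts <- pmin(pmax(starts, lb + 1), ub - 1)
  best <- NULL
  for (s in seq_len(n_starts)) {
    op <- tryCatch(
      optim(starts[s, ], nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best) || best$value >= 1e10)
    stop("MuSSE optimization failed to converge from any start")
  kpar <- ncl + 2L
  ll <- -best$value
  structure(list(lambda = exp(best$par[1L]), mu = exp(best$par[2L]),
                 rates = exp(best$par[-(1:2)]),
                 Q = make_rate_matrix(exp(best$par[-(1:2)]), spec),
                 loglik = ll, k_params = kpar,
                 AIC = -2 * ll + 2 * kpar, AICc = aicc(ll, kpar, n),
                 n = n, f = f, model_id = model_id, spec = spec,
                 convergence = best$convergence, seed = seed),
            class = "musse_fit")
}

#' @export
print.musse_fit <- function(x, ...) {
  cat("MuSSE fit (model ", x$model_id, "): lnL = ", format(x$loglik),
      ", k = ", x$k_params, ", AICc = ", format(x$AICc), "\n", sep = "")
  cat("lambda = ", signif(x$lambda, 4), ", mu = ", signif(x$mu, 4),
      ", q = ", paste(signif(x$rates, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Model-comparison table over the four stripe-evolution models
#'
#' Fits models i-iv and ranks them by AICc with Akaike weights.  When the
#' coding is polymorphic, one table is produced per enumerated coding
#' combination, plus per-coding model-iv rate estimates so their mean and
#' SD across combinations can be reported.
#'
#' @inheritParams fit_musse
#' @param models subset of `c("i", "ii", "iii", "iv")`.
#' @return For a fixed coding, a `data.frame` (an [aicc_table()] with a
#'   `constraint` column); for a polymorphic coding, a list of class
#'   `"musse_model_tables"` with one table per coding and `rates_iv`, the
#'   per-coding model-iv rate matrix estimates.
#' @export
musse_model_table <- function(tree, coding, f = 1,
                              models = c("i", "ii", "iii", "iv"),
                              n_starts = 3L, seed = 1L, ...) {
  codings <- enumerate_codings(coding)
  n <- length(tree$tip.label)
  one_table <- function(cd, seed_c) {
    fits <- lapply(seq_along(models), function(j)
      fit_musse(tree, cd, models[j], f = f, n_starts = n_starts,
                seed = seed_c + j, ...))
    names(fits) <- models
    tab <- aicc_table(fits, n)
    tab$constraint <- musse_model_labels[tab$model]
    list(table = tab[, c("model", "constraint", "k", "loglik", "AIC",
                         "AICc", "delta_AICc", "weight")],
         rates_iv = if ("iv" %in% models) fits[["iv"]]$rates else NULL)
  }
  if (length(codings) == 1L) {
    return(one_table(codings[[1L]], seed)$table)
  }
  res <- lapply(seq_along(codings), function(i)
    one_table(codings[[i]], seed + 100L * i))
  tables <- lapply(res, `[[`, "table")
  names(tables) <- names(codings)
  rates_iv <- do.call(rbind, lapply(res, `[[`, "rates_iv"))
  if (!is.null(rates_iv)) rownames(rates_iv) <- names(codings)
  structure(list(tables = tables, rates_iv = rates_iv),
            class = "musse_model_tables")
}

#' @export
print.musse_model_tables <- function(x, ...) {
  cat("MuSSE model tables over", length(x$tables), "coding combinations\n")
  best <- vapply(x$tables, function(t) t$model[1L], "")
  cat("best model per coding:", paste(best, collapse = ", "), "\n")
  if (!is.null(x$rates_iv)) {
    cat("model-iv rates, mean +/- SD across codings:\n")
    m <- colMeans(x$rates_iv)
    s <- apply(x$rates_iv, 2L, sd)
    for (j in seq_along(m))
      cat("  q", j, ": ", signif(m[j], 3), " +/- ", signif(s[j], 2),
          "\n", sep = "")
  }
  invisible(x)
}
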