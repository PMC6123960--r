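## Mk (continuous-time Markov) models for discrete characters on a
## phylogeny, with arbitrary constraint structures on the transition-rate
## matrix Q.  The four candidate structures for the stripe character are:
##   i   all off-diagonal rates free and distinct
##   ii  symmetric rates, q_ij = q_ji
##   iii gain or loss of two or more stripes forbidden
##       (q31 = q41 = q42 = q13 = q14 = q24 = 0, states ordered A..D)
##   iv  constraints of ii and iii combined: three symmetric stepwise rates
##       A<->B, B<->C, C<->D

#' Build a constrained transition-matrix structure
#'
#' Returns a k x k index matrix over off-diagonal cells: 0 forces the rate
#' to zero, equal positive indices share one free parameter.
#'
#' @param model_id one of `"i"`, `"ii"`, `"iii"`, `"iv"` (see file header);
#'   `"ER"` (single shared rate) and `"ARD"` (alias of `"i"`) are also
#'   accepted for the classical equal-rates / all-rates-different models.
#' @param k number of states (must be 4 for models iii and iv, whose zero
#'   set is defined for the four ordered stripe morphs).
#' @return An integer matrix of class `"constraint_spec"` with attributes
#'   `model_id` and `n_classes`.
#' @examples
#' build_model_matrix("iv", 4)  # 3 free classes
#' @export
build_model_matrix <- function(model_id, k = 4L) {
  model_id <- match.arg(model_id, c("i", "ii", "iii", "iv", "ER", "ARD"))
  if (model_id == "ARD") model_id <- "i"
  stopifnot(k >= 2L)
  if (model_id %in% c("iii", "iv") && k != 4L)
    stop("models iii and iv are defined for k = 4 ordered states")
  m <- matrix(0L, k, k)
  off <- which(row(m) != col(m))
  if (model_id == "ER") {
    m[off] <- 1L
  } else if (model_id == "i") {
    m[off] <- seq_along(off)
  } else if (model_id == "ii") {
    idx <- 0L
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      idx <- idx + 1L
      m[a, b] <- idx
      m[b, a] <- idx
    }
  } else {
    ## forbidden jumps of two or more states (1-based rows = from)
    zero <- rbind(c(3L, 1L), c(4L, 1L), c(4L, 2L),
                  c(1L, 3L), c(1L, 4L), c(2L, 4L))
    keep <- matrix(TRUE, k, k)
    keep[zero] <- FALSE
    if (model_id == "iii") {
      cells <- which(row(m) != col(m) & keep)
      m[cells] <- seq_along(cells)
    } else {
      ## iv: symmetric classes on the surviving adjacent pairs
      cls <- 0L
      for (a in seq_len(k - 1L)) {
        b <- a + 1L
        cls <- cls + 1L
        m[a, b] <- cls
        m[b, a] <- cls
      }
    }
  }
  diag(m) <- NA_integer_
  structure(m, class = "constraint_spec", model_id = model_id,
            n_classes = length(unique(m[!is.na(m) & m > 0L])))
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat("constraint_spec (model ", attr(x, "model_id"), "): ",
      attr(x, "n_classes"), " free rate classes\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Assemble a transition-rate matrix from class rates
#'
#' @param rates non-negative rates, one per parameter class of `spec`.
#' @param spec a [build_model_matrix()] structure.
#' @return A k x k rate matrix with zero row sums.
#' @export
make_rate_matrix <- function(rates, spec) {
  ncl <- attr(spec, "n_classes")
  stopifnot(length(rates) == ncl, all(rates >= 0), all(is.finite(rates)))
  k <- nrow(spec)
  Q <- matrix(0, k, k)
  for (cls in seq_len(ncl))
    Q[which(!is.na(spec) & spec == cls)] <- rates[cls]
  diag(Q) <- -rowSums(Q)
  Q
}

check_rate_matrix <- function(Q) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  off <- Q[row(Q) != col(Q)]
  if (any(!is.finite(Q)) || any(off < 0))
    stop("Q must have finite entries and non-negative off-diagonal rates")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
    stop("Q rows must sum to zero")
  invisible(Q)
}

resolve_root_prior <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("uniform", "stationary"))
    if (root_prior == "uniform") return(rep(1 / k, k))
    ## stationary distribution: left null vector of Q
    ns <- t(rbind(t(Q), rep(1, k)))
    pi <- qr.solve(ns, c(rep(0, k), 1))
    pi <- pmax(pi, 0)
    return(pi / sum(pi))
  }
  stopifnot(is.numeric(root_prior), length(root_prior) == k,
            abs(sum(root_prior) - 1) < 1e-8, all(root_prior >= 0))
  root_prior
}

## Felsenstein pruning engine.  Returns the pieces reused by the marginal
## reconstruction and the stochastic-mapping sampler: postordered tree,
## per-edge transition matrices, scaled partials, per-edge propagated
## child messages, and the log-likelihood.
mk_engine <- function(tree, coding, Q, root_prior = "uniform",
                      ambiguous = FALSE) {
  check_rate_matrix(Q)
  k <- nrow(Q)
  lv <- coding_levels(coding)
  if (length(lv) != k)
    stop("Q dimension (", k, ") does not match coding levels (",
         length(lv), ")")
  prior <- resolve_root_prior(root_prior, Q)
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  ntot <- nt + nn
  tipmat <- tip_indicator(tree, coding, ambiguous = ambiguous)
  partial <- matrix(0, k, ntot)
  partial[, seq_len(nt)] <- tipmat
  Pm <- lapply(tree$edge.length, function(t) expm_pade(Q * t))
  edge_up <- vector("list", nrow(tree$edge))
  acc <- matrix(1, k, ntot)
  logcomp <- 0
  bad <- FALSE
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch > nt) {  # finalize internal child from its accumulated messages
      s <- sum(acc[, ch])
      if (s <= 0 || !is.finite(s)) { bad <- TRUE; break }
      partial[, ch] <- acc[, ch] / s
      logcomp <- logcomp + log(s)
    }
    v <- drop(Pm[[e]] %*% partial[, ch])
    edge_up[[e]] <- v
    pa <- tree$edge[e, 1L]
    acc[, pa] <- acc[, pa] * v
  }
  root <- nt + 1L
  if (!bad) {
    s <- sum(acc[, root])
    if (s <= 0 || !is.finite(s)) bad <- TRUE
    else {
      partial[, root] <- acc[, root] / s
      logcomp <- logcomp + log(s)
    }
  }
  loglik <- if (bad) -Inf else log(sum(prior * partial[, root])) + logcomp
  list(tree = tree, k = k, levels = lv, prior = prior, Pm = Pm,
       partial = partial, edge_up = edge_up, ntip = nt, root = root,
       loglik = loglik)
}

#' Mk log-likelihood of a discrete character on a tree
#'
#' Felsenstein pruning: tip partials are indicators over each tip's state
#' set (polymorphic tips may be treated as ambiguous), branch propagation is
#' `exp(Q t)`, and the root combines partials under `root_prior`.
#'
#' @param tree a `phylo` object.
#' @param coding a [morph_coding()] covering all tips.
#' @param Q transition-rate matrix (rows sum to zero).
#' @param root_prior `"uniform"` (default), `"stationary"`, or a probability
#'   vector over states.
#' @param ambiguous treat polymorphic tips as state ambiguity instead of
#'   erroring (per-coding enumeration is the default analysis route).
#' @return The log-likelihood (may be `-Inf` for impossible data).
#' @export
mk_loglik <- function(tree, coding, Q, root_prior = "uniform",
                      ambiguous = FALSE) {
  mk_engine(tree, coding, Q, root_prior, ambiguous)$loglik
}

#' Maximum-likelihood fit of a constrained Mk model
#'
#' Optimizes the free rate classes of `spec` on the log scale with
#' box constraints (rates in `[1e-9, 1e3]` per Myr) and seeded multi-start
#' L-BFGS-B.  Reproducible for a fixed seed.
#'
#' @inheritParams mk_loglik
#' @param spec a [build_model_matrix()] structure.
#' @param n_starts number of optimizer starts (first start is a
#'   deterministic heuristic, the rest are jittered).
#' @param seed integer seed.
#' @return An object of class `"mk_fit"`: rates, `Q`, `loglik`, `k_params`,
#'   `AIC`, `AICc`, `n` (tips) and optimizer diagnostics.
#' @export
fit_mk <- function(tree, coding, spec, n_starts = 10L, seed = 1L,
                   root_prior = "uniform", ambiguous = FALSE) {
  stopifnot(inherits(spec, "constraint_spec"))
  lv <- coding_levels(coding)
  if (length(unique(unlist(coding[tree$tip.label]))) < 2L &&
      attr(spec, "n_classes") > 0L) {
    ## single observed state: all rates at the lower bound is the MLE
  }
  ncl <- attr(spec, "n_classes")
  depth <- max(tip_depths(tree))
  lb <- log(1e-9); ub <- log(1e3)
  nll <- function(lpar) {
    Q <- make_rate_matrix(exp(lpar), spec)
    ll <- mk_loglik(tree, coding, Q, root_prior, ambiguous)
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  starts <- matrix(log(1 / depth), n_starts, ncl)
  if (n_starts > 1L)
    starts[-1L, ] <- starts[-1L, ] + rnorm((n_starts - 1L) * ncl, 0, 1.5)
  starts <- pmin(pmax(starts, lb + 1), ub - 1)
  best <- NULL
  diags <- list()
  for (s in seq_len(n_starts)) {
    op <- tryCatch(
      optim(starts[s, ], nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(op)) next
    diags[[length(diags) + 1L]] <- op
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best) || best$value >= 1e10)
    stop("Mk optimization failed to converge from any start; ",
         "best objective: ",
         if (is.null(best)) "none" else format(best$value))
  rates <- exp(best$par)
  Q <- make_rate_matrix(rates, spec)
  n <- length(tree$tip.label)
  ll <- -best$value
  structure(list(rates = rates, Q = Q, loglik = ll, k_params = ncl,
                 AIC = -2 * ll + 2 * ncl,
                 AICc = aicc(ll, ncl, n), n = n,
                 model_id = attr(spec, "model_id"), spec = spec,
                 convergence = best$convergence, seed = seed,
                 levels = lv),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (model ", x$model_id, "): lnL = ", format(x$loglik),
      ", k = ", x$k_params, ", AICc = ", format(x$AICc), "\n", sep = "")
  cat("rates: ", paste(signif(x$rates, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

## sample-size-corrected AIC
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood-ratio test of nested Mk or MuSSE fits
#'
#' @param fit_nested,fit_full fitted models with `loglik` and `k_params`;
#'   the nested model must have fewer free parameters.
#' @param tol tolerance below zero for the statistic before declaring an
#'   optimizer failure.
#' @return A list with `statistic`, `df` and `p.value` (chi-square upper
#'   tail).
#' @export
likelihood_ratio_test <- function(fit_nested, fit_full, tol = 1e-6) {
  stopifnot(fit_nested$k_params < fit_full$k_params)
  stat <- 2 * (fit_full$loglik - fit_nested$loglik)
  if (stat < -tol)
    stop("negative LRT statistic (", format(stat),
         "): the full-model optimizer likely failed")
  stat <- max(stat, 0)
  df <- fit_full$k_params - fit_nested$k_params
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' AICc comparison table
#'
#' Ranks fitted models by AICc and attaches Akaike weights,
#' `exp(-delta/2) / sum(exp(-delta/2))`.  A delta of 4 or more is the
#' conventional support threshold used throughout this package.  Plain AIC
#' is reported alongside AICc.
#'
#' @param fits list of fitted models (`mk_fit` or `musse_fit`).
#' @param n sample size for the AICc correction (number of tips).
#' @return A `data.frame` with columns `model`, `k`, `loglik`, `AIC`,
#'   `AICc`, `delta_AICc`, `weight`, sorted best first.
#' @export
aicc_table <- function(fits, n) {
  stopifnot(length(fits) >= 1L)
  k <- vapply(fits, function(f) as.numeric(f$k_params), 0)
  if (any(n <= k + 1)) stop("AICc undefined: n must exceed k + 1 for all fits")
  ll <- vapply(fits, function(f) f$loglik, 0)
  id <- vapply(seq_along(fits), function(i) {
    m <- fits[[i]]$model_id
    if (is.null(m)) paste0("model", i) else as.character(m)
  }, "")
  ac <- aicc(ll, k, n)
  d <- ac - min(ac)
  w <- exp(-d / 2)
  w <- w / sum(w)
  out <- data.frame(model = id, k = k, loglik = ll, AIC = -2 * ll + 2 * k,
                    AICc = ac, delta_AICc = d, weight = w,
                    stringsAsFactors = FALSE)
  out[order(out$AICc), , drop = FALSE]
}

#' Marginal ancestral-state reconstruction
#'
#' Standard two-pass marginal reconstruction: the pruning up-pass computes
#' subtree partials, a preorder down-pass computes the complementary
#' likelihood of everything outside each subtree, and their product gives
#' each node's posterior state distribution.
#'
#' @inheritParams mk_loglik
#' @return A matrix (tips + internal nodes) x states of posterior
#'   probabilities; each row sums to 1.  Rows follow ape node numbering,
#'   tip rows are named by tip label.
#' @export
marginal_asr <- function(tree, coding, Q, root_prior = "uniform",
                         ambiguous = FALSE) {
  eng <- mk_engine(tree, coding, Q, root_prior, ambiguous)
  if (!is.finite(eng$loglik)) stop("data have zero likelihood under Q")
  tr <- eng$tree
  k <- eng$k
  ntot <- eng$ntip + tr$Nnode
  down <- matrix(0, k, ntot)
  down[, eng$root] <- eng$prior
  ## children edge lists per parent
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder
    pa <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    sib <- setdiff(kids[[as.character(pa)]], e)
    msg <- down[, pa]
    for (e2 in sib) msg <- msg * eng$edge_up[[e2]]
    v <- drop(crossprod(eng$Pm[[e]], msg))
    s <- sum(v)
    down[, ch] <- if (s > 0) v / s else v
  }
  post <- t(down * eng$partial)
  post <- post / rowSums(post)
  colnames(post) <- eng$levels
  rownames(post) <- c(tr$tip.label, rep("", tr$Nnode))
  rownames(post)[eng$root] <- "root"
  ## map back to the caller's node numbering (identical: reorder.phylo
  ## permutes edges only, node indices are preserved)
  post
}
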