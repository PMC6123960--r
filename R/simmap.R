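## Stochastic character mapping: sample complete character histories
## conditional on tip data and a rate matrix Q, then summarize the ensemble.
## Node states are drawn from their joint conditional distribution (root
## from its posterior, then descending conditional draws); branch interiors
## are endpoint-conditioned CTMC bridges sampled by uniformization (the
## dominated-Poisson construction).  A naive rejection sampler is kept as an
## independent cross-check for the test suite.

#' Sample stochastic character histories
#'
#' @inheritParams mk_loglik
#' @param n_maps number of histories to sample.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return An object of class `"simmap_ensemble"` holding the (postordered)
#'   tree, the sampled node states (`n_maps` x nodes matrix), the within-
#'   branch transition events per edge, the generating `Q` and the seed.
#'   Use [get_history()] to materialize one history as per-branch
#'   (state, duration) segments and [summarize_simmap()] for ensemble
#'   summaries.
#' @export
sample_histories <- function(tree, coding, Q, root_prior = "uniform",
                             n_maps = 10000L, seed = 1L,
                             ambiguous = FALSE) {
  stopifnot(n_maps >= 1L)
  eng <- mk_engine(tree, coding, Q, root_prior, ambiguous)
  if (!is.finite(eng$loglik))
    stop("data have zero likelihood under Q; cannot sample histories")
  tr <- eng$tree
  k <- eng$k
  ntot <- eng$ntip + tr$Nnode
  ne <- nrow(tr$edge)
  set.seed(seed)

  ## ---- joint node-state sampling, vectorized across maps ----
  S <- matrix(0L, n_maps, ntot)
  pr <- eng$prior * eng$partial[, eng$root]
  S[, eng$root] <- sample.int(k, n_maps, replace = TRUE, prob = pr)
  for (e in rev(seq_len(ne))) {  # preorder
    pa <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    M <- eng$Pm[[e]] * rep(eng$partial[, ch], each = k)
    for (i in seq_len(k)) {
      idx <- which(S[, pa] == i)
      if (!length(idx)) next
      if (sum(M[i, ]) <= 0)
        stop("impossible endpoint configuration on edge ", e)
      S[idx, ch] <- sample.int(k, length(idx), replace = TRUE,
                               prob = M[i, ])
    }
  }

  ## ---- endpoint-conditioned bridges per edge ----
  mu_max <- max(-diag(Q))
  events <- vector("list", ne)
  for (e in seq_len(ne)) {
    t_e <- tr$edge.length[e]
    a <- S[, tr$edge[e, 1L]]
    b <- S[, tr$edge[e, 2L]]
    if (mu_max <= 0 || t_e <= 0) {
      if (any(a != b)) stop("state change on a zero-length branch ", e)
      events[[e]] <- list(map = integer(0), time = numeric(0),
                          from = integer(0), to = integer(0))
      next
    }
    events[[e]] <- sample_bridges(Q, t_e, a, b, mu_max, edge_id = e)
  }

  structure(list(tree = tr, levels = eng$levels, Q = Q, seed = seed,
                 n_maps = n_maps, node_states = S, events = events,
                 prior = eng$prior),
            class = "simmap_ensemble")
}

## Vectorized uniformization bridge over one edge for all maps.
## a, b: endpoint state vectors (length n_maps).  Returns flat event lists.
sample_bridges <- function(Q, t_e, a, b, mu_max, edge_id) {
  k <- nrow(Q)
  n_maps <- length(a)
  R <- diag(k) + Q / mu_max
  lam <- mu_max * t_e
  n_max <- max(5L, qpois(1 - 1e-12, lam) + 2L)
  Rpow <- vector("list", n_max + 1L)
  Rpow[[1L]] <- diag(k)
  for (n in seq_len(n_max)) Rpow[[n + 1L]] <- Rpow[[n]] %*% R
  ## weights over the number of virtual jumps, per endpoint pair
  W <- array(0, c(n_max + 1L, k, k))
  pois <- dpois(0:n_max, lam)
  for (n in 0:n_max) W[n + 1L, , ] <- pois[n + 1L] * Rpow[[n + 1L]]

  N <- integer(n_maps)
  pair <- (a - 1L) * k + b
  for (p in unique(pair)) {
    ai <- (p - 1L) %/% k + 1L
    bi <- (p - 1L) %% k + 1L
    w <- W[, ai, bi]
    tot <- sum(w)
    if (tot <= 0)
      stop("bridge sampling failure on edge ", edge_id,
           ": endpoint pair has zero probability")
    idx <- which(pair == p)
    N[idx] <- findInterval(runif(length(idx)), cumsum(w / tot))
  }

  ev_map <- list(); ev_time <- list(); ev_from <- list(); ev_to <- list()
  push <- function(m, tm, fr, to) {
    i <- length(ev_map) + 1L
    ev_map[[i]] <<- m; ev_time[[i]] <<- tm
    ev_from[[i]] <<- fr; ev_to[[i]] <<- to
  }
  ## N = 1 with distinct endpoints: single real jump at a uniform time
  one <- which(N == 1L & a != b)
  if (length(one))
    push(one, runif(length(one)) * t_e, a[one], b[one])
  ## N >= 2: walk the discrete bridge through R
  multi <- which(N >= 2L)
  for (m in multi) {
    nj <- N[m]
    times <- sort(runif(nj)) * t_e
    s <- integer(nj + 1L)
    s[1L] <- a[m]
    for (j in seq_len(nj - 1L)) {
      p <- R[s[j], ] * Rpow[[nj - j + 1L]][, b[m]]
      s[j + 1L] <- sample.int(k, 1L, prob = p)
    }
    s[nj + 1L] <- b[m]
    real <- which(s[-1L] != s[-(nj + 1L)])
    if (length(real))
      push(rep.int(m, length(real)), times[real], s[real], s[real + 1L])
  }
  list(map = as.integer(unlist(ev_map)), time = as.numeric(unlist(ev_time)),
       from = as.integer(unlist(ev_from)), to = as.integer(unlist(ev_to)))
}

## Standalone single-branch endpoint-conditioned sampler (uniformization),
## returning jump times and states; used by tests against the rejection
## oracle.
sample_path_unif <- function(Q, t_e, a, b) {
  mu_max <- max(-diag(Q))
  if (mu_max <= 0 || t_e <= 0) {
    if (a != b) stop("impossible endpoints on a zero-length branch")
    return(list(time = numeric(0), from = integer(0), to = integer(0)))
  }
  ev <- sample_bridges(Q, t_e, a, b, mu_max, edge_id = NA)
  o <- order(ev$time)
  list(time = ev$time[o], from = ev$from[o], to = ev$to[o])
}

## Naive rejection sampler: forward-simulate from state a until the branch
## end lands in b.  Exponential in the rarity of (a -> b); test oracle only.
sample_path_rejection <- function(Q, t_e, a, b, max_tries = 10000L) {
  k <- nrow(Q)
  for (tries in seq_len(max_tries)) {
    s <- a; tm <- 0
    times <- numeric(0); from <- integer(0); to <- integer(0)
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      tm <- tm + rexp(1L, rate)
      if (tm >= t_e) break
      s_new <- sample.int(k, 1L, prob = pmax(Q[s, ], 0) *
                            (seq_len(k) != s))
      times <- c(times, tm); from <- c(from, s); to <- c(to, s_new)
      s <- s_new
    }
    if (s == b) return(list(time = times, from = from, to = to))
  }
  stop("rejection sampling failed after ", max_tries, " tries")
}

#' Materialize one sampled history
#'
#' @param ensemble a [sample_histories()] result.
#' @param m history index in `1:n_maps`.
#' @return A list with `node_states` and `segments`: per edge a matrix with
#'   columns `state` and `duration`; durations sum to the branch length,
#'   the first segment starts in the parent's state and the last ends in
#'   the child's state.
#' @export
get_history <- function(ensemble, m) {
  stopifnot(inherits(ensemble, "simmap_ensemble"),
            m >= 1L, m <= ensemble$n_maps)
  tr <- ensemble$tree
  segs <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    ev <- ensemble$events[[e]]
    sel <- which(ev$map == m)
    t_e <- tr$edge.length[e]
    a <- ensemble$node_states[m, tr$edge[e, 1L]]
    if (!length(sel)) {
      segs[[e]] <- cbind(state = a, duration = t_e)
    } else {
      o <- sel[order(ev$time[sel])]
      tms <- c(0, ev$time[o], t_e)
      st <- c(ev$from[o][1L], ev$to[o])
      segs[[e]] <- cbind(state = st, duration = diff(tms))
    }
  }
  list(node_states = ensemble$node_states[m, ], segments = segs)
}

#' Summarize a stochastic-mapping ensemble
#'
#' @param ensemble a [sample_histories()] result.
#' @return An object of class `"simmap_summary"`: `node_freq` (nodes x
#'   states posterior frequencies), `transitions` (expected i -> j counts
#'   per history), `dwell` (expected time per state), `n_transitions`
#'   (per-history totals) and `branch_majority` (per edge, the parent and
#'   child modal-state frequencies).
#' @export
summarize_simmap <- function(ensemble) {
  stopifnot(inherits(ensemble, "simmap_ensemble"), ensemble$n_maps >= 1L)
  tr <- ensemble$tree
  k <- length(ensemble$levels)
  n_maps <- ensemble$n_maps
  ntot <- ncol(ensemble$node_states)

  node_freq <- t(apply(ensemble$node_states, 2L,
                       function(s) tabulate(s, k))) / n_maps
  colnames(node_freq) <- ensemble$levels
  rownames(node_freq) <- c(tr$tip.label, rep("", tr$Nnode))
  rownames(node_freq)[length(tr$tip.label) + 1L] <- "root"

  trans <- matrix(0, k, k, dimnames = list(ensemble$levels, ensemble$levels))
  n_trans <- integer(n_maps)
  dwell <- numeric(k)
  for (e in seq_len(nrow(tr$edge))) {
    ev <- ensemble$events[[e]]
    t_e <- tr$edge.length[e]
    pa_states <- ensemble$node_states[, tr$edge[e, 1L]]
    ## baseline: whole branch dwelt in the parent state
    dwell <- dwell + tabulate(pa_states, k) * t_e
    if (!length(ev$map)) next
    for (j in seq_along(ev$map)) trans[ev$from[j], ev$to[j]] <-
        trans[ev$from[j], ev$to[j]] + 1
    n_trans_e <- tabulate(ev$map, n_maps)
    n_trans <- n_trans + n_trans_e
    ## dwell corrections for maps with events on this edge
    for (m in unique(ev$map)) {
      sel <- which(ev$map == m)
      o <- sel[order(ev$time[sel])]
      tms <- c(0, ev$time[o], t_e)
      st <- c(ev$from[o][1L], ev$to[o])
      dd <- diff(tms)
      dwell[st[1L]] <- dwell[st[1L]] - t_e  # remove baseline
      for (i in seq_along(st)) dwell[st[i]] <- dwell[st[i]] + dd[i]
    }
  }
  trans <- trans / n_maps
  dwell <- dwell / n_maps
  names(dwell) <- ensemble$levels

  bm <- data.frame(edge = seq_len(nrow(tr$edge)),
                   parent = tr$edge[, 1L], child = tr$edge[, 2L])
  structure(list(node_freq = node_freq, transitions = trans, dwell = dwell,
                 n_transitions = n_trans, branch_majority = bm,
                 tree = tr, levels = ensemble$levels, n_maps = n_maps),
            class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, ...) {
  cat("simmap_summary over ", x$n_maps, " histories\n", sep = "")
  cat("expected transitions per history: ",
      format(sum(x$transitions)), "\n", sep = "")
  cat("expected dwell times: ",
      paste(names(x$dwell), signif(x$dwell, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Count evolutionary transitions of a binary character
#'
#' A node's majority state is the state whose posterior frequency reaches
#' `threshold`; a branch carries a transition when parent and child
#' majority states are both defined and differ.  The number of such
#' branches is the minimum number of evolutionary transitions displayed by
#' the summary map (the rule behind statements like "a minimum of five
#' transitions to ontogenetic stripe loss").
#'
#' @param summary a [summarize_simmap()] result for a 2-state character.
#' @param threshold posterior frequency a state needs to count as the
#'   majority (default 0.5).
#' @return A `data.frame` of transition-carrying edges (edge index, parent
#'   and child node, majority states); the transition count is `nrow()` and
#'   is attached as attribute `"count"`.
#' @export
count_trajectory_transitions <- function(summary, threshold = 0.5) {
  stopifnot(inherits(summary, "simmap_summary"))
  if (length(summary$levels) != 2L)
    stop("transition counting is defined for a binary character")
  nf <- summary$node_freq
  maj <- apply(nf, 1L, function(p) {
    i <- which.max(p)
    if (p[i] >= threshold) i else NA_integer_
  })
  tr <- summary$tree
  pa <- maj[tr$edge[, 1L]]
  ch <- maj[tr$edge[, 2L]]
  hit <- which(!is.na(pa) & !is.na(ch) & pa != ch)
  out <- data.frame(edge = hit,
                    parent = tr$edge[hit, 1L], child = tr$edge[hit, 2L],
                    parent_state = summary$levels[pa[hit]],
                    child_state = summary$levels[ch[hit]],
                    stringsAsFactors = FALSE)
  attr(out, "count") <- nrow(out)
  out
}

#' Write ensemble summaries to TSV files
#'
#' Writes `<prefix>_node_freq.tsv`, `<prefix>_transitions.tsv` and
#' `<prefix>_dwell.tsv`.
#'
#' @param summary a [summarize_simmap()] result.
#' @param prefix output path prefix.
#' @return The three paths, invisibly.
#' @export
write_simmap_summary <- function(summary, prefix) {
  p1 <- paste0(prefix, "_node_freq.tsv")
  p2 <- paste0(prefix, "_transitions.tsv")
  p3 <- paste0(prefix, "_dwell.tsv")
  nf <- data.frame(node = seq_len(nrow(summary$node_freq)),
                   label = rownames(summary$node_freq),
                   summary$node_freq, check.names = FALSE)
  write.table(nf, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(from = rep(rownames(summary$transitions),
                                    ncol(summary$transitions)),
                         to = rep(colnames(summary$transitions),
                                  each = nrow(summary$transitions)),
                         expected = as.vector(summary$transitions)),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(state = names(summary$dwell),
                         expected_dwell = summary$dwell),
              p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Export one history as an annotated Newick string
#'
#' Branches are annotated with their (state, duration) segments in the
#' `{state,duration:state,duration}` convention used by stochastic-mapping
#' tools, child-to-parent order reversed to run from the parent end.
#'
#' @param ensemble a [sample_histories()] result.
#' @param m history index.
#' @return A character scalar.
#' @export
write_history_newick <- function(ensemble, m) {
  h <- get_history(ensemble, m)
  tr <- ensemble$tree
  lv <- ensemble$levels
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  ann <- function(e) {
    sg <- h$segments[[e]]
    paste0("{", paste(paste(lv[sg[, "state"]], signif(sg[, "duration"], 10),
                            sep = ","), collapse = ":"), "}")
  }
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    if (is.null(es)) return(tr$tip.label[node])
    inner <- vapply(es, function(e)
      paste0(rec(tr$edge[e, 2L]), ":", ann(e),
             signif(tr$edge.length[e], 10)), "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(rec(length(tr$tip.label) + 1L), ";")
}
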