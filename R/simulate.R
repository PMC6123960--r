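## Seeded generators for every input the analyses consume: birth-death
## trees, Markov characters with their full latent histories, Brownian
## traits with a known regression slope, and community pools with
## polymorphism.  All generators are pure functions of (parameters, seed)
## and attach a "sim_record" attribute so any fixture can be regenerated.

## forward birth-death simulation from a crown of two lineages; stops at
## stop_n extant lineages or at time stop_t.  Returns the lineage records.
bd_forward <- function(birth, death, stop_n = NULL, stop_t = NULL,
                       max_events = 1e6) {
  stopifnot(xor(is.null(stop_n), is.null(stop_t)))
  ## records: parent lineage, start/end time, fate (0 active, 1 died,
  ## 2 speciated)
  parent <- c(0L, 0L); t0 <- c(0, 0); t1 <- c(NA_real_, NA_real_)
  fate <- c(0L, 0L)
  active <- c(1L, 2L)
  t <- 0
  ev <- 0L
  repeat {
    n_act <- length(active)
    if (!is.null(stop_n) && n_act >= stop_n) {
      ## sample a stopping time uniformly within the next holding interval
      t <- t + runif(1) * rexp(1L, n_act * (birth + death) + 1e-12)
      break
    }
    if (n_act == 0L) break
    dt <- rexp(1L, n_act * (birth + death))
    if (!is.null(stop_t) && t + dt > stop_t) { t <- stop_t; break }
    t <- t + dt
    ev <- ev + 1L
    if (ev > max_events) stop("birth-death simulation event budget exhausted")
    who <- active[sample.int(n_act, 1L)]
    if (runif(1) < birth / (birth + death)) {
      t1[who] <- t; fate[who] <- 2L
      parent <- c(parent, who, who); t0 <- c(t0, t, t)
      t1 <- c(t1, NA_real_, NA_real_); fate <- c(fate, 0L, 0L)
      active <- c(setdiff(active, who),
                  length(parent) - 1L, length(parent))
    } else {
      t1[who] <- t; fate[who] <- 1L
      active <- setdiff(active, who)
    }
  }
  t1[active] <- t
  list(parent = parent, t0 = t0, t1 = t1, fate = fate,
       n_extant = length(active), time = t)
}

## collapse a lineage record set to a Newick string over extant tips
bd_to_newick <- function(rec, tip_prefix = "t") {
  kids <- split(seq_along(rec$parent), rec$parent)
  tip_id <- 0L
  build <- function(l) {
    len <- rec$t1[l] - rec$t0[l]
    if (rec$fate[l] == 1L) return(NULL)
    if (rec$fate[l] == 0L) {
      tip_id <<- tip_id + 1L
      return(paste0(tip_prefix, tip_id, ":", format(len, digits = 12)))
    }
    sub <- Filter(Negate(is.null), lapply(kids[[as.character(l)]], build))
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L) {
      ## unary chain from an extinct sister: absorb this branch length
      parts <- strsplit(sub[[1L]], ":(?=[^:]*$)", perl = TRUE)[[1L]]
      inner_len <- as.numeric(parts[2L])
      return(paste0(parts[1L], ":", format(inner_len + len, digits = 12)))
    }
    paste0("(", paste(unlist(sub), collapse = ","), "):",
           format(len, digits = 12))
  }
  left <- build(1L); right <- build(2L)
  if (is.null(left) || is.null(right)) return(NULL)  # crown not preserved
  paste0("(", left, ",", right, ");")
}

#' Simulate an ultrametric birth-death tree with a fixed tip count
#'
#' Forward birth-death simulation from a crown of two lineages, stopped
#' when the extant count reaches `n_tips` (at a time drawn uniformly within
#' the holding interval); runs in which the clade dies out or loses one
#' crown lineage are rejected and retried.
#'
#' @param birth speciation rate (> death).
#' @param death extinction rate (>= 0).
#' @param n_tips required number of extant tips (>= 2).
#' @param seed integer seed.
#' @param max_tries rejection budget.
#' @return An ultrametric `phylo` with tips `t1..tn` and a `sim_record`
#'   attribute.
#' @export
simulate_bd_tree <- function(birth, death = 0, n_tips, seed = 1L,
                             max_tries = 1000L) {
  stopifnot(birth > death, death >= 0, n_tips >= 2L)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    rec <- bd_forward(birth, death, stop_n = n_tips)
    if (rec$n_extant != n_tips) next
    nwk <- bd_to_newick(rec)
    if (is.null(nwk)) next
    tr <- parse_phylo(nwk)
    attr(tr, "sim_record") <- list(generator = "simulate_bd_tree",
                                   birth = birth, death = death,
                                   n_tips = n_tips, seed = seed,
                                   tries = try)
    return(tr)
  }
  stop("simulate_bd_tree: rejection budget exhausted after ",
       max_tries, " tries")
}

#' Simulate a discrete character on a tree under a rate matrix
#'
#' Forward CTMC along every branch from a root state, returning the tip
#' coding plus the complete latent history (node states and per-branch
#' (state, duration) segments) for recovery tests.
#'
#' @param tree a `phylo` object.
#' @param Q transition-rate matrix.
#' @param levels state labels (length `nrow(Q)`).
#' @param root_state root state label, or `NULL` to draw from `root_prior`.
#' @param root_prior distribution used when `root_state` is `NULL`
#'   (default uniform).
#' @param seed integer seed.
#' @return An object of class `"mk_sim"`: `coding` (singleton
#'   [morph_coding()]), `node_states` (integer vector over tips + nodes),
#'   `segments` (per postordered edge), the postordered `tree`, and a
#'   `record`.
#' @export
simulate_mk <- function(tree, Q, levels, root_state = NULL,
                        root_prior = NULL, seed = 1L) {
  check_rate_matrix(Q)
  k <- nrow(Q)
  stopifnot(length(levels) == k)
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  ntot <- nt + tr$Nnode
  states <- integer(ntot)
  root <- nt + 1L
  states[root] <- if (is.null(root_state)) {
    pr <- if (is.null(root_prior)) rep(1 / k, k) else root_prior
    sample.int(k, 1L, prob = pr)
  } else match(root_state, levels)
  segs <- vector("list", nrow(tr$edge))
  for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder
    s <- states[tr$edge[e, 1L]]
    t_e <- tr$edge.length[e]
    tm <- 0
    st <- s; dur <- numeric(0); path <- integer(0)
    repeat {
      rate <- -Q[s, s]
      w <- if (rate > 0) rexp(1L, rate) else Inf
      if (tm + w >= t_e) {
        path <- c(path, s); dur <- c(dur, t_e - tm)
        break
      }
      tm <- tm + w
      path <- c(path, s); dur <- c(dur, w)
      s <- sample.int(k, 1L, prob = pmax(Q[s, ], 0) * (seq_len(k) != s))
      dur[length(dur)] <- w  # duration until this jump
    }
    ## fix first segment durations: rebuild from jump times
    segs[[e]] <- cbind(state = path, duration = dur)
    states[tr$edge[e, 2L]] <- s
  }
  coding <- morph_coding(setNames(levels[states[seq_len(nt)]],
                                  tr$tip.label), levels = levels)
  structure(list(coding = coding, node_states = states, segments = segs,
                 tree = tr,
                 record = list(generator = "simulate_mk", Q = Q,
                               levels = levels, seed = seed,
                               root_state = levels[states[root]])),
            class = "mk_sim")
}

#' Simulate Brownian traits with a known regression slope
#'
#' The predictor evolves by Brownian motion on the tree (or is supplied);
#' the response is `intercept + slope * predictor` plus Brownian noise with
#' variance rate `sigma2`, so [pgls_fit()] should recover `slope`.
#'
#' @param tree a `phylo` object.
#' @param sigma2 Brownian variance rate of the response noise (> 0, or 0
#'   for the noiseless limit).
#' @param slope,intercept regression coefficients.
#' @param predictor optional named predictor vector; drawn as BM with rate
#'   `predictor_sigma2` when `NULL`.
#' @param predictor_sigma2 BM rate of the generated predictor.
#' @param seed integer seed.
#' @return A list with named vectors `x`, `y` and a `record`.
#' @export
simulate_bm_traits <- function(tree, sigma2, slope, intercept = 0,
                               predictor = NULL, predictor_sigma2 = 1,
                               seed = 1L) {
  stopifnot(sigma2 >= 0)
  set.seed(seed)
  C <- phylo_vcv(tree)
  ch <- chol(C)
  nt <- nrow(C)
  bm_draw <- function(rate)
    drop(crossprod(ch, rnorm(nt))) * sqrt(rate)
  x <- if (is.null(predictor)) {
    setNames(bm_draw(predictor_sigma2), rownames(C))
  } else predictor[rownames(C)]
  noise <- if (sigma2 > 0) bm_draw(sigma2) else numeric(nt)
  y <- setNames(intercept + slope * x + noise, rownames(C))
  list(x = x, y = y,
       record = list(generator = "simulate_bm_traits", sigma2 = sigma2,
                     slope = slope, intercept = intercept,
                     predictor_sigma2 = predictor_sigma2, seed = seed))
}

#' Simulate a species pool and communities
#'
#' Pool morphs are drawn from `morph_probs`; a fraction of species receives
#' a second (adjacent) morph.  Communities are drawn uniformly from the
#' pool (`assembly = "random"`, the null) or by a dissimilarity-biased rule
#' in which each added species is weighted by
#' `exp(-strength * increase in max identical pairs)`
#' (`assembly = "dissimilar"`, the species-recognition alternative).
#'
#' @param n_species pool size.
#' @param morph_probs named morph sampling probabilities (names = levels).
#' @param polymorphic_fraction fraction of pool species given a second
#'   morph.
#' @param richness_list community richness values, one community each.
#' @param assembly `"random"` or `"dissimilar"`.
#' @param strength selection strength for `"dissimilar"` assembly.
#' @param seed integer seed.
#' @return A list with `pool` (a [morph_coding()]), `communities`
#'   (`data.frame` with `location`, `species`) and a `record`.
#' @export
simulate_pool_and_communities <- function(n_species = 10L,
                                          morph_probs = c(A = 0.2, B = 0.2,
                                                          C = 0.3, D = 0.3),
                                          polymorphic_fraction = 0.3,
                                          richness_list = c(4L, 3L, 3L, 3L,
                                                            3L, 5L, 3L, 6L),
                                          assembly = c("random",
                                                       "dissimilar"),
                                          strength = 2, seed = 1L) {
  assembly <- match.arg(assembly)
  stopifnot(all(richness_list <= n_species))
  set.seed(seed)
  lv <- names(morph_probs)
  sp <- sprintf("pool_sp%02d", seq_len(n_species))
  morphs <- sample(lv, n_species, replace = TRUE, prob = morph_probs)
  sets <- as.list(morphs)
  names(sets) <- sp
  n_poly <- round(polymorphic_fraction * n_species)
  if (n_poly > 0L) {
    poly <- sample(sp, n_poly)
    for (s in poly) {
      i <- match(sets[[s]], lv)
      j <- if (i < length(lv)) i + 1L else i - 1L
      sets[[s]] <- c(sets[[s]], lv[j])
    }
  }
  pool <- morph_coding(sets, levels = lv)
  draw_community <- function(richness) {
    if (assembly == "random") return(sample(sp, richness))
    chosen <- sample(sp, 1L)
    while (length(chosen) < richness) {
      cand <- setdiff(sp, chosen)
      cur <- max_identical_pairs(chosen, pool)
      w <- vapply(cand, function(s)
        exp(-strength * (max_identical_pairs(c(chosen, s), pool) - cur)),
        0)
      chosen <- c(chosen, sample(cand, 1L, prob = w))
    }
    chosen
  }
  comm <- do.call(rbind, lapply(seq_along(richness_list), function(i) {
    data.frame(location = sprintf("loc%02d", i),
               species = draw_community(richness_list[i]),
               stringsAsFactors = FALSE)
  }))
  list(pool = pool, communities = comm,
       record = list(generator = "simulate_pool_and_communities",
                     n_species = n_species, morph_probs = morph_probs,
                     polymorphic_fraction = polymorphic_fraction,
                     richness_list = richness_list, assembly = assembly,
                     strength = strength, seed = seed))
}
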