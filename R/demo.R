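## A packaged synthetic dataset at the scale of the clownfish system:
## a 27-tip ultrametric tree, a 4-state stripe character with three
## polymorphic species (hence 8 coding combinations), a binary ontogeny
## character, morphometric and ecological traits in which only the anterior
## dorsal-fin lobe tracks stripe number, a 10-species pool and 8
## communities of richness 3-6 assembled with a dissimilarity bias.  It is
## entirely simulated (species are labelled syn_sp*) and exists so the full
## pipeline runs and is testable without external data.

#' Generate the synthetic clownfish-scale demonstration dataset
#'
#' @param seed integer master seed (split deterministically per stage).
#' @return A list with `tree`, `stripes` (polymorphic [morph_coding()]),
#'   `ontogeny` (binary coding), `traits` (`data.frame`), `pool`,
#'   `communities` and a `manifest` of all generating parameters.
#' @export
synthetic_clownfish_demo <- function(seed = 16L) {
  n_tips <- 27L
  tr <- simulate_bd_tree(birth = 0.25, death = 0.1, n_tips = n_tips,
                         seed = split_seed(seed, "tree"))
  tr$tip.label <- sprintf("syn_sp%02d", seq_len(n_tips))

  ## stripe character under the stepwise symmetric model (iv), rates as a
  ## slow peduncle stripe and faster trunk/head stripes, rooted in the
  ## three-stripe state
  spec_iv <- build_model_matrix("iv", 4L)
  q_iv <- c(0.123, 0.103, 0.052)  # A<->B, B<->C, C<->D per Myr
  Q <- make_rate_matrix(q_iv, spec_iv)
  sim_ch <- simulate_mk(tr, Q, levels = stripe_levels(), root_state = "D",
                        seed = split_seed(seed, "character"))
  stripes <- sim_ch$coding
  ## three polymorphic species: add an adjacent second morph
  set.seed(split_seed(seed, "character") + 1L)
  poly <- sort(sample(names(stripes), 3L))
  lv <- stripe_levels()
  st <- unclass(stripes)
  for (s in poly) {
    i <- match(st[[s]], lv)
    j <- if (i < 4L) i + 1L else i - 1L
    st[[s]] <- c(st[[s]], lv[j])
  }
  stripes <- morph_coding(st, levels = lv)

  ## binary ontogenetic-trajectory character (stripe loss during ontogeny)
  Q2 <- make_rate_matrix(0.03, build_model_matrix("ER", 2L))
  onto <- simulate_mk(tr, Q2, levels = c("no_loss", "loss"),
                      root_state = "no_loss",
                      seed = split_seed(seed, "character") + 2L)$coding

  ## traits: anterior lobe index tracks stripe number, the rest do not
  set.seed(split_seed(seed, "traits"))
  nstripes <- setNames(match(vapply(unclass(stripes), `[`, "", 1L), lv) - 1L,
                       names(stripes))
  bm <- simulate_bm_traits(tr, sigma2 = 0.0004, slope = 0,
                           seed = split_seed(seed, "traits") + 1L)
  set.seed(split_seed(seed, "traits") + 2L)
  L <- exp(rnorm(n_tips, log(2), 0.1))
  l2 <- 0.22 * L
  anterior <- 0.05 + 0.05 * nstripes[tr$tip.label] + bm$y[tr$tip.label]
  posterior <- 0.12 + 0.01 * nstripes[tr$tip.label] +
    rnorm(n_tips, 0, 0.03)
  l1 <- l2 + anterior * L
  lr <- l2 + posterior * L
  SL <- exp(rnorm(n_tips, log(9), 0.2))
  height <- (0.45 + rnorm(n_tips, 0, 0.05)) * SL
  traits <- data.frame(species = tr$tip.label,
                       stripes = as.integer(nstripes[tr$tip.label]),
                       l1 = round(l1, 4), l2 = round(l2, 4),
                       lr = round(lr, 4), L = round(L, 4),
                       height = round(height, 3), SL = round(SL, 3),
                       max_size = round(exp(rnorm(n_tips, log(11), 0.3)), 1),
                       n_hosts = sample(1:10, n_tips, replace = TRUE),
                       stringsAsFactors = FALSE)
  ## five species lack morphometric measurements (dropped per-regression)
  unmeasured <- sort(sample(tr$tip.label, 5L))
  traits[traits$species %in% unmeasured,
         c("l1", "l2", "lr", "L", "height", "SL")] <- NA

  ## pool of 10 species (a subset of the tips, keeping their morph sets,
  ## including at least two polymorphic ones) and 8 communities
  set.seed(split_seed(seed, "community"))
  pool_sp <- sort(c(poly[1:2], sample(setdiff(names(stripes), poly[1:2]),
                                      8L)))
  pool <- morph_coding(unclass(stripes)[pool_sp], levels = lv)
  richness <- c(4L, 3L, 3L, 3L, 3L, 5L, 3L, 6L)
  draw <- function(r) {
    chosen <- sample(pool_sp, 1L)
    while (length(chosen) < r) {
      cand <- setdiff(pool_sp, chosen)
      cur <- max_identical_pairs(chosen, pool)
      w <- vapply(cand, function(s)
        exp(-2 * (max_identical_pairs(c(chosen, s), pool) - cur)), 0)
      chosen <- c(chosen, sample(cand, 1L, prob = w))
    }
    chosen
  }
  communities <- do.call(rbind, lapply(seq_along(richness), function(i)
    data.frame(location = sprintf("loc%02d", i),
               species = draw(richness[i]), stringsAsFactors = FALSE)))

  list(tree = tr, stripes = stripes, ontogeny = onto, traits = traits,
       pool = pool, communities = communities,
       manifest = list(seed = seed, n_tips = n_tips,
                       birth = 0.25, death = 0.1,
                       q_iv = q_iv, root_state = "D",
                       onto_rate = 0.03, polymorphic = poly,
                       unmeasured = unmeasured,
                       pool_species = pool_sp, richness = richness,
                       assembly = "dissimilar", strength = 2))
}

#' Write the demonstration dataset to plain-text files
#'
#' Writes `synthetic_tree.nwk`, `synthetic_stripes.tsv`,
#' `synthetic_ontogeny.tsv`, `synthetic_traits.tsv`, `synthetic_pool.tsv`,
#' `synthetic_communities.tsv` and `synthetic_manifest.json`.
#'
#' @param demo a [synthetic_clownfish_demo()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_demo_files <- function(demo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(tree = file.path(dir, "synthetic_tree.nwk"),
         stripes = file.path(dir, "synthetic_stripes.tsv"),
         ontogeny = file.path(dir, "synthetic_ontogeny.tsv"),
         traits = file.path(dir, "synthetic_traits.tsv"),
         pool = file.path(dir, "synthetic_pool.tsv"),
         communities = file.path(dir, "synthetic_communities.tsv"),
         manifest = file.path(dir, "synthetic_manifest.json"))
  write_phylo(demo$tree, p[["tree"]])
  write_character_tsv(demo$stripes, p[["stripes"]])
  write_character_tsv(demo$ontogeny, p[["ontogeny"]])
  write.table(demo$traits, p[["traits"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(species = names(demo$pool),
                         morphs = vapply(demo$pool, paste, "",
                                         collapse = ",")),
              p[["pool"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(demo$communities, p[["communities"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(demo$manifest, p[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(p)
}

#' Paths to the packaged demonstration files
#'
#' @return Named character vector of installed file paths.
#' @export
demo_file_paths <- function() {
  dir <- system.file("extdata", package = "stripemorph")
  p <- c(tree = "synthetic_tree.nwk", stripes = "synthetic_stripes.tsv",
         ontogeny = "synthetic_ontogeny.tsv",
         traits = "synthetic_traits.tsv", pool = "synthetic_pool.tsv",
         communities = "synthetic_communities.tsv")
  setNames(file.path(dir, p), names(p))
}
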