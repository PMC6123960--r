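## Orchestration of the full analysis from one configuration: coding
## enumeration -> Mk ER/ARD fits and LRT -> stochastic mapping summaries ->
## MuSSE model tables -> PGLS battery -> community randomization tests.
## Every random stage receives a seed split deterministically from the
## master seed, and the provenance block records every setting.

#' Build a run configuration
#'
#' @param tree,stripes,ontogeny,traits,pool,communities input file paths
#'   (`ontogeny` and later stages may be `NULL` to skip them).
#' @param character which character drives the Mk/simmap/MuSSE stages:
#'   `"stripes"` (4 states) or `"ontogeny"` (2 states).
#' @param n_maps stochastic maps per coding.
#' @param n_random random communities per location.
#' @param sampling_fraction MuSSE sampling fraction; `NULL` means
#'   `min(1, n_tips / 30)`, treating the tree as a sample from the 30
#'   described clownfish species.
#' @param n_starts optimizer starts for Mk and MuSSE fits.
#' @param delta_aicc_support AICc difference counted as support.
#' @param transition_threshold majority threshold for transition counting.
#' @param seed master seed.
#' @param out_dir output directory for TSV/JSON reports.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(tree, stripes, ontogeny = NULL, traits = NULL,
                       pool = NULL, communities = NULL,
                       character = c("stripes", "ontogeny"),
                       n_maps = 10000L, n_random = 9999L,
                       sampling_fraction = NULL, n_starts = 3L,
                       delta_aicc_support = 4, transition_threshold = 0.5,
                       seed = 1L, out_dir = tempfile("stripemorph_run")) {
  cfg <- list(tree = tree, stripes = stripes, ontogeny = ontogeny,
              traits = traits, pool = pool, communities = communities,
              character = match.arg(character), n_maps = n_maps,
              n_random = n_random, sampling_fraction = sampling_fraction,
              n_starts = n_starts,
              delta_aicc_support = delta_aicc_support,
              transition_threshold = transition_threshold,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param file YAML path.
#' @return A `run_config`.
#' @export
load_config <- function(file) {
  y <- yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (key in c("tree", "stripes", "ontogeny", "traits", "pool",
                "communities"))
    y[[key]] <- fix(y[[key]])
  do.call(run_config, y)
}

#' Validate inputs and report reconciliation before any computation
#'
#' @param config a [run_config()].
#' @return A list: per-input species mismatches against the tree,
#'   polymorphism count and the number of coding combinations.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (key in c("tree", "stripes"))
    if (is.null(config[[key]]) || !file.exists(config[[key]]))
      stop("config input missing or not found: ", key)
  for (key in c("ontogeny", "traits", "pool", "communities")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config input not found: ", key, " (", p, ")")
  }
  tree <- read_phylo(config$tree)
  stripes <- read_character_tsv(config$stripes, levels = stripe_levels())
  rec <- reconcile_species(tree, names(stripes))
  poly <- names(stripes)[lengths(stripes) > 1L]
  out <- list(n_tips = length(tree$tip.label),
              tips_missing_character = rec$tips_missing_traits,
              character_missing_tips = rec$traits_missing_tips,
              polymorphic_species = poly,
              n_coding_combinations = prod(lengths(stripes)[poly]))
  if (length(poly) == 0L) out$n_coding_combinations <- 1L
  if (!is.null(config$traits)) {
    tt <- read_traits_tsv(config$traits)
    rt <- reconcile_species(tree, tt$species)
    out$tips_missing_traits <- rt$tips_missing_traits
    out$traits_missing_tips <- rt$traits_missing_tips
  }
  if (!is.null(config$pool) && !is.null(config$communities)) {
    pool <- read_pool_tsv(config$pool)
    comm <- read_communities_tsv(config$communities)
    out$community_species_missing_pool <-
      setdiff(comm$species, names(pool))
  }
  out
}

#' Run the full stripe-evolution analysis
#'
#' Executes, over every coding combination of the chosen character:
#' ER-vs-ARD Mk fits with a likelihood-ratio test, marginal ancestral-state
#' reconstruction, stochastic mapping with ensemble summaries, and the
#' MuSSE model table (models i-iv); then the PGLS battery of stripe number
#' against eco-morphological traits, and the community randomization test.
#' All tables are written as TSV under `config$out_dir` together with a
#' JSON provenance block; rerunning with the same config reproduces them
#' byte for byte.
#'
#' @param config a [run_config()].
#' @return An object of class `"analysis_report"` (all tables, in memory).
#' @export
run_full_analysis <- function(config) {
  checks <- validate_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- read_phylo(config$tree)
  char_file <- if (config$character == "stripes") config$stripes
               else config$ontogeny
  lv <- if (config$character == "stripes") stripe_levels()
        else NULL
  coding <- read_character_tsv(char_file, levels = lv)
  rec <- reconcile_species(tree, names(coding), prune = TRUE)
  tree <- rec$tree
  coding <- morph_coding(unclass(coding)[tree$tip.label],
                         levels = coding_levels(coding))
  n <- length(tree$tip.label)
  f <- config$sampling_fraction
  if (is.null(f)) f <- min(1, n / 30)
  codings <- enumerate_codings(coding)
  k <- length(coding_levels(coding))

  mk_tables <- list(); lrt <- list(); asr <- list(); simmap_sum <- list()
  for (i in seq_along(codings)) {
    cd <- codings[[i]]
    er <- fit_mk(tree, cd, build_model_matrix("ER", k),
                 n_starts = config$n_starts,
                 seed = split_seed(config$seed, "mk") + i)
    ard <- fit_mk(tree, cd, build_model_matrix("ARD", k),
                  n_starts = config$n_starts,
                  seed = split_seed(config$seed, "mk") + 100L + i)
    lrt[[i]] <- likelihood_ratio_test(er, ard)
    mk_tables[[i]] <- aicc_table(list(er, ard), n)
    best <- if (lrt[[i]]$p.value < 0.05) ard else er
    asr[[i]] <- marginal_asr(tree, cd, best$Q)
    ens <- sample_histories(tree, cd, best$Q, n_maps = config$n_maps,
                            seed = split_seed(config$seed, "simmap") + i)
    simmap_sum[[i]] <- summarize_simmap(ens)
  }
  names(mk_tables) <- names(lrt) <- names(asr) <- names(simmap_sum) <-
    names(codings)

  musse_models <- if (k == 4L) c("i", "ii", "iii", "iv") else c("i", "ii")
  musse <- musse_model_table(tree, coding, f = f, models = musse_models,
                             n_starts = config$n_starts,
                             seed = split_seed(config$seed, "musse"))

  pgls <- NULL
  if (!is.null(config$traits)) {
    traits <- read_traits_tsv(config$traits)
    pgls <- pgls_stripe_battery(tree, traits)
  }
  comm_tab <- NULL
  if (!is.null(config$pool) && !is.null(config$communities)) {
    pool <- read_pool_tsv(config$pool)
    comm <- read_communities_tsv(config$communities)
    comm_tab <- community_table(comm, pool, n_random = config$n_random,
                                seed = split_seed(config$seed, "random"))
  }
  transitions <- NULL
  if (length(coding_levels(coding)) == 2L)
    transitions <- lapply(simmap_sum, count_trajectory_transitions,
                          threshold = config$transition_threshold)

  report <- structure(
    list(checks = checks, mk_tables = mk_tables, lrt = lrt, asr = asr,
         simmap = simmap_sum, musse = musse, pgls = pgls,
         communities = comm_tab, transitions = transitions,
         provenance = list(
           seed = config$seed, n_maps = config$n_maps,
           n_random = config$n_random, sampling_fraction = f,
           n_starts = config$n_starts,
           delta_aicc_support = config$delta_aicc_support,
           transition_threshold = config$transition_threshold,
           character = config$character, n_tips = n,
           package_version = as.character(utils::packageVersion(
             "stripemorph")))),
    class = "analysis_report")
  write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  for (i in seq_along(report$mk_tables))
    write.table(report$mk_tables[[i]],
                file.path(dir, sprintf("mk_table_coding%02d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  musse <- report$musse
  tabs <- if (inherits(musse, "musse_model_tables")) musse$tables
          else list(musse)
  for (i in seq_along(tabs))
    write.table(tabs[[i]],
                file.path(dir, sprintf("musse_table_coding%02d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(report$asr))
    write.table(data.frame(node = seq_len(nrow(report$asr[[i]])),
                           label = rownames(report$asr[[i]]),
                           report$asr[[i]], check.names = FALSE),
                file.path(dir, sprintf("asr_coding%02d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(report$simmap))
    write_simmap_summary(report$simmap[[i]],
                         file.path(dir, sprintf("simmap_coding%02d", i)))
  if (!is.null(report$pgls))
    write.table(report$pgls, file.path(dir, "pgls_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$communities))
    write.table(report$communities, file.path(dir, "community_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("stripe-evolution analysis report\n")
  cat("  ", x$provenance$n_tips, " tips, ",
      length(x$mk_tables), " coding combination(s), character = ",
      x$provenance$character, "\n", sep = "")
  musse <- x$musse
  if (inherits(musse, "musse_model_tables")) {
    best <- vapply(musse$tables, function(t) t$model[1L], "")
    cat("  best MuSSE model per coding: ", paste(best, collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  best MuSSE model: ", musse$model[1L], " (weight ",
        signif(musse$weight[1L], 3), ")\n", sep = "")
  }
  if (!is.null(x$pgls)) {
    sig <- x$pgls[x$pgls$p < 0.05, "X"]
    cat("  PGLS predictors with p < 0.05: ",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n",
        sep = "")
  }
  if (!is.null(x$communities))
    cat("  community tests with p < 0.05: ",
        sum(x$communities$p < 0.05), " of ", nrow(x$communities), "\n",
        sep = "")
  invisible(x)
}
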