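## Morphometric indexes and phylogenetic generalized least squares.
## The dorsal-fin lobe indexes quantify the indentation between the spiny
## anterior lobe and the soft posterior lobe, normalized by fin length;
## elongation is body height over standard length.  PGLS regresses stripe
## number on one trait at a time with Brownian-motion error covariance.

#' Anterior dorsal-fin lobe index
#'
#' `(l1 - l2) / L`: third dorsal spine minus most posterior spine,
#' normalized by dorsal-fin length.  Dimensionless; invariant to a common
#' rescaling of the measurements; may be negative.
#'
#' @param l1 length of the third dorsal spine.
#' @param l2 length of the most posterior spine.
#' @param L length of the dorsal fin (> 0).
#' @return Numeric index (vectorized).
#' @export
anterior_lobe_index <- function(l1, l2, L) {
  if (any(L <= 0, na.rm = TRUE)) stop("fin length L must be > 0")
  (l1 - l2) / L
}

#' Posterior dorsal-fin lobe index
#'
#' `(lr - l2) / L`: longest soft ray minus most posterior spine, normalized
#' by dorsal-fin length.
#'
#' @param lr length of the longest soft ray.
#' @inheritParams anterior_lobe_index
#' @return Numeric index (vectorized).
#' @export
posterior_lobe_index <- function(lr, l2, L) {
  if (any(L <= 0, na.rm = TRUE)) stop("fin length L must be > 0")
  (lr - l2) / L
}

#' Body elongation ratio
#'
#' Body height over standard length.
#'
#' @param height body height.
#' @param standard_length standard length (> 0).
#' @return Numeric ratio (vectorized).
#' @export
elongation <- function(height, standard_length) {
  if (any(standard_length <= 0, na.rm = TRUE))
    stop("standard length must be > 0")
  height / standard_length
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Simple regression `y ~ x` with error covariance proportional to the
#' Brownian-motion variance-covariance matrix of the tree:
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`.  The slope is tested with
#' `F = (RSS0 - RSS1) / (RSS1 / (n - 2))` where residual sums of squares
#' are taken in the `C^-1` metric and `RSS0` comes from the intercept-only
#' GLS fit; the p-value is the `F(1, n - 2)` upper tail.  On a star tree
#' (`C = I`) this reduces exactly to ordinary least squares.  Estimates are
#' invariant to scaling `C` by a positive constant.
#'
#' @param tree a `phylo` object.
#' @param response named numeric vector (names = species).
#' @param predictor named numeric vector (names = species).
#' @return An object of class `"pgls_fit"`: `coefficients` (intercept,
#'   slope), `se`, `ci95` (slope), `sigma2`, `F`, `p.value`, `n`,
#'   `dropped` (species removed for missing data).
#' @export
pgls_fit <- function(tree, response, predictor) {
  stopifnot(!is.null(names(response)), !is.null(names(predictor)))
  common <- intersect(intersect(tree$tip.label, names(response)),
                      names(predictor))
  y0 <- response[common]
  x0 <- predictor[common]
  keep <- common[is.finite(y0) & is.finite(x0)]
  dropped <- setdiff(union(tree$tip.label,
                           union(names(response), names(predictor))), keep)
  n <- length(keep)
  if (n < 3L) stop("PGLS needs at least 3 jointly observed species")
  tr <- if (length(setdiff(tree$tip.label, keep)))
    ape::drop.tip(tree, setdiff(tree$tip.label, keep)) else tree
  C <- phylo_vcv(tr)[keep, keep]
  y <- as.numeric(response[keep])
  x <- as.numeric(predictor[keep])
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance; jitter zero-length branches"))
  ## whiten: solve(t(ch)) %*% v
  wh <- function(v) backsolve(ch, v, transpose = TRUE)
  X <- cbind(intercept = 1, slope = x)
  Xw <- wh(X)
  yw <- wh(y)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss1 <- sum(fit$residuals^2)
  fit0 <- stats::lm.fit(Xw[, 1L, drop = FALSE], yw)
  rss0 <- sum(fit0$residuals^2)
  df2 <- n - 2L
  ## guard the degenerate cases: an exactly-constant response (both RSS at
  ## rounding level) carries no evidence; an exact linear fit is infinite
  ## evidence
  eps <- 1e-12 * (sum(yw^2) + 1e-300)
  Fstat <- if (rss1 <= eps) {
    if (rss0 <= eps) 0 else Inf
  } else ((rss0 - rss1) / 1) / (rss1 / df2)
  Fstat <- max(Fstat, 0)
  p <- pf(Fstat, 1L, df2, lower.tail = FALSE)
  sigma2 <- rss1 / df2
  XtX_inv <- chol2inv(qr.R(qr(Xw)))
  se <- sqrt(pmax(diag(XtX_inv) * sigma2, 0))
  tq <- qt(0.975, df2)
  structure(list(coefficients = setNames(beta, c("intercept", "slope")),
                 se = setNames(se, c("intercept", "slope")),
                 ci95 = c(lower = unname(beta[2L] - tq * se[2L]),
                          upper = unname(beta[2L] + tq * se[2L])),
                 sigma2 = sigma2, F = Fstat, p.value = p, n = n,
                 dropped = dropped),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (Brownian motion), n = ", x$n, "\n", sep = "")
  cat("  slope = ", signif(x$coefficients[2L], 4),
      " (SE ", signif(x$se[2L], 3), "), F = ", signif(x$F, 4),
      ", p = ", format.pval(x$p.value, digits = 3), "\n", sep = "")
  if (length(x$dropped))
    cat("  dropped ", length(x$dropped), " species with missing data\n",
        sep = "")
  invisible(x)
}

#' Battery of single-predictor PGLS regressions of stripe number
#'
#' Mirrors the analysis layout of regressing the number of white stripes on
#' each eco-morphological variable separately: host count, maximum body
#' size, elongation and the two dorsal-fin lobe indexes.  Species lacking a
#' measurement are dropped per-regression.  No multiple-testing correction
#' is applied (each regression is reported as its own test).
#'
#' @param tree a `phylo` object.
#' @param traits a `data.frame` with columns `species`, `stripes`, and any
#'   of `n_hosts`, `max_size`, `height`, `SL`, `l1`, `l2`, `lr`, `L`
#'   (indexes are derived when their parts are present).
#' @return A `data.frame` with one row per regression: `X`, `Y`, `n`,
#'   `slope`, `F`, `p`.
#' @export
pgls_stripe_battery <- function(tree, traits) {
  stopifnot(all(c("species", "stripes") %in% names(traits)))
  y <- setNames(as.numeric(traits$stripes), traits$species)
  preds <- list()
  if ("n_hosts" %in% names(traits))
    preds$n_hosts <- setNames(as.numeric(traits$n_hosts), traits$species)
  if ("max_size" %in% names(traits))
    preds$max_size <- setNames(as.numeric(traits$max_size), traits$species)
  if (all(c("height", "SL") %in% names(traits)))
    preds$elongation <- setNames(elongation(traits$height, traits$SL),
                                 traits$species)
  if (all(c("l1", "l2", "L") %in% names(traits)))
    preds$anterior_lobe <- setNames(
      anterior_lobe_index(traits$l1, traits$l2, traits$L), traits$species)
  if (all(c("lr", "l2", "L") %in% names(traits)))
    preds$posterior_lobe <- setNames(
      posterior_lobe_index(traits$lr, traits$l2, traits$L), traits$species)
  rows <- lapply(names(preds), function(nm) {
    ft <- pgls_fit(tree, y, preds[[nm]])
    data.frame(X = nm, Y = "stripes", n = ft$n,
               slope = ft$coefficients[2L], F = ft$F, p = ft$p.value,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Read a species trait table
#'
#' TSV with a mandatory `species` column; remaining columns are kept as-is.
#'
#' @param file path to the TSV.
#' @return A `data.frame`.
#' @export
read_traits_tsv <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"species" %in% names(d)) stop("trait table needs a 'species' column")
  if (anyDuplicated(d$species)) stop("duplicate species in trait table")
  d
}
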