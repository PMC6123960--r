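## Character codings.  A morph_coding maps each species to a non-empty set
## of discrete states; polymorphic species carry two or more.  For the
## clownfish stripe character the four states are A (no stripe), B (head),
## C (head + trunk) and D (head + trunk + peduncle), i.e. 0-3 vertical white
## stripes.  The same machinery serves the binary ontogenetic-trajectory
## character (whether juveniles lose extra stripes before adulthood).

#' Stripe morph state labels
#'
#' The four adult stripe categories, in rostral-to-caudal order of stripe
#' gain: `A` = 0 stripes, `B` = 1 (head), `C` = 2 (head + trunk),
#' `D` = 3 (head + trunk + peduncle).
#'
#' @return `c("A", "B", "C", "D")`.
#' @export
stripe_levels <- function() c("A", "B", "C", "D")

#' Construct a species-to-morph coding
#'
#' @param x either a named list of character vectors (species -> state set)
#'   or a named character vector whose elements may be comma-joined sets,
#'   e.g. `c(sp1 = "C,D", sp2 = "B")`.
#' @param levels ordered state labels; defaults to the sorted unique states
#'   observed.
#' @return An object of class `"morph_coding"`: a named list of state sets
#'   with a `levels` attribute.
#' @examples
#' cd <- morph_coding(c(ocellaris = "D", clarkii = "C,D"),
#'                    levels = stripe_levels())
#' @export
morph_coding <- function(x, levels = NULL) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("coding vector must be named by species")
    x <- lapply(x, function(s) trimws(strsplit(s, ",", fixed = TRUE)[[1L]]))
  }
  stopifnot(is.list(x), !is.null(names(x)), !anyDuplicated(names(x)))
  x <- lapply(x, function(s) unique(as.character(s)))
  if (any(lengths(x) == 0L)) stop("every species needs at least one state")
  obs <- sort(unique(unlist(x)))
  if (is.null(levels)) levels <- obs
  bad <- setdiff(obs, levels)
  if (length(bad)) stop("states not in levels: ", paste(bad, collapse = ", "))
  structure(x, class = "morph_coding", levels = levels)
}

#' @export
print.morph_coding <- function(x, ...) {
  lv <- attr(x, "levels")
  poly <- names(x)[lengths(x) > 1L]
  cat("morph_coding: ", length(x), " species, ", length(lv),
      " states (", paste(lv, collapse = ", "), ")\n", sep = "")
  if (length(poly))
    cat("polymorphic: ", paste(poly, collapse = ", "), "\n", sep = "")
  invisible(x)
}

coding_levels <- function(coding) attr(coding, "levels")

is_polymorphic <- function(coding) any(lengths(coding) > 1L)

#' Enumerate fully resolved codings of a polymorphic character
#'
#' Expands the Cartesian product of the state sets of all polymorphic
#' species, in a deterministic order (states in listed order, first
#' polymorphic species varying fastest).  Three species with two morphs each
#' give eight combinations.
#'
#' @param coding a [morph_coding()].
#' @return A list of singleton-state `morph_coding` objects; names encode
#'   the chosen states, e.g. `"clarkii=C|melanopus=B"`.
#' @export
enumerate_codings <- function(coding) {
  stopifnot(inherits(coding, "morph_coding"))
  poly <- names(coding)[lengths(coding) > 1L]
  if (!length(poly)) {
    out <- list(coding)
    names(out) <- "fixed"
    return(out)
  }
  grid <- expand.grid(coding[poly], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cd <- coding
    for (sp in poly) cd[[sp]] <- grid[i, sp]
    out[[i]] <- morph_coding(unclass(cd), levels = coding_levels(coding))
  }
  names(out) <- apply(grid, 1L, function(r)
    paste(paste0(poly, "=", r), collapse = "|"))
  out
}

#' Read a character coding from a TSV file
#'
#' Expects columns `species` and `state`; `state` may be a comma-joined set
#' (e.g. `"C,D"`) for polymorphic species.
#'
#' @param file path to the TSV.
#' @param levels ordered state labels (defaults to observed states).
#' @return A [morph_coding()].
#' @export
read_character_tsv <- function(file, levels = NULL) {
  d <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("species", "state") %in% names(d)))
    stop("character table needs columns 'species' and 'state'")
  morph_coding(setNames(as.character(d$state), d$species), levels = levels)
}

#' Write a character coding to a TSV file
#'
#' @param coding a [morph_coding()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_character_tsv <- function(coding, file) {
  d <- data.frame(species = names(coding),
                  state = vapply(coding, paste, "", collapse = ","),
                  stringsAsFactors = FALSE)
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

## k x ntip indicator matrix of allowed states per tip (tree tip order)
tip_indicator <- function(tree, coding, ambiguous = FALSE) {
  lv <- coding_levels(coding)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(coding))
  if (length(missing))
    stop("tips absent from coding: ", paste(missing, collapse = ", "))
  if (is_polymorphic(coding[tips]) && !ambiguous)
    stop("polymorphic tips present; resolve them with enumerate_codings() ",
         "or set ambiguous = TRUE to treat them as state ambiguity")
  m <- matrix(0, length(lv), length(tips),
              dimnames = list(lv, tips))
  for (i in seq_along(tips)) m[coding[[tips[i]]], i] <- 1
  m
}
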