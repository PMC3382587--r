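# The package's RNA thermodynamic model. It is deliberately simple: a 6x6
# nearest-neighbor stacking table over {CG,GC,GU,UG,AU,UA} plus linear loop
# penalties and an affine multiloop cost, in kcal/mol. The table is derived
# from per-pair strengths (CG 2.6, AU 1.4, GU 0.8 kcal/mol) by a midpoint
# rule with a fixed helix-contiguity bonus, and is shipped as a plain-text
# config so users can swap in their own values. The model is small enough
# that the optimal fold can be cross-checked by exhaustive enumeration.

.ovamir_env <- new.env(parent = emptyenv())

.pair_order <- c("CG", "GC", "GU", "UG", "AU", "UA")

#' Energy model parameters
#'
#' Loads (and caches) the nearest-neighbor stacking table and loop/duplex
#' parameters shipped in `inst/extdata`. Individual values can be overridden
#' through `...`.
#'
#' @param ... named overrides, e.g. `energy_params(hairpin_a = 5)` or a
#'   replacement 6x6 `stacks` matrix with rows/columns ordered
#'   CG, GC, GU, UG, AU, UA.
#' @return list with elements `stacks` (6x6 numeric matrix, kcal/mol) and the
#'   scalar parameters `hairpin_a`, `hairpin_b` (hairpin loop penalty
#'   intercept/slope), `loop_a`, `loop_b` (interior/bulge penalty),
#'   `multi_a`, `multi_b`, `multi_c` (multiloop close/branch/unpaired),
#'   `max_interior`, `min_loop`, `duplex_init` (duplex initiation penalty)
#'   and `end_penalty` (AU/GU helix end penalty).
#' @export
energy_params <- function(...) {
  if (is.null(.ovamir_env$params)) {
    sf <- system.file("extdata", "nn_stacks.tsv", package = "ovamir")
    pf <- system.file("extdata", "energy_params.tsv", package = "ovamir")
    st <- utils::read.delim(sf, row.names = 1, check.names = FALSE)
    st <- as.matrix(st)[.pair_order, .pair_order]
    sc <- utils::read.delim(pf)
    p <- as.list(setNames(sc$value, sc$param))
    p$stacks <- st
    .ovamir_env$params <- p
  }
  p <- .ovamir_env$params
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

# pair type index (1-based into .pair_order) or NA; a, b are single chars
# with T treated as U
.pair_type <- function(a, b) {
  key <- paste0(chartr("T", "U", a), chartr("T", "U", b))
  match(key, c("CG", "GC", "GU", "UG", "AU", "UA"))
}

#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' Single-optimal dynamic programming fold under the package's
#' nearest-neighbor style energy model (see [energy_params()]): Watson-Crick
#' and G:U pairs, minimum hairpin loop of 3 nt, interior loops capped at
#' `max_interior` unpaired bases, affine multiloop cost. Pseudoknots are not
#' considered. The input may be DNA (T is treated as U). Sequences too
#' short to form any pair (under 5 nt) are returned unpaired with energy 0.
#'
#' @param sequence a single DNA/RNA string.
#' @param unpaired optional integer vector of 1-based positions that are
#'   constrained to stay unpaired (used for accessibility calculations).
#' @param params energy model, from [energy_params()].
#' @return object of class `ovamir_fold`: list with `sequence`,
#'   `dot_bracket`, `partner` (1-based pairing partner, 0 if unpaired) and
#'   `energy` (kcal/mol, <= 0).
#' @examples
#' fold_rna("GGGGGAAAACCCCC")
#' @export
fold_rna <- function(sequence, unpaired = NULL, params = energy_params()) {
  sequence <- as_dna(sequence)
  n <- nchar(sequence)
  if (!.is_dna(sequence))
    stop("fold_rna: sequence contains non-ACGTN characters")
  if (n < 5) {
    res <- list(sequence = sequence, dot_bracket = strrep(".", n),
                partner = integer(n), energy = 0)
    class(res) <- "ovamir_fold"
    return(res)
  }
  forbid <- rep(FALSE, n)
  if (!is.null(unpaired)) {
    stopifnot(all(unpaired >= 1 & unpaired <= n))
    forbid[unpaired] <- TRUE
  }
  r <- .fold_engine(sequence, forbid, params$stacks,
                    params$hairpin_a, params$hairpin_b,
                    params$loop_a, params$loop_b,
                    params$multi_a, params$multi_b, params$multi_c,
                    as.integer(params$max_interior),
                    as.integer(params$min_loop))
  res <- list(sequence = sequence, dot_bracket = r$dot_bracket,
              partner = as.integer(r$partner), energy = r$energy)
  class(res) <- "ovamir_fold"
  res
}

#' @export
print.ovamir_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "\n",
      sprintf("energy: %.2f kcal/mol, %d pairs\n",
              x$energy, sum(x$partner > 0) / 2), sep = "")
  invisible(x)
}

#' Energy of a given nested structure under the package model
#'
#' Scores an explicit structure (as a pairing-partner vector) with the same
#' decomposition the folding DP optimizes: useful for validating the DP
#' against enumeration and for scoring externally proposed structures.
#'
#' @param sequence DNA/RNA string.
#' @param partner integer vector, 1-based partner per position (0 =
#'   unpaired). Must be nested and respect the minimum loop.
#' @param params energy model.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, partner, params = energy_params()) {
  sequence <- as_dna(sequence)
  s <- .chars(sequence)
  n <- length(s)
  stopifnot(length(partner) == n)
  pairs <- which(partner > seq_len(n))
  total <- 0
  for (i in pairs) {
    j <- partner[i]
    inner <- which(partner[(i + 1):(j - 1)] > 0) + i
    inner_open <- inner[partner[inner] > inner & partner[inner] <= j]
    # direct children: opening pairs inside (i,j) not nested in another child
    if (length(inner_open)) {
      keep <- logical(length(inner_open))
      last_end <- i
      for (k in seq_along(inner_open)) {
        if (inner_open[k] > last_end) {
          keep[k] <- TRUE
          last_end <- partner[inner_open[k]]
        }
      }
      inner_open <- inner_open[keep]
    }
    nb <- length(inner_open)
    if (nb == 0) {
      total <- total + params$hairpin_a + params$hairpin_b * (j - i - 1)
    } else if (nb == 1) {
      k <- inner_open; l <- partner[k]
      u <- (k - i - 1) + (j - l - 1)
      if (u == 0) {
        pt1 <- .pair_type(s[i], s[j]); pt2 <- .pair_type(s[k], s[l])
        total <- total + params$stacks[pt1, pt2]
      } else {
        total <- total + params$loop_a + params$loop_b * u
      }
    } else {
      unp <- (j - i - 1) - sum(partner[inner_open] - inner_open + 1)
      total <- total + params$multi_a + params$multi_b * nb +
        params$multi_c * unp
    }
  }
  total
}
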