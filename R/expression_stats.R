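# qPCR standard-curve quantification, multi-reference normalization, fold
# changes, ANOVA with compact letter display, and the Kruskal-Wallis rank
# comparison used for the microarray-derived target-expression analysis.

#' Fit a qPCR standard curve
#'
#' Least-squares line Cq = slope * log10(quantity) + intercept over a
#' dilution series; amplification efficiency is derived from the slope as
#' (10^(-1/slope) - 1) * 100.
#'
#' @param dilution_log10 log10 quantities of the dilution points (>= 3).
#' @param cq measured Cq values.
#' @return list of class `ovamir_curve`: `slope`, `intercept`, `efficiency`
#'   (percent), `r2`.
#' @export
fit_standard_curve <- function(dilution_log10, cq) {
  if (length(dilution_log10) < 3 || length(cq) != length(dilution_log10))
    stop("fit_standard_curve: need >= 3 matched dilution points")
  if (stats::var(dilution_log10) == 0)
    stop("fit_standard_curve: zero variance in dilutions")
  fit <- stats::lm(cq ~ dilution_log10)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  out <- list(slope = slope, intercept = intercept,
              efficiency = (10^(-1 / slope) - 1) * 100,
              r2 = suppressWarnings(summary(fit)$r.squared))
  class(out) <- "ovamir_curve"
  out
}

#' Interpolate a quantity from a standard curve
#'
#' @param cq Cq value(s).
#' @param curve from [fit_standard_curve()] (or a list with `slope`,
#'   `intercept`).
#' @return quantity = 10^((cq - intercept) / slope).
#' @export
curve_quantity <- function(cq, curve) {
  10^((cq - curve$intercept) / curve$slope)
}

#' Quantify and normalize a Cq table
#'
#' Each Cq is interpolated on its target's standard curve; each sample's
#' target quantities are divided by the geometric mean of its two
#' reference-gene quantities. Samples missing a reference Cq are dropped
#' with a warning.
#'
#' @param cq_table data.frame with columns `sample`, `tissue`, `target`,
#'   `cq`.
#' @param curves named list of standard curves (one per target, including
#'   both references).
#' @param reference_targets character vector of exactly 2 reference genes.
#' @return data.frame with `sample`, `tissue`, `target`, `quantity`,
#'   `normalized` (reference rows are excluded from the output).
#' @export
quantify_normalize <- function(cq_table, curves, reference_targets) {
  stopifnot(length(reference_targets) == 2)
  cq_table$quantity <- NA_real_
  for (tg in unique(cq_table$target)) {
    cv <- curves[[tg]]
    if (is.null(cv)) stop("quantify_normalize: no curve for target ", tg)
    sel <- cq_table$target == tg
    cq_table$quantity[sel] <- curve_quantity(cq_table$cq[sel], cv)
  }
  out <- list()
  dropped <- character(0)
  for (sm in unique(cq_table$sample)) {
    sub <- cq_table[cq_table$sample == sm, , drop = FALSE]
    refq <- sub$quantity[match(reference_targets, sub$target)]
    if (any(is.na(refq))) { dropped <- c(dropped, sm); next }
    gm <- sqrt(refq[1] * refq[2])
    tgt <- sub[!(sub$target %in% reference_targets), , drop = FALSE]
    tgt$normalized <- tgt$quantity / gm
    out[[sm]] <- tgt
  }
  if (length(dropped) > 0)
    warning("quantify_normalize: samples missing reference Cq dropped: ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  rownames(res) <- NULL
  res[, c("sample", "tissue", "target", "quantity", "normalized")]
}

#' Group means as fold changes over the lowest group
#'
#' The group with the lowest mean is the calibrator (fold change 1).
#'
#' @param values numeric vector of (normalized) expression values.
#' @param groups grouping factor/character vector.
#' @return data.frame with `group`, `mean`, `fold_change`, ordered by
#'   decreasing fold change.
#' @export
fold_changes <- function(values, groups) {
  mu <- tapply(values, groups, mean)
  out <- data.frame(group = names(mu), mean = as.numeric(mu),
                    fold_change = as.numeric(mu) / min(mu),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal cliques of an undirected graph given as an adjacency matrix
# (Bron-Kerbosch without pivoting; fine for the handful of groups used here)
.max_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      cliques[[length(cliques) + 1L]] <<- sort(R)
      return(invisible())
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

#' One-way ANOVA with Tukey multiple comparisons and letter groups
#'
#' Runs a one-way ANOVA on the values, performs all-pairs Tukey HSD at
#' `alpha`, and summarizes the pairwise outcome as a compact letter display:
#' groups sharing no letter differ significantly. Letters are assigned from
#' the maximal cliques of the "not significantly different" graph, so the
#' display is exact. When all values are identical the F statistic is
#' undefined and a single shared letter is reported.
#'
#' @param values numeric response.
#' @param groups grouping vector (>= 2 groups, each n >= 2 unless constant).
#' @param alpha significance level for the letter display.
#' @return list with `F`, `p`, `letters` (named character vector, one entry
#'   per group, ordered by decreasing group mean) and `tukey` (the p-value
#'   matrix).
#' @export
anova_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  stopifnot(k >= 2)
  if (stats::var(values) == 0) {
    lv <- levels(groups)
    return(list(F = NA_real_, p = NA_real_,
                letters = setNames(rep("a", k), lv), tukey = NULL))
  }
  if (any(tapply(values, groups, length) < 2))
    stop("anova_letters: every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]; pv <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  lv <- levels(groups)
  padj <- matrix(1, k, k, dimnames = list(lv, lv))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    padj[pair[1], pair[2]] <- padj[pair[2], pair[1]] <- tk[r, "p adj"]
  }
  # non-significant graph; cliques -> letters
  adj <- padj >= alpha
  diag(adj) <- FALSE
  cl <- .max_cliques(adj)
  # order groups by decreasing mean for conventional letter ordering
  mu <- tapply(values, groups, mean)
  ord <- order(-mu)
  cl <- cl[order(vapply(cl, function(x) min(match(x, ord)), numeric(1)))]
  letters_vec <- setNames(rep("", k), lv)
  for (ci in seq_along(cl)) {
    for (g in cl[[ci]])
      letters_vec[g] <- paste0(letters_vec[g], letters[ci])
  }
  list(F = Fv, p = pv, letters = letters_vec[ord], tukey = padj)
}

#' Kruskal-Wallis rank comparison across tissues
#'
#' Ranks are computed over the pooled value set (average ranks for ties);
#' the tie-corrected H statistic is tested against a chi-square null with
#' k - 1 degrees of freedom, and per-group mean ranks are reported (the
#' quantity compared descriptively across tissues).
#'
#' @param values numeric expression values (e.g. normalized microarray
#'   values or their ranks).
#' @param groups tissue labels.
#' @return list with `H` (tie-corrected), `df`, `p`, `mean_ranks` (named),
#'   `n` per group.
#' @export
kw_test <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 1))
  if (length(unique(values)) == 1) {
    mr <- tapply(rank(values), groups, mean)
    return(list(H = 0, df = nlevels(groups) - 1, p = 1,
                mean_ranks = mr, n = table(groups)))
  }
  kt <- stats::kruskal.test(values, groups)
  mr <- tapply(rank(values), groups, mean)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, mean_ranks = mr, n = table(groups))
}
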