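PROPERTY_INDICES <- c("boman", "aliphatic", "instability", "gravy",
                      "charge", "pI", "mw", "mz")

#' Summarise a peptide pool
#'
#' Mean and standard deviation of every property index over a pool of
#' distinct sequences, plus the threshold fractions used to call
#' interaction propensity and stability.
#'
#' @param properties An [annotate_atlas()] (or [peptide_properties()])
#'   table.
#' @param isoform Optional isoform id to filter on.
#' @param config A [property_config()] (supplies the thresholds).
#' @return A `pool_summary` list: `N`, `mean` and `sd` (named vectors over
#'   the indices), and `fractions` (`boman_high`, `boman_low`,
#'   `aliphatic_stable`, `instability_stable`).
#' @export
summarize_pool <- function(properties, isoform = NULL,
                           config = property_config()) {
  tab <- as.data.frame(properties)
  if (!is.null(isoform)) {
    if (!"isoform" %in% names(tab)) stop("summarize_pool: no isoform column")
    tab <- tab[tab$isoform %in% isoform, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("summarize_pool: empty pool")
  idx <- intersect(PROPERTY_INDICES, names(tab))
  means <- vapply(idx, function(i) mean(tab[[i]]), 0)
  sds <- vapply(idx, function(i) stats::sd(tab[[i]]), 0)
  structure(list(
    N = nrow(tab),
    isoform = if (is.null(isoform)) "all" else paste(isoform, collapse = "+"),
    mean = means, sd = sds,
    fractions = c(
      boman_high = mean(tab$boman > config$boman_high),
      boman_low = mean(tab$boman <= config$boman_high),
      aliphatic_stable = mean(tab$aliphatic > config$aliphatic_stable),
      instability_stable = mean(tab$instability < config$instability_stable)
    )
  ), class = "pool_summary")
}

#' @export
print.pool_summary <- function(x, ...) {
  cat(sprintf("<pool_summary> %s: N = %s\n", x$isoform,
              format(x$N, big.mark = ",")))
  for (i in names(x$mean)) {
    cat(sprintf("  %-12s %8.2f +/- %.2f\n", i, x$mean[[i]], x$sd[[i]]))
  }
  f <- x$fractions
  cat(sprintf("  boman > thr %.1f%%; aliphatic > thr %.1f%%; instability < thr %.1f%%\n",
              100 * f[["boman_high"]], 100 * f[["aliphatic_stable"]],
              100 * f[["instability_stable"]]))
  invisible(x)
}

#' Compare an index between labelled peptide pools
#'
#' Two groups are compared with Welch's unpaired two-sample t test; three or
#' more with a one-way ANOVA F test (exact p values, no multiplicity
#' correction).
#'
#' @param groups Named list: each element either a numeric vector of index
#'   values or a property table carrying `index` as a column.
#' @param index Property column name, when tables are supplied.
#' @return A `pool_comparison` list: `kind` (`"t"` or `"F"`), `statistic`,
#'   `df`, `p_value`, `groups` (sizes), `means`.
#' @export
compare_pools <- function(groups, index = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  values <- lapply(groups, function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    g <- as.data.frame(g)
    if (is.null(index) || !index %in% names(g)) {
      stop("compare_pools: 'index' must name a column of the supplied tables")
    }
    as.numeric(g[[index]])
  })
  sizes <- vapply(values, length, 0L)
  if (any(sizes < 2L)) {
    stop("compare_pools: every group needs at least 2 peptides (variance undefined)")
  }
  means <- vapply(values, mean, 0)
  if (length(values) == 2L) {
    tt <- stats::t.test(values[[1L]], values[[2L]])
    out <- list(kind = "t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value)
  } else {
    dat <- data.frame(
      value = unlist(values, use.names = FALSE),
      group = factor(rep(names(values), sizes)))
    fit <- stats::anova(stats::lm(value ~ group, data = dat))
    out <- list(kind = "F", statistic = fit$`F value`[1L],
                df = fit$Df, p_value = fit$`Pr(>F)`[1L])
  }
  structure(c(out, list(groups = sizes, means = means)),
            class = "pool_comparison")
}

#' @export
print.pool_comparison <- function(x, ...) {
  cat(sprintf("<pool_comparison> %s = %.3f, df = %s, p = %.3g\n", x$kind,
              x$statistic, paste(signif(x$df, 4), collapse = "/"), x$p_value))
  invisible(x)
}

#' Regress cleavage-site count on protein length
#'
#' Ordinary least squares of the per-record distinct site count `x` on the
#' sequence length `L`.
#'
#' @param records List of [protein_record()].
#' @param sitemaps List of matching [find_sites()] results.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
sites_vs_length_regression <- function(records, sitemaps) {
  stopifnot(length(records) == length(sitemaps), length(records) >= 3L)
  L <- vapply(records, `[[`, 0L, "length")
  x <- vapply(sitemaps, `[[`, 0L, "x")
  if (length(unique(L)) == 1L) {
    stop("sites_vs_length_regression: all lengths equal; fit is degenerate")
  }
  fit <- stats::lm(x ~ L)
  n <- length(L)
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((x - mean(x))^2)
  r2 <- 1 - sse / sst
  # F test of the slope computed directly so that a perfect fit (sse = 0)
  # degenerates cleanly to p = 0 instead of a summary() warning
  p <- if (sse == 0) 0 else stats::pf((sst - sse) / (sse / (n - 2)),
                                      1, n - 2, lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       p_value = p,
       n = n)
}

#' Flag aggregation-prone peptides
#'
#' The conjunction used for aggregation screening: thermodynamically stable
#' (instability < 40 and aliphatic > 70), low interaction potential
#' (Boman <= 2.48) and near-zero net charge in the tissue pH window,
#' i.e. pI inside `ph_window` (default the neuronal range 6.6-7.9).
#'
#' @param properties An [annotate_atlas()] table.
#' @param ph_window Numeric length-2 pH interval.
#' @param config A [property_config()] (thresholds).
#' @return The subset of rows satisfying all four conditions.
#' @export
flag_aggregation_prone <- function(properties, ph_window = c(6.6, 7.9),
                                   config = property_config()) {
  stopifnot(length(ph_window) == 2L, ph_window[1L] <= ph_window[2L])
  tab <- as.data.frame(properties)
  keep <- tab$instability < config$instability_stable &
    tab$aliphatic > config$aliphatic_stable &
    tab$boman < config$boman_high &
    tab$pI >= ph_window[1L] & tab$pI <= ph_window[2L]
  tab[keep, , drop = FALSE]
}

apr_env <- new.env(parent = emptyenv())

#' Pluggable aggregation-nucleation classifier
#'
#' No aggregation-region model is shipped; `set_apr_classifier()` registers
#' a user function mapping a character vector of sequences to a logical
#' vector, and `classify_apr()` delegates to it. Calling `classify_apr()`
#' without a registered classifier is an explicit error, never a silent
#' default.
#'
#' @param classifier Function `character -> logical`, or `NULL` to clear.
#' @param sequences Character vector of peptide sequences.
#' @return `classify_apr()`: logical vector, one element per sequence.
#' @export
set_apr_classifier <- function(classifier) {
  if (!is.null(classifier)) stopifnot(is.function(classifier))
  apr_env$classifier <- classifier
  invisible(classifier)
}

#' @rdname set_apr_classifier
#' @export
classify_apr <- function(sequences) {
  fn <- apr_env$classifier
  if (is.null(fn)) {
    stop("classify_apr: no classifier configured; register one with ",
         "set_apr_classifier()")
  }
  out <- fn(sequences)
  if (!is.logical(out) || length(out) != length(sequences)) {
    stop("classify_apr: classifier must return one logical per sequence")
  }
  out
}
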