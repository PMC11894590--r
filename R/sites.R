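#' Detect all cleavage sites of a protein
#'
#' Scans the record with every reagent of the rule set and reports, for each
#' inter-residue position, the set of reagents whose context pattern matches
#' there. Position `p` denotes cleavage of the bond following residue `p`
#' (1-based). Under the default `"compat"` terminal policy a P1-anchored
#' match at the last residue is admitted as well (see [load_rules()]).
#'
#' @param record A [protein_record()].
#' @param ruleset A [load_rules()] result.
#' @return A `site_map` object with fields `record_id`, `length`, `hits`
#'   (data.frame of `position`, `reagent`, one row per reagent-position
#'   match) and `x`, the number of distinct cleavage positions.
#' @export
find_sites <- function(record, ruleset) {
  stopifnot(inherits(record, "protein_record"),
            inherits(ruleset, "cleavage_ruleset"))
  codes <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  L <- record$length
  maxp <- if (ruleset$terminal == "compat") L else L - 1L
  positions <- integer(0)
  reagents <- character(0)
  for (nm in names(ruleset$rules)) {
    rule <- ruleset$rules[[nm]]
    ok <- rep(FALSE, maxp)
    for (pat in rule$cleave) {
      ok <- ok | match_pattern(codes, pat, maxp, L)
    }
    if (length(rule$exception) && any(ok)) {
      veto <- rep(FALSE, maxp)
      for (pat in rule$exception) {
        veto <- veto | match_pattern(codes, pat, maxp, L)
      }
      ok <- ok & !veto
    }
    hit <- which(ok)
    positions <- c(positions, hit)
    reagents <- c(reagents, rep(nm, length(hit)))
  }
  ord <- order(positions, reagents)
  hits <- data.frame(position = positions[ord], reagent = reagents[ord],
                     stringsAsFactors = FALSE)
  structure(
    list(record_id = record$id, length = L, hits = hits,
         x = length(unique(hits$position))),
    class = "site_map"
  )
}

# Evaluate one context pattern at every candidate position 1..maxp.
# A pattern is a list of (offset, required, set) constraints; slots outside
# the sequence satisfy forbidden constraints and fail required ones.
match_pattern <- function(codes, pat, maxp, L) {
  ok <- rep(TRUE, maxp)
  p <- seq_len(maxp)
  for (con in pat) {
    i <- p + con$offset
    inside <- i >= 1L & i <= L
    res <- rep(NA_character_, maxp)
    res[inside] <- codes[i[inside]]
    if (con$required) {
      ok <- ok & inside & res %in% con$set
    } else {
      ok <- ok & (!inside | !res %in% con$set)
    }
    if (!any(ok)) break
  }
  ok
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("<site_map> %s: x = %d cleavage positions, %d reagent hits\n",
              x$record_id, x$x, nrow(x$hits)))
  invisible(x)
}

#' Distinct cleavage positions of a site map
#' @param sitemap A [find_sites()] result.
#' @return Sorted integer vector of positions.
#' @export
site_positions <- function(sitemap) {
  stopifnot(inherits(sitemap, "site_map"))
  sort(unique(sitemap$hits$position))
}

#' Enzyme sets per position
#' @param sitemap A [find_sites()] result.
#' @return Named list mapping position to the character vector of reagents
#'   matching there.
#' @export
site_reagents <- function(sitemap) {
  stopifnot(inherits(sitemap, "site_map"))
  split(sitemap$hits$reagent, sitemap$hits$position)
}

#' Tabulate positions by enzyme multiplicity
#'
#' Counts distinct cleavage positions keyed by the number of reagents
#' matching there (the per-site enzyme multiplicity). Values sum to `x`.
#'
#' @param sitemap A [find_sites()] result.
#' @return Named integer vector, names = multiplicity.
#' @export
multiplicity_table <- function(sitemap) {
  stopifnot(inherits(sitemap, "site_map"))
  if (nrow(sitemap$hits) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  per_pos <- table(sitemap$hits$position)
  out <- table(as.integer(per_pos))
  stats::setNames(as.integer(out), names(out))
}

#' Positions cleaved by exactly one reagent
#'
#' @param sitemap A [find_sites()] result.
#' @param reagent Reagent name; must occur in the site map's rule set (any
#'   reagent name is accepted if it simply has no hits, but a name that never
#'   appears anywhere and is not part of the default table is likely a typo,
#'   so unknown names raise an error when a ruleset is supplied).
#' @param ruleset Optional [load_rules()] result used to validate `reagent`.
#' @return Integer vector of positions whose enzyme set is exactly
#'   `{reagent}`.
#' @export
exclusive_sites <- function(sitemap, reagent, ruleset = NULL) {
  stopifnot(inherits(sitemap, "site_map"))
  if (!is.null(ruleset) && !reagent %in% reagent_names(ruleset)) {
    stop("exclusive_sites: unknown reagent '", reagent, "'")
  }
  h <- sitemap$hits
  if (nrow(h) == 0L) return(integer(0))
  counts <- table(h$position)
  single <- names(counts)[counts == 1L]
  sort(as.integer(intersect(single, h$position[h$reagent == reagent])))
}
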