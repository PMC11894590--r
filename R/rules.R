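#' Load a cleavage-rule table
#'
#' A rule table is a TSV with columns `name`, `type` and the context slots
#' `P6 P5 P4 P3 P2 P1 P1p P2p` around the scissile bond (P1 is the residue
#' N-terminal to the bond; P1p the residue C-terminal to it). Each cell is
#' either `-` (unconstrained), a residue set such as `FWYL` (the slot must be
#' one of these), or a braced set such as `{PEDQKR}` (the slot must not be
#' one of these). A reagent may span several `cleave` rows — alternative
#' context patterns, any one of which suffices — and `exception` rows, any
#' one of which vetoes a match of the same reagent.
#'
#' `source = "default"` loads the packaged table transcribed from the ExPASy
#' PeptideCutter specificities for 37 reagents (the pepsin entry split into
#' its two pH variants), including the Keil-rule exception table for trypsin
#' and the caspase tetrapeptide motifs.
#'
#' @param source `"default"` or the path of a rule table.
#' @param terminal Terminal-site policy. `"compat"` (default) admits
#'   positions `1..L`: a pattern may match at the C-terminal residue when its
#'   C-side slots are unconstrained or forbidden-only (an unfilled slot
#'   satisfies a forbidden constraint and fails a required one). `"strict"`
#'   admits `1..L-1` only, so that every site corresponds to an existing
#'   peptide bond.
#' @return A `cleavage_ruleset` object.
#' @export
load_rules <- function(source = "default", terminal = c("compat", "strict")) {
  terminal <- match.arg(terminal)
  path <- if (identical(source, "default")) {
    system.file("extdata", "cleavage_rules.tsv", package = "degradome",
                mustWork = TRUE)
  } else {
    if (!file.exists(source)) stop("load_rules: no such file: ", source)
    source
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  slots <- c("P6", "P5", "P4", "P3", "P2", "P1", "P1p", "P2p")
  need <- c("name", "type", slots)
  if (!all(need %in% names(tab))) {
    stop("load_rules: table must have columns ", paste(need, collapse = ", "))
  }
  if (!all(tab$type %in% c("cleave", "exception"))) {
    stop("load_rules: 'type' must be 'cleave' or 'exception'")
  }
  if (anyDuplicated(tab)) {
    stop("load_rules: duplicated rule row for '",
         tab$name[duplicated(tab)][1L], "'")
  }
  offsets <- c(P6 = -5L, P5 = -4L, P4 = -3L, P3 = -2L, P2 = -1L, P1 = 0L,
               P1p = 1L, P2p = 2L)
  parse_row <- function(row) {
    pat <- list()
    for (slot in slots) {
      cell <- trimws(row[[slot]])
      if (cell == "-" || cell == "") next
      forb <- startsWith(cell, "{")
      set <- strsplit(if (forb) substr(cell, 2L, nchar(cell) - 1L) else cell,
                      "", fixed = TRUE)[[1L]]
      bad <- setdiff(set, AA_ALPHABET)
      if (length(bad)) {
        stop("load_rules: unknown residue code '", bad[1L], "' in rule '",
             row[["name"]], "' slot ", slot)
      }
      pat[[length(pat) + 1L]] <- list(offset = offsets[[slot]],
                                      required = !forb, set = set)
    }
    pat
  }
  rules <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, , drop = FALSE]
    nm <- row$name
    if (is.null(rules[[nm]])) rules[[nm]] <- list(cleave = list(), exception = list())
    pat <- parse_row(row)
    if (row$type == "cleave") {
      if (trimws(row$P1) %in% c("-", "") && trimws(row$P1p) %in% c("-", "")) {
        stop("load_rules: rule '", nm, "' constrains neither P1 nor P1'")
      }
      rules[[nm]]$cleave <- c(rules[[nm]]$cleave, list(pat))
    } else {
      exc_off <- vapply(pat, `[[`, 0L, "offset")
      if (any(exc_off < -3L)) {
        stop("load_rules: exception for '", nm, "' uses slots beyond P4..P2'")
      }
      rules[[nm]]$exception <- c(rules[[nm]]$exception, list(pat))
    }
  }
  orphans <- names(rules)[vapply(rules, function(r) length(r$cleave) == 0L, TRUE)]
  if (length(orphans)) {
    stop("load_rules: reagent '", orphans[1L], "' has exceptions but no cleave pattern")
  }
  structure(list(rules = rules, terminal = terminal, source = source),
            class = "cleavage_ruleset")
}

#' @export
print.cleavage_ruleset <- function(x, ...) {
  cat(sprintf("<cleavage_ruleset> %d reagents (%s), terminal policy '%s'\n",
              length(x$rules),
              if (identical(x$source, "default")) "default table" else x$source,
              x$terminal))
  invisible(x)
}

#' Reagent names of a rule set
#' @param ruleset A [load_rules()] result.
#' @return Character vector of reagent names.
#' @export
reagent_names <- function(ruleset) {
  stopifnot(inherits(ruleset, "cleavage_ruleset"))
  names(ruleset$rules)
}

#' Remove one reagent from a rule set
#'
#' Used to model selective enzyme inhibition: the returned set is identical
#' except that the named reagent no longer contributes sites.
#'
#' @param ruleset A [load_rules()] result.
#' @param reagent Reagent name (must exist).
#' @return A `cleavage_ruleset` without that reagent.
#' @export
drop_reagent <- function(ruleset, reagent) {
  stopifnot(inherits(ruleset, "cleavage_ruleset"))
  if (!reagent %in% names(ruleset$rules)) {
    stop("drop_reagent: unknown reagent '", reagent, "'")
  }
  ruleset$rules[[reagent]] <- NULL
  ruleset
}
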