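# Independent oracles used across the suite. These deliberately share no
# code with the production scanner/enumerator: the site oracle inspects one
# position at a time with substr(), the fragment oracle is a double loop.

# Position-by-position matcher over a parsed rule set.
naive_find_sites <- function(record, ruleset) {
  seq <- record$sequence
  L <- nchar(seq)
  maxp <- if (ruleset$terminal == "compat") L else L - 1L
  res_at <- function(i) if (i >= 1L && i <= L) substr(seq, i, i) else NA_character_
  pattern_ok <- function(p, pat) {
    for (con in pat) {
      r <- res_at(p + con$offset)
      if (con$required) {
        if (is.na(r) || !(r %in% con$set)) return(FALSE)
      } else {
        if (!is.na(r) && r %in% con$set) return(FALSE)
      }
    }
    TRUE
  }
  hits <- list()
  for (nm in names(ruleset$rules)) {
    rule <- ruleset$rules[[nm]]
    for (p in seq_len(maxp)) {
      cleaves <- any(vapply(rule$cleave, function(pat) pattern_ok(p, pat), TRUE))
      if (cleaves && length(rule$exception)) {
        if (any(vapply(rule$exception, function(pat) pattern_ok(p, pat), TRUE))) {
          cleaves <- FALSE
        }
      }
      if (cleaves) hits[[length(hits) + 1L]] <- data.frame(position = p, reagent = nm)
    }
  }
  if (!length(hits)) {
    return(data.frame(position = integer(0), reagent = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$reagent), , drop = FALSE]
}

# Brute-force fragment enumeration: all boundary pairs by explicit loops.
brute_fragments <- function(sequence, sites) {
  L <- nchar(sequence)
  bounds <- sort(unique(c(0L, sites[sites > 0L & sites < L], L)))
  out <- character(0)
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_along(bounds)) {
    for (j in seq_along(bounds)) {
      if (j <= i) next
      s <- bounds[i] + 1L
      e <- bounds[j]
      if (s == 1L && e == L) next
      starts <- c(starts, s)
      ends <- c(ends, e)
      out <- c(out, substr(sequence, s, e))
    }
  }
  data.frame(start = starts, end = ends, sequence = out,
             stringsAsFactors = FALSE)
}

# Restrict a loaded rule set to a few reagents (tests only).
keep_reagents <- function(ruleset, names) {
  stopifnot(all(names %in% base::names(ruleset$rules)))
  ruleset$rules <- ruleset$rules[names]
  ruleset
}

# A single-rule table: cleave after K (LysC-like), written to a temp file.
single_rule_table <- function(name = "after K", p1 = "K", p1p = "-") {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("name\ttype\tP6\tP5\tP4\tP3\tP2\tP1\tP1p\tP2p",
               paste(name, "cleave", "-", "-", "-", "-", "-", p1, p1p, "-",
                     sep = "\t")), path)
  path
}

random_protein <- function(len, id = "toy") {
  protein_record(id, paste(sample(AA_ALPHABET_TEST, len, replace = TRUE),
                           collapse = ""))
}

AA_ALPHABET_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
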