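#' Construct a protein record
#'
#' A protein record is the basic sequence container of the package: an
#' identifier, an optional UniProt accession, and an amino-acid sequence over
#' the 20 canonical one-letter codes. Residue positions are 1-based
#' throughout the package.
#'
#' @param id Short label, e.g. `"NfL"`.
#' @param sequence Amino-acid sequence (character scalar; lower case is
#'   accepted and upper-cased).
#' @param accession UniProt accession or `""`.
#' @return An object of class `protein_record` with fields `id`, `accession`,
#'   `sequence` and `length`.
#' @export
protein_record <- function(id, sequence, accession = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("[ \t\r\n]", "", sequence))
  if (!nzchar(sequence)) {
    stop("protein_record: sequence of '", id, "' is empty")
  }
  check_alphabet(sequence, id)
  structure(
    list(id = id, accession = accession, sequence = sequence,
         length = nchar(sequence)),
    class = "protein_record"
  )
}

check_alphabet <- function(sequence, id) {
  codes <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!codes %in% AA_ALPHABET)
  if (length(bad)) {
    stop("non-canonical residue '", codes[bad[1L]], "' in record '", id,
         "' at position ", bad[1L])
  }
  invisible(TRUE)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s%s  L = %d\n", x$id,
              if (nzchar(x$accession)) paste0(" (", x$accession, ")") else "",
              x$length))
  invisible(x)
}

#' Read protein records from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and validates every record against
#' the canonical 20-letter alphabet. The first whitespace-delimited word of
#' each header is the record id; a second word, if present, is kept as the
#' accession.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects, in file order.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("load_fasta: no such file: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("load_fasta: cannot parse '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) return(list())
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    words <- strsplit(trimws(headers[i]), "[ \t]+")[[1L]]
    protein_record(
      id = words[1L],
      sequence = as.character(set[[i]]),
      accession = if (length(words) >= 2L) words[2L] else ""
    )
  })
}

#' Write protein records to a FASTA file
#'
#' @param records A list of [protein_record()] objects.
#' @param path Output path.
#' @param width Sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$accession)) paste(r$id, r$accession) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' The built-in neurofilament isoform panel
#'
#' Returns the five human neurofilament intermediate-filament subunits
#' packaged with the library: NfH (P12036), NfM (P07197), NfL (P07196),
#' alpha-internexin INA (Q16352) and peripherin PRP (P41219), with their
#' canonical UniProt sequences (lengths 1026, 916, 543, 499 and 470).
#'
#' @return A list of five [protein_record()] objects.
#' @export
builtin_isoforms <- function() {
  path <- system.file("extdata", "nf_isoforms.fasta", package = "degradome",
                      mustWork = TRUE)
  load_fasta(path)
}

#' Parse a mutation specification string
#'
#' Grammar:
#' \itemize{
#'   \item `"G336S"` — substitution: reference residue, 1-based position,
#'     replacement residue;
#'   \item `"del@88"` / `"del@88-90"` — deletion of one residue or an
#'     inclusive range;
#'   \item `"ins@88:AAA"` — insertion of residues after position 88.
#' }
#'
#' @param spec Specification string.
#' @return A `mutation_spec` object with fields `kind`
#'   (`"substitution"`, `"deletion"` or `"insertion"`), `position`, `ref`,
#'   `alt` and `label`.
#' @export
parse_mutation <- function(spec) {
  if (inherits(spec, "mutation_spec")) return(spec)
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- trimws(spec)
  out <- NULL
  if (grepl("^[A-Y]\\d+[A-Y]$", spec)) {
    n <- nchar(spec)
    out <- list(kind = "substitution",
                position = as.integer(substr(spec, 2L, n - 1L)),
                ref = substr(spec, 1L, 1L), alt = substr(spec, n, n))
  } else if (grepl("^del@\\d+(-\\d+)?$", spec)) {
    rng <- strsplit(sub("^del@", "", spec), "-", fixed = TRUE)[[1L]]
    from <- as.integer(rng[1L])
    to <- if (length(rng) == 2L) as.integer(rng[2L]) else from
    if (to < from) stop("parse_mutation: empty deletion range in '", spec, "'")
    out <- list(kind = "deletion", position = from, ref = strrep("?", to - from + 1L),
                alt = "")
  } else if (grepl("^ins@\\d+:[A-Za-z]+$", spec)) {
    body <- sub("^ins@", "", spec)
    pos <- as.integer(sub(":.*$", "", body))
    alt <- toupper(sub("^[0-9]+:", "", body))
    out <- list(kind = "insertion", position = pos, ref = "", alt = alt)
  } else {
    stop("parse_mutation: cannot parse '", spec, "'; expected forms are ",
         "'G336S', 'del@88', 'del@88-90' or 'ins@88:AAA'")
  }
  out$label <- spec
  for (r in strsplit(paste0(out$ref, out$alt), "")[[1L]]) {
    if (r != "?" && !r %in% AA_ALPHABET) {
      stop("parse_mutation: non-canonical residue '", r, "' in '", spec, "'")
    }
  }
  structure(out, class = "mutation_spec")
}

#' Apply a mutation to a protein record
#'
#' Substitutions and deletions verify the reference residue(s) at the stated
#' position and refuse to proceed on a mismatch. Insertions insert after the
#' stated position (`ins@0:...` prepends). The input record is not modified;
#' the returned record's id is suffixed with the mutation label.
#'
#' @param record A [protein_record()].
#' @param spec A mutation string or [parse_mutation()] result.
#' @return A new [protein_record()].
#' @export
apply_mutation <- function(record, spec) {
  stopifnot(inherits(record, "protein_record"))
  spec <- parse_mutation(spec)
  s <- record$sequence
  L <- record$length
  p <- spec$position
  if (spec$kind %in% c("substitution", "deletion")) {
    if (p < 1L || p > L) {
      stop("apply_mutation: position ", p, " outside [1, ", L, "] of '",
           record$id, "'")
    }
  }
  new_seq <- switch(spec$kind,
    substitution = {
      have <- substr(s, p, p)
      if (have != spec$ref) {
        stop("apply_mutation: reference mismatch in '", record$id, "' at ",
             p, ": expected '", spec$ref, "', observed '", have, "'")
      }
      paste0(substr(s, 1L, p - 1L), spec$alt, substr(s, p + 1L, L))
    },
    deletion = {
      to <- p + nchar(spec$ref) - 1L
      if (to > L) stop("apply_mutation: deletion range ", p, "-", to,
                       " outside '", record$id, "' (L = ", L, ")")
      paste0(substr(s, 1L, p - 1L), substr(s, to + 1L, L))
    },
    insertion = {
      if (p < 0L || p > L) stop("apply_mutation: insertion point ", p,
                                " outside [0, ", L, "]")
      paste0(substr(s, 1L, p), spec$alt, substr(s, p + 1L, L))
    }
  )
  protein_record(paste0(record$id, "_", spec$label), new_seq, record$accession)
}
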