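#' Load a reference-peptide list
#'
#' A reference peptide is a previously reported cleavage product given by a
#' label, an isoform, coordinates and/or a sequence (at least one of
#' coordinates or sequence must be present). `source = "builtin"` loads the
#' packaged list of 16 literature-reported neurofilament cleavage products;
#' note that its first entry carries both coordinates and a published
#' sequence that disagree in span — such conflicts are surfaced by
#' [match_sequences()], never reconciled silently.
#'
#' @param source `"builtin"` or a TSV path with columns
#'   `label, isoform, start, end, sequence` (blanks allowed).
#' @return data.frame of reference peptides.
#' @export
reference_peptides <- function(source = "builtin") {
  path <- if (identical(source, "builtin")) {
    system.file("extdata", "nf_reference_peptides.tsv", package = "degradome",
                mustWork = TRUE)
  } else source
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                           fill = TRUE)
  for (col in c("start", "end")) tab[[col]] <- as.integer(tab[[col]])
  if (!"sequence" %in% names(tab)) tab$sequence <- NA_character_
  no_coord <- is.na(tab$start) | is.na(tab$end)
  no_seq <- is.na(tab$sequence) | !nzchar(tab$sequence)
  if (any(no_coord & no_seq)) {
    stop("reference_peptides: row ", which(no_coord & no_seq)[1L],
         " has neither coordinates nor a sequence")
  }
  tab
}

#' Look up a fragment by coordinates
#'
#' Returns the fragment at `(start, end)` iff that span is a
#' boundary-delimited member of the isoform's degradome (the intact protein
#' is never a member).
#'
#' @param atlas A [build_atlas()] result.
#' @param isoform Isoform id.
#' @param start,end 1-based inclusive residue coordinates.
#' @return A one-row data.frame (`isoform`, `start`, `end`, `sequence`,
#'   `fragment_id`) or `NULL` when the span is not a fragment.
#' @export
fragment_at <- function(atlas, isoform, start, end) {
  stopifnot(inherits(atlas, "degradome_atlas"))
  rec <- atlas$records[[isoform]]
  if (is.null(rec)) stop("fragment_at: unknown isoform '", isoform, "'")
  if (start < 1L || end > rec$length || start > end) {
    stop("fragment_at: coordinates (", start, ", ", end,
         ") outside [1, ", rec$length, "]")
  }
  fr <- atlas$fragments
  hit <- fr$isoform == isoform & fr$start == start & fr$end == end
  if (!any(hit)) return(NULL)
  data.frame(isoform = isoform, start = start, end = end,
             sequence = substring(rec$sequence, start, end),
             fragment_id = paste0(isoform, ":", start, "-", end),
             stringsAsFactors = FALSE)
}

#' Match reference peptides against the atlas
#'
#' For each reference with a sequence, reports exact-sequence membership in
#' the atlas together with every isoform/coordinate occurrence; for
#' coordinate-only references, delegates to [fragment_at()]. References
#' carrying both are checked both ways and reported as `"conflict"` when the
#' two disagree (e.g. a published sequence whose length does not equal its
#' published span).
#'
#' Published products are often reported with loose termini, so a sequence
#' that is not an exact boundary-delimited fragment is additionally tested
#' for identity-level containment: does it occur verbatim inside a panel
#' protein (and therefore inside larger atlas fragments)? This is reported
#' in `contained_in` and never upgrades an exact miss to `"hit"`.
#'
#' @param atlas A [build_atlas()] result.
#' @param references A [reference_peptides()] data.frame.
#' @return data.frame, one row per reference: `label`, `status` (`"hit"`,
#'   `"miss"` or `"conflict"`), `coordinate_hit`, `sequence_hit`,
#'   `isoforms` (panel members whose degradome contains the exact
#'   sequence), `contained_in` (panel members containing it as a
#'   substring), `note`.
#' @export
match_sequences <- function(atlas, references) {
  stopifnot(inherits(atlas, "degradome_atlas"))
  references <- as.data.frame(references)
  if (nrow(references) == 0L) stop("match_sequences: no references supplied")
  rows <- lapply(seq_len(nrow(references)), function(i) {
    ref <- references[i, ]
    has_coord <- !is.na(ref$start) && !is.na(ref$end) &&
      !is.null(ref$isoform) && !is.na(ref$isoform)
    has_seq <- !is.na(ref$sequence) && nzchar(ref$sequence)
    if (!has_coord && !has_seq) {
      stop("match_sequences: reference '", ref$label,
           "' has neither coordinates nor a sequence")
    }
    coord_hit <- NA
    note <- ""
    if (has_coord) {
      coord_hit <- !is.null(fragment_at(atlas, ref$isoform, ref$start, ref$end))
    }
    seq_hit <- NA
    isoforms <- ""
    contained_in <- ""
    if (has_seq) {
      s <- toupper(ref$sequence)
      m <- atlas$membership
      j <- match(s, m$sequence)
      seq_hit <- !is.na(j)
      if (seq_hit) isoforms <- m$isoforms[j]
      hosts <- names(atlas$records)[vapply(atlas$records, function(r) {
        grepl(s, r$sequence, fixed = TRUE)
      }, TRUE)]
      contained_in <- paste(hosts, collapse = ",")
    }
    status <- if (has_coord && has_seq) {
      span_len <- ref$end - ref$start + 1L
      if (nchar(ref$sequence) != span_len) {
        note <- sprintf("sequence length %d != coordinate span %d",
                        nchar(ref$sequence), span_len)
        "conflict"
      } else if (isTRUE(coord_hit) != isTRUE(seq_hit)) {
        note <- "coordinate and sequence lookups disagree"
        "conflict"
      } else if (isTRUE(coord_hit)) "hit" else "miss"
    } else if (isTRUE(coord_hit) || isTRUE(seq_hit)) "hit" else "miss"
    data.frame(label = ref$label, status = status,
               coordinate_hit = coord_hit, sequence_hit = seq_hit,
               isoforms = isoforms, contained_in = contained_in,
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parse an m/z tolerance
#'
#' Accepts a numeric value (Da), `"0.1%"` (relative), or `"500ppm"`.
#'
#' @param tolerance Tolerance specification.
#' @param mz Peak m/z values (needed to resolve relative tolerances).
#' @return Numeric vector of absolute tolerances in Da.
#' @export
mz_tolerance <- function(tolerance, mz) {
  if (is.numeric(tolerance)) {
    if (any(tolerance <= 0)) stop("mz_tolerance: tolerance must be positive")
    return(rep_len(tolerance, length(mz)))
  }
  tolerance <- trimws(tolerance)
  if (grepl("%$", tolerance)) {
    frac <- as.numeric(sub("%$", "", tolerance)) / 100
    if (is.na(frac) || frac <= 0) stop("mz_tolerance: bad tolerance '", tolerance, "'")
    return(mz * frac)
  }
  if (grepl("ppm$", tolerance, ignore.case = TRUE)) {
    ppm <- as.numeric(sub("ppm$", "", tolerance, ignore.case = TRUE))
    if (is.na(ppm) || ppm <= 0) stop("mz_tolerance: bad tolerance '", tolerance, "'")
    return(mz * ppm * 1e-6)
  }
  val <- suppressWarnings(as.numeric(tolerance))
  if (is.na(val) || val <= 0) stop("mz_tolerance: bad tolerance '", tolerance, "'")
  rep_len(val, length(mz))
}

#' Match observed m/z peaks against annotated peptides
#'
#' For each peak, returns every distinct peptide whose computed singly
#' protonated m/z lies within the tolerance, sorted by absolute mass error,
#' and flags candidates whose sequence is unique to one isoform of the
#' atlas.
#'
#' @param properties An [annotate_atlas()] table (must carry `mz`).
#' @param peaks data.frame with columns `mz` and (optionally) `intensity`.
#' @param tolerance See [mz_tolerance()]; default `"0.1%"`.
#' @param atlas Optional [build_atlas()] result supplying membership for the
#'   uniqueness flag.
#' @return data.frame with one row per (peak, candidate) pair: `peak_mz`,
#'   `intensity`, `isoform`, `sequence`, `mz`, `mass_error`, `unique_hit`;
#'   peaks without candidates yield no rows.
#' @export
match_mz <- function(properties, peaks, tolerance = "0.1%", atlas = NULL) {
  peaks <- as.data.frame(peaks)
  if (!"mz" %in% names(peaks) || nrow(peaks) == 0L) {
    stop("match_mz: peaks must be a non-empty table with an 'mz' column")
  }
  if (any(peaks$mz <= 0)) stop("match_mz: m/z values must be positive")
  if (!"intensity" %in% names(peaks)) peaks$intensity <- NA_real_
  tol <- mz_tolerance(tolerance, peaks$mz)
  props <- as.data.frame(properties)
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    err <- props$mz - peaks$mz[i]
    keep <- which(abs(err) <= tol[i])
    if (!length(keep)) return(NULL)
    keep <- keep[order(abs(err[keep]))]
    cand <- props[keep, intersect(c("isoform", "sequence", "mz"), names(props)),
                  drop = FALSE]
    cand$peak_mz <- peaks$mz[i]
    cand$intensity <- peaks$intensity[i]
    cand$mass_error <- err[keep]
    cand
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(isoform = character(0), sequence = character(0),
                      mz = numeric(0), peak_mz = numeric(0),
                      intensity = numeric(0), mass_error = numeric(0),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(atlas) && nrow(out) > 0L) {
    m <- atlas$membership
    j <- match(out$sequence, m$sequence)
    out$unique_hit <- !is.na(j) & m$n_iso[j] == 1L
  } else {
    out$unique_hit <- rep(NA, nrow(out))
  }
  rownames(out) <- NULL
  out
}
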