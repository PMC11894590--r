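#' Theoretical degradome size
#'
#' For a protein with `x` cleavage sites, the number of possible partial
#' cleavage products (every fragment delimited by two boundaries, all
#' missed-cleavage products included, the intact protein excluded) is
#' `Z = (x + 1)(x + 2)/2 - 1`.
#'
#' @param x Non-negative integer vector of site counts.
#' @return Numeric vector of `Z` values (exact integers).
#' @export
count_possible <- function(x) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    stop("count_possible: x must be a non-negative integer")
  }
  x <- as.numeric(x)
  (x + 1) * (x + 2) / 2 - 1
}

#' Enumerate every boundary-delimited fragment
#'
#' The boundary set is `{0}`, every in-sequence cleavage position (a site at
#' the last residue adds no boundary beyond `L`), and `L`. Every ordered
#' boundary pair `(b_i, b_j)`, `i < j`, yields the fragment spanning residues
#' `b_i + 1 .. b_j`, except the full-length pair `(0, L)`.
#'
#' @param record A [protein_record()].
#' @param sitemap The [find_sites()] result for that record.
#' @param with_sequence Attach the fragment sequences (default `TRUE`).
#' @return A data.frame with columns `isoform`, `start`, `end`,
#'   `fragment_id` and (optionally) `sequence`, ordered by `(start, end)`.
#' @export
enumerate_fragments <- function(record, sitemap, with_sequence = TRUE) {
  stopifnot(inherits(record, "protein_record"), inherits(sitemap, "site_map"))
  if (sitemap$record_id != record$id) {
    stop("enumerate_fragments: site map belongs to '", sitemap$record_id,
         "', not '", record$id, "'")
  }
  L <- record$length
  bounds <- sort(unique(c(0L, site_positions(sitemap), L)))
  bounds <- bounds[bounds >= 0L & bounds <= L]
  coords <- boundary_pairs(bounds, L)
  out <- data.frame(isoform = rep(record$id, nrow(coords)),
                    start = coords$start, end = coords$end,
                    fragment_id = if (nrow(coords)) {
                      paste0(record$id, ":", coords$start, "-", coords$end)
                    } else character(0),
                    stringsAsFactors = FALSE)
  if (with_sequence) {
    out$sequence <- if (nrow(out)) {
      substring(record$sequence, out$start, out$end)
    } else character(0)
  }
  out
}

# all (start, end) residue spans from a sorted boundary vector, excluding
# the intact (1, L) span
boundary_pairs <- function(bounds, L) {
  m <- length(bounds)
  if (m < 2L) return(data.frame(start = integer(0), end = integer(0)))
  n_after <- (m - 1L):1L
  i <- rep.int(seq_len(m - 1L), n_after)
  j <- sequence(n_after) + i
  start <- bounds[i] + 1L
  end <- bounds[j]
  keep <- !(start == 1L & end == L)
  data.frame(start = start[keep], end = end[keep])
}

#' Build a degradome atlas over a protein panel
#'
#' Runs site detection and fragment enumeration for every record, then
#' deduplicates: within an isoform, coordinate-level duplicates of the same
#' sequence collapse to one distinct entry (keeping the first coordinates
#' and a copy count); across isoforms, each distinct sequence is annotated
#' with the set of isoforms whose degradome contains it.
#'
#' @param records List of [protein_record()] (unique ids required).
#' @param ruleset A [load_rules()] result.
#' @param verbose Print per-isoform progress counts.
#' @return A `degradome_atlas` object with fields:
#'   \describe{
#'     \item{records}{named list of the input records}
#'     \item{sitemaps}{named list of `site_map`s}
#'     \item{fragments}{data.table of all coordinate-level fragments
#'       (`isoform`, `start`, `end`)}
#'     \item{index}{data.table of per-isoform distinct sequences
#'       (`isoform`, `sequence`, `start`, `end`, `copies`)}
#'     \item{membership}{data.table of globally distinct sequences
#'       (`sequence`, `n_iso`, `isoforms`)}
#'     \item{counts}{data.frame per isoform: `x` sites, theoretical `Z`,
#'       `enumerated` coordinate fragments, `distinct` sequences}
#'   }
#' @export
build_atlas <- function(records, ruleset, verbose = FALSE) {
  if (inherits(records, "protein_record")) records <- list(records)
  stopifnot(length(records) >= 1L, inherits(ruleset, "cleavage_ruleset"))
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("build_atlas: duplicate record id '", ids[duplicated(ids)][1L], "'")
  }
  names(records) <- ids
  sitemaps <- list()
  frag_list <- list()
  index_list <- list()
  counts <- data.frame(isoform = ids, L = NA_integer_, x = NA_integer_,
                       Z = NA_real_, enumerated = NA_real_,
                       distinct = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    sm <- find_sites(rec, ruleset)
    sitemaps[[rec$id]] <- sm
    fr <- enumerate_fragments(rec, sm, with_sequence = TRUE)
    dup <- duplicated(fr$sequence)
    idx <- data.table::data.table(
      isoform = rec$id,
      sequence = fr$sequence[!dup],
      start = fr$start[!dup],
      end = fr$end[!dup]
    )
    # copy counts; .N by sequence preserves first-appearance order = idx order
    cnt <- data.table::data.table(sequence = fr$sequence)[, list(N = .N),
                                                          by = "sequence"]
    idx$copies <- cnt$N
    counts$L[k] <- rec$length
    counts$x[k] <- sm$x
    counts$Z[k] <- count_possible(sm$x)
    counts$enumerated[k] <- nrow(fr)
    counts$distinct[k] <- nrow(idx)
    frag_list[[rec$id]] <- data.table::data.table(
      isoform = fr$isoform, start = fr$start, end = fr$end)
    index_list[[rec$id]] <- idx
    if (verbose) {
      message(sprintf("%s: x=%d, enumerated=%d, distinct=%d",
                      rec$id, sm$x, nrow(fr), nrow(idx)))
    }
  }
  fragments <- data.table::rbindlist(frag_list)
  index <- data.table::rbindlist(index_list)
  membership <- index[, list(n_iso = .N), by = "sequence"]
  # first-occurrence isoform covers the n_iso == 1 majority; collapse the rest
  memb_str <- index$isoform[match(membership$sequence, index$sequence)]
  multi <- membership$sequence[membership$n_iso > 1L]
  if (length(multi)) {
    sub <- index[index$sequence %in% multi, c("sequence", "isoform")]
    agg <- sub[, list(isoforms = paste(sort(.SD$isoform), collapse = ",")),
               by = "sequence"]
    memb_str[match(agg$sequence, membership$sequence)] <- agg$isoforms
  }
  membership$isoforms <- memb_str
  structure(
    list(records = records, sitemaps = sitemaps, fragments = fragments,
         index = index, membership = membership, counts = counts,
         terminal = ruleset$terminal),
    class = "degradome_atlas"
  )
}

#' @export
print.degradome_atlas <- function(x, ...) {
  cat(sprintf(
    "<degradome_atlas> %d isoform(s): %s\n  coordinate fragments: %s; distinct per isoform: %s; globally distinct: %s\n",
    length(x$records), paste(names(x$records), collapse = ", "),
    format(sum(x$counts$enumerated), big.mark = ","),
    format(sum(x$counts$distinct), big.mark = ","),
    format(nrow(x$membership), big.mark = ",")))
  invisible(x)
}

#' Per-isoform and total atlas counts
#'
#' @param atlas A [build_atlas()] result.
#' @return The atlas count table (per isoform: sequence length `L`, site
#'   count `x`, theoretical `Z`, enumerated coordinate fragments, distinct
#'   sequences) with a `Total` row appended; the total `distinct` is the
#'   sum of per-isoform distinct counts, while `attr(, "global_distinct")`
#'   carries the globally deduplicated sequence count.
#' @export
atlas_counts <- function(atlas) {
  stopifnot(inherits(atlas, "degradome_atlas"))
  tab <- atlas$counts
  total <- data.frame(isoform = "Total", L = sum(tab$L), x = sum(tab$x),
                      Z = sum(tab$Z), enumerated = sum(tab$enumerated),
                      distinct = sum(tab$distinct), stringsAsFactors = FALSE)
  out <- rbind(tab, total)
  attr(out, "global_distinct") <- nrow(atlas$membership)
  out
}

#' Sequences shared by every isoform of the atlas
#'
#' The pan set: distinct sequences whose membership equals the full isoform
#' panel, reported at or above a minimum length.
#'
#' @param atlas A [build_atlas()] result over at least two isoforms.
#' @param min_len Minimum reported length (default 5).
#' @return Character vector sorted by decreasing length, ties broken
#'   lexicographically.
#' @export
pan_sequences <- function(atlas, min_len = 5L) {
  stopifnot(inherits(atlas, "degradome_atlas"))
  if (length(atlas$records) < 2L) {
    stop("pan_sequences: atlas must cover at least two isoforms")
  }
  m <- atlas$membership
  seqs <- m$sequence[m$n_iso == length(atlas$records)]
  seqs <- seqs[nchar(seqs) >= min_len]
  seqs[order(-nchar(seqs), seqs)]
}

#' Sequences unique to one isoform
#'
#' @param atlas A [build_atlas()] result.
#' @param isoform_id Isoform id present in the atlas.
#' @return Character vector of distinct sequences found in that isoform's
#'   degradome and in no other isoform of the atlas.
#' @export
unique_sequences <- function(atlas, isoform_id) {
  stopifnot(inherits(atlas, "degradome_atlas"))
  if (!isoform_id %in% names(atlas$records)) {
    stop("unique_sequences: unknown isoform '", isoform_id, "'")
  }
  m <- atlas$membership
  m$sequence[m$n_iso == 1L & m$isoforms == isoform_id]
}

#' Export an atlas as FASTA and/or TSV
#'
#' The FASTA export writes one entry per coordinate-level fragment with
#' header `>{isoform}:{start}-{end}`; the TSV export writes one row per
#' distinct per-isoform sequence with its coordinates, copy count and
#' panel membership count (plus property columns when a property table is
#' supplied).
#'
#' @param atlas A [build_atlas()] result.
#' @param destination Output directory (created if missing).
#' @param format `"fasta"`, `"tsv"` or both.
#' @param properties Optional [annotate_atlas()] table to merge into the TSV.
#' @return Character vector of the files written, invisibly.
#' @export
export_atlas <- function(atlas, destination,
                         format = c("fasta", "tsv"), properties = NULL) {
  stopifnot(inherits(atlas, "degradome_atlas"))
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(destination)) {
    ok <- dir.create(destination, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("export_atlas: cannot create '", destination, "'")
  }
  written <- character(0)
  if ("fasta" %in% format) {
    path <- file.path(destination, "atlas.fasta")
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    for (id in names(atlas$records)) {
      fr <- atlas$fragments[atlas$fragments$isoform == id, ]
      seqs <- substring(atlas$records[[id]]$sequence, fr$start, fr$end)
      headers <- paste0(">", id, ":", fr$start, "-", fr$end)
      wrapped <- vapply(seqs, function(s) {
        paste(substring(s, seq(1L, nchar(s), 60L),
                        pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))),
              collapse = "\n")
      }, "", USE.NAMES = FALSE)
      writeLines(paste0(headers, "\n", wrapped), con)
    }
    written <- c(written, path)
  }
  if ("tsv" %in% format) {
    path <- file.path(destination, "atlas.tsv")
    tab <- as.data.frame(atlas$index)
    tab$membership_n <- atlas$membership$n_iso[
      match(tab$sequence, atlas$membership$sequence)]
    if (!is.null(properties)) {
      props <- as.data.frame(properties)
      keep <- setdiff(names(props), names(tab))
      tab <- cbind(tab, props[match(paste(tab$isoform, tab$start, tab$end),
                                    paste(props$isoform, props$start, props$end)),
                              keep, drop = FALSE])
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}
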