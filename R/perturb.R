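all_distinct_sequences <- function(atlas) unique(atlas$membership$sequence)

direction_call <- function(delta, p_value, alpha) {
  if (is.na(p_value) || p_value >= alpha) "unchanged"
  else if (delta > 0) "up"
  else "down"
}

profile_delta <- function(ref_props, pert_props, alpha,
                          indices = c("boman", "aliphatic", "instability",
                                      "gravy", "charge", "pI")) {
  rows <- lapply(indices, function(i) {
    cmp <- compare_pools(list(reference = ref_props[[i]],
                              perturbed = pert_props[[i]]))
    delta <- mean(pert_props[[i]]) - mean(ref_props[[i]])
    data.frame(index = i,
               mean_reference = mean(ref_props[[i]]),
               mean_perturbed = mean(pert_props[[i]]),
               delta = delta,
               statistic = cmp$statistic,
               p_value = cmp$p_value,
               direction = direction_call(delta, cmp$p_value, alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Differential degradome under a point mutation
#'
#' Builds the mutant record's degradome with the same rule set and compares
#' it against the complete wild-type reference atlas: `gained` are distinct
#' mutant sequences absent from the reference atlas as a whole (all
#' isoforms), `lost` are distinct wild-type sequences of the mutated isoform
#' found neither in the mutant pool nor in any other isoform of the
#' reference. Property profiles are compared mutant vs wild type for the
#' mutated isoform.
#'
#' @param record The wild-type [protein_record()] (must be in the atlas).
#' @param spec Mutation string or [parse_mutation()] result.
#' @param reference_atlas The wild-type [build_atlas()] result.
#' @param ruleset A [load_rules()] result.
#' @param config A [property_config()].
#' @param alpha Significance level for the direction calls (default 1e-4).
#' @return A `degradome_differential` list: `kind`, `label`, `gained`,
#'   `lost` (character vectors of distinct sequences), `profile`
#'   (per-index comparison table), `counts`.
#' @export
mutation_differential <- function(record, spec, reference_atlas, ruleset,
                                  config = property_config(), alpha = 1e-4) {
  stopifnot(inherits(record, "protein_record"),
            inherits(reference_atlas, "degradome_atlas"))
  if (!record$id %in% names(reference_atlas$records)) {
    stop("mutation_differential: '", record$id, "' is not in the reference atlas")
  }
  spec <- parse_mutation(spec)
  mutant <- apply_mutation(record, spec)
  mut_atlas <- build_atlas(list(mutant), ruleset)
  mut_seqs <- mut_atlas$index$sequence
  if (length(mut_seqs) == 0L) stop("mutation_differential: empty mutant pool")
  ref_all <- all_distinct_sequences(reference_atlas)
  wt_seqs <- reference_atlas$index$sequence[
    reference_atlas$index$isoform == record$id]
  gained <- setdiff(mut_seqs, ref_all)
  lost <- setdiff(setdiff(wt_seqs, mut_seqs),
                  reference_atlas$index$sequence[
                    reference_atlas$index$isoform != record$id])
  ref_props <- annotate_atlas(reference_atlas, config)
  ref_props <- ref_props[ref_props$isoform == record$id, ]
  mut_props <- annotate_atlas(mut_atlas, config)
  structure(list(
    kind = "mutation", label = paste0(record$id, ":", spec$label),
    gained = gained, lost = lost,
    profile = profile_delta(ref_props, mut_props, alpha),
    counts = c(mutant_distinct = length(mut_seqs),
               reference_distinct = length(ref_all),
               gained = length(gained), lost = length(lost))
  ), class = "degradome_differential")
}

#' Differential degradome under selective enzyme inhibition
#'
#' Rebuilds site maps and degradomes with one reagent removed. Positions
#' cleaved exclusively by that reagent disappear, so the perturbed fragment
#' set of every record is a subset of the reference set. Emits a per-isoform,
#' per-index direction matrix (up/down/unchanged at `alpha`).
#'
#' @param atlas The reference [build_atlas()] result (uninhibited).
#' @param ruleset The [load_rules()] result used to build `atlas`.
#' @param reagent Reagent to remove (must be in the rule set).
#' @param config A [property_config()].
#' @param alpha Significance level for direction calls (default 1e-4).
#' @return A `degradome_differential` list; `profile` has one row per
#'   (isoform, index), `direction` is an index x isoform character matrix,
#'   `lost` the distinct sequences absent after inhibition, `gained` empty
#'   by construction.
#' @export
inhibition_differential <- function(atlas, ruleset, reagent,
                                    config = property_config(), alpha = 1e-4) {
  stopifnot(inherits(atlas, "degradome_atlas"),
            inherits(ruleset, "cleavage_ruleset"))
  reduced <- drop_reagent(ruleset, reagent) # errors on unknown reagent
  pert_atlas <- build_atlas(unname(atlas$records), reduced)
  ref_props <- annotate_atlas(atlas, config)
  pert_props <- annotate_atlas(pert_atlas, config)
  indices <- c("boman", "aliphatic", "instability", "gravy", "charge", "pI")
  profiles <- list()
  for (id in names(atlas$records)) {
    rp <- ref_props[ref_props$isoform == id, ]
    pp <- pert_props[pert_props$isoform == id, ]
    prof <- profile_delta(rp, pp, alpha, indices)
    prof$isoform <- id
    profiles[[id]] <- prof
  }
  profile <- do.call(rbind, profiles)
  rownames(profile) <- NULL
  direction <- matrix(profile$direction, nrow = length(indices),
                      dimnames = list(indices, names(atlas$records)))
  lost <- setdiff(all_distinct_sequences(atlas),
                  all_distinct_sequences(pert_atlas))
  structure(list(
    kind = "inhibition", label = reagent,
    gained = character(0), lost = lost,
    profile = profile, direction = direction,
    counts = c(reference_distinct = length(all_distinct_sequences(atlas)),
               perturbed_distinct = length(all_distinct_sequences(pert_atlas)),
               lost = length(lost))
  ), class = "degradome_differential")
}

#' @export
print.degradome_differential <- function(x, ...) {
  cat(sprintf("<degradome_differential> %s '%s': gained %s, lost %s\n",
              x$kind, x$label,
              format(length(x$gained), big.mark = ","),
              format(length(x$lost), big.mark = ",")))
  invisible(x)
}

#' Run a batch of perturbations
#'
#' Applies a list of perturbations (mutation specs as `"isoform:spec"`
#' strings, or reagent names for inhibition) in order; an element that fails
#' is reported in the `error` column and processing continues.
#'
#' @param perturbations Character vector of perturbation labels.
#' @param kind `"mutation"` or `"inhibition"` (recycled to the length of
#'   `perturbations`).
#' @param atlas Reference [build_atlas()] result.
#' @param ruleset The [load_rules()] result used to build it.
#' @param config A [property_config()].
#' @param alpha Significance level for direction calls.
#' @return data.frame, one row per perturbation: `label`, `kind`, `gained`,
#'   `lost`, `error`; the full differential objects are attached as
#'   `attr(, "results")`.
#' @export
batch_perturbation_report <- function(perturbations, kind, atlas, ruleset,
                                      config = property_config(),
                                      alpha = 1e-4) {
  if (length(perturbations) == 0L) {
    out <- data.frame(label = character(0), kind = character(0),
                      gained = integer(0), lost = integer(0),
                      error = character(0), stringsAsFactors = FALSE)
    attr(out, "results") <- list()
    return(out)
  }
  kind <- rep_len(kind, length(perturbations))
  results <- vector("list", length(perturbations))
  rows <- vector("list", length(perturbations))
  for (i in seq_along(perturbations)) {
    lab <- perturbations[i]
    res <- tryCatch({
      if (kind[i] == "mutation") {
        parts <- strsplit(lab, ":", fixed = TRUE)[[1L]]
        if (length(parts) != 2L) {
          stop("mutation label must be 'isoform:spec', got '", lab, "'")
        }
        rec <- atlas$records[[parts[1L]]]
        if (is.null(rec)) stop("unknown isoform '", parts[1L], "'")
        mutation_differential(rec, parts[2L], atlas, ruleset, config, alpha)
      } else {
        inhibition_differential(atlas, ruleset, lab, config, alpha)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(label = lab, kind = kind[i], gained = NA_integer_,
                              lost = NA_integer_,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      results[[i]] <- res
      rows[[i]] <- data.frame(label = lab, kind = kind[i],
                              gained = length(res$gained),
                              lost = length(res$lost), error = "",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
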