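#' Pipeline run configuration
#'
#' @param fasta Input FASTA path or `"builtin"` (the packaged
#'   neurofilament panel).
#' @param rules Rule-table path or `"default"`.
#' @param terminal Terminal-site policy, see [load_rules()].
#' @param property A [property_config()].
#' @param out_dir Output directory.
#' @param export_fasta Also write the (possibly very large) coordinate-level
#'   FASTA export; default `FALSE`.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed only matters for toy-fixture generation).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = "builtin", rules = "default",
                       terminal = "compat", property = property_config(),
                       out_dir = "degradome_out", export_fasta = FALSE,
                       seed = 1L) {
  if (!identical(fasta, "builtin") && !file.exists(fasta)) {
    stop("run_config: no such FASTA: ", fasta)
  }
  if (!identical(rules, "default") && !file.exists(rules)) {
    stop("run_config: no such rule table: ", rules)
  }
  structure(list(fasta = fasta, rules = rules, terminal = terminal,
                 property = property, out_dir = out_dir,
                 export_fasta = export_fasta, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Site detection, atlas construction, property annotation and pool
#' summaries in one call. Writes `sites.tsv`, `atlas.tsv` (distinct
#' sequences with properties), `properties.tsv`, `summary.tsv` (pool
#' summary per isoform) and `manifest.json` (inputs, rule-table checksum,
#' per-isoform site counts `x`, theoretical `Z`, enumerated and distinct
#' counts) to the output directory. Identical configurations produce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `atlas`, `properties`, `summaries` and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  records <- stage("load", {
    if (identical(config$fasta, "builtin")) builtin_isoforms()
    else load_fasta(config$fasta)
  })
  ruleset <- stage("rules", load_rules(config$rules, terminal = config$terminal))
  atlas <- stage("atlas", build_atlas(records, ruleset))
  props <- stage("annotate", annotate_atlas(atlas, config$property))
  summaries <- stage("profile", {
    with_pool <- names(atlas$records)[vapply(names(atlas$records), function(id) {
      any(props$isoform == id)
    }, TRUE)]
    lapply(stats::setNames(nm = with_pool),
           function(id) summarize_pool(props, id, config$property))
  })
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage("export", {
    sites <- do.call(rbind, lapply(atlas$sitemaps, function(sm) {
      mult <- table(sm$hits$position)
      data.frame(isoform = rep(sm$record_id, length(mult)),
                 position = as.integer(names(mult)),
                 multiplicity = as.integer(mult),
                 reagents = if (length(mult)) {
                   vapply(split(sm$hits$reagent, sm$hits$position),
                          paste, "", collapse = ";")
                 } else character(0),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(sites, out("sites.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    export_atlas(atlas, config$out_dir,
                 format = if (config$export_fasta) c("fasta", "tsv") else "tsv",
                 properties = props)
    utils::write.table(as.data.frame(props), out("properties.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sum_tab <- do.call(rbind, lapply(names(summaries), function(id) {
      s <- summaries[[id]]
      data.frame(isoform = id, N = s$N,
                 index = names(s$mean), mean = unname(s$mean),
                 sd = unname(s$sd), stringsAsFactors = FALSE)
    }))
    utils::write.table(sum_tab, out("summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  rules_path <- if (identical(config$rules, "default")) {
    system.file("extdata", "cleavage_rules.tsv", package = "degradome")
  } else config$rules
  manifest <- list(
    inputs = list(fasta = config$fasta, rules = config$rules,
                  terminal = config$terminal,
                  rules_md5 = unname(tools::md5sum(rules_path)),
                  pH = config$property$pH, pka_set = config$property$pka_set,
                  mass = config$property$mass, seed = config$seed),
    counts = list(
      isoforms = atlas$counts$isoform,
      L = atlas$counts$L,
      x = atlas$counts$x,
      Z_theoretical = atlas$counts$Z,
      Z_sum = sum(atlas$counts$Z),
      enumerated = atlas$counts$enumerated,
      distinct = atlas$counts$distinct,
      global_distinct = nrow(atlas$membership)
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(atlas = atlas, properties = props, summaries = summaries,
                 manifest = manifest))
}

#' Deterministic toy fixtures for testing
#'
#' Generates small random proteins (lengths 8-60) with hand-checkable site
#' patterns: the set always contains one protein with no cleavage sites
#' under the default table's trypsin/CNBr subset and one with a
#' multiplicity-2 site (a KR motif hit by trypsin and the Arg-C/clostripain
#' pair at R). A companion table of brute-force fragments is returned so
#' tests can compare the production enumerator against an independent
#' double-loop oracle.
#'
#' @param seed Integer seed; fixed seed gives fixed fixtures.
#' @param n Number of random proteins in addition to the two constructed
#'   ones.
#' @return List with `records` (protein records) and `write(dir)` writing
#'   `toys.fasta` to a directory.
#' @export
make_toy_fixtures <- function(seed = 1L, n = 6L) {
  set.seed(seed)
  quiet <- c("G", "S", "Q") # inert under the default table (no N: Asn-Gly
                            # would draw hydroxylamine)
  records <- list(
    protein_record("toy_nosite", paste(sample(quiet, 12L, TRUE), collapse = "")),
    protein_record("toy_mult2", {
      # K-R motif: R preceded by K gives trypsin at K and trypsin+Arg-C+
      # clostripain at R; the GG margin keeps other rules out
      paste0(paste(sample(quiet, 6L, TRUE), collapse = ""), "KRGG",
             paste(sample(quiet, 6L, TRUE), collapse = ""))
    })
  )
  for (i in seq_len(n)) {
    len <- sample(8:60, 1L)
    records[[length(records) + 1L]] <- protein_record(
      paste0("toy_", i),
      paste(sample(AA_ALPHABET, len, TRUE), collapse = ""))
  }
  list(
    records = records,
    write = function(dir) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(records, file.path(dir, "toys.fasta"))
      file.path(dir, "toys.fasta")
    }
  )
}
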