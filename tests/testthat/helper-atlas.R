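# The full five-isoform atlas is expensive enough (~20 s with annotation)
# that the acceptance tests share one lazily built copy.
.atlas_cache <- new.env(parent = emptyenv())

full_nf_atlas <- function() {
  if (is.null(.atlas_cache$atlas)) {
    rs <- load_rules()
    .atlas_cache$ruleset <- rs
    .atlas_cache$atlas <- build_atlas(builtin_isoforms(), rs)
  }
  .atlas_cache$atlas
}

full_nf_ruleset <- function() {
  full_nf_atlas()
  .atlas_cache$ruleset
}

full_nf_properties <- function() {
  if (is.null(.atlas_cache$props)) {
    .atlas_cache$props <- annotate_atlas(full_nf_atlas())
  }
  .atlas_cache$props
}

published_site_positions <- function() {
  path <- system.file("extdata", "published_site_positions.tsv",
                      package = "degradome", mustWork = TRUE)
  utils::read.delim(path)
}
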