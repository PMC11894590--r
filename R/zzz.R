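#' @importFrom data.table data.table as.data.table rbindlist .N :=
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(".N", ".SD"))
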