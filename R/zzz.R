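# data.table NSE (:=, .SD) is used throughout; mark the namespace aware so
# cedta() routes [.data.table correctly when the package is imported.
.datatable.aware <- TRUE

#' @importFrom data.table data.table as.data.table is.data.table setkeyv
#'   setnames setcolorder setattr setorderv rbindlist fread fwrite CJ copy
#'   dcast
#' @importFrom stats lm coef var approx rlnorm setNames
#' @importFrom utils head packageVersion
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
NULL
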