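#' @useDynLib lsdkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table data.table rbindlist .N
#' @importFrom igraph graph_from_data_frame components max_flow V bfs
#' @importFrom jsonlite read_json write_json
#' @importFrom stats quantile setNames fft nextn
#' @importFrom utils read.csv write.csv read.table head
NULL

.datatable.aware <- TRUE
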